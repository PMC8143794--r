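# Behavioural analyses: per-subject log-RT and accuracy regressions on the six
# repetition-suppression regressors with group-level tests, the three-way
# training ANOVA, and psychometric curves.

#' Per-subject behavioural regressions with group tests
#'
#' For each subject: an ordinary linear regression of log RT on the six RS
#' regressors (correct trials with RT inside `rt_bounds`) and an unpenalized
#' maximum-likelihood logistic regression of correctness on the same
#' regressors (all responded trials). Group level: a one-sample t test with
#' Hedges' g per regressor on the subject coefficients. Logistic fits showing
#' separation are flagged and excluded from that measure's group test.
#'
#' @param trials Trial tibble with a `subject` column and filled outcomes.
#' @param design Optional RS design; recomputed from `trials` if `NULL`.
#' @param rt_bounds RT inclusion bounds in ms (default `c(150, 2000)`).
#' @param rt_correct_only Restrict the RT regression to correct trials
#'   (default `TRUE`).
#' @param min_trials Minimum responded trials per subject (default 50).
#' @return A list of class `behav_glm`: `coefficients` (subject x regressor
#'   tibble with `rt_beta`, `acc_beta`, `acc_converged`) and `group`
#'   (regressor x measure effect sizes).
#' @export
fit_behav_regressions <- function(trials, design = NULL,
                                  rt_bounds = c(150, 2000),
                                  rt_correct_only = TRUE, min_trials = 50) {
  stopifnot("subject" %in% names(trials))
  if (is.null(design)) design <- code_rs_regressors(trials)
  dat <- dplyr::bind_cols(trials, design[, rs_regressors()])
  coefs <- purrr::map_dfr(split(dat, dat$subject), function(d) {
    responded <- !is.na(d$ts_response)
    if (sum(responded) < min_trials) {
      stop(sprintf("subject %s has fewer than %d responded trials",
        d$subject[1], min_trials), call. = FALSE)
    }
    rt_keep <- responded & !is.na(d$ts_rt_ms) &
      d$ts_rt_ms >= rt_bounds[1] & d$ts_rt_ms <= rt_bounds[2]
    if (rt_correct_only) rt_keep <- rt_keep & d$ts_correct == 1
    fml <- stats::as.formula(paste(
      "y ~", paste(rs_regressors(), collapse = " + ")
    ))
    d$y <- log(d$ts_rt_ms)
    rt_fit <- stats::lm(fml, data = d[rt_keep, ])
    d$y <- d$ts_correct
    acc_fit <- suppressWarnings(
      stats::glm(fml, data = d[responded, ], family = stats::binomial())
    )
    converged <- acc_fit$converged && all(abs(stats::coef(acc_fit)[-1]) < 15)
    tibble::tibble(
      subject = d$subject[1],
      regressor = rs_regressors(),
      rt_beta = unname(stats::coef(rt_fit)[rs_regressors()]),
      acc_beta = unname(stats::coef(acc_fit)[rs_regressors()]),
      acc_converged = converged
    )
  })
  na_es <- tibble::tibble(
    t = NA_real_, df = NA_real_, p = NA_real_, p_corrected = NA_real_,
    hedges_g = NA_real_, ci_low = NA_real_, ci_high = NA_real_
  )
  group <- purrr::map_dfr(rs_regressors(), function(r) {
    sub <- coefs[coefs$regressor == r, ]
    rt_es <- if (nrow(sub) >= 3) {
      paired_t_hedges(sub$rt_beta, 0, n_boot = 2000)
    } else {
      na_es
    }
    acc_ok <- sub$acc_converged & is.finite(sub$acc_beta)
    acc_es <- if (sum(acc_ok) >= 3) {
      paired_t_hedges(sub$acc_beta[acc_ok], 0, n_boot = 2000)
    } else {
      na_es
    }
    dplyr::bind_rows(
      dplyr::mutate(rt_es, regressor = r, measure = "log_rt",
        mean_beta = mean(sub$rt_beta), .before = 1),
      dplyr::mutate(acc_es, regressor = r, measure = "accuracy",
        mean_beta = mean(sub$acc_beta[acc_ok]), .before = 1)
    )
  })
  structure(list(coefficients = coefs, group = group), class = "behav_glm")
}

#' @export
print.behav_glm <- function(x, ...) {
  cat(sprintf(
    "<behav_glm> %d subjects x %d regressors\n",
    length(unique(x$coefficients$subject)), length(rs_regressors())
  ))
  print(x$group[, c("regressor", "measure", "mean_beta", "t", "p", "hedges_g")])
  invisible(x)
}

#' Training ANOVA on behavioural cell means
#'
#' Three-way repeated-measures ANOVA with within-subject factors context
#' (colour/motion), training (pre/post) and coherence (three levels: the
#' 70% adaptation stimulus and the easy/hard test stimulus).
#'
#' @param cell_means Tibble with columns `subject`, `context`, `training`,
#'   `coherence`, and the value column named by `dv`.
#' @param dv Name of the value column (e.g. `"log_rt"` or `"pct_correct"`).
#' @return An `rm_anova` tibble.
#' @export
training_anova <- function(cell_means, dv) {
  rm_anova(cell_means, dv = dv, subject = "subject",
    within = c("context", "training", "coherence"))
}

#' Psychometric fit per context
#'
#' Logistic regression of the probability of choosing the positive pole
#' (rightward motion / red colour, the middle finger) on signed relevant and
#' irrelevant evidence, fitted separately per context. Perfect separation is
#' reported via a `saturated` flag rather than an error.
#'
#' @param trials Trial tibble with filled `ts_response`.
#' @param contexts Contexts to fit (default both).
#' @param curve_at Relevant-evidence grid for fitted-curve samples.
#' @return A list of class `psychometric_fit`: `parameters` (context x term
#'   tibble with estimates, SEs, `saturated`) and `curves` (fitted
#'   P(positive-pole choice) per relevant-evidence point and observed
#'   irrelevant level).
#' @export
fit_psychometric <- function(trials, contexts = c("colour", "motion"),
                             curve_at = seq(-2, 2, by = 0.1)) {
  s <- signed_strengths(trials)
  dat <- tibble::tibble(
    context = trials$ts_context,
    rel = s$rel_strength, irrel = s$irrel_strength,
    pos = as.integer(trials$ts_response == "middle")
  )
  dat <- dat[!is.na(dat$pos), ]
  params <- purrr::map_dfr(contexts, function(cx) {
    d <- dat[dat$context == cx, ]
    stopifnot(length(unique(sign(d$rel))) == 2, length(unique(abs(d$rel))) == 2)
    fit <- suppressWarnings(
      stats::glm(pos ~ rel + irrel, data = d, family = stats::binomial())
    )
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    tibble::tibble(
      context = cx,
      term = c("intercept", "slope_relevant", "slope_irrelevant"),
      estimate = unname(est), se = unname(se),
      saturated = !fit$converged || any(abs(est[-1]) > 15)
    )
  })
  curves <- purrr::map_dfr(contexts, function(cx) {
    p <- params[params$context == cx, ]
    est <- stats::setNames(p$estimate, p$term)
    purrr::map_dfr(sort(unique(dat$irrel[dat$context == cx])), function(iv) {
      tibble::tibble(
        context = cx, irrel_level = iv, rel_strength = curve_at,
        p_positive = stats::plogis(
          est["intercept"] + est["slope_relevant"] * curve_at +
            est["slope_irrelevant"] * iv
        )
      )
    })
  })
  structure(list(parameters = params, curves = curves),
    class = "psychometric_fit")
}

#' Behavioural cell means for the training ANOVA
#'
#' Summarises trials into per-subject cell means of log RT and percent correct
#' over context x training x coherence, treating the adaptation-stimulus
#' response as the 70% coherence level.
#'
#' @param trials Trial tibble with `subject`, a `training` column
#'   (`"pre"`/`"post"`), filled outcomes, and (for the AS level) columns
#'   `as_rt_ms`/`as_correct` if available; otherwise only the two TS coherence
#'   levels are summarised.
#' @return A tibble `subject`, `context`, `training`, `coherence`, `log_rt`,
#'   `pct_correct`.
#' @export
behav_cell_means <- function(trials) {
  stopifnot(all(c("subject", "training") %in% names(trials)))
  ts <- trials |>
    dplyr::filter(!is.na(.data$ts_rt_ms), !is.na(.data$ts_correct)) |>
    dplyr::group_by(
      subject = .data$subject, context = .data$ts_context,
      training = .data$training,
      coherence = format(.data$ts_coherence_pct, trim = TRUE)
    ) |>
    dplyr::summarise(
      log_rt = mean(log(.data$ts_rt_ms)),
      pct_correct = 100 * mean(.data$ts_correct),
      .groups = "drop"
    )
  if (all(c("as_rt_ms", "as_correct") %in% names(trials))) {
    as_lvl <- trials |>
      dplyr::filter(!is.na(.data$as_rt_ms), !is.na(.data$as_correct)) |>
      dplyr::group_by(
        subject = .data$subject, context = .data$ts_context,
        training = .data$training
      ) |>
      dplyr::summarise(
        coherence = "70",
        log_rt = mean(log(.data$as_rt_ms)),
        pct_correct = 100 * mean(.data$as_correct),
        .groups = "drop"
      )
    ts <- dplyr::bind_rows(ts, as_lvl)
  }
  ts
}
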