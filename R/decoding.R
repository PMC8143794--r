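# Residualized, nested cross-validated decoding of signed input strength from
# multi-parcel epochs. Choice direction is regressed out of every parcel
# before decoding because relevant evidence and choice are strongly correlated
# by design; decoders are trained per context for the relevant and the
# irrelevant dimension and compared over time.

#' Decoding configuration
#'
#' @param outer_folds Outer cross-validation folds (default 10).
#' @param inner_folds Inner folds tuning the ridge penalty (default 3).
#' @param lambda_grid Penalty grid (default `10^c(-5,-3,-1,1,3,5)`).
#' @param half_width_ms Sliding-window half width (default 75 ms).
#' @param step_ms Window step (default 63.3 ms).
#' @param stat_window Statistical window bounds in ms (default
#'   `c(-190, 1036.7)`).
#' @param residualize Regress choice direction out of each parcel before
#'   decoding (default `TRUE`).
#' @param leakage_free Fit the residualization inside training folds only
#'   (default `FALSE`: fitted once on all correct trials, mirroring the
#'   sequential procedure; the leakage-free variant serves calibration tests).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `decode_config`.
#' @export
decode_config <- function(outer_folds = 10, inner_folds = 3,
                          lambda_grid = 10^c(-5, -3, -1, 1, 3, 5),
                          half_width_ms = 75, step_ms = 190 / 3,
                          stat_window = c(-190, 3110 / 3),
                          residualize = TRUE, leakage_free = FALSE, seed = 1) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, all(lambda_grid >= 0))
  structure(
    list(
      outer_folds = outer_folds, inner_folds = inner_folds,
      lambda_grid = sort(lambda_grid), half_width_ms = half_width_ms,
      step_ms = step_ms, stat_window = stat_window,
      residualize = residualize, leakage_free = leakage_free, seed = seed
    ),
    class = "decode_config"
  )
}

#' Regress choice direction out of windowed parcel signals
#'
#' Ordinary regression of each parcel's signal on the choice indicator plus an
#' intercept; the returned residuals are exactly uncorrelated with choice.
#'
#' @param parcel_windows Trials x parcels numeric matrix.
#' @param choice 0/1 vector (both classes must be present).
#' @return Residual matrix of the same shape.
#' @export
residualize_choice <- function(parcel_windows, choice) {
  W <- as.matrix(parcel_windows)
  stopifnot(nrow(W) == length(choice))
  if (length(unique(choice)) < 2) {
    stop("choice has a single class; residualization undefined", call. = FALSE)
  }
  M <- cbind(1, choice)
  W - M %*% solve(crossprod(M), crossprod(M, W))
}

# One window's nested-CV decode: returns pooled held-out predictions and the
# outer-fold assignment.
nested_cv_predict <- function(W, target, config) {
  n <- nrow(W)
  fold <- sample(rep_len(seq_len(config$outer_folds), n))
  pred <- numeric(n)
  for (k in seq_len(config$outer_folds)) {
    te <- fold == k
    Wtr <- W[!te, , drop = FALSE]
    ytr <- target[!te]
    if (stats::var(ytr) == 0) {
      stop("outer fold with zero target variance", call. = FALSE)
    }
    if (config$leakage_free && config$residualize) {
      ch <- attr(W, "choice")
      Wtr <- residualize_choice(Wtr, ch[!te])
    }
    lam <- tune_lambda_cv(Wtr, ytr, config$lambda_grid, config$inner_folds)
    fit <- fit_ridge(Wtr, ytr, lam)
    pred[te] <- fit$intercept +
      drop(W[te, , drop = FALSE] %*% fit$coefficients)
  }
  list(pred = pred, fold = fold)
}

# Pooled correlation score with predictions and targets centred within outer
# folds. Raw pooled correlations are biased negative under the null because
# ridge predictions shrink towards each training fold's mean, which
# anti-correlates with the held-out fold; fold-centring removes that bias.
fold_centered_cor <- function(pred, target, fold) {
  pc <- pred - stats::ave(pred, fold)
  tc <- target - stats::ave(target, fold)
  if (stats::sd(pc) == 0 || stats::sd(tc) == 0) {
    return(0)
  }
  stats::cor(pc, tc)
}

#' Nested cross-validated decoding over sliding windows
#'
#' Per window: average parcel samples in the window, residualize choice
#' direction (unless disabled), split trials into seeded outer folds, choose
#' the ridge penalty by inner cross-validation on each training set, refit,
#' and pool the held-out predictions. The score is the Pearson correlation
#' between pooled predictions and true targets, both centred within outer
#' folds so that the score is unbiased at chance (with R² as a secondary
#' measure); the decoding metric is a package choice.
#'
#' @param epochs A 3-D `source_epochs` (trials x parcels x samples).
#' @param target Numeric targets in `{-2, -1, 1, 2}` (signed input strength).
#' @param choice 0/1 choice-direction vector used for residualization.
#' @param grid Optional [build_window_grid()]; defaults to the config's step
#'   and half-width over the epoch.
#' @param config A [decode_config()].
#' @return A tibble of class `decoding_series`: `window_center_ms`, `score`,
#'   `r_squared`, `n`.
#' @export
nested_cv_decode <- function(epochs, target, choice = NULL, grid = NULL,
                             config = decode_config()) {
  stopifnot(length(dim(epochs$data)) == 3)
  n <- dim(epochs$data)[1]
  stopifnot(length(target) == n)
  if (config$residualize && is.null(choice)) {
    stop("choice vector required for residualization", call. = FALSE)
  }
  if (n < config$outer_folds * 2) {
    stop("too few trials for the outer folds", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- build_window_grid(
      min(epochs$time_ms) + config$half_width_ms,
      max(epochs$time_ms) - config$half_width_ms,
      step_ms = config$step_ms, half_width_ms = config$half_width_ms
    )
  }
  A <- window_average(epochs, grid) # trials x parcels x windows
  out <- withr::with_seed(config$seed, {
    purrr::map_dfr(seq_along(grid$centers_ms), function(w) {
      W <- A[, , w, drop = TRUE]
      W <- matrix(W, nrow = n)
      if (config$residualize && !config$leakage_free) {
        W <- residualize_choice(W, choice)
      }
      if (config$leakage_free) attr(W, "choice") <- choice
      cv <- nested_cv_predict(W, target, config)
      ss_res <- sum((target - cv$pred)^2)
      ss_tot <- sum((target - mean(target))^2)
      tibble::tibble(
        window_center_ms = grid$centers_ms[w],
        score = fold_centered_cor(cv$pred, target, cv$fold),
        r_squared = 1 - ss_res / ss_tot,
        n = n
      )
    })
  })
  class(out) <- c("decoding_series", class(out))
  out
}

#' Decode relevant and irrelevant input strength per context
#'
#' Builds the encoding regressors from the trial table, restricts to correct
#' trials, and runs [nested_cv_decode()] separately per context for the
#' relevant and the irrelevant dimension; scores are also averaged across
#' contexts for group summaries.
#'
#' @param epochs 3-D `source_epochs` aligned with `trials`.
#' @param trials Trial tibble with filled outcomes.
#' @param grid Optional window grid (shared across contexts).
#' @param config A [decode_config()].
#' @return A list: `by_context` (tibble `context`, `target`, window, score)
#'   and `averaged` (tibble `target`, window, mean score across contexts).
#' @export
decode_relevant_irrelevant <- function(epochs, trials, grid = NULL,
                                       config = decode_config()) {
  enc <- code_encoding_regressors(trials)
  keep <- !is.na(trials$ts_correct) & trials$ts_correct == 1
  by_context <- purrr::map_dfr(c("colour", "motion"), function(cx) {
    sel <- keep & trials$ts_context == cx
    sub <- epochs
    sub$data <- epochs$data[sel, , , drop = FALSE]
    purrr::map_dfr(c("relevant", "irrelevant"), function(tg) {
      y <- if (tg == "relevant") enc$rel_strength[sel] else enc$irrel_strength[sel]
      res <- nested_cv_decode(sub, y, choice = enc$choice[sel],
        grid = grid, config = config)
      dplyr::mutate(res, context = cx, target = tg, .before = 1)
    })
  })
  averaged <- by_context |>
    dplyr::group_by(.data$target, .data$window_center_ms) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  list(by_context = by_context, averaged = averaged)
}

#' Compare relevant vs irrelevant decoding across subjects
#'
#' Per window centre inside the statistical window: a paired t test of
#' relevant vs irrelevant scores across subjects, Bonferroni-corrected over
#' the number of window centres tested. When a `training` column is present, a
#' two-way repeated-measures ANOVA (input x training) on window-averaged
#' scores is returned as well.
#'
#' @param series Tibble with columns `subject`, `target`
#'   (`"relevant"`/`"irrelevant"`), `window_center_ms`, `score`, and
#'   optionally `training`.
#' @param stat_window Length-2 numeric bounds in ms (default the decoding
#'   statistical window).
#' @param familywise Familywise alpha (default 0.05).
#' @return A list: `per_window` tibble (`window_center_ms`, `t`, `p`,
#'   `p_bonferroni`, `significant`) and `anova` (an `rm_anova` tibble or
#'   `NULL`).
#' @export
compare_relevant_irrelevant <- function(series, stat_window = c(-190, 3110 / 3),
                                        familywise = 0.05) {
  stopifnot(all(c("subject", "target", "window_center_ms", "score") %in% names(series)))
  wide <- tidyr::pivot_wider(
    series,
    id_cols = dplyr::any_of(c("subject", "window_center_ms", "training")),
    names_from = "target", values_from = "score",
    values_fn = mean
  )
  if (any(is.na(wide$relevant)) || any(is.na(wide$irrelevant))) {
    stop("both targets must be decoded for all subjects and windows", call. = FALSE)
  }
  centers <- sort(unique(wide$window_center_ms))
  centers <- centers[centers >= stat_window[1] - 1e-9 & centers <= stat_window[2] + 1e-9]
  m <- length(centers)
  alpha <- bonferroni_alpha(m, familywise)
  per_window <- purrr::map_dfr(centers, function(cc) {
    d <- wide[abs(wide$window_center_ms - cc) < 1e-9, ]
    # average over training sessions within subject if present
    d <- d |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(
        relevant = mean(.data$relevant), irrelevant = mean(.data$irrelevant)
      )
    tt <- stats::t.test(d$relevant, d$irrelevant, paired = TRUE)
    tibble::tibble(
      window_center_ms = cc, t = unname(tt$statistic), p = tt$p.value,
      p_bonferroni = min(1, tt$p.value * m), significant = tt$p.value < alpha
    )
  })
  anova <- NULL
  if ("training" %in% names(wide)) {
    long <- wide |>
      tidyr::pivot_longer(c("relevant", "irrelevant"),
        names_to = "input", values_to = "score"
      ) |>
      dplyr::group_by(.data$subject, .data$input, .data$training) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
    anova <- rm_anova(long, dv = "score", subject = "subject",
      within = c("input", "training"))
  }
  list(per_window = per_window, anova = anova)
}
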