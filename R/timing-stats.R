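# Peak-latency estimation and group statistics on coefficient series.

#' Leave-one-subject-out peak latencies
#'
#' For each subject, the group peak is the argmax of the mean series of all
#' *other* subjects; the subject's own peak is then the argmax of their series
#' within `peak +/- half_width_ms`. Constraining the search this way keeps
#' single-subject peaks from wandering onto noise excursions. Ties break to
#' the earliest time.
#'
#' @param series A long tibble with columns `subject`, `window_center_ms`,
#'   `regressor`, `coef` (e.g. per-subject [fit_subsampled_glm()] outputs bound
#'   together).
#' @param regressor Regressor whose peak is sought.
#' @param half_width_ms Half-width of the search window around the group peak
#'   (default 66.7 ms; a widened variant uses 133.6).
#' @return A tibble of class `peak_estimates`: `subject`, `regressor`,
#'   `peak_time_ms`, `peak_value`, `search_lo_ms`, `search_hi_ms`.
#' @export
loo_peak_times <- function(series, regressor, half_width_ms = 200 / 3) {
  stopifnot(all(c("subject", "window_center_ms", "regressor", "coef") %in% names(series)))
  s <- dplyr::filter(series, .data$regressor == !!regressor)
  subjects <- unique(s$subject)
  if (length(subjects) < 3) stop("need at least 3 subjects", call. = FALSE)
  centers <- sort(unique(s$window_center_ms))
  wide <- tidyr::pivot_wider(
    s[, c("subject", "window_center_ms", "coef")],
    names_from = "subject", values_from = "coef"
  )
  wide <- wide[order(wide$window_center_ms), ]
  M <- as.matrix(wide[, subjects])
  purrr::map_dfr(seq_along(subjects), function(i) {
    others <- rowMeans(M[, -i, drop = FALSE])
    g_peak <- centers[which.max(others)]
    in_win <- centers >= g_peak - half_width_ms - 1e-9 &
      centers <= g_peak + half_width_ms + 1e-9
    if (!any(in_win)) {
      stop("search window falls outside the grid", call. = FALSE)
    }
    own <- M[, i]
    k <- which(in_win)[which.max(own[in_win])]
    tibble::tibble(
      subject = subjects[i], regressor = regressor,
      peak_time_ms = centers[k], peak_value = own[k],
      search_lo_ms = g_peak - half_width_ms,
      search_hi_ms = g_peak + half_width_ms
    )
  }) |>
    structure(class = c("peak_estimates", class(tibble::tibble())))
}

#' Repeated-measures ANOVA with partial eta squared
#'
#' Classical within-subject decomposition via `stats::aov` with an `Error()`
#' stratum per effect; partial eta squared is `SS_effect / (SS_effect +
#' SS_error)` using each effect's own error stratum. Sphericity corrections
#' are not applied (degrees of freedom are reported uncorrected).
#'
#' @param data Long tibble with one row per subject x cell.
#' @param dv Name of the value column.
#' @param subject Name of the subject column.
#' @param within Character vector of within-subject factor names (1-3).
#' @return A tibble of class `rm_anova`: `effect`, `df_num`, `df_den`,
#'   `statistic` (F), `p_value`, `pes`.
#' @export
rm_anova <- function(data, dv, subject, within) {
  stopifnot(all(c(dv, subject, within) %in% names(data)))
  df <- data.frame(
    .value = data[[dv]],
    .subject = factor(data[[subject]])
  )
  for (f in within) df[[f]] <- factor(data[[f]])
  counts <- table(df[, c(".subject", within), drop = FALSE])
  if (any(counts == 0)) stop("missing cells in the within-subject table", call. = FALSE)
  if (length(unique(as.vector(counts))) != 1) {
    stop("unbalanced within-subject table", call. = FALSE)
  }
  # average replicates within cells so each subject contributes one value/cell
  agg <- stats::aggregate(
    df$.value,
    by = df[, c(".subject", within), drop = FALSE], FUN = mean
  )
  names(agg)[ncol(agg)] <- ".value"
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(
    paste0(".value ~ ", rhs, " + Error(.subject/(", rhs, "))")
  )
  fit <- stats::aov(fml, data = agg)
  smry <- summary(fit)
  out <- purrr::map_dfr(smry, function(stratum) {
    tab <- stratum[[1]]
    terms <- rownames(tab)
    res_i <- grep("^Residuals", trimws(terms))
    if (!length(res_i) || nrow(tab) < 2) {
      return(tibble::tibble())
    }
    ss_err <- tab[res_i, "Sum Sq"]
    df_err <- tab[res_i, "Df"]
    eff_i <- setdiff(seq_len(nrow(tab)), res_i)
    ss_eff <- tab[eff_i, "Sum Sq"]
    f_val <- tab[eff_i, "F value"]
    p_val <- tab[eff_i, "Pr(>F)"]
    # a zero effect sum of squares is no effect, whatever the error term
    zero <- ss_eff <= 1e-12 * max(ss_eff + ss_err, 1e-300)
    f_val[zero] <- 0
    p_val[zero] <- 1
    tibble::tibble(
      effect = gsub(" ", "", trimws(terms[eff_i])),
      df_num = tab[eff_i, "Df"],
      df_den = df_err,
      statistic = f_val,
      p_value = p_val,
      pes = ifelse(zero, 0, ss_eff / (ss_eff + ss_err))
    )
  })
  class(out) <- c("rm_anova", class(out))
  out
}

#' Paired t test with Hedges' g and bootstrap CI
#'
#' Hedges' g is the bias-corrected standardised mean difference of the paired
#' differences: `g = mean(d)/sd(d) * J` with `J = 1 - 3/(4 df - 1)`. The 95%
#' confidence interval uses a seeded bias-corrected percentile bootstrap. The
#' p-value can be Bonferroni-scaled by `n_comparisons` (capped at 1).
#'
#' @param x Numeric vector.
#' @param y Numeric vector paired with `x`, or a scalar (one-sample test
#'   against that value).
#' @param n_comparisons Bonferroni factor applied to the p-value.
#' @param n_boot Bootstrap resamples for the CI (default 10000).
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return A tibble of class `effect_size`: `t`, `df`, `p`, `p_corrected`,
#'   `hedges_g`, `ci_low`, `ci_high`.
#' @export
paired_t_hedges <- function(x, y = 0, n_comparisons = 1, n_boot = 10000,
                            conf = 0.95, seed = 1) {
  if (length(y) == 1) y <- rep(y, length(x))
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (stats::sd(d) == 0) stop("zero-variance differences", call. = FALSE)
  n <- length(d)
  df <- n - 1
  tt <- stats::t.test(d)
  J <- 1 - 3 / (4 * df - 1)
  g_of <- function(v) mean(v) / stats::sd(v) * J
  g <- g_of(d)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      v <- d[sample.int(n, n, replace = TRUE)]
      if (stats::sd(v) == 0) return(NA_real_)
      g_of(v)
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  # bias-corrected percentile interval
  z0 <- stats::qnorm(mean(boots < g))
  a <- (1 - conf) / 2
  lo_p <- stats::pnorm(2 * z0 + stats::qnorm(a))
  hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - a))
  ci <- stats::quantile(boots, c(lo_p, hi_p), names = FALSE)
  out <- tibble::tibble(
    t = unname(tt$statistic), df = df, p = tt$p.value,
    p_corrected = min(1, tt$p.value * n_comparisons),
    hedges_g = g, ci_low = ci[1], ci_high = ci[2]
  )
  class(out) <- c("effect_size", class(out))
  out
}

#' Assemble a choice trace from a coefficient series
#'
#' A choice trace is a 2-D trajectory over window centres plotting the
#' magnitude of the input-adaptation coefficient (x) against the
#' response-adaptation coefficient (y), mimicking neural state-space
#' trajectories from sensory input to motor response.
#'
#' @param series A `coef_series` tibble (typically the group series).
#' @param input_regressor Regressor for the x axis (default `"rel_adapt"`;
#'   pass `c("rel_adapt", "irrel_adapt")` to obtain one trace per input type).
#' @param response_regressor Regressor for the y axis (default `"resp_adapt"`).
#' @param window Optional length-2 numeric restricting the trace in ms.
#' @return A tibble of class `choice_trace`: `input`, `t`, `x`, `y`, ordered
#'   by time within each input type.
#' @export
build_choice_trace <- function(series, input_regressor = "rel_adapt",
                               response_regressor = "resp_adapt",
                               window = NULL) {
  stopifnot(all(c(input_regressor, response_regressor) %in% series$regressor))
  wide <- tidyr::pivot_wider(
    series[, c("window_center_ms", "regressor", "coef")],
    names_from = "regressor", values_from = "coef"
  )
  wide <- wide[order(wide$window_center_ms), ]
  if (!is.null(window)) {
    wide <- wide[
      wide$window_center_ms >= window[1] - 1e-9 &
        wide$window_center_ms <= window[2] + 1e-9,
    ]
  }
  out <- purrr::map_dfr(input_regressor, function(ir) {
    tibble::tibble(
      input = ir, t = wide$window_center_ms,
      x = wide[[ir]], y = wide[[response_regressor]]
    )
  })
  class(out) <- c("choice_trace", class(out))
  out
}

#' Peak-time density for visualisation
#'
#' Kernel density of individual peak latencies, for plots only (it enters no
#' statistics).
#'
#' @param peaks A `peak_estimates` tibble.
#' @param ... Passed to [stats::density()].
#' @return A tibble `peak_time_ms`, `density`, `regressor`.
#' @export
peak_density <- function(peaks, ...) {
  purrr::map_dfr(split(peaks, peaks$regressor), function(g) {
    d <- stats::density(g$peak_time_ms, ...)
    tibble::tibble(
      peak_time_ms = d$x, density = d$y, regressor = g$regressor[1]
    )
  })
}
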