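# broom-style tidiers for the package's result objects.

#' Tidy an effect-size result
#'
#' @param x An `effect_size` tibble from [paired_t_hedges()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p.value`,
#'   `p.value.corrected`, `estimate` (Hedges' g), `conf.low`, `conf.high`.
#' @export
tidy.effect_size <- function(x, ...) {
  tibble::tibble(
    statistic = x$t, df = x$df, p.value = x$p,
    p.value.corrected = x$p_corrected, estimate = x$hedges_g,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` tibble.
#' @param ... Unused.
#' @return A tibble with `term`, `statistic`, `df`, `df.residual`, `p.value`,
#'   `pes` (partial eta squared).
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(
    term = x$effect, statistic = x$statistic, df = x$df_num,
    df.residual = x$df_den, p.value = x$p_value, pes = x$pes
  )
}

#' Tidy behavioural regression results
#'
#' @param x A `behav_glm` list from [fit_behav_regressions()].
#' @param ... Unused.
#' @return The group-level tibble with broom-style names.
#' @export
tidy.behav_glm <- function(x, ...) {
  dplyr::rename(x$group,
    term = "regressor", estimate = "mean_beta", statistic = "t",
    p.value = "p"
  )
}

#' @export
glance.behav_glm <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(unique(x$coefficients$subject)),
    n_regressors = length(rs_regressors()),
    n_acc_converged = sum(x$coefficients$acc_converged) / length(rs_regressors())
  )
}

#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit` from [fit_psychometric()].
#' @param ... Unused.
#' @return The parameter tibble with broom-style names.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  dplyr::rename(x$parameters, estimate = "estimate", std.error = "se")
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  x$parameters |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(saturated = any(.data$saturated), .groups = "drop")
}
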