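# Synthetic trial-locked source epochs with known ground truth. Each trial's
# trace is a sum of regressor-locked temporal kernels weighted by the design
# matrix, plus AR(1) noise; behaviour is sampled from a logistic choice model.
# The generator exists so that every downstream stage has a parameter-recovery
# test without the study's raw recordings.

#' Temporal effect specification for the epoch generator
#'
#' One row per regressor of the repetition-suppression design. Sustained
#' effects (context, switch) use a half-Gaussian rise at onset held to the end
#' of the epoch; transient effects (inputs, response, choice) are Gaussian
#' bumps parameterised by peak time and FWHM.
#'
#' Defaults follow the reported latencies: context/switch sustained from 8 ms;
#' input adaptation with onset 108 ms and peak 429.5 ms; response adaptation
#' and choice with onset 275 ms and peak 531.1 ms. The relevant-input
#' amplitude is twice the irrelevant-input amplitude. `phase = "post"` shifts
#' transient peaks 75 ms earlier (training speeds processing; amplitudes
#' unchanged).
#'
#' @param phase `"pre"` or `"post"` defaults, or pass columns directly.
#' @param regressor,shape,onset_ms,peak_ms,width_ms,amplitude Vectors
#'   overriding the defaults (recycled per tibble rules).
#' @return A tibble with columns `regressor`, `shape`, `onset_ms`, `peak_ms`,
#'   `width_ms`, `amplitude`.
#' @export
effect_spec <- function(phase = c("pre", "post"),
                        regressor = NULL, shape = NULL, onset_ms = NULL,
                        peak_ms = NULL, width_ms = NULL, amplitude = NULL) {
  phase <- match.arg(phase)
  if (is.null(regressor)) {
    spec <- tibble::tibble(
      regressor = rs_regressors(),
      shape = c(
        "half_gaussian_sustained", "half_gaussian_sustained",
        "gaussian_bump", "gaussian_bump", "gaussian_bump", "gaussian_bump"
      ),
      onset_ms = c(8, 8, 108, 108, 275, 275),
      peak_ms = c(150, 150, 429.5, 429.5, 531.1, 531.1),
      width_ms = c(150, 150, 300, 300, 300, 300),
      amplitude = c(1.0, 0.8, 1.0, 0.5, 1.0, 0.8)
    )
    if (phase == "post") {
      bump <- spec$shape == "gaussian_bump"
      spec$peak_ms[bump] <- spec$peak_ms[bump] - 75
    }
  } else {
    spec <- tibble::tibble(
      regressor = regressor, shape = shape, onset_ms = onset_ms,
      peak_ms = peak_ms, width_ms = width_ms, amplitude = amplitude
    )
  }
  stopifnot(
    all(spec$shape %in% c("half_gaussian_sustained", "gaussian_bump")),
    all(spec$onset_ms < spec$peak_ms),
    all(spec$amplitude >= 0)
  )
  spec
}

#' Noise specification for the epoch generator
#'
#' @param ar1_coefficient Lag-1 autocorrelation of the additive noise, in
#'   `[0, 1)`.
#' @param noise_sd Marginal standard deviation of the AR(1) noise (signal
#'   units).
#' @param trial_gain_sd SD of a multiplicative per-trial gain on the signal.
#' @param subject_amplitude_sd SD of a multiplicative per-subject amplitude
#'   factor (used by [simulate_rs_dataset()]).
#' @return A list with the four fields.
#' @export
noise_spec <- function(ar1_coefficient = 0.7, noise_sd = 1,
                       trial_gain_sd = 0.1, subject_amplitude_sd = 0.2) {
  stopifnot(
    ar1_coefficient >= 0, ar1_coefficient < 1,
    noise_sd >= 0, trial_gain_sd >= 0, subject_amplitude_sd >= 0
  )
  list(
    ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
    trial_gain_sd = trial_gain_sd, subject_amplitude_sd = subject_amplitude_sd
  )
}

# Time axis in ms relative to TS onset. The window must hold an integer
# number of sampling intervals.
epoch_time_axis <- function(window_ms = c(-500, 1350), sampling_rate_hz = 300) {
  stopifnot(window_ms[2] > window_ms[1], sampling_rate_hz > 0)
  step <- 1000 / sampling_rate_hz
  n_steps <- (window_ms[2] - window_ms[1]) / step
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("epoch window is not an integer number of samples", call. = FALSE)
  }
  window_ms[1] + step * (0:round(n_steps))
}

# samples x regressors kernel matrix evaluated on a time axis.
regressor_kernels <- function(time_ms, effects) {
  K <- vapply(seq_len(nrow(effects)), function(i) {
    e <- effects[i, ]
    if (e$shape == "gaussian_bump") {
      sigma <- e$width_ms / (2 * sqrt(2 * log(2)))
      e$amplitude * exp(-(time_ms - e$peak_ms)^2 / (2 * sigma^2))
    } else {
      # half-Gaussian rise from onset, saturating at the nominal peak time
      mid <- (e$onset_ms + e$peak_ms) / 2
      sd <- (e$peak_ms - e$onset_ms) / 4
      e$amplitude * stats::pnorm(time_ms, mean = mid, sd = sd)
    }
  }, numeric(length(time_ms)))
  colnames(K) <- effects$regressor
  K
}

# AR(1) rows with marginal sd `noise_sd`, lag-1 autocorrelation `phi`.
ar1_noise <- function(n_rows, n_cols, phi, noise_sd) {
  if (noise_sd == 0) {
    return(matrix(0, n_rows, n_cols))
  }
  innov_sd <- noise_sd * sqrt(1 - phi^2)
  E <- matrix(stats::rnorm(n_rows * n_cols, sd = innov_sd), n_rows, n_cols)
  if (phi > 0) {
    E[, 1] <- stats::rnorm(n_rows, sd = noise_sd)
    # recursive filter along the time axis, vectorised across trials
    for (j in 2:n_cols) E[, j] <- phi * E[, j - 1] + E[, j]
  }
  E
}

new_source_epochs <- function(data, time_ms, sampling_rate_hz, session_id,
                              ground_truth = NULL) {
  structure(
    list(
      data = data, time_ms = time_ms, sampling_rate_hz = sampling_rate_hz,
      session_id = session_id, ground_truth = ground_truth
    ),
    class = "source_epochs"
  )
}

#' @export
print.source_epochs <- function(x, ...) {
  d <- dim(x$data)
  what <- if (length(d) == 3) {
    sprintf("%d trials x %d parcels x %d samples", d[1], d[2], d[3])
  } else {
    sprintf("%d trials x %d samples", d[1], d[2])
  }
  cat(sprintf(
    "<source_epochs> %s, %g Hz, t = [%g, %g] ms, session %s\n",
    what, x$sampling_rate_hz, min(x$time_ms), max(x$time_ms), x$session_id
  ))
  invisible(x)
}

#' Simulate trial-locked source epochs for one virtual sensor
#'
#' Each trial's trace is `sum_k design[i, k] * kernel_k(t) * (1 + gain_i)`
#' plus AR(1) noise, where the kernels come from an [effect_spec()].
#'
#' @param design A design tibble whose columns match `effects$regressor`
#'   (typically from [code_rs_regressors()]).
#' @param effects An [effect_spec()] tibble.
#' @param noise A [noise_spec()] list.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @param window_ms Epoch window in ms relative to TS onset.
#' @param sampling_rate_hz Sampling rate (default 300 Hz).
#' @param session_id Session identifier stored on the object.
#' @return A `source_epochs` object: `data` (trials x samples), `time_ms`,
#'   `sampling_rate_hz`, `session_id`, and a `ground_truth` list recording the
#'   inputs.
#' @export
simulate_source_epochs <- function(design, effects = effect_spec(),
                                   noise = noise_spec(), seed = 1,
                                   window_ms = c(-500, 1350),
                                   sampling_rate_hz = 300,
                                   session_id = "S01") {
  X <- as.matrix(design[, effects$regressor, drop = FALSE])
  time_ms <- epoch_time_axis(window_ms, sampling_rate_hz)
  K <- regressor_kernels(time_ms, effects)
  S <- X %*% t(K) # trials x samples
  dat <- withr::with_seed(seed, {
    gains <- stats::rnorm(nrow(X), sd = noise$trial_gain_sd)
    S * (1 + gains) +
      ar1_noise(nrow(S), ncol(S), noise$ar1_coefficient, noise$noise_sd)
  })
  new_source_epochs(
    dat, time_ms, sampling_rate_hz, session_id,
    ground_truth = list(effects = effects, noise = noise, seed = seed)
  )
}

#' Default parcel loading matrix
#'
#' Random non-negative loadings (parcels x regressors) in which the
#' `rel_strength` column is `rel_irrel_ratio` times stronger than the
#' `irrel_strength` column on average.
#'
#' @param n_parcels Number of parcels (the whole-brain parcellation uses 38).
#' @param regressors Regressor names (columns).
#' @param rel_irrel_ratio Mean relevant:irrelevant loading ratio.
#' @param seed Integer seed.
#' @return A numeric matrix, parcels x regressors.
#' @export
default_loadings <- function(n_parcels = 38, regressors = encoding_regressors(),
                             rel_irrel_ratio = 2, seed = 1) {
  L <- withr::with_seed(
    seed,
    matrix(stats::runif(n_parcels * length(regressors), 0.2, 1),
      n_parcels, length(regressors),
      dimnames = list(NULL, regressors)
    )
  )
  if ("irrel_strength" %in% regressors) {
    L[, "irrel_strength"] <- L[, "irrel_strength"] / rel_irrel_ratio
  }
  L
}

#' Simulate multi-parcel epochs
#'
#' Parcel `p` carries `sum_k loading[p, k] * design[i, k] * kernel_k(t)` plus
#' independent AR(1) noise per parcel.
#'
#' @inheritParams simulate_source_epochs
#' @param loadings Parcels x regressors matrix; columns must match
#'   `effects$regressor` and the design columns.
#' @return A `source_epochs` object with 3-D `data` (trials x parcels x
#'   samples).
#' @export
simulate_parcel_epochs <- function(design, loadings, effects, noise = noise_spec(),
                                   seed = 1, window_ms = c(-500, 1350),
                                   sampling_rate_hz = 300, session_id = "S01") {
  stopifnot(is.matrix(loadings), all(is.finite(loadings)))
  if (!identical(sort(colnames(loadings)), sort(effects$regressor))) {
    stop("loading columns must match effect regressors", call. = FALSE)
  }
  loadings <- loadings[, effects$regressor, drop = FALSE]
  X <- as.matrix(design[, effects$regressor, drop = FALSE])
  if (nrow(X) == 0) stop("empty design", call. = FALSE)
  time_ms <- epoch_time_axis(window_ms, sampling_rate_hz)
  K <- regressor_kernels(time_ms, effects)
  n_parcels <- nrow(loadings)
  dat <- array(0, dim = c(nrow(X), n_parcels, length(time_ms)))
  withr::with_seed(seed, {
    for (p in seq_len(n_parcels)) {
      S <- (X %*% diag(loadings[p, ], ncol(X))) %*% t(K)
      dat[, p, ] <- S +
        ar1_noise(nrow(S), ncol(S), noise$ar1_coefficient, noise$noise_sd)
    }
  })
  new_source_epochs(
    dat, time_ms, sampling_rate_hz, session_id,
    ground_truth = list(
      effects = effects, noise = noise, loadings = loadings, seed = seed
    )
  )
}

#' Behavioural ground-truth coefficients
#'
#' Defaults encode the qualitative behavioural signature of repetition
#' suppression: relevant-input adaptation and context switches slow responses
#' and lower accuracy, response adaptation lowers accuracy, the irrelevant
#' input does neither; the psychometric slope on relevant evidence is strong
#' and the slope on irrelevant evidence weak but positive.
#'
#' @param rt Named numeric: log-RT effects of the six RS regressors.
#' @param acc Named numeric: accuracy (log-odds) penalties of the six RS
#'   regressors; positive values lower accuracy.
#' @param slope_relevant,slope_irrelevant Psychometric slopes on signed
#'   relevant/irrelevant evidence (per strength unit).
#' @param intercept Psychometric intercept (bias towards the positive pole).
#' @param rt_intercept_log Mean log-RT (log ms) of an unadapted trial.
#' @param rt_sd SD of log-RT noise.
#' @param rt_coherence Log-RT change per unit of absolute relevant evidence
#'   (negative: easier trials are faster).
#' @return A list of class `behav_coefficients`.
#' @export
behav_coefficients <- function(rt = c(
                                 context = 0, switch = 0.03, rel_adapt = 0.05,
                                 irrel_adapt = 0, resp_adapt = 0, choice = 0
                               ),
                               acc = c(
                                 context = 0, switch = 0.3, rel_adapt = 0.4,
                                 irrel_adapt = 0, resp_adapt = 0.4, choice = 0
                               ),
                               slope_relevant = 2,
                               slope_irrelevant = 0.2,
                               intercept = 0,
                               rt_intercept_log = log(600),
                               rt_sd = 0.25,
                               rt_coherence = -0.05) {
  stopifnot(
    all(rs_regressors() %in% names(rt)),
    all(rs_regressors() %in% names(acc))
  )
  structure(
    list(
      rt = rt[rs_regressors()], acc = acc[rs_regressors()],
      slope_relevant = slope_relevant, slope_irrelevant = slope_irrelevant,
      intercept = intercept, rt_intercept_log = rt_intercept_log,
      rt_sd = rt_sd, rt_coherence = rt_coherence
    ),
    class = "behav_coefficients"
  )
}

#' Simulate behavioural outcomes for a schedule
#'
#' Choices are sampled from a logistic model in the signed relevant and
#' irrelevant evidence, with adaptation/switch terms subtracting evidence in
#' the correct direction (lowering accuracy); log-RT is a linear model in the
#' RS regressors plus Gaussian noise.
#'
#' @param trials A trial tibble (outcome columns are overwritten).
#' @param coef A [behav_coefficients()] list.
#' @param seed Integer seed.
#' @return `trials` with `ts_response`, `ts_correct`, `ts_rt_ms` filled.
#' @export
simulate_behaviour <- function(trials, coef = behav_coefficients(), seed = 1) {
  s <- signed_strengths(trials)
  design <- code_rs_regressors(trials)
  X <- as.matrix(design[, rs_regressors()])
  pole <- sign(s$rel_strength) # +1 when "middle" is correct
  eta <- coef$intercept +
    coef$slope_relevant * s$rel_strength +
    coef$slope_irrelevant * s$irrel_strength -
    pole * as.vector(X %*% coef$acc)
  withr::with_seed(seed, {
    middle <- stats::runif(nrow(trials)) < stats::plogis(eta)
    resp <- ifelse(middle, "middle", "index")
    req <- required_response(trials$ts_context, trials$ts_direction, trials$ts_colour)
    correct <- as.integer(resp == req)
    log_rt <- coef$rt_intercept_log +
      as.vector(X %*% coef$rt) +
      coef$rt_coherence * abs(s$rel_strength) +
      stats::rnorm(nrow(trials), sd = coef$rt_sd)
    trials$ts_response <- resp
    trials$ts_correct <- correct
    trials$ts_rt_ms <- exp(log_rt)
  })
  trials
}

#' Apply per-session sign flips
#'
#' Source-reconstructed dipole signs are arbitrary per session; this utility
#' multiplies flagged sessions by -1 and records the truth for recovery tests.
#'
#' @param epochs A `source_epochs` object or a list of them (one per session).
#' @param flags Logical, one per session; if `NULL`, drawn Bernoulli with
#'   `probability` under `seed`.
#' @param probability Flip probability used when `flags` is `NULL`.
#' @param seed Integer seed for random flags.
#' @return Epochs of the same shape; each carries attribute `sign_flipped`.
#' @export
apply_session_sign_flips <- function(epochs, flags = NULL, probability = 0.5,
                                     seed = 1) {
  single <- inherits(epochs, "source_epochs")
  lst <- if (single) list(epochs) else epochs
  if (is.null(flags)) {
    flags <- withr::with_seed(seed, stats::runif(length(lst)) < probability)
  }
  stopifnot(length(flags) == length(lst))
  out <- purrr::map2(lst, flags, function(e, f) {
    if (isTRUE(f)) e$data <- -e$data
    prev <- attr(e, "sign_flipped") %||% FALSE
    attr(e, "sign_flipped") <- xor(prev, isTRUE(f))
    e
  })
  if (single) out[[1]] else out
}

#' Simulate a full multi-subject dataset
#'
#' Convenience wrapper: per subject, a balanced schedule, behavioural
#' outcomes, the RS design, and source epochs, with a per-subject amplitude
#' factor drawn from the noise spec. Per-subject seeds are derived from the
#' master seed by fixed offsets.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject (multiple of 64).
#' @param effects,noise,coef Generator specifications.
#' @param seed Master integer seed.
#' @param ... Passed to [simulate_source_epochs()] (window, sampling rate).
#' @return A list of per-subject lists with elements `subject`, `trials`,
#'   `design`, `epochs`.
#' @export
simulate_rs_dataset <- function(n_subjects, n_trials, effects = effect_spec(),
                                noise = noise_spec(),
                                coef = behav_coefficients(), seed = 1, ...) {
  stopifnot(n_trials %% 64 == 0)
  purrr::map(seq_len(n_subjects), function(s) {
    s_seed <- (seed + 7919L * s) %% .Machine$integer.max
    trials <- generate_session_schedule(1, n_trials,
      seed = s_seed,
      session_id = sprintf("sub%02d", s)
    )
    trials <- simulate_behaviour(trials, coef, seed = s_seed + 1L)
    design <- code_rs_regressors(trials)
    amp <- withr::with_seed(
      s_seed + 2L,
      max(0.2, 1 + stats::rnorm(1, sd = noise$subject_amplitude_sd))
    )
    eff <- effects
    eff$amplitude <- eff$amplitude * amp
    epochs <- simulate_source_epochs(design,
      effects = eff, noise = noise,
      seed = s_seed + 3L, session_id = sprintf("sub%02d", s), ...
    )
    list(
      subject = sprintf("sub%02d", s), trials = trials,
      design = design, epochs = epochs
    )
  })
}
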