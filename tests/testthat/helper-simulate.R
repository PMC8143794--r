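# Shared fixtures, all generated in code.

# A balanced schedule with every response correct (choice = required response).
balanced_correct_trials <- function(reps = 1, seed = 1) {
  trials <- generate_session_schedule(1, 64 * reps, seed = seed)
  trials$ts_response <- required_response(
    trials$ts_context, trials$ts_direction, trials$ts_colour
  )
  trials$ts_correct <- 1L
  trials$ts_rt_ms <- 600
  trials
}

# The 32 distinct AS x context x direction x colour combinations.
combo32_trials <- function() {
  g <- unique(condition_grid()[, c(
    "as_type", "ts_context", "ts_direction", "ts_colour"
  )])
  g$ts_coherence_pct <- 12.8
  g$as_response <- choicetrace:::as_required_response(g$as_type)
  g$ts_response <- NA_character_
  g
}

# Low-cost ridge configuration for tests that only need the machinery.
quick_ridge <- function(seed = 1, n_subsamples = 2) {
  ridge_config(n_subsamples = n_subsamples, seed = seed)
}

# A small single-subject dataset with the default ground truth, correct trials
# only, ready for fitting.
quick_fit_input <- function(seed = 1, n_trials = 192, effects = effect_spec(),
                            noise = noise_spec()) {
  trials <- generate_session_schedule(1, n_trials, seed = seed)
  trials <- simulate_behaviour(trials, seed = seed + 1L)
  design <- code_rs_regressors(trials)
  epochs <- simulate_source_epochs(design, effects, noise, seed = seed + 2L)
  keep <- trials$ts_correct == 1
  epochs$data <- epochs$data[keep, , drop = FALSE]
  list(trials = trials[keep, ], design = design[keep, ], epochs = epochs)
}

# Independent ridge oracle: explicit normal-equations solve written separately
# from the package's fitting code path (QR on the augmented system).
ridge_oracle <- function(X, y, lambda) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  aug_X <- rbind(Xc, sqrt(n * lambda) * diag(ncol(X)))
  aug_y <- c(yc, rep(0, ncol(X)))
  qr.solve(aug_X, aug_y)
}
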