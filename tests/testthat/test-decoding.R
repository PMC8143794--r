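enc_effects <- function(amps = c(0, 1, 0.5, 0.8)) {
  effect_spec(
    regressor = encoding_regressors(),
    shape = c("half_gaussian_sustained", rep("gaussian_bump", 3)),
    onset_ms = c(8, 108, 108, 275),
    peak_ms = c(150, 429.5, 429.5, 531.1),
    width_ms = c(150, 300, 300, 300),
    amplitude = amps
  )
}

decode_fixture <- function(seed, n_trials = 128, n_parcels = 8,
                           noise = noise_spec(ar1_coefficient = 0.5, noise_sd = 0.8),
                           ratio = 2) {
  trials <- balanced_correct_trials(reps = n_trials / 64, seed = seed)
  enc <- code_encoding_regressors(trials)
  L <- default_loadings(n_parcels, rel_irrel_ratio = ratio, seed = seed)
  ep <- simulate_parcel_epochs(enc, L, enc_effects(), noise, seed = seed + 1)
  list(trials = trials, enc = enc, epochs = ep)
}

test_that("choice residualization is exact", {
  set.seed(41)
  W <- matrix(rnorm(400), 100, 4)
  choice <- rep(0:1, each = 50)

  # random signal: residuals exactly orthogonal to choice
  R <- residualize_choice(W, choice)
  expect_true(all(abs(cor(R, choice)) < 1e-12))

  # pure choice indicator signal vanishes
  Wc <- matrix(choice, 100, 3) * matrix(c(1, -2, 0.5), 100, 3, byrow = TRUE)
  expect_lt(max(abs(residualize_choice(Wc, choice))), 1e-12)

  # signal orthogonal to choice: residuals equal the demeaned signal
  Wo <- W - outer(choice, colSums(W * choice) / sum(choice)) # crude, then exact:
  M <- cbind(1, choice)
  Wo <- W - M %*% solve(crossprod(M), crossprod(M, W)) + # orthogonalized
    matrix(colMeans(W), 100, 4, byrow = TRUE)
  Ro <- residualize_choice(Wo, choice)
  expect_equal(Ro, scale(Wo, scale = FALSE), ignore_attr = TRUE, tolerance = 1e-10)

  expect_error(residualize_choice(W, rep(1, 100)), "single class")
})

test_that("noiseless linear encoding decodes almost perfectly", {
  fx <- decode_fixture(51,
    noise = noise_spec(ar1_coefficient = 0, noise_sd = 0, trial_gain_sd = 0)
  )
  grid <- build_window_grid(430, 430)
  res <- nested_cv_decode(
    fx$epochs, fx$enc$rel_strength,
    choice = fx$enc$choice,
    grid = grid, config = decode_config(residualize = FALSE, seed = 1)
  )
  expect_gt(res$score, 0.99)
})

test_that("outer folds predict every trial exactly once", {
  n <- 100
  fold <- withr::with_seed(1, sample(rep_len(1:10, n)))
  expect_equal(sort(unname(unlist(split(seq_len(n), fold)))), seq_len(n))
  # and through the public interface: predictions are complete and finite
  fx <- decode_fixture(52)
  res <- nested_cv_decode(fx$epochs, fx$enc$rel_strength,
    choice = fx$enc$choice,
    grid = build_window_grid(430, 430), config = decode_config(seed = 2)
  )
  expect_true(is.finite(res$score))
  expect_equal(res$n, nrow(fx$enc))
})

test_that("label-shuffled decoding sits at chance", {
  scores <- vapply(1:12, function(s) {
    fx <- decode_fixture(60 + s, n_trials = 192)
    y <- withr::with_seed(s, sample(fx$enc$rel_strength))
    nested_cv_decode(fx$epochs, y,
      choice = fx$enc$choice,
      grid = build_window_grid(430, 430), config = decode_config(seed = s)
    )$score
  }, numeric(1))
  expect_lt(abs(mean(scores)), 0.1)
})

test_that("residualization removes the choice shortcut", {
  # signal carries only the choice kernel; relevant strength is decodable
  # only through its 0.95 design correlation with choice
  trials <- balanced_correct_trials(reps = 2, seed = 71)
  enc <- code_encoding_regressors(trials)
  L <- matrix(0, 6, 4, dimnames = list(NULL, encoding_regressors()))
  L[, "choice"] <- seq(0.5, 1.5, length.out = 6)
  ep <- simulate_parcel_epochs(
    enc, L, enc_effects(),
    noise_spec(ar1_coefficient = 0.3, noise_sd = 0.3), seed = 72
  )
  grid <- build_window_grid(531.1, 531.1)
  raw <- nested_cv_decode(ep, enc$rel_strength,
    choice = enc$choice, grid = grid,
    config = decode_config(residualize = FALSE, seed = 3)
  )
  resid <- nested_cv_decode(ep, enc$rel_strength,
    choice = enc$choice, grid = grid,
    config = decode_config(residualize = TRUE, seed = 3)
  )
  expect_gt(raw$score, 0.5)
  expect_lt(resid$score, raw$score - 0.3)
})

test_that("relevant decoding exceeds irrelevant under a 2:1 loading ratio", {
  # without choice residualization the decoders see the full signal, so the
  # injected loading ratio sets the ordering directly
  diffs <- vapply(1:5, function(s) {
    fx <- decode_fixture(80 + s, n_trials = 192)
    res <- decode_relevant_irrelevant(
      fx$epochs, fx$trials,
      grid = build_window_grid(430, 430),
      config = decode_config(seed = s, residualize = FALSE)
    )
    avg <- res$averaged
    avg$score[avg$target == "relevant"] - avg$score[avg$target == "irrelevant"]
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("group comparison flags only genuinely different windows", {
  centers <- seq(0, 800, by = 200)
  series <- tidyr::expand_grid(
    subject = paste0("s", 1:8), target = c("relevant", "irrelevant"),
    window_center_ms = centers
  )
  set.seed(91)
  series$score <- 0.2 + rnorm(nrow(series), sd = 0.01)
  boost <- series$target == "relevant" & series$window_center_ms %in% c(400, 600)
  series$score[boost] <- series$score[boost] + 0.3
  res <- compare_relevant_irrelevant(series, stat_window = c(0, 800))
  sig <- res$per_window$window_center_ms[res$per_window$significant]
  expect_setequal(sig, c(400, 600))

  # statistically identical series -> nothing significant, and the two-way
  # ANOVA (input x training) runs and finds nothing
  same <- tidyr::expand_grid(
    subject = paste0("s", 1:8), target = c("relevant", "irrelevant"),
    window_center_ms = centers, training = c("pre", "post")
  )
  set.seed(92)
  same$score <- 0.2 + rnorm(nrow(same), sd = 0.01)
  res2 <- compare_relevant_irrelevant(same, stat_window = c(0, 800))
  expect_false(any(res2$per_window$significant))
  expect_s3_class(res2$anova, "rm_anova")
  expect_true(all(res2$anova$p_value > 0.05, na.rm = TRUE))
})
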