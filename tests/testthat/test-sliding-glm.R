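test_that("window grids follow the centre +/- half-width convention", {
  g <- build_window_grid(8, 8)
  expect_equal(g$centers_ms, 8)
  expect_equal(c(8 - g$half_width_ms, 8 + g$half_width_ms), c(-67, 83))

  g0 <- build_window_grid(0, 0)
  expect_equal(c(-75, 75), c(-g0$half_width_ms, g0$half_width_ms))

  # a 150 ms half-open window at 300 Hz selects 45 samples
  time_ms <- choicetrace:::epoch_time_axis(c(-500, 1350), 300)
  idx <- choicetrace:::window_sample_index(time_ms, 8, 75)
  expect_length(idx, 45)
})

test_that("window averaging equals the brute-force index-set mean", {
  trials <- balanced_correct_trials(seed = 1)
  design <- code_rs_regressors(trials)
  ep <- simulate_source_epochs(design, seed = 3)
  grid <- build_window_grid(-100, 500)
  W <- window_average(ep, grid)
  for (w in c(1, 5, length(grid$centers_ms))) {
    c0 <- grid$centers_ms[w]
    idx <- which(ep$time_ms >= c0 - 75 & ep$time_ms < c0 + 75)
    expect_equal(W[, w], rowMeans(ep$data[, idx]), ignore_attr = TRUE)
  }

  # constant trace -> every window mean equals the constant
  epc <- ep
  epc$data <- matrix(3.5, nrow(ep$data), ncol(ep$data))
  expect_true(all(window_average(epc, grid) == 3.5))

  # linear ramp -> window mean equals the value at the centre of the
  # averaged samples
  epr <- ep
  epr$data <- matrix(rep(ep$time_ms, each = nrow(ep$data)), nrow(ep$data))
  Wr <- window_average(epr, grid)
  idx <- which(ep$time_ms >= grid$centers_ms[2] - 75 &
    ep$time_ms < grid$centers_ms[2] + 75)
  expect_equal(unname(Wr[1, 2]), mean(ep$time_ms[idx]))

  expect_error(
    window_average(ep, build_window_grid(5000, 5000)),
    "5000"
  )
})

test_that("ridge matches the closed-form oracle and its limits", {
  set.seed(11)
  X <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20)

  # OLS limit
  f0 <- fit_ridge(X, y, 0)
  ols <- lm(y ~ X)
  expect_equal(unname(f0$coefficients), unname(coef(ols)[-1]), tolerance = 1e-10)
  expect_equal(f0$intercept, unname(coef(ols)[1]), tolerance = 1e-10)

  # heavy shrinkage
  Xs <- scale(X)
  f_big <- fit_ridge(Xs, y, 1e5)
  expect_lt(
    sqrt(sum(f_big$coefficients^2)),
    1e-2 * sqrt(sum(fit_ridge(Xs, y, 0)$coefficients^2))
  )

  # random problems against the independent oracle
  for (i in 1:25) {
    set.seed(100 + i)
    Xi <- matrix(rnorm(20 * 4), 20, 4)
    yi <- rnorm(20)
    lam <- 10^runif(1, -5, 2)
    got <- fit_ridge(Xi, yi, lam)$coefficients
    want <- ridge_oracle(Xi, yi, lam)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-8)
  }

  expect_error(fit_ridge(matrix(c(1, NA, 2, 3), 2), 1:2, 1), "non-finite")
})

test_that("penalty tuning prefers no shrinkage for clean signals and returns singletons", {
  grid <- 10^c(-5, -3, -1, 1, 3, 5)
  set.seed(2)
  X <- matrix(rnorm(600), 200, 3)
  y <- drop(X %*% c(1, -2, 0.5))
  lam <- withr::with_seed(1, tune_lambda_cv(X, y, grid))
  expect_equal(lam, 1e-5)

  expect_equal(withr::with_seed(1, tune_lambda_cv(X, y, 42)), 42)
  expect_error(
    withr::with_seed(1, tune_lambda_cv(X, rep(1, 200), grid)),
    "zero variance"
  )

  # pure noise at tiny n: a large penalty wins in the majority of seeds
  big <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      Xn <- matrix(rnorm(8 * 3), 8, 3)
      yn <- rnorm(8)
      tune_lambda_cv(Xn, yn, grid)
    })
  }, numeric(1))
  expect_gt(mean(big >= 10), 0.5)
})

test_that("the degenerate subsampled estimator reduces to plain OLS", {
  inp <- quick_fit_input(seed = 4)
  grid <- build_window_grid(300, 500)
  config <- ridge_config(
    lambda_grid = 0, n_subsamples = 1, subsample_fraction = 1,
    use_absolute = FALSE, seed = 1
  )
  series <- fit_subsampled_glm(inp$epochs, inp$design, grid, config)
  W <- window_average(inp$epochs, grid)
  for (w in seq_along(grid$centers_ms)) {
    ols <- lm(W[, w] ~ ., data = inp$design)
    got <- series$coef[series$window_center_ms == grid$centers_ms[w]]
    expect_equal(got,
      unname(coef(ols)[rs_regressors()]),
      tolerance = 1e-10, ignore_attr = TRUE
    )
  }
  expect_error(
    fit_subsampled_glm(
      list(data = inp$epochs$data[1:5, ]), inp$design[1:5, ], grid, config
    ),
    "fewer than 10"
  )
})

test_that("estimator is permutation-equivariant without subsampling or tuning", {
  inp <- quick_fit_input(seed = 6)
  grid <- build_window_grid(300, 450)
  config <- ridge_config(
    lambda_grid = 0.1, n_subsamples = 1, subsample_fraction = 1, seed = 1
  )
  base <- fit_subsampled_glm(inp$epochs, inp$design, grid, config)
  perm <- withr::with_seed(8, sample.int(nrow(inp$design)))
  ep2 <- inp$epochs
  ep2$data <- ep2$data[perm, ]
  shuf <- fit_subsampled_glm(ep2, inp$design[perm, ], grid, config)
  expect_equal(base$coef, shuf$coef, tolerance = 1e-12)
})

test_that("a subsampled ridge fit recovers an injected bump near its peak", {
  inp <- quick_fit_input(seed = 12)
  grid <- build_window_grid(250, 750)
  series <- fit_subsampled_glm(inp$epochs, inp$design, grid, quick_ridge(seed = 12))
  rel <- series[series$regressor == "rel_adapt", ]
  peak <- rel$window_center_ms[which.max(rel$coef)]
  expect_lt(abs(peak - 429.5), 200 / 3 + 1e-9)
  expect_true(all(series$coef >= 0))
})

test_that("session sign alignment flags negatively correlated pairs", {
  t <- seq(-200, 1500, by = 10)
  erp <- sin(t / 200)
  expect_equal(
    align_session_signs(list(erp, erp, erp, erp)),
    rep(FALSE, 4)
  )
  expect_equal(
    align_session_signs(list(erp, -erp, erp, erp)),
    c(FALSE, TRUE, FALSE, FALSE)
  )
  expect_error(align_session_signs(list(erp, erp * 0)), "zero-variance")

  # recovery on simulated flipped sessions at the default SNR
  hits <- vapply(1:5, function(s) {
    trials <- generate_session_schedule(1, 128, seed = s)
    design <- code_rs_regressors(trials)
    e1 <- simulate_source_epochs(design, seed = s * 10 + 1)
    e2 <- simulate_source_epochs(design, seed = s * 10 + 2)
    flipped <- apply_session_sign_flips(list(e1, e2), flags = c(FALSE, TRUE))
    erps <- lapply(flipped, function(e) colMeans(e$data))
    identical(align_session_signs(erps), c(FALSE, TRUE))
  }, logical(1))
  expect_true(all(hits))
})

test_that("permutation machinery preserves design structure and p-value bounds", {
  trials <- balanced_correct_trials(seed = 13)
  design <- code_rs_regressors(trials)
  perm <- withr::with_seed(3, design[sample.int(nrow(design)), ])
  expect_equal(colMeans(as.matrix(perm)), colMeans(as.matrix(design)))
  expect_equal(cor(as.matrix(perm)), cor(as.matrix(design)))

  inp <- quick_fit_input(seed = 14, n_trials = 64)
  grid <- build_window_grid(350, 450)
  config <- quick_ridge(seed = 14)
  series <- fit_subsampled_glm(inp$epochs, inp$design, grid, config)
  null1 <- permutation_null(inp$epochs, inp$design, grid, config,
    n_perm = 1, seed = 5
  )
  pv <- permutation_pvalues(series, null1, stat_window = c(300, 500))
  expect_true(all(pv$p %in% c(1 / 2, 1)))

  # observed above every null sample gives the add-one lower bound
  boosted <- series
  boosted$coef <- boosted$coef + 1e6
  null_stat <- null1
  null_stat$n_perm <- 1000
  null_stat$stat <- array(
    rep(null1$stat, each = 1000), c(1000, dim(null1$stat)[2:3])
  )
  pv_hi <- permutation_pvalues(boosted, null_stat, stat_window = c(300, 500))
  expect_true(all(pv_hi$p == 1 / 1001))

  # observed below every null sample gives p = 1
  sunk <- series
  sunk$coef <- sunk$coef - 1e6
  pv_lo <- permutation_pvalues(sunk, null_stat, stat_window = c(300, 500))
  expect_true(all(pv_lo$p == 1))

  expect_error(
    permutation_pvalues(series,
      permutation_null(inp$epochs, inp$design, build_window_grid(0, 100),
        config,
        n_perm = 1, seed = 5
      )
    ),
    "different grids"
  )
})

test_that("Bonferroni per-test alpha and stat-window derivation behave", {
  expect_equal(bonferroni_alpha(29), 0.05 / 29)
  expect_equal(round(bonferroni_alpha(29), 4), 0.0017)

  grid <- build_window_grid()
  centers <- suppressMessages(stat_window_centers(grid))
  expect_true(all(centers >= -400 / 3 - 1e-9 & centers <= 950 + 1e-9))
  expect_equal(min(centers), -400 / 3, tolerance = 1e-9)
  # the derived count differs from the conventionally quoted 29 and says so
  expect_message(stat_window_centers(grid, expected = 29), "expected 29")
})
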