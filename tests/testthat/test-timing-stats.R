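bump_series <- function(subjects, centers, peak_at, width = 100,
                        scale = 1, offset = 0) {
  purrr::map_dfr(seq_along(subjects), function(i) {
    tibble::tibble(
      subject = subjects[i], window_center_ms = centers, regressor = "rel_adapt",
      coef = offset + scale * exp(-(centers - peak_at[i])^2 / (2 * width^2))
    )
  })
}

test_that("LOO peaks find a shared noiseless bump exactly", {
  centers <- seq(0, 800, by = 100 / 3)
  s <- bump_series(paste0("s", 1:5), centers, rep(400, 5))
  pk <- loo_peak_times(s, "rel_adapt")
  expect_true(all(abs(pk$peak_time_ms - 400) < 1e-9))
  expect_equal(nrow(pk), 5)
  expect_error(loo_peak_times(s[s$subject %in% c("s1", "s2"), ], "rel_adapt"),
    "3 subjects")
})

test_that("an outlier subject is clamped into the LOO search window", {
  centers <- seq(0, 800, by = 100 / 3)
  s <- bump_series(paste0("s", 1:6), centers, c(400, 400, 400, 400, 400, 800))
  pk <- loo_peak_times(s, "rel_adapt", half_width_ms = 200 / 3)
  outlier <- pk[pk$subject == "s6", ]
  # oracle: windowed argmax of the outlier's own series around the others' peak
  own <- s[s$subject == "s6", ]
  in_win <- abs(own$window_center_ms - 400) <= 200 / 3 + 1e-9
  oracle <- own$window_center_ms[in_win][which.max(own$coef[in_win])]
  expect_equal(outlier$peak_time_ms, oracle)
  expect_lte(abs(outlier$peak_time_ms - 400), 200 / 3 + 1e-9)
})

test_that("LOO peaks are invariant to common offset and positive scaling", {
  centers <- seq(0, 800, by = 100 / 3)
  peaks <- c(350, 380, 420, 450, 400)
  base <- bump_series(paste0("s", 1:5), centers, peaks)
  moved <- bump_series(paste0("s", 1:5), centers, peaks, scale = 3.7, offset = 11)
  expect_equal(
    loo_peak_times(base, "rel_adapt")$peak_time_ms,
    loo_peak_times(moved, "rel_adapt")$peak_time_ms
  )
})

test_that("repeated-measures ANOVA matches hand-computed decompositions", {
  # identical cells -> F = 0 everywhere
  flat <- tidyr::expand_grid(subject = 1:4, a = c("x", "y"), b = c("u", "v"))
  flat$value <- 5
  res <- suppressWarnings(rm_anova(flat, "value", "subject", c("a", "b")))
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p_value == 1))
  expect_true(all(res$pes == 0))

  # textbook toy: 3 subjects x 2 conditions, hand SS oracle (paired t gives
  # t = 7, so F must be 49)
  toy <- tibble::tibble(
    subject = rep(1:3, each = 2), cond = rep(c("a", "b"), 3),
    value = c(1, 3, 2, 5, 0, 2)
  )
  res <- rm_anova(toy, "value", "subject", "cond")
  expect_equal(res$statistic, 49, tolerance = 1e-9)
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, 2)
  expect_equal(res$pes, 49 / (49 + 2), tolerance = 1e-9) # SSe/(SSe+SSerr) with dfs equal

  # one-way with two levels reproduces the paired t: F = t^2
  set.seed(21)
  x <- rnorm(8)
  y <- rnorm(8)
  d <- tibble::tibble(
    subject = rep(1:8, 2), cond = rep(c("a", "b"), each = 8), value = c(x, y)
  )
  tt <- t.test(x, y, paired = TRUE)
  res <- rm_anova(d, "value", "subject", "cond")
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)

  expect_error(rm_anova(toy[-1, ], "value", "subject", "cond"), "missing cells")
})

test_that("a regressor-by-training peak shift yields an interaction at cohort size", {
  # simulated post-training speeding of the input peak only
  set.seed(31)
  vals <- tidyr::expand_grid(
    subject = 1:22, regressor = c("input", "response"),
    training = c("pre", "post")
  )
  shift <- ifelse(vals$regressor == "input" & vals$training == "post", -60, 0)
  vals$peak <- 450 + ifelse(vals$regressor == "response", 100, 0) + shift +
    rnorm(nrow(vals), sd = 35)
  res <- rm_anova(vals, "peak", "subject", c("regressor", "training"))
  inter <- res[res$effect == "regressor:training", ]
  expect_lt(inter$p_value, 0.05)
})

test_that("Hedges' g matches its closed formula with Bonferroni scaling", {
  d <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4)
  es <- paired_t_hedges(d, 0, n_boot = 2000, seed = 3)
  J <- 1 - 3 / 35
  expect_equal(es$hedges_g, mean(d) / sd(d) * J, tolerance = 1e-12)
  expect_equal(es$df, 9)
  expect_true(es$ci_low <= es$hedges_g && es$hedges_g <= es$ci_high)

  # x = y + shift: one-sample equivalence and corrected p
  x <- c(2, 4, 6, 9)
  y <- c(1, 2, 3, 4)
  es2 <- paired_t_hedges(x, y, n_comparisons = 29, n_boot = 500)
  tt <- t.test(x - y)
  expect_equal(es2$t, unname(tt$statistic))
  expect_equal(es2$p_corrected, min(1, tt$p.value * 29))

  expect_equal(min(1, 0.001 * 29), 0.029) # the Bonferroni scaling rule itself
  expect_error(paired_t_hedges(c(1, 1, 1), 1), "zero-variance")
})

test_that("choice traces order input before response excursions", {
  centers <- seq(0, 800, by = 100 / 3)
  series <- dplyr::bind_rows(
    tibble::tibble(
      window_center_ms = centers, regressor = "rel_adapt",
      coef = exp(-(centers - 300)^2 / (2 * 80^2))
    ),
    tibble::tibble(
      window_center_ms = centers, regressor = "irrel_adapt",
      coef = 0.5 * exp(-(centers - 300)^2 / (2 * 80^2))
    ),
    tibble::tibble(
      window_center_ms = centers, regressor = "resp_adapt",
      coef = exp(-(centers - 550)^2 / (2 * 80^2))
    )
  )
  tr <- build_choice_trace(series)
  expect_lt(which.max(tr$x), which.max(tr$y))

  # flat series collapse to a point
  flat <- series
  flat$coef <- 2
  trf <- build_choice_trace(flat)
  expect_equal(diff(range(trf$x)), 0)
  expect_equal(diff(range(trf$y)), 0)

  # 2:1 relevant:irrelevant amplitude doubles the x excursion
  both <- build_choice_trace(series, input_regressor = c("rel_adapt", "irrel_adapt"))
  ex <- tapply(both$x, both$input, function(v) diff(range(v)))
  expect_equal(unname(ex["rel_adapt"] / ex["irrel_adapt"]), 2, tolerance = 1e-9)

  # window restriction
  narrow <- build_choice_trace(series, window = c(200, 400))
  expect_true(all(narrow$t >= 200 & narrow$t <= 400))
})
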