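test_that("time shift is bacteria time minus phage time", {
  expect_identical(compute_time_shift(4, 10), 6)
  expect_identical(compute_time_shift(7, 7), 0)
  expect_identical(compute_time_shift(10, 4), -6)
})

test_that("mean infectivity averages the full clone panel per cell", {
  cfg <- synthetic_config("noise", n_populations = 1, treatments = "high",
                          seed = 2)
  tn <- generate_community(cfg)
  mi <- mean_infectivity(tn)
  expect_equal(nrow(mi), 36)
  expect_true(all(mi$n == 400))
  # all-ones / all-zeros tensors
  t1 <- data.table::copy(tn); t1$infected <- 1L
  expect_true(all(mean_infectivity(as_cross_infection_tensor(t1))$
                    mean_infectivity == 1))
  t0 <- data.table::copy(tn); t0$infected <- 0L
  expect_true(all(mean_infectivity(as_cross_infection_tensor(t0))$
                    mean_infectivity == 0))
  # constructed 20 x 20 block with 100 successes
  one <- tn[tn$population == "high_1" & tn$phage_time == 2 &
              tn$bacteria_time == 2]
  one$infected <- rep(c(1L, 0L), c(100, 300))
  one <- as_cross_infection_tensor(one)
  expect_equal(mean_infectivity(one)$mean_infectivity, 0.25)
})

test_that("time-shift model recovers a known slope with the F(1, n_pop-1) shape", {
  set.seed(10)
  tb <- sim_mean_table(slope = -0.05, pop_slope_sd = 0.005)
  fit <- fit_time_shift_model(tb, "high")
  expect_equal(fit$df, c(1, 5))
  expect_lt(fit$p_value, 0.05)
  expect_equal(fit$slope, -0.05, tolerance = 0.15)
  se <- stats::sd(fit$per_population$slope) / sqrt(6)
  expect_lt(abs(fit$slope - (-0.05)), 4 * se + 1e-3)
  # constant infectivity: slope and F collapse
  tbc <- sim_mean_table(slope = 0, noise_sd = 1e-9)
  fitc <- suppressWarnings(fit_time_shift_model(tbc, "high"))
  expect_lt(abs(fitc$slope), 1e-6)
  # preconditions
  expect_error(fit_time_shift_model(tb[tb$population == "high_1", ]),
               ">= 2 populations")
})

test_that("time-shift test holds its nominal size under a heterogeneous null", {
  set.seed(11)
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    tb <- sim_mean_table(slope = 0, pop_slope_sd = 0.01, noise_sd = 0.02)
    fit_time_shift_model(tb, "high")$p_value < 0.05
  }, logical(1))
  rate <- mean(rej)
  bound <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), bound + 1e-9)
})

test_that("range-FSD mean squares match the hand-computed decomposition", {
  # 6 x 6 table, phage-time means (.2,.6,.2,.6,.2,.6), no bacteria effect:
  # SS_phage = 6 * sum((mean_t - .4)^2) = 6 * 6 * .04 = 1.44, df = 5
  times <- seq(2, 12, 2)
  grid <- expand.grid(phage_time = times, bacteria_time = times)
  grid$mean_infectivity <- rep(c(0.2, 0.6), 3)[match(grid$phage_time, times)]
  grid$population <- "high_1"
  r <- range_fsd_anova(grid)
  expect_equal(r$ms_phage_time, 1.44 / 5)
  expect_equal(r$ms_bacteria_time, 0)
  expect_equal(r$ms_interaction, 0)
  # constant table: all mean squares vanish
  gc <- grid; gc$mean_infectivity <- 0.37
  rc <- range_fsd_anova(gc)
  expect_equal(rc$ms_phage_time, 0)
  expect_equal(rc$ms_bacteria_time, 0)
  # adding a pure time-shift trend inflates both main effects (the
  # documented confound motivating the joint interpretation rule)
  gt <- grid
  gt$mean_infectivity <- gt$mean_infectivity -
    0.02 * (gt$bacteria_time - gt$phage_time)
  rt <- range_fsd_anova(gt)
  expect_gt(rt$ms_phage_time, r$ms_phage_time)
  expect_gt(rt$ms_bacteria_time, r$ms_bacteria_time)
})

test_that("balanced two-way ANOVA decomposition is exact", {
  set.seed(12)
  times <- seq(2, 12, 2)
  grid <- expand.grid(phage_time = times, bacteria_time = times)
  grid$mean_infectivity <- runif(36)
  grid$population <- "p1"
  r <- range_fsd_anova(grid)
  ss_tot <- sum((grid$mean_infectivity - mean(grid$mean_infectivity))^2)
  ss_parts <- 5 * r$ms_phage_time + 5 * r$ms_bacteria_time +
    25 * r$ms_interaction
  expect_equal(ss_parts, ss_tot, tolerance = 1e-12)
})

test_that("Welch t reproduces the Welch-Satterthwaite formulas", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 4, p_value = 1))
  r0 <- welch_t(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(r0$t, 0); expect_equal(r0$p_value, 1)
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = 2)
    r <- welch_t(x, y)
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    expect_equal(r$t, (mean(x) - mean(y)) / sqrt(vx + vy))
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    expect_equal(r$df, df)
    expect_equal(r$p_value, 2 * stats::pt(-abs(r$t), df))
  }
})

test_that("Holm step-down decisions follow the sequential thresholds", {
  expect_equal(sequential_bonferroni(c(0.01, 0.04), 0.05), c(TRUE, TRUE))
  expect_equal(sequential_bonferroni(c(0.03, 0.04), 0.05), c(FALSE, FALSE))
  expect_equal(sequential_bonferroni(rep(1, 5)), rep(FALSE, 5))
  expect_equal(sequential_bonferroni(numeric(0)), logical(0))
  # monotone in p: rejections form a prefix of the sorted p-values
  set.seed(14)
  p <- runif(10)
  d <- sequential_bonferroni(p, 0.2)
  expect_true(all(diff(d[order(p)]) <= 0))
})
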