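test_that("the default design has the canonical dimensions", {
  cfg <- synthetic_config("noise", seed = 1)
  tn <- generate_community(cfg)
  expect_equal(length(unique(tn$population)), 12)
  per_pop <- tn[, .N, by = "population"]
  expect_true(all(per_pop$N == 14400))
  expect_setequal(unique(tn$treatment), c("high", "low"))
})

test_that("ard communities escalate clone ranges monotonically", {
  cfg <- synthetic_config("ard", n_populations = 1, treatments = "high",
                          noise = 0, seed = 3)
  tn <- generate_community(cfg)
  # mean infectivity of contemporary assays stays flat while the
  # time-shifted ones are asymmetric: past bacteria are easier targets
  mi <- mean_infectivity(tn)
  sh <- compute_time_shift(mi$phage_time, mi$bacteria_time)
  expect_gt(mean(mi$mean_infectivity[sh < 0]),
            mean(mi$mean_infectivity[sh > 0]))
  # fitted slope is negative
  cfg6 <- synthetic_config("ard", treatments = "high", noise = 0, seed = 3)
  fit <- fit_time_shift_model(mean_infectivity(generate_community(cfg6)),
                              "high")
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.05)
})

test_that("noise communities sit at an infection fraction of one half", {
  cfg <- synthetic_config("noise", n_populations = 2, treatments = "high",
                          seed = 4)
  tn <- generate_community(cfg)
  n <- nrow(tn)
  expect_lt(abs(mean(tn$infected) - 0.5), 2.58 * sqrt(0.25 / n))
})

test_that("specialism communities hold population means constant while clones cross", {
  cfg <- synthetic_config("specialism_fsd", n_populations = 1,
                          treatments = "high", noise = 0, seed = 5)
  tn <- generate_community(cfg)
  mi <- mean_infectivity(tn)
  # population mean infectivity is near-constant across all time pairs
  # (exact in expectation by the orthogonal-composition construction)
  expect_lt(stats::sd(mi$mean_infectivity), 0.05)
  fit <- fit_time_shift_model(mean_infectivity(generate_community(
    synthetic_config("specialism_fsd", treatments = "high", seed = 5))),
    "high")
  expect_gt(fit$p_value, 0.01)
  # clone-level reaction norms cross: inconsistency well above zero
  ip <- inconsistency_profile(tn)
  expect_gt(mean(ip$inconsistency_infectivity), 0.5)
})

test_that("tensors are byte-identical under a fixed config and seed", {
  cfg <- synthetic_config("mixed", n_populations = 2, seed = 6)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_tensor(generate_community(cfg), f1)
  write_tensor(generate_community(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(
    generate_community(cfg)$infected,
    generate_community(synthetic_config("mixed", n_populations = 2,
                                        seed = 7))$infected))
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synthetic_config("range_fsd", oscillation_amplitude = 0.9,
                                base_range = 0.5), "amplitude")
  expect_error(synthetic_config("ard", noise = 1.5), "probability")
  expect_error(synthetic_config("specialism_fsd", clones_per_time = 10),
               "divisible by 4")
  expect_error(synthetic_config("ard", times = c(4, 2)), "increasing")
})

test_that("tensors sampled from simulated trajectories carry the model's signal", {
  p <- eco_params()
  tr <- simulate_coevolution(p, n_events = 60, seed = 21,
                             init = list(u = 0.3, v = 0.5))
  # flip 0: outcomes within a time pair are Bernoulli draws from the
  # kernel; with a single strain per species all probabilities match
  tn <- sample_from_simulation(tr, times = c(10, 30, 50),
                               clones_per_time = 5, flip = 0, seed = 9)
  expect_s3_class(tn, "cross_infection_tensor")
  expect_equal(nrow(tn), 9 * 25)
  expect_error(sample_from_simulation(tr, times = c(10, 500)),
               "does not cover")
  # determinism
  tn2 <- sample_from_simulation(tr, times = c(10, 30, 50),
                                clones_per_time = 5, flip = 0, seed = 9)
  expect_identical(tn$infected, tn2$infected)
})
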