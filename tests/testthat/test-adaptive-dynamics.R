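test_that("singular point zeroes the gradients and matches a grid search", {
  p <- eco_params()
  sp <- find_singular_point(p)
  expect_false(is.null(sp))
  g <- selection_gradients(sp$traits, p, "analytic")
  expect_lt(max(abs(g)), 1e-8)
  # exhaustive coarse grid oracle: the root lies within one cell of the
  # grid minimiser of |g_h| + |g_p|
  gs <- seq(0.02, 0.98, length.out = 33)
  cell <- gs[2] - gs[1]
  best <- c(NA, NA); bestval <- Inf
  for (u in gs) for (v in gs) {
    val <- tryCatch({
      res <- endemic_equilibrium(trait_pair(u, v), p)
      if (!res$endemic) Inf else sum(abs(selection_gradients(
        trait_pair(u, v), p, "analytic")))
    }, error = function(e) Inf)
    if (val < bestval) { bestval <- val; best <- c(u, v) }
  }
  expect_lt(abs(sp$traits$u - best[1]), cell)
  expect_lt(abs(sp$traits$v - best[2]), cell)
})

test_that("cost-free parameters admit no interior singular point", {
  p <- eco_params(a_min = 3.4, a_max = 3.4, beta_max = 11, beta_min = 11)
  expect_null(find_singular_point(p))
})

test_that("classification is consistent with eigenvalues and curvatures", {
  p <- eco_params()
  # strong competition: the attractor is a convergence-stable ESS
  p_css <- set_param(p, "q", 3)
  sp <- classify_singular_point(find_singular_point(p_css), p_css)
  expect_equal(sp$classification, "CSS")
  expect_true(all(Re(sp$eigenvalues) < 0))
  expect_lt(sp$curv_host, 0)
  expect_lt(sp$curv_parasite, 0)
  # at the default parameters the point is convergence stable but the
  # host sits at a fitness minimum (branching point)
  sp2 <- classify_singular_point(find_singular_point(p), p)
  expect_equal(sp2$classification, "branching_host")
  expect_true(all(Re(sp2$eigenvalues) < 0))
  expect_gt(sp2$curv_host, 0)
  # beyond the Hopf the pair is complex with positive real part
  p_h <- set_param(p, "a_min", 2.2)
  sp3 <- classify_singular_point(find_singular_point(p_h), p_h)
  expect_equal(sp3$classification, "hopf_unstable")
  expect_gt(abs(Im(sp3$eigenvalues[1])), 0)
  expect_gt(max(Re(sp3$eigenvalues)), 0)
})

test_that("scan tracks the branch continuously and brackets the Hopf", {
  p <- eco_params()
  grid <- seq(1.6, 2.3, by = 0.05)
  sc <- scan_parameter(p, "a_min", grid)
  expect_equal(nrow(sc$points), length(grid))
  ok <- !is.na(sc$points$u)
  expect_true(all(ok))
  # tracked u* varies continuously off bifurcation brackets
  du <- abs(diff(sc$points$u))
  expect_lt(max(du / pmax(stats::median(du), 1e-4)), 10)
  hb <- sc$bifurcations[sc$bifurcations$type == "hopf", ]
  expect_equal(nrow(hb), 1)
  expect_true(hb$lower >= 2.0 && hb$upper <= 2.15)
  # bisection refinement preserves and narrows the bracket
  ref <- detect_hopf(sc)
  expect_equal(nrow(ref), 1)
  expect_gte(ref$lower, hb$lower)
  expect_lte(ref$upper, hb$upper)
  expect_lt(ref$upper - ref$lower, 1e-4 * diff(range(grid)))
  expect_error(scan_parameter(p, "a_min", numeric(0)), "empty")
  expect_error(scan_parameter(p, "nope", 1:3), "unknown parameter")
})

test_that("all-stable scans yield no Hopf bracket", {
  p <- eco_params()
  sc <- scan_parameter(p, "q", seq(3.5, 2.5, by = -0.25))
  expect_true(all(sc$points$classification == "CSS"))
  expect_equal(nrow(detect_hopf(sc)), 0)
})

test_that("simulator is deterministic and recovers pure ecology", {
  p <- eco_params()
  t1 <- simulate_coevolution(p, n_events = 25, seed = 7)
  t2 <- simulate_coevolution(p, n_events = 25, seed = 7)
  expect_identical(t1$event_log, t2$event_log)
  expect_identical(t1$host_density, t2$host_density)
  t3 <- simulate_coevolution(p, n_events = 25, seed = 8)
  expect_false(identical(t1$event_log, t3$event_log))
  # with mutation disabled, the final state is the resident equilibrium
  t0 <- simulate_coevolution(p, n_events = 0, seed = 1,
                             init = list(u = 0.3, v = 0.5))
  lat <- t0$host_lattice
  iu <- which.min(abs(lat - 0.3)); iv <- which.min(abs(lat - 0.5))
  res <- endemic_equilibrium(trait_pair(lat[iu], lat[iv]), p)
  expect_equal(t0$host_density[1, iu], res$X, tolerance = 1e-5)
  expect_equal(t0$parasite_density[1, iv], res$Y, tolerance = 1e-5)
  expect_equal(sum(t0$host_density[1, -iu]), 0)
  # non-negativity throughout
  expect_true(all(t1$host_density >= 0))
  expect_true(all(t1$parasite_density >= 0))
  # at most one new strain per event
  nh <- t1$event_log$n_host
  expect_true(all(diff(nh) <= 1))
})

test_that("regime classifier labels constructed trajectories correctly", {
  lat <- seq(0, 1, length.out = 51)
  mk <- function(series_u, series_v = NULL) {
    n <- length(series_u)
    H <- matrix(0, n, 51); P <- matrix(0, n, 51)
    for (i in seq_len(n)) {
      H[i, which.min(abs(lat - series_u[i]))] <- 1
      vv <- if (is.null(series_v)) series_u[i] else series_v[i]
      P[i, which.min(abs(lat - vv))] <- 1
    }
    structure(list(host_lattice = lat, parasite_lattice = lat,
                   host_density = H, parasite_density = P,
                   truncated = FALSE, host_extinct = FALSE,
                   parasite_extinct = FALSE,
                   params = eco_params()), class = "coevo_trajectory")
  }
  # constant at the top: maximised
  expect_equal(classify_regime(mk(rep(1, 100))), "range_maximised")
  expect_equal(classify_regime(mk(rep(0, 100), rep(0.2, 100))),
               "range_minimised")
  # synthetic sawtooth: cycles
  saw <- rep(c(seq(0.2, 0.7, by = 0.025), seq(0.7, 0.2, by = -0.025)), 4)
  expect_equal(classify_regime(mk(saw)), "cycles")
  # interior constant: ESS
  expect_equal(classify_regime(mk(rep(0.5, 100))), "intermediate_ESS")
  # two persistent host strains far apart: branching
  H <- matrix(0, 100, 51); P <- matrix(0, 100, 51)
  H[, 10] <- 0.5; H[, 20] <- 0.5; P[, 25] <- 1
  tr <- structure(list(host_lattice = lat, parasite_lattice = lat,
                       host_density = H, parasite_density = P,
                       truncated = FALSE, host_extinct = FALSE,
                       parasite_extinct = FALSE, params = eco_params()),
                  class = "coevo_trajectory")
  expect_equal(classify_regime(tr), "branching")
})

test_that("neutral host drift has no directional bias", {
  # costs off and parasite unable to invade: the host mean trait is a
  # reflected random walk; its mean displacement over seeds is ~ 0
  p <- eco_params(a_min = 2, a_max = 2, beta_max = 0.05, beta_min = 0.05,
                  alpha = 0.5)
  disp <- vapply(1:12, function(s) {
    tr <- simulate_coevolution(p, n_events = 40, n_strains = 21, seed = s,
                               relax_time = 50)
    mt <- mean_trait_series(tr)
    mt$u[nrow(mt)] - mt$u[1]
  }, numeric(1))
  step <- 1 / 20
  # Monte-Carlo bound: each event moves the mean by at most one step
  expect_lt(abs(mean(disp)), 3 * step * sqrt(40) / sqrt(12))
})

test_that("a branching-classified point yields coexisting host strains in simulation", {
  p1 <- set_param(set_param(eco_params(), "a_min", 2.0), "q", 1.5)
  sp <- classify_singular_point(find_singular_point(p1), p1)
  expect_equal(sp$classification, "branching_host")
  tr <- simulate_coevolution(p1, n_events = 800, seed = 11,
                             init = list(u = 0.15, v = 0.45))
  H <- tr$host_density[241:801, ]
  dimorphic <- mean(apply(H, 1, function(d) {
    tot <- sum(d)
    if (tot == 0) return(FALSE)
    big <- which(d >= 0.1 * tot)
    length(big) >= 2 && (max(big) - min(big)) > 2
  }))
  expect_gte(dimorphic, 0.25)
})
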