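test_that("cost functions interpolate between their extremes", {
  p <- eco_params(c_h = 1, c_p = 1)
  expect_equal(birth_rate(p$trait_lo, p), p$a_max)
  expect_equal(birth_rate(p$trait_hi, p), p$a_min)
  expect_equal(birth_rate(0.5, p), (p$a_max + p$a_min) / 2)
  expect_equal(max_transmission(p$trait_lo, p), p$beta_max)
  expect_equal(max_transmission(p$trait_hi, p), p$beta_min)
  expect_equal(max_transmission(0.5, p), (p$beta_max + p$beta_min) / 2)
  # strictly decreasing whenever there is a cost
  u <- seq(0, 1, 0.05)
  expect_true(all(diff(birth_rate(u, eco_params())) < 0))
  expect_true(all(diff(max_transmission(u, eco_params())) < 0))
  expect_error(birth_rate(1.2, p), "out of bounds")
})

test_that("infection kernel saturates, halves at u = v, and is monotone", {
  p <- eco_params(s_k = 0.05) # sharp kernel so saturation fits in-bounds
  v <- 0.9
  expect_lt(abs(transmission_rate(v - 10 * p$s_k, v, p) /
                  max_transmission(v, p) - 1), 1e-4)
  p <- eco_params()
  expect_equal(transmission_rate(v, v, p), max_transmission(v, p) / 2)
  # beta non-increasing in u; beta/beta0 non-decreasing in v (trait grid)
  g <- seq(0, 1, 0.02)
  for (vv in c(0.2, 0.5, 0.9))
    expect_true(all(diff(transmission_rate(g, vv, p)) <= 0))
  for (uu in c(0.2, 0.5, 0.9))
    expect_true(all(diff(transmission_rate(uu, g, p) /
                           max_transmission(g, p)) >= 0))
})

test_that("ecological derivatives vanish at the closed-form equilibria", {
  set.seed(41)
  for (i in 1:25) {
    cs <- random_endemic_case()
    # endemic closed form
    d <- eco_derivatives(cs$res$X, cs$res$Y, cs$tr, cs$p)
    expect_lt(max(abs(d)), 1e-9)
    # disease-free closed form
    a <- birth_rate(cs$tr$u, cs$p)
    d0 <- eco_derivatives((a - cs$p$b) / cs$p$q, 0, cs$tr, cs$p)
    expect_lt(max(abs(d0)), 1e-9)
    # extinction is absorbing
    expect_equal(unname(eco_derivatives(0, 0, cs$tr, cs$p)), c(0, 0))
  }
  expect_error(eco_derivatives(-1, 0.5, trait_pair(0.5, 0.5), eco_params()),
               "non-negative")
})

test_that("endemic equilibrium matches X* = (alpha+b)/beta and long-run ODE", {
  set.seed(42)
  cs <- random_endemic_case()
  p <- cs$p; tr <- cs$tr
  beta <- transmission_rate(tr$u, tr$v, p)
  expect_equal(cs$res$X, (p$alpha + p$b) / beta, tolerance = 1e-9)
  # numerical ODE oracle: converges to the returned state
  derivs <- function(t, y, parms)
    list(eco_derivatives(y[1], y[2], tr, p))
  a <- birth_rate(tr$u, p)
  y0 <- c((a - p$b) / (2 * p$q), 1e-3)
  sol <- deSolve::lsoda(y0, c(0, 3000), derivs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sol[nrow(sol), 2:3] - c(cs$res$X, cs$res$Y))), 1e-4)
  # below-threshold parasite goes extinct
  p2 <- eco_params(beta_max = 0.2, beta_min = 0.1)
  r2 <- endemic_equilibrium(trait_pair(0.3, 0.5), p2)
  expect_false(r2$endemic)
  expect_equal(r2$Y, 0)
  # non-viable host errors (constructed past the validator, which
  # otherwise guarantees a_min > b)
  p3 <- eco_params()
  p3$a_min <- 0.5
  expect_error(endemic_equilibrium(trait_pair(1, 0.5), p3), "extinct")
})

test_that("resident invasion fitnesses vanish at the resident traits", {
  set.seed(43)
  for (i in 1:25) {
    cs <- random_endemic_case()
    expect_lt(abs(invasion_fitness_host(cs$tr$u, cs$res, cs$p)), 1e-9)
    expect_lt(abs(invasion_fitness_parasite(cs$tr$v, cs$res, cs$p)), 1e-9)
  }
})

test_that("disease-free selection favours zero resistance; parasite fitness needs a parasite", {
  p <- eco_params(beta_max = 0.2, beta_min = 0.1)
  res <- endemic_equilibrium(trait_pair(0.4, 0.5), p)
  expect_false(res$endemic)
  g <- seq(0, 1, 0.01)
  s <- invasion_fitness_host(g, res, p)
  expect_equal(which.max(s), 1L) # maximised at trait_lo
  expect_error(invasion_fitness_parasite(0.5, res, p), "endemic")
})

test_that("parasite benefit without cost gives monotone invasion fitness", {
  p <- eco_params(beta_max = 9, beta_min = 9)
  res <- endemic_equilibrium(trait_pair(0.4, 0.5), p)
  expect_true(res$endemic)
  g <- seq(0.01, 0.99, 0.01)
  expect_true(all(diff(invasion_fitness_parasite(g, res, p)) > 0))
})

test_that("numeric selection gradients match the analytic derivatives", {
  set.seed(44)
  for (i in 1:50) {
    cs <- random_endemic_case()
    gn <- selection_gradients(cs$tr, cs$p, "numeric")
    ga <- selection_gradients(cs$tr, cs$p, "analytic")
    expect_lt(max(abs(gn - ga) / pmax(abs(ga), 1e-8)), 1e-6)
  }
})

test_that("cost-free evolution escalates both ranges", {
  p <- eco_params(a_min = 3.4, a_max = 3.4, beta_max = 11, beta_min = 11)
  for (u in c(0.2, 0.5)) for (v in c(0.4, 0.7)) {
    res <- endemic_equilibrium(trait_pair(u, v), p)
    if (!res$endemic) next
    g <- selection_gradients(trait_pair(u, v), p, "analytic")
    expect_gt(g[1], 0)
    expect_gt(g[2], 0)
  }
})

test_that("invasion-fitness sign agrees with the three-class ODE oracle", {
  set.seed(45)
  done <- 0
  while (done < 8) { # a deeper sweep runs in the acceptance suite
    cs <- random_endemic_case()
    kind <- if (done %% 2 == 0) "host" else "parasite"
    resident <- if (kind == "host") cs$tr$u else cs$tr$v
    mt <- min(max(resident + runif(1, -0.15, 0.15), 0.01), 0.99)
    s <- if (kind == "host") invasion_fitness_host(mt, cs$res, cs$p)
         else invasion_fitness_parasite(mt, cs$res, cs$p)
    if (abs(s) < 5e-2) next # skip near-neutral draws (sign is fragile)
    growth <- ode_invasion_sign(kind, mt, cs$res, cs$p)
    expect_equal(sign(growth), sign(s))
    done <- done + 1
  }
})
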