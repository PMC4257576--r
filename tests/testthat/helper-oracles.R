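# Shared fixtures and independent oracles used across the suite.

# random endemic parameter set + resident traits (rejection sampling)
random_endemic_case <- function() {
  repeat {
    p <- tryCatch(eco_params(
      q = runif(1, 0.5, 3), b = 1, alpha = runif(1, 0.5, 3),
      a_max = runif(1, 3, 8), a_min = runif(1, 1.3, 2.5),
      beta_max = runif(1, 6, 20), beta_min = runif(1, 2, 6),
      c_h = runif(1, 0.8, 2), c_p = runif(1, 0.5, 1.5),
      s_k = runif(1, 0.05, 0.2)), error = function(e) NULL)
    if (is.null(p)) next
    tr <- trait_pair(runif(1, 0.1, 0.7), runif(1, 0.2, 0.9))
    res <- tryCatch(endemic_equilibrium(tr, p), error = function(e) NULL)
    if (!is.null(res) && res$endemic && res$Y > 1e-3) return(list(p = p,
                                                                  tr = tr,
                                                                  res = res))
  }
}

# brute-force invasion oracle: add a rare mutant class to the resident
# ODE system and measure its realised per-capita growth
ode_invasion_sign <- function(kind, mutant_trait, res, p, t_end = 4) {
  u <- res$traits$u; v <- res$traits$v
  eps <- 1e-7
  if (kind == "host") {
    derivs <- function(t, y, parms) {
      X <- y[1]; Y <- y[2]; Xm <- y[3]
      Ntot <- X + Y + Xm
      dX <- X * (birth_rate(u, p) - p$q * Ntot - p$b -
                   transmission_rate(u, v, p) * Y)
      dY <- transmission_rate(u, v, p) * X * Y +
        transmission_rate(mutant_trait, v, p) * Xm * Y -
        (p$alpha + p$b) * Y
      dXm <- Xm * (birth_rate(mutant_trait, p) - p$q * Ntot - p$b -
                     transmission_rate(mutant_trait, v, p) * Y)
      list(c(dX, dY, dXm))
    }
    y0 <- c(res$X, res$Y, eps)
  } else {
    derivs <- function(t, y, parms) {
      X <- y[1]; Y <- y[2]; Ym <- y[3]
      Ntot <- X + Y + Ym
      dX <- X * (birth_rate(u, p) - p$q * Ntot - p$b -
                   transmission_rate(u, v, p) * Y -
                   transmission_rate(u, mutant_trait, p) * Ym)
      dY <- transmission_rate(u, v, p) * X * Y - (p$alpha + p$b) * Y
      dYm <- transmission_rate(u, mutant_trait, p) * X * Ym -
        (p$alpha + p$b) * Ym
      list(c(dX, dY, dYm))
    }
    y0 <- c(res$X, res$Y, eps)
  }
  sol <- deSolve::lsoda(y0, c(0, t_end), derivs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  unname(log(sol[nrow(sol), 4] / eps) / t_end)
}

# simulate a mean-infectivity table with a known time-shift slope and
# between-population slope heterogeneity (tests with known truth)
sim_mean_table <- function(slope = 0, pop_slope_sd = 0, phage_effect = 0,
                           noise_sd = 0.01, n_pop = 6,
                           times = seq(2, 12, 2), treatment = "high") {
  grid <- expand.grid(phage_time = times, bacteria_time = times)
  out <- lapply(seq_len(n_pop), function(i) {
    b_i <- slope + rnorm(1, 0, pop_slope_sd)
    sh <- grid$bacteria_time - grid$phage_time
    data.frame(population = paste0(treatment, "_", i),
               treatment = treatment,
               phage_time = grid$phage_time,
               bacteria_time = grid$bacteria_time,
               mean_infectivity = 0.5 + b_i * sh +
                 phage_effect * sin(grid$phage_time) +
                 rnorm(nrow(grid), 0, noise_sd),
               n = 400)
  })
  data.table::rbindlist(out)
}

# naive O(n^3) average-linkage agglomeration straight from the
# definition, as an independent clustering oracle
naive_average_linkage <- function(m, threshold) {
  d <- as.matrix(stats::dist(m))^2 / ncol(m)
  clusters <- as.list(seq_len(nrow(m)))
  repeat {
    best <- NULL; bestd <- Inf
    if (length(clusters) == 1) break
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < bestd - 1e-12) { bestd <- dij; best <- c(i, j) }
    }
    if (bestd > 1 - threshold) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  labels <- integer(nrow(m))
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  # canonical relabelling by first member
  first <- tapply(seq_along(labels), labels, min)
  as.integer(rank(first)[as.character(labels)])
}

# default model parameters used across model-half tests
default_params <- function() eco_params()
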