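#' Configuration for synthetic cross-infection communities
#'
#' Describes a synthetic serial-transfer study design: replicate
#' populations in two nutrient treatments, sampled at a set of transfers,
#' with a fixed number of phage and bacteria clones isolated per time and
#' every combination cross-assayed. Defaults mirror the canonical design:
#' 6 populations per treatment, transfers 2, 4, ..., 12, and 20 clones
#' per trophic level per time (so 120 clones per trophic level and
#' 20 x 20 x 36 = 14,400 assays per population).
#'
#' Regimes:
#' * `ard` - clone range levels drawn around a mean escalating linearly
#'   with time in both species; infection by the nested gene-for-gene
#'   rule (phage infects iff its infectivity level >= the bacterium's
#'   resistance level).
#' * `range_fsd` - same machinery but the mean range follows a sinusoid
#'   with no linear trend.
#' * `specialism_fsd` - matching-allele layer: clones carry one of four
#'   alleles; infection probability is `p_match` on a matching allele and
#'   `p_match - specialism_contrast` otherwise; allele frequencies cycle
#'   across times along orthogonal directions for the two species, so the
#'   population mean infectivity is constant across all time pairs by
#'   construction while clone reaction norms cross.
#' * `noise` - i.i.d. Bernoulli(0.5) outcomes.
#' * `mixed` - `ard` in the high-nutrient populations, `range_fsd` in the
#'   low-nutrient ones.
#'
#' All outcomes are finally flipped with probability `noise` (assay
#' error).
#'
#' @param regime one of `"ard"`, `"range_fsd"`, `"specialism_fsd"`,
#'   `"noise"`, `"mixed"`.
#' @param n_populations replicate populations per treatment.
#' @param times sampling transfers (ordered).
#' @param clones_per_time clones per trophic level per time.
#' @param escalation mean range increase per transfer (ard).
#' @param oscillation_amplitude,oscillation_period sinusoid of the mean
#'   range (range_fsd), in range units / transfers.
#' @param specialism_contrast probability gap between matching and
#'   non-matching alleles (specialism_fsd).
#' @param clone_sd spread of clone range levels around the time mean.
#' @param base_range mean range level at the first transfer.
#' @param noise flip probability applied to every assay outcome.
#' @param treatments treatment labels to generate.
#' @param seed integer seed; the tensor is reproducible from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(regime = c("ard", "range_fsd", "specialism_fsd",
                                        "noise", "mixed"),
                             n_populations = 6, times = seq(2, 12, by = 2),
                             clones_per_time = 20, escalation = 0.1,
                             oscillation_amplitude = 0.3,
                             oscillation_period = 10,
                             specialism_contrast = 0.6,
                             clone_sd = 0.15, base_range = 0.5,
                             noise = 0.02,
                             treatments = c("high", "low"), seed = 1) {
  regime <- match.arg(regime)
  cfg <- list(regime = regime, n_populations = as.integer(n_populations),
              times = as.numeric(times),
              clones_per_time = as.integer(clones_per_time),
              escalation = escalation,
              oscillation_amplitude = oscillation_amplitude,
              oscillation_period = oscillation_period,
              specialism_contrast = specialism_contrast,
              clone_sd = clone_sd, base_range = base_range, noise = noise,
              treatments = treatments, seed = as.integer(seed))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(cfg$n_populations >= 1, "n_populations must be >= 1")
  chk(length(cfg$times) >= 2 && !is.unsorted(cfg$times, strictly = TRUE),
      "times must be strictly increasing")
  chk(cfg$clones_per_time >= 2, "need >= 2 clones per time")
  chk(cfg$noise >= 0 && cfg$noise <= 1, "noise must be a probability")
  chk(cfg$specialism_contrast >= 0 && cfg$specialism_contrast <= 0.9,
      "specialism_contrast must lie in [0, 0.9]")
  chk(cfg$oscillation_amplitude >= 0 &&
        cfg$oscillation_amplitude <= cfg$base_range,
      "oscillation_amplitude must not exceed base_range")
  chk(cfg$oscillation_period > 0, "oscillation_period must be positive")
  chk(cfg$clone_sd > 0, "clone_sd must be positive")
  if (regime == "specialism_fsd")
    chk(cfg$clones_per_time %% 4 == 0,
        "specialism_fsd needs clones_per_time divisible by 4 (four alleles)")
  class(cfg) <- "synthetic_config"
  cfg
}

# mean range level at time t under a regime
range_mean <- function(cfg, t, regime) {
  switch(regime,
    ard = cfg$base_range + cfg$escalation * (t - cfg$times[1]),
    # cosine phase: symmetric about the window midpoint, so the linear
    # trend over the design is exactly zero (fluctuation without
    # escalation by construction)
    range_fsd = cfg$base_range + cfg$oscillation_amplitude *
      cos(2 * pi * (t - cfg$times[1]) / cfg$oscillation_period),
    stop("no range mean for regime ", regime))
}

# allele count vectors cycling along orthogonal directions so that the
# cross product (hence population mean infectivity) is constant
allele_counts <- function(cfg, t, species) {
  n <- cfg$clones_per_time
  base <- n / 4
  amp <- floor(base) # full-amplitude composition swings
  s <- cos(2 * pi * (t - cfg$times[1]) / cfg$oscillation_period)
  k <- round(amp * s)
  dirn <- if (species == "phage") c(1, 1, -1, -1) else c(1, -1, 1, -1)
  counts <- rep(floor(base), 4) + k * dirn
  counts[1] <- counts[1] + (n - sum(rep(floor(base), 4))) # absorb remainder
  stopifnot(all(counts >= 0), sum(counts) == n)
  counts
}

#' Generate a synthetic cross-infection community
#'
#' Builds a complete cross-infection tensor under the configured regime;
#' see [synthetic_config()] for the generative models. Deterministic
#' given the config (including its seed).
#'
#' @param cfg a [synthetic_config()].
#' @return a `cross_infection_tensor`.
#' @export
generate_community <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  out <- list()
  for (trt in cfg$treatments) {
    pop_regime <- if (cfg$regime == "mixed") {
      if (trt == "high") "ard" else "range_fsd"
    } else cfg$regime
    for (ip in seq_len(cfg$n_populations)) {
      popn <- paste0(trt, "_", ip)
      out[[length(out) + 1]] <- generate_population(cfg, popn, trt,
                                                   pop_regime)
    }
  }
  as_cross_infection_tensor(data.table::rbindlist(out))
}

generate_population <- function(cfg, popn, trt, regime) {
  times <- cfg$times
  nc <- cfg$clones_per_time
  nt <- length(times)
  grid <- data.table::CJ(phage_time = times, bacteria_time = times,
                         phage_clone = seq_len(nc),
                         bacteria_clone = seq_len(nc))
  if (regime %in% c("ard", "range_fsd")) {
    # clone range levels around the time mean; nested gene-for-gene rule
    v <- matrix(stats::rnorm(nt * nc, mean = range_mean(cfg, times, regime),
                             sd = cfg$clone_sd), nrow = nt)
    u <- matrix(stats::rnorm(nt * nc, mean = range_mean(cfg, times, regime),
                             sd = cfg$clone_sd), nrow = nt)
    ti <- match(grid$phage_time, times)
    bi <- match(grid$bacteria_time, times)
    lvl_v <- v[cbind(ti, grid$phage_clone)]
    lvl_u <- u[cbind(bi, grid$bacteria_clone)]
    infected <- as.integer(lvl_v >= lvl_u)
  } else if (regime == "specialism_fsd") {
    p_match <- 0.3 + cfg$specialism_contrast
    p_miss <- 0.3
    if (p_match > 1) { p_match <- 1; p_miss <- 1 - cfg$specialism_contrast }
    alle <- function(species) {
      m <- matrix(0L, nt, nc)
      for (i in seq_len(nt)) {
        counts <- allele_counts(cfg, times[i], species)
        m[i, ] <- sample(rep.int(1:4, counts))
      }
      m
    }
    ap <- alle("phage"); ab <- alle("bacteria")
    ti <- match(grid$phage_time, times)
    bi <- match(grid$bacteria_time, times)
    match_allele <- ap[cbind(ti, grid$phage_clone)] ==
      ab[cbind(bi, grid$bacteria_clone)]
    prob <- ifelse(match_allele, p_match, p_miss)
    infected <- stats::rbinom(nrow(grid), 1L, prob)
  } else { # noise
    infected <- stats::rbinom(nrow(grid), 1L, 0.5)
  }
  if (cfg$noise > 0) {
    flip <- stats::rbinom(nrow(grid), 1L, cfg$noise)
    infected <- as.integer(xor(infected, flip))
  }
  data.table::data.table(population = popn, treatment = trt,
                         phage_time = grid$phage_time,
                         bacteria_time = grid$bacteria_time,
                         phage_clone = grid$phage_clone,
                         bacteria_clone = grid$bacteria_clone,
                         infected = infected)
}

#' Sample a cross-infection tensor from a simulated trajectory
#'
#' Emulates the wet-lab time-shift assay on a [simulate_coevolution()]
#' run: at each requested mutation-event index, `clones_per_time` phage
#' and bacteria clones are drawn with probability proportional to strain
#' density, and every phage clone is assayed against every bacteria
#' clone across all sampled times. A phage with infectivity range `v`
#' infects a bacterium with resistance range `u` with probability
#' `logistic((v - u) / s_k)` (the model's kernel read as an infection
#' probability), and outcomes are then flipped with the noise
#' probability.
#'
#' @param traj a `coevo_trajectory`.
#' @param times event indices at which to sample (must be covered by the
#'   trajectory and have both species extant).
#' @param clones_per_time clones sampled per species per time.
#' @param flip assay-error flip probability.
#' @param seed integer seed.
#' @param population,treatment labels for the emitted tensor.
#' @return a `cross_infection_tensor` whose `phage_time`/`bacteria_time`
#'   are the event indices.
#' @export
sample_from_simulation <- function(traj, times, clones_per_time = 20,
                                   flip = 0.02, seed = 1,
                                   population = "sim_1",
                                   treatment = "high") {
  stopifnot(inherits(traj, "coevo_trajectory"))
  n_rec <- nrow(traj$host_density)
  if (any(times < 1 | times > n_rec - 1))
    stop("trajectory does not cover requested event indices", call. = FALSE)
  set.seed(seed)
  draw <- function(M, i, lat) {
    d <- M[i + 1, ] # row 1 is the pre-mutation state
    if (sum(d) == 0)
      stop("species extinct at event index ", i, call. = FALSE)
    lat[sample.int(length(d), clones_per_time, replace = TRUE, prob = d)]
  }
  u_cl <- lapply(times, function(i) draw(traj$host_density, i,
                                         traj$host_lattice))
  v_cl <- lapply(times, function(i) draw(traj$parasite_density, i,
                                         traj$parasite_lattice))
  grid <- data.table::CJ(phage_time = times, bacteria_time = times,
                         phage_clone = seq_len(clones_per_time),
                         bacteria_clone = seq_len(clones_per_time))
  ti <- match(grid$phage_time, times)
  bi <- match(grid$bacteria_time, times)
  v <- mapply(function(i, j) v_cl[[i]][j], ti, grid$phage_clone)
  u <- mapply(function(i, j) u_cl[[i]][j], bi, grid$bacteria_clone)
  prob <- logistic((v - u) / traj$params$s_k)
  infected <- stats::rbinom(nrow(grid), 1L, prob)
  if (flip > 0) {
    fl <- stats::rbinom(nrow(grid), 1L, flip)
    infected <- as.integer(xor(infected, fl))
  }
  as_cross_infection_tensor(data.table::data.table(
    population = population, treatment = treatment,
    phage_time = grid$phage_time, bacteria_time = grid$bacteria_time,
    phage_clone = grid$phage_clone, bacteria_clone = grid$bacteria_clone,
    infected = infected))
}
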