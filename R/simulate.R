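#' Stochastic trait-substitution simulation of range coevolution
#'
#' Discretises the trait interval into `n_strains` lattice values for
#' each species and simulates the coevolutionary process: starting from a
#' single resident strain per species, the multi-strain epidemiological
#' dynamics are integrated for a relaxation window, strains below the
#' extinction threshold are culled, and a mutation event introduces a
#' mutant one lattice step up or down from a parent strain chosen with
#' probability proportional to density (the mutating species is chosen by
#' the evolutionary speed weights, and mutation direction is uniform,
#' reflecting inward at the lattice bounds; a mutant landing on an
#' occupied strain adds to its density). The multi-strain dynamics
#' generalise the resident system: susceptible hosts of strain `i` and
#' infections by parasite strain `j` follow
#' \deqn{dX_i/dt = X_i (a(u_i) - qN - b - \sum_j \beta(u_i,v_j) Y_j)}
#' \deqn{dY_j/dt = Y_j (\sum_i \beta(u_i,v_j) X_i - \alpha - b)}
#' with `N` the total host density (susceptible plus infected).
#'
#' Host extinction terminates the run with a truncation flag; parasite
#' extinction sets a flag and continues host-only.
#'
#' @param p an [eco_params()] object.
#' @param n_events number of mutation events.
#' @param n_strains lattice size per species.
#' @param relax_time ecological integration horizon between mutation
#'   events (time units). In cyclic ecological regimes equilibrium is not
#'   reached and the end state is used as-is.
#' @param mutant_frac mutant introduction density as a fraction of the
#'   mutating species' mean resident density.
#' @param extinction_threshold absolute density below which a strain is
#'   culled before each mutation.
#' @param speeds relative mutation rates (host, parasite).
#' @param init optional list with starting traits `u`, `v` (defaults to
#'   the trait-box centre).
#' @param seed integer seed; the trajectory is fully reproducible from
#'   it.
#' @return a `coevo_trajectory`: `host_lattice`, `parasite_lattice`,
#'   `host_density`, `parasite_density` (event x strain matrices recorded
#'   after each event), `event_log` (data.table), flags
#'   `host_extinct`, `parasite_extinct`, `truncated`, plus `seed` and the
#'   config echo.
#' @export
simulate_coevolution <- function(p, n_events = 400, n_strains = 51,
                                 relax_time = 200, mutant_frac = 1e-3,
                                 extinction_threshold = 1e-6,
                                 speeds = c(1, 0.5), init = NULL, seed = 1) {
  stopifnot(n_strains >= 3, extinction_threshold > 0, mutant_frac > 0,
            all(speeds >= 0), sum(speeds) > 0)
  set.seed(seed)
  lattice <- seq(p$trait_lo, p$trait_hi, length.out = n_strains)
  B <- outer(lattice, lattice,
             function(u, v) transmission_rate(u, v, p)) # B[i, j] = beta(u_i, v_j)
  a_vec <- birth_rate(lattice, p)

  if (is.null(init))
    init <- list(u = (p$trait_lo + p$trait_hi) / 2,
                 v = (p$trait_lo + p$trait_hi) / 2)
  iu <- which.min(abs(lattice - init$u))
  iv <- which.min(abs(lattice - init$v))
  xh <- numeric(n_strains); xp <- numeric(n_strains)
  st0 <- endemic_equilibrium(trait_pair(lattice[iu], lattice[iv]), p)
  xh[iu] <- st0$X
  xp[iv] <- if (st0$endemic) st0$Y else 10 * extinction_threshold

  host_hist <- matrix(0, n_events + 1, n_strains)
  para_hist <- matrix(0, n_events + 1, n_strains)
  log_rows <- vector("list", n_events)
  host_extinct <- FALSE; parasite_extinct <- FALSE; truncated <- FALSE

  relax <- function(xh, xp) {
    ah <- which(xh > 0); ap <- which(xp > 0)
    state <- c(xh[ah], xp[ap])
    nh <- length(ah)
    Bs <- B[ah, ap, drop = FALSE]
    as <- a_vec[ah]
    derivs <- function(t, y, parms) {
      X <- y[seq_len(nh)]; Y <- y[-seq_len(nh)]
      Ntot <- sum(X) + sum(Y)
      infect <- if (length(Y)) drop(Bs %*% Y) else numeric(nh)
      dX <- X * (as - p$q * Ntot - p$b - infect)
      dY <- if (length(Y)) Y * (drop(crossprod(Bs, X)) - p$alpha - p$b)
            else numeric(0)
      list(c(dX, dY))
    }
    sol <- deSolve::lsoda(state, c(0, relax_time), derivs, NULL,
                          rtol = 1e-8, atol = 1e-10)
    yend <- pmax(sol[nrow(sol), -1], 0)
    xh[] <- 0; xp[] <- 0
    xh[ah] <- yend[seq_len(nh)]
    if (length(ap)) xp[ap] <- yend[-seq_len(nh)]
    list(xh = xh, xp = xp)
  }

  st <- relax(xh, xp)
  xh <- st$xh; xp <- st$xp
  host_hist[1, ] <- xh; para_hist[1, ] <- xp

  ev <- 0
  while (ev < n_events) {
    ev <- ev + 1
    # cull below-threshold strains
    xh[xh < extinction_threshold] <- 0
    xp[xp < extinction_threshold] <- 0
    if (all(xh == 0)) {
      host_extinct <- TRUE; truncated <- TRUE
      host_hist <- host_hist[seq_len(ev), , drop = FALSE]
      para_hist <- para_hist[seq_len(ev), , drop = FALSE]
      break
    }
    if (all(xp == 0)) parasite_extinct <- TRUE

    # choose mutating species by speed weights (parasite needs extant strains)
    w <- c(speeds[1], if (all(xp == 0)) 0 else speeds[2])
    species <- sample(c("host", "parasite"), 1, prob = w / sum(w))
    dens <- if (species == "host") xh else xp
    parent <- sample.int(length(dens), 1, prob = dens)
    dirn <- sample(c(-1L, 1L), 1)
    child <- parent + dirn
    if (child < 1L || child > n_strains) child <- parent - dirn # reflect
    mdens <- mutant_frac * mean(dens[dens > 0])
    if (species == "host") xh[child] <- xh[child] + mdens
    else xp[child] <- xp[child] + mdens

    st <- relax(xh, xp)
    xh <- st$xh; xp <- st$xp
    host_hist[ev + 1, ] <- xh
    para_hist[ev + 1, ] <- xp
    log_rows[[ev]] <- data.table::data.table(
      event = ev, species = species, parent = parent, child = child,
      direction = dirn,
      n_host = sum(xh > 0), n_parasite = sum(xp > 0))
  }

  structure(list(
    host_lattice = lattice, parasite_lattice = lattice,
    host_density = host_hist, parasite_density = para_hist,
    event_log = data.table::rbindlist(log_rows),
    host_extinct = host_extinct, parasite_extinct = parasite_extinct,
    truncated = truncated, seed = seed,
    config = list(n_events = n_events, n_strains = n_strains,
                  relax_time = relax_time, mutant_frac = mutant_frac,
                  extinction_threshold = extinction_threshold,
                  speeds = speeds, init = init),
    params = p), class = "coevo_trajectory")
}

#' @export
print.coevo_trajectory <- function(x, ...) {
  cat(sprintf("coevolution trajectory: %d events on a %d-strain lattice (seed %d)\n",
              nrow(x$host_density) - 1, length(x$host_lattice), x$seed))
  mt <- mean_trait_series(x)
  cat(sprintf("  final mean traits: u = %.3f, v = %.3f\n",
              utils::tail(mt$u, 1), utils::tail(mt$v, 1)))
  if (x$truncated) cat("  [truncated: host extinction]\n")
  else if (x$parasite_extinct) cat("  [parasite went extinct]\n")
  invisible(x)
}

#' Density-weighted mean trait series of a trajectory
#'
#' @param traj a `coevo_trajectory`.
#' @return data.frame with `event`, `u`, `v` (NA where the species is
#'   extinct).
#' @export
mean_trait_series <- function(traj) {
  wmean <- function(M, lat) {
    tot <- rowSums(M)
    ifelse(tot > 0, as.vector(M %*% lat) / tot, NA_real_)
  }
  data.frame(event = seq_len(nrow(traj$host_density)) - 1L,
             u = wmean(traj$host_density, traj$host_lattice),
             v = wmean(traj$parasite_density, traj$parasite_lattice))
}

# count alternating excursions of a series exceeding `amp` peak-to-trough
count_excursions <- function(x, amp) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(0L)
  n_exc <- 0L; dirn <- 0L
  runmin <- x[1]; runmax <- x[1]
  for (xi in x[-1]) {
    if (xi < runmin) runmin <- xi
    if (xi > runmax) runmax <- xi
    if (dirn >= 0 && xi >= runmin + amp) {
      # rose by >= amp from the running trough: upward excursion
      n_exc <- n_exc + 1L; dirn <- -1L; runmax <- xi
    } else if (dirn <= 0 && xi <= runmax - amp) {
      n_exc <- n_exc + 1L; dirn <- 1L; runmin <- xi
    }
  }
  n_exc
}

#' Classify the dynamical regime of a simulated trajectory
#'
#' Operates on the post-burn-in density-weighted mean-trait series:
#' * `extinct` - the trajectory was truncated by host extinction.
#' * `range_minimised` / `range_maximised` - both species' mean traits
#'   sit within 2 lattice steps of the trait bound for >= 90% of events.
#' * `cycles` - either species' mean-trait series shows >= 3 alternating
#'   excursions exceeding 5 lattice steps peak-to-trough.
#' * `branching` - >= 2 strains of one species, separated by more than 2
#'   lattice steps, each hold >= 10% of that species' density for >= 25%
#'   of events.
#' * `intermediate_ESS` - otherwise.
#'
#' @param traj a `coevo_trajectory`.
#' @param burn_in fraction of events discarded before classification.
#' @return a regime label (character scalar).
#' @export
classify_regime <- function(traj, burn_in = 0.2) {
  if (traj$truncated) return("extinct")
  n <- nrow(traj$host_density)
  keep <- seq.int(max(1L, floor(burn_in * n) + 1L), n)
  if (length(keep) < 3) stop("trajectory shorter than burn-in", call. = FALSE)
  lat <- traj$host_lattice
  step <- lat[2] - lat[1]
  mt <- mean_trait_series(traj)
  u <- mt$u[keep]; v <- mt$v[keep]

  near <- function(x, bound) abs(x - bound) <= 2 * step
  # at the lower bound the parasite's range rides a few kernel widths
  # above the host's (v - u ~ s_k), so v gets that allowance
  near_lo_v <- function(x) (x - min(lat)) <= 2 * step + 3 * traj$params$s_k
  if (mean(near(u, min(lat)) & near_lo_v(v), na.rm = TRUE) >= 0.9)
    return("range_minimised")
  if (mean(near(u, max(lat)) & near(v, max(lat)), na.rm = TRUE) >= 0.9)
    return("range_maximised")

  if (count_excursions(u, 5 * step) >= 3 || count_excursions(v, 5 * step) >= 3)
    return("cycles")

  branched <- function(M) {
    hits <- vapply(keep, function(i) {
      d <- M[i, ]; tot <- sum(d)
      if (tot == 0) return(FALSE)
      big <- which(d >= 0.1 * tot)
      length(big) >= 2 && (max(big) - min(big)) > 2
    }, logical(1))
    mean(hits) >= 0.25
  }
  if (branched(traj$host_density) || branched(traj$parasite_density))
    return("branching")
  "intermediate_ESS"
}
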