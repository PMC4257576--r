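#' Locate a coevolutionary singular point
#'
#' Finds an interior trait pair where both selection gradients vanish, by
#' damped Newton iteration on `(g_h, g_p)` with a finite-difference
#' Jacobian, starting from `guess`. If the iteration leaves the trait box
#' (or the endemic region) the function signals absence by returning
#' `NULL` — the caller then expects a boundary regime.
#'
#' @param p an [eco_params()] object.
#' @param guess starting `trait_pair` (default: centre of the trait box).
#' @param tol residual tolerance on `max(|g_h|, |g_p|)`.
#' @param max_iter Newton iteration cap.
#' @return a `singular_point` (traits, gradient_norm, unclassified) or
#'   `NULL` when no interior root is reachable from the guess.
#' @export
find_singular_point <- function(p, guess = NULL, tol = 1e-10,
                                max_iter = 60) {
  if (!is.null(guess)) {
    sp <- newton_singular(p, c(guess$u, guess$v), tol, max_iter)
    if (!is.null(sp)) return(sp)
  }
  # multistart: coarse residual grid, best cells first
  span <- p$trait_hi - p$trait_lo
  gs <- seq(p$trait_lo + 0.02 * span, p$trait_hi - 0.02 * span,
            length.out = 13)
  cand <- expand.grid(u = gs, v = gs)
  resid <- vapply(seq_len(nrow(cand)), function(i) {
    g <- tryCatch({
      tr <- trait_pair(cand$u[i], cand$v[i])
      res <- endemic_equilibrium(tr, p)
      if (!res$endemic) return(NA_real_)
      sum(abs(analytic_gradients(tr, res, p)))
    }, error = function(e) NA_real_)
    g
  }, numeric(1))
  ord <- order(resid)
  for (i in ord[seq_len(min(6, sum(!is.na(resid))))]) {
    sp <- newton_singular(p, c(cand$u[i], cand$v[i]), tol, max_iter)
    if (!is.null(sp)) return(sp)
  }
  NULL
}

# Damped Newton iteration on the analytic selection gradients; iterates
# are clamped to the (slightly shrunken) trait box rather than failing,
# so near-boundary roots remain reachable.
newton_singular <- function(p, x, tol = 1e-10, max_iter = 60) {
  span <- p$trait_hi - p$trait_lo
  eps <- 1e-7 * span
  margin <- 1e-7 * span
  lo <- p$trait_lo + margin; hi <- p$trait_hi - margin
  grad_at <- function(x) {
    tr <- trait_pair(x[1], x[2])
    res <- tryCatch(endemic_equilibrium(tr, p), error = function(e) NULL)
    if (is.null(res) || !res$endemic) return(NULL)
    analytic_gradients(tr, res, p)
  }
  x <- pmin(pmax(x, lo), hi)
  stuck <- 0L
  for (it in seq_len(max_iter)) {
    g <- grad_at(x)
    if (is.null(g)) return(NULL)
    if (max(abs(g)) < tol) {
      # a clamped pseudo-root pinned to the box edge is not an interior
      # singular point
      if (any(x < p$trait_lo + 1e-5 * span) ||
          any(x > p$trait_hi - 1e-5 * span)) return(NULL)
      return(structure(list(traits = trait_pair(x[1], x[2]),
                            gradient_norm = max(abs(g)),
                            classification = NA_character_,
                            eigenvalues = NULL),
                       class = "singular_point"))
    }
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xm <- x
      xp[j] <- min(xp[j] + eps, hi); xm[j] <- max(xm[j] - eps, lo)
      gp <- grad_at(xp); gm <- grad_at(xm)
      if (is.null(gp) || is.null(gm)) return(NULL)
      J[, j] <- (gp - gm) / (xp[j] - xm[j])
    }
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lim <- 0.2 * span
    if (max(abs(step)) > lim) step <- step * lim / max(abs(step))
    xn <- pmin(pmax(x + step, lo), hi)
    if (max(abs(xn - x)) < 1e-14) {
      stuck <- stuck + 1L
      if (stuck > 2L) return(NULL) # pinned to the box edge, no root here
    } else stuck <- 0L
    x <- xn
  }
  NULL
}

#' Locate all distinct singular points on a coarse multistart
#'
#' Runs the Newton iteration from every cell of a coarse trait grid and
#' deduplicates converged roots; useful when a stable/unstable pair
#' coexists.
#'
#' @inheritParams find_singular_point
#' @param n_starts grid resolution per trait axis.
#' @return list of `singular_point` objects (possibly empty).
#' @export
find_singular_points <- function(p, n_starts = 9, tol = 1e-10) {
  span <- p$trait_hi - p$trait_lo
  gs <- seq(p$trait_lo + 0.02 * span, p$trait_hi - 0.02 * span,
            length.out = n_starts)
  roots <- list()
  for (u0 in gs) for (v0 in gs) {
    sp <- newton_singular(p, c(u0, v0), tol)
    if (is.null(sp)) next
    dup <- any(vapply(roots, function(r) {
      max(abs(c(r$traits$u - sp$traits$u, r$traits$v - sp$traits$v))) <
        1e-5 * span
    }, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- sp
  }
  roots
}

#' @export
print.singular_point <- function(x, ...) {
  cat(sprintf("singular point: u* = %.5f, v* = %.5f (|g| = %.2e)\n",
              x$traits$u, x$traits$v, x$gradient_norm))
  if (!is.na(x$classification)) {
    cat(sprintf("  classification: %s\n", x$classification))
    ev <- x$eigenvalues
    cat(sprintf("  eigenvalues: %.4g%+.4gi, %.4g%+.4gi\n",
                Re(ev[1]), Im(ev[1]), Re(ev[2]), Im(ev[2])))
  }
  invisible(x)
}

# Weighted canonical trait dynamics: du/dt, dv/dt proportional to the
# selection gradients scaled by evolutionary speed times the density of
# the evolving population (mutation supply).
weighted_gradient_map <- function(u, v, p, speeds) {
  tr <- trait_pair(u, v)
  res <- endemic_equilibrium(tr, p)
  if (!res$endemic) return(NULL)
  g <- analytic_gradients(tr, res, p)
  c(speeds[1] * res$X * g[1], speeds[2] * res$Y * g[2])
}

#' Classify a singular point
#'
#' Builds the Jacobian of the weighted trait dynamics (selection gradients
#' scaled by evolutionary speeds times the evolving population's density)
#' by central differences, and combines convergence stability (eigenvalue
#' real parts) with evolutionary stability per species (second derivative
#' of invasion fitness in the mutant trait):
#' * `CSS` — both eigenvalue real parts negative, both second derivatives
#'   negative: a convergence-stable ESS.
#' * `branching_host` / `branching_parasite` — convergence stable but the
#'   named species sits at a fitness minimum (positive second derivative).
#' * `hopf_unstable` — complex eigenvalue pair with positive real part:
#'   the point spins off coevolutionary range cycles.
#' * `repeller` — real eigenvalue(s) with positive real part.
#'
#' @param sp a `singular_point` from [find_singular_point()].
#' @param p an [eco_params()] object.
#' @param speeds length-2 positive weights: relative evolutionary rates of
#'   host and parasite.
#' @param h step for the Jacobian / curvature differences (trait units).
#' @return the `singular_point` with `classification`, `eigenvalues`, and
#'   second derivatives (`curv_host`, `curv_parasite`) filled in.
#' @export
classify_singular_point <- function(sp, p, speeds = c(1, 0.5), h = 1e-5) {
  stopifnot(inherits(sp, "singular_point"))
  u <- sp$traits$u; v <- sp$traits$v
  # difference stencils are shifted inward so near-boundary points stay
  # evaluable
  clamp <- function(x) pmin(pmax(x, p$trait_lo), p$trait_hi)
  J <- matrix(NA_real_, 2, 2)
  f0 <- weighted_gradient_map(u, v, p, speeds)
  if (is.null(f0)) stop("singular point not in the endemic region")
  up <- clamp(u + h); um <- clamp(u - h)
  fp <- weighted_gradient_map(up, v, p, speeds)
  fm <- weighted_gradient_map(um, v, p, speeds)
  J[, 1] <- (fp - fm) / (up - um)
  vp <- clamp(v + h); vm <- clamp(v - h)
  fp <- weighted_gradient_map(u, vp, p, speeds)
  fm <- weighted_gradient_map(u, vm, p, speeds)
  J[, 2] <- (fp - fm) / (vp - vm)
  if (any(!is.finite(J))) stop("degenerate (singular) Jacobian")
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)

  res <- endemic_equilibrium(sp$traits, p)
  hc <- 1e-4 * (p$trait_hi - p$trait_lo)
  cu <- min(max(u, p$trait_lo + hc), p$trait_hi - hc)
  cv <- min(max(v, p$trait_lo + hc), p$trait_hi - hc)
  curv_h <- (invasion_fitness_host(cu + hc, res, p) -
               2 * invasion_fitness_host(cu, res, p) +
               invasion_fitness_host(cu - hc, res, p)) / hc^2
  curv_p <- (invasion_fitness_parasite(cv + hc, res, p) -
               2 * invasion_fitness_parasite(cv, res, p) +
               invasion_fitness_parasite(cv - hc, res, p)) / hc^2

  re <- Re(ev)
  complex_pair <- abs(Im(ev[1])) > 1e-12
  conv_stable <- all(re < 0)
  cls <- if (!conv_stable && complex_pair) {
    "hopf_unstable"
  } else if (!conv_stable) {
    "repeller"
  } else if (curv_h > 0) {
    "branching_host"
  } else if (curv_p > 0) {
    "branching_parasite"
  } else {
    "CSS"
  }
  sp$classification <- cls
  sp$eigenvalues <- ev
  sp$jacobian <- J
  sp$curv_host <- curv_h
  sp$curv_parasite <- curv_p
  sp$speeds <- speeds
  sp
}
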