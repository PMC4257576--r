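#' Ecological derivatives of the SI model
#'
#' Resident dynamics of susceptible hosts `X` and infected hosts `Y`:
#' \deqn{dX/dt = X (a(u) - q(X+Y)) - bX - \beta(u,v) X Y}
#' \deqn{dY/dt = \beta(u,v) X Y - (\alpha + b) Y}
#' Crowding reduces births only; infected hosts do not reproduce and there
#' is no recovery.
#'
#' @param X,Y non-negative densities of susceptible and infected hosts.
#' @param traits a `trait_pair` (or a list with elements `u`, `v`).
#' @param p an [eco_params()] object.
#' @return numeric vector `c(dX, dY)`.
#' @export
eco_derivatives <- function(X, Y, traits, p) {
  if (X < 0 || Y < 0) stop("densities must be non-negative", call. = FALSE)
  a <- birth_rate(traits$u, p)
  beta <- transmission_rate(traits$u, traits$v, p)
  c(dX = X * (a - p$q * (X + Y)) - p$b * X - beta * X * Y,
    dY = beta * X * Y - (p$alpha + p$b) * Y)
}

#' Host and parasite trait pair
#'
#' @param u host resistance range.
#' @param v parasite infectivity range.
#' @param p optionally, an [eco_params()] object to bounds-check against.
#' @return a `trait_pair` list.
#' @export
trait_pair <- function(u, v, p = NULL) {
  if (!is.null(p)) {
    u <- check_trait(u, p, "u")
    v <- check_trait(v, p, "v")
  }
  structure(list(u = u, v = v), class = "trait_pair")
}

#' Resident ecological equilibrium
#'
#' Closed-form equilibrium of the resident SI dynamics. The disease-free
#' host density is `X_df = (a(u) - b) / q`. The parasite persists iff its
#' invasion threshold is met there, `beta(u,v) * X_df > alpha + b`; then
#' \deqn{X^* = (\alpha + b)/\beta, \quad Y^* = (a(u) - b - qX^*)/(q + \beta).}
#'
#' @inheritParams eco_derivatives
#' @return a `resident_state` list with `traits`, `X`, `Y`, `endemic`.
#' @export
endemic_equilibrium <- function(traits, p) {
  a <- birth_rate(traits$u, p)
  if (a <= p$b)
    stop("host not viable: a(u) <= b, host goes extinct", call. = FALSE)
  beta <- transmission_rate(traits$u, traits$v, p)
  X_df <- (a - p$b) / p$q
  if (beta * X_df > p$alpha + p$b) {
    X <- (p$alpha + p$b) / beta
    Y <- (a - p$b - p$q * X) / (p$q + beta)
    endemic <- TRUE
  } else {
    X <- X_df
    Y <- 0
    endemic <- FALSE
  }
  structure(list(traits = traits, X = X, Y = Y, endemic = endemic),
            class = "resident_state")
}

#' @export
print.resident_state <- function(x, ...) {
  cat(sprintf("resident (u = %.4f, v = %.4f): X* = %.5f, Y* = %.5f [%s]\n",
              x$traits$u, x$traits$v, x$X, x$Y,
              if (x$endemic) "endemic" else "disease-free"))
  invisible(x)
}

check_resident <- function(res, p, need_endemic = FALSE, tol = 1e-6) {
  stopifnot(inherits(res, "resident_state"))
  d <- eco_derivatives(res$X, res$Y, res$traits, p)
  if (max(abs(d)) > tol)
    stop("resident state is not at ecological equilibrium", call. = FALSE)
  if (need_endemic && (!res$endemic || res$Y <= 0))
    stop("resident must be endemic (parasite present)", call. = FALSE)
  invisible(res)
}

#' Invasion fitness of a rare mutant host
#'
#' Per-capita initial growth rate of a rare host mutant with resistance
#' range `u_m` in the resident's equilibrium environment:
#' \deqn{s(u_m) = a(u_m) - q(X^* + Y^*) - b - \beta(u_m, v) Y^*.}
#' Vanishes at `u_m = u` (resident neutrality).
#'
#' @param u_m mutant host trait(s).
#' @param res a `resident_state` from [endemic_equilibrium()].
#' @param p an [eco_params()] object.
#' @return growth rate(s).
#' @export
invasion_fitness_host <- function(u_m, res, p) {
  check_resident(res, p)
  birth_rate(u_m, p) - p$q * (res$X + res$Y) - p$b -
    transmission_rate(u_m, res$traits$v, p) * res$Y
}

#' Invasion fitness of a rare mutant parasite
#'
#' \deqn{r(v_m) = \beta(u, v_m) X^* - (\alpha + b),} zero at `v_m = v` for
#' an endemic resident.
#'
#' @param v_m mutant parasite trait(s).
#' @inheritParams invasion_fitness_host
#' @return growth rate(s).
#' @export
invasion_fitness_parasite <- function(v_m, res, p) {
  check_resident(res, p, need_endemic = TRUE)
  transmission_rate(res$traits$u, v_m, p) * res$X - (p$alpha + p$b)
}

#' Selection gradients of the coevolving ranges
#'
#' Derivatives of the invasion fitnesses with respect to the mutant trait,
#' evaluated at the resident: `g_h = ds/du_m |_{u_m = u}` and
#' `g_p = dr/dv_m |_{v_m = v}`. Computed by central differences with step
#' `h_grad` (default 1e-5 trait units) or from the closed-form derivatives.
#'
#' @inheritParams eco_derivatives
#' @param method `"numeric"` (central differences) or `"analytic"`.
#' @param h_grad finite-difference step in trait units.
#' @return numeric vector `c(g_h, g_p)`.
#' @export
selection_gradients <- function(traits, p, method = c("numeric", "analytic"),
                                h_grad = 1e-5) {
  method <- match.arg(method)
  res <- endemic_equilibrium(traits, p)
  if (!res$endemic)
    stop("no endemic equilibrium at these traits; gradients undefined",
         call. = FALSE)
  if (method == "numeric") {
    u <- traits$u; v <- traits$v
    hu <- min(h_grad, u - p$trait_lo, p$trait_hi - u)
    hv <- min(h_grad, v - p$trait_lo, p$trait_hi - v)
    if (hu <= 0 || hv <= 0)
      stop("traits on the boundary: use analytic gradients", call. = FALSE)
    g_h <- (invasion_fitness_host(u + hu, res, p) -
              invasion_fitness_host(u - hu, res, p)) / (2 * hu)
    g_p <- (invasion_fitness_parasite(v + hv, res, p) -
              invasion_fitness_parasite(v - hv, res, p)) / (2 * hv)
  } else {
    g <- analytic_gradients(traits, res, p)
    g_h <- g[1]; g_p <- g[2]
  }
  c(g_h = unname(g_h), g_p = unname(g_p))
}

# Closed-form mutant-trait derivatives of s and r at the resident.
analytic_gradients <- function(traits, res, p) {
  u <- traits$u; v <- traits$v
  span <- p$trait_hi - p$trait_lo
  zu <- scale_trait(u, p); zv <- scale_trait(v, p)
  a_prime <- -(p$a_max - p$a_min) * p$c_h * zu^(p$c_h - 1) / span
  b0 <- max_transmission(v, p)
  b0_prime <- -(p$beta_max - p$beta_min) * p$c_p * zv^(p$c_p - 1) / span
  sig <- logistic((v - u) / p$s_k)
  dsig <- sig * (1 - sig) / p$s_k
  g_h <- a_prime + b0 * dsig * res$Y
  g_p <- (b0_prime * sig + b0 * dsig) * res$X
  c(g_h, g_p)
}
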