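#' Ecological and coevolutionary model parameters
#'
#' Constructs the parameter set for the susceptible-infected (SI) model of
#' host resistance range (`u`) and parasite infectivity range (`v`)
#' coevolution. Hosts with a broader resistance range pay a birth-rate cost
#' (birth rate falls from `a_max` at minimal range to `a_min` at maximal
#' range); parasites with a broader infectivity range pay a transmission cost
#' (maximum transmission falls from `beta_max` to `beta_min`). The infection
#' kernel is a logistic sigmoid in `(v - u) / s_k`, so hosts with higher `u`
#' resist stronger parasites and parasites with higher `v` infect stronger
#' hosts.
#'
#' @param q crowding coefficient reducing births (per density per time).
#' @param b natural death rate (per time).
#' @param alpha additional infection-induced mortality (per time).
#' @param a_max birth rate of a fully susceptible host (per time).
#' @param a_min birth rate of a maximally resistant host (per time);
#'   `a_min` is the cost-severity knob (lower `a_min` = costlier resistance).
#' @param beta_max maximum transmission coefficient of a narrowest-range
#'   parasite (per density per time).
#' @param beta_min maximum transmission coefficient of a broadest-range
#'   parasite.
#' @param c_h,c_p cost-curvature exponents (> 0); 1 is a linear cost,
#'   values > 1 accelerate, values < 1 decelerate.
#' @param s_k infection-kernel steepness in trait units (smaller = sharper
#'   range boundary).
#' @param trait_lo,trait_hi bounds of the trait interval for `u` and `v`.
#'
#' @return An object of class `eco_params` (a validated named list).
#' @examples
#' p <- eco_params()
#' birth_rate(0, p)      # a_max: no cost at minimal range
#' birth_rate(1, p)      # a_min: full cost at maximal range
#' @export
eco_params <- function(q = 1, b = 1, alpha = 1.7,
                       a_max = 3.4, a_min = 2,
                       beta_max = 11, beta_min = 6.8,
                       c_h = 1.3, c_p = 0.7,
                       s_k = 0.11, trait_lo = 0, trait_hi = 1) {
  p <- list(q = q, b = b, alpha = alpha, a_max = a_max, a_min = a_min,
            beta_max = beta_max, beta_min = beta_min, c_h = c_h, c_p = c_p,
            s_k = s_k, trait_lo = trait_lo, trait_hi = trait_hi)
  p <- lapply(p, as.numeric)
  class(p) <- "eco_params"
  validate_eco_params(p)
  p
}

#' @rdname eco_params
#' @param p an `eco_params` object to validate.
#' @export
validate_eco_params <- function(p) {
  stopifnot(inherits(p, "eco_params"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  with(p, {
    chk(all(vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                     is.finite(x), logical(1))),
        "all parameters must be finite scalars")
    chk(a_max >= a_min, "a_max must be >= a_min")
    chk(a_min > b, "a_min must exceed the death rate b (host viability)")
    chk(b > 0, "b must be positive")
    chk(beta_max >= beta_min, "beta_max must be >= beta_min")
    chk(beta_min > 0, "beta_min must be positive")
    chk(q > 0, "q must be positive")
    chk(alpha >= 0, "alpha must be non-negative")
    chk(s_k > 0, "s_k must be positive")
    chk(c_h > 0 && c_p > 0, "cost exponents must be positive")
    chk(trait_lo < trait_hi, "trait_lo must be below trait_hi")
  })
  invisible(p)
}

#' @export
print.eco_params <- function(x, ...) {
  cat("SI range-coevolution parameters:\n")
  cat(sprintf("  demography: a in [%g, %g] (c_h = %g), b = %g, q = %g\n",
              x$a_min, x$a_max, x$c_h, x$b, x$q))
  cat(sprintf("  infection:  beta0 in [%g, %g] (c_p = %g), alpha = %g, s_k = %g\n",
              x$beta_min, x$beta_max, x$c_p, x$alpha, x$s_k))
  cat(sprintf("  traits:     u, v in [%g, %g]\n", x$trait_lo, x$trait_hi))
  invisible(x)
}

check_trait <- function(x, p, what = "trait") {
  if (any(x < p$trait_lo - 1e-12 | x > p$trait_hi + 1e-12))
    stop(sprintf("%s out of bounds [%g, %g]", what, p$trait_lo, p$trait_hi),
         call. = FALSE)
  pmin(pmax(x, p$trait_lo), p$trait_hi)
}

scale_trait <- function(x, p) (x - p$trait_lo) / (p$trait_hi - p$trait_lo)

#' Host birth rate under the resistance-range cost
#'
#' `a(u) = a_max - (a_max - a_min) * z^c_h` with `z` the position of `u` in
#' the trait interval: strictly decreasing in `u` whenever `a_max > a_min`.
#'
#' @param u host resistance range(s), within the trait interval.
#' @param p an [eco_params()] object.
#' @return per-capita birth rate(s).
#' @export
birth_rate <- function(u, p) {
  u <- check_trait(u, p, "u")
  p$a_max - (p$a_max - p$a_min) * scale_trait(u, p)^p$c_h
}

#' Maximum transmission under the infectivity-range cost
#'
#' `beta0(v) = beta_max - (beta_max - beta_min) * z^c_p`: broader-range
#' parasites transmit less well on any single host.
#'
#' @param v parasite infectivity range(s).
#' @inheritParams birth_rate
#' @return transmission coefficient(s).
#' @export
max_transmission <- function(v, p) {
  v <- check_trait(v, p, "v")
  p$beta_max - (p$beta_max - p$beta_min) * scale_trait(v, p)^p$c_p
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Pairwise transmission rate (infection kernel)
#'
#' `beta(u, v) = beta0(v) * logistic((v - u) / s_k)`: increasing in the
#' trait difference `v - u`, equal to half the maximum at `v = u`, and
#' saturating at `beta0(v)` when the parasite's range far exceeds the
#' host's resistance.
#'
#' @param u host resistance range(s).
#' @param v parasite infectivity range(s).
#' @inheritParams birth_rate
#' @return transmission coefficient(s), recycled over `u` and `v`.
#' @export
transmission_rate <- function(u, v, p) {
  u <- check_trait(u, p, "u")
  v <- check_trait(v, p, "v")
  max_transmission(v, p) * logistic((v - u) / p$s_k)
}
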