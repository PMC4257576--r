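# End state of the deterministic weighted trait flow, used to label
# boundary regimes when no interior singular point exists.
trait_flow_end <- function(p, speeds = c(1, 0.5), start = NULL,
                           n_steps = 30000) {
  mid <- (p$trait_lo + p$trait_hi) / 2
  x <- if (is.null(start)) c(mid, mid) else c(start$u, start$v)
  lo <- p$trait_lo + 1e-6; hi <- p$trait_hi - 1e-6
  stalled <- 0L; exited <- FALSE
  for (i in seq_len(n_steps)) {
    f <- tryCatch(weighted_gradient_map(x[1], x[2], p, speeds),
                  error = function(e) NULL)
    if (is.null(f)) { exited <- TRUE; break } # crossed the endemic boundary
    dt <- min(0.05, 0.01 / max(abs(f), 1e-9))
    xn <- pmin(pmax(x + dt * f, lo), hi)
    # pinned at a box corner: converged
    if (max(abs(xn - x)) < 1e-12) {
      stalled <- stalled + 1L
      if (stalled > 20L) { x <- xn; break }
    } else stalled <- 0L
    x <- xn
  }
  out <- trait_pair(x[1], x[2])
  attr(out, "exited_endemic") <- exited
  out
}

# Map a classified singular point (or its absence) to a regime label.
# Regimes describe where the coevolutionary attractor lies: a stable
# point pinned to the trait bounds is a boundary regime even though it
# is formally a CSS/branching point, and an unstable focus is `cycles`
# only while its limit cycle is bounded (beyond the homoclinic loss of
# the cycle the flow escapes to a boundary regime). The parasite's range
# is allowed to ride a few kernel widths above the host's at the lower
# bound, since v - u ~ s_k is what "both ranges minimised" looks like
# under a sigmoidal infection kernel.
regime_label <- function(sp, p, speeds, boundary_margin = 0.04) {
  span <- p$trait_hi - p$trait_lo
  near_lo <- function(x) (x - p$trait_lo) <= boundary_margin * span
  near_hi <- function(x) (p$trait_hi - x) <= boundary_margin * span
  near_lo_v <- function(v) (v - p$trait_lo) <=
    boundary_margin * span + 3 * p$s_k
  flow_label <- function(start, n_steps, interior) {
    fe <- trait_flow_end(p, speeds, start = start, n_steps = n_steps)
    if (near_hi(fe$u) && near_hi(fe$v)) "range_maximised"
    else if (near_lo(fe$u) && near_lo_v(fe$v)) "range_minimised"
    else if (isTRUE(attr(fe, "exited_endemic"))) {
      # the host out-ran the parasite's persistence boundary; label by
      # where the host ended up
      if (fe$u >= (p$trait_lo + p$trait_hi) / 2) "range_maximised"
      else "range_minimised"
    }
    else interior
  }
  if (is.null(sp))
    return(flow_label(NULL, 30000, "intermediate_ESS"))
  off <- function(d) trait_pair(
    min(sp$traits$u + d * span, p$trait_hi),
    min(sp$traits$v + d * span, p$trait_hi))
  switch(sp$classification,
    hopf_unstable = flow_label(off(0.01), 30000, "cycles"),
    repeller = flow_label(NULL, 30000, "intermediate_ESS"),
    branching_host = ,
    branching_parasite = ,
    CSS = {
      if (near_lo(sp$traits$u) && near_lo_v(sp$traits$v)) "range_minimised"
      else if (near_hi(sp$traits$u) && near_hi(sp$traits$v)) "range_maximised"
      else if (sp$classification == "CSS") "intermediate_ESS"
      else "branching"
    },
    "intermediate_ESS")
}

#' Replace one model parameter, re-validating the set
#'
#' @param p an [eco_params()] object.
#' @param name parameter name.
#' @param value new value.
#' @return the modified, validated `eco_params` object.
#' @export
set_param <- function(p, name, value) {
  if (!name %in% names(p)) stop("unknown parameter: ", name, call. = FALSE)
  p[[name]] <- value
  validate_eco_params(p)
  p
}

#' Track the singular point along a parameter grid
#'
#' Grid continuation of the coevolutionary singular point: the root found
#' at one grid value seeds the search at the next (with a default-guess
#' and coarse-grid fallback when the branch is lost), each point is
#' classified, every grid value is labelled with a regime
#' (`range_minimised`, `intermediate_ESS`, `branching`, `cycles`,
#' `range_maximised`), and sign changes of the leading eigenvalue real
#' part between adjacent grid values are recorded as bifurcation brackets
#' (`hopf` when the pair is complex on at least one side, `other`
#' otherwise). Where no interior singular point exists the regime is
#' labelled from the end state of the deterministic weighted trait flow.
#'
#' @param p an [eco_params()] object (the swept parameter's value in `p`
#'   is ignored in favour of `grid`).
#' @param name name of the swept parameter (any `eco_params` field, e.g.
#'   `"a_min"` for cost severity or `"q"` for competition).
#' @param grid ordered parameter values.
#' @param speeds evolutionary rate weights passed to the classifier.
#' @return a `bifurcation_scan`: data.frame `points` (one row per grid
#'   value: value, regime, classification, u, v, re, im), list
#'   `singular_points`, data.frame `bifurcations` (type, lower, upper),
#'   plus `parameter`, `speeds`.
#' @export
scan_parameter <- function(p, name, grid, speeds = c(1, 0.5)) {
  if (length(grid) == 0) stop("empty parameter grid", call. = FALSE)
  if (!name %in% names(p)) stop("unknown parameter: ", name, call. = FALSE)
  guess <- NULL
  sps <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    pi_ <- tryCatch(set_param(p, name, grid[i]), error = function(e) NULL)
    if (is.null(pi_)) {
      rows[[i]] <- data.frame(value = grid[i], regime = "invalid",
                              classification = NA, u = NA, v = NA,
                              re = NA, im = NA)
      next
    }
    sp <- NULL
    if (!is.null(guess)) {
      # continuity first: follow the tracked branch
      sp <- tryCatch(newton_singular(pi_, c(guess$u, guess$v)),
                     error = function(e) NULL)
      if (!is.null(sp))
        sp <- tryCatch(classify_singular_point(sp, pi_, speeds),
                       error = function(e) NULL)
    }
    if (is.null(sp)) {
      # branch lost (or scan start): enumerate roots, prefer the one
      # defining the attractor (stable, then branching, then Hopf)
      roots <- tryCatch(find_singular_points(pi_), error = function(e) list())
      roots <- lapply(roots, function(r) {
        tryCatch(classify_singular_point(r, pi_, speeds),
                 error = function(e) NULL)
      })
      roots <- Filter(Negate(is.null), roots)
      if (length(roots)) {
        pref <- c(CSS = 1, branching_host = 2, branching_parasite = 2,
                  hopf_unstable = 3, repeller = 4)
        sp <- roots[[order(pref[vapply(roots, `[[`, "", "classification")])[1]]]
      }
    }
    sps[[i]] <- sp
    guess <- if (!is.null(sp)) sp$traits else NULL
    rows[[i]] <- data.frame(
      value = grid[i],
      regime = regime_label(sp, pi_, speeds),
      classification = if (is.null(sp)) NA_character_ else sp$classification,
      u = if (is.null(sp)) NA_real_ else sp$traits$u,
      v = if (is.null(sp)) NA_real_ else sp$traits$v,
      re = if (is.null(sp)) NA_real_ else max(Re(sp$eigenvalues)),
      im = if (is.null(sp)) NA_real_ else max(abs(Im(sp$eigenvalues))))
  }
  points <- do.call(rbind, rows)

  bifs <- list()
  for (i in seq_len(length(grid) - 1)) {
    r1 <- points$re[i]; r2 <- points$re[i + 1]
    if (!is.na(r1) && !is.na(r2) && sign(r1) != sign(r2) && r1 != 0) {
      complex_pair <- isTRUE(points$im[i] > 1e-9) ||
        isTRUE(points$im[i + 1] > 1e-9)
      bifs[[length(bifs) + 1]] <- data.frame(
        type = if (complex_pair) "hopf" else "other",
        lower = grid[i], upper = grid[i + 1])
    } else if (is.na(r1) != is.na(r2)) {
      bifs[[length(bifs) + 1]] <- data.frame(
        type = "branch_end", lower = grid[i], upper = grid[i + 1])
    }
  }
  structure(list(parameter = name, points = points,
                 singular_points = sps,
                 bifurcations = if (length(bifs)) do.call(rbind, bifs)
                                else data.frame(type = character(),
                                                lower = numeric(),
                                                upper = numeric()),
                 speeds = speeds, params = p),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("bifurcation scan over %s (%d grid values)\n",
              x$parameter, nrow(x$points)))
  r <- rle(x$points$regime)
  cat("  regimes:", paste(sprintf("%s x%d", r$values, r$lengths),
                          collapse = " | "), "\n")
  if (nrow(x$bifurcations))
    for (i in seq_len(nrow(x$bifurcations)))
      cat(sprintf("  %s bracket: (%g, %g)\n", x$bifurcations$type[i],
                  x$bifurcations$lower[i], x$bifurcations$upper[i]))
  invisible(x)
}

#' Locate and refine Hopf bifurcations from a scan
#'
#' Extracts the brackets where a complex eigenvalue pair's real part
#' changes sign and refines each by bisection (re-solving and
#' re-classifying the singular point at every midpoint) until the bracket
#' is narrower than `tol` times the scanned parameter range.
#'
#' @param scan a `bifurcation_scan`.
#' @param tol relative bracket width to refine to.
#' @return data.frame with `lower`, `upper` (refined brackets); zero rows
#'   when the scan shows no Hopf bifurcation.
#' @export
detect_hopf <- function(scan, tol = 1e-4) {
  stopifnot(inherits(scan, "bifurcation_scan"))
  hb <- scan$bifurcations[scan$bifurcations$type == "hopf", , drop = FALSE]
  if (nrow(hb) == 0)
    return(data.frame(lower = numeric(), upper = numeric()))
  rng <- diff(range(scan$points$value)) * tol
  out <- lapply(seq_len(nrow(hb)), function(k) {
    lo <- min(hb$lower[k], hb$upper[k])
    up <- max(hb$lower[k], hb$upper[k])
    i_lo <- which(scan$points$value == hb$lower[k])
    guess <- scan$singular_points[[i_lo]]$traits
    re_at <- function(val, guess) {
      pv <- set_param(scan$params, scan$parameter, val)
      sp <- find_singular_point(pv, guess)
      if (is.null(sp)) return(NULL)
      sp <- classify_singular_point(sp, pv, scan$speeds)
      list(re = max(Re(sp$eigenvalues)), traits = sp$traits)
    }
    r_lo <- re_at(lo, guess)
    while ((up - lo) > rng) {
      mid <- (lo + up) / 2
      r_mid <- re_at(mid, r_lo$traits)
      if (is.null(r_mid)) break
      if (sign(r_mid$re) == sign(r_lo$re)) {
        lo <- mid; r_lo <- r_mid
      } else {
        up <- mid
      }
    }
    data.frame(lower = lo, upper = up)
  })
  do.call(rbind, out)
}
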