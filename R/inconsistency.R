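#' Partition a time design into past / present / future eras
#'
#' For a focal transfer interior to the design, all earlier transfers pool
#' into `past`, the focal transfer is `present`, and all later transfers
#' pool into `future`. Clones' era means average outcomes against every
#' enemy clone in the era, weighting all enemy clones equally regardless
#' of era size.
#'
#' @param times the ordered design transfers.
#' @param t_focal the focal transfer (must have at least one transfer on
#'   each side).
#' @return list with `past`, `present`, `future` transfer vectors.
#' @export
eras_for_focal_time <- function(times, t_focal) {
  times <- sort(unique(times))
  if (!t_focal %in% times)
    stop("focal time not in the design", call. = FALSE)
  if (t_focal == min(times) || t_focal == max(times))
    stop("focal time at the design boundary: no past or no future",
         call. = FALSE)
  list(past = times[times < t_focal], present = t_focal,
       future = times[times > t_focal])
}

#' Inconsistency of clone reaction norms across eras
#'
#' The inconsistency component of the clone-by-era interaction, summed
#' over unordered clone pairs:
#' \deqn{\sum_{e_1 < e_2} \sigma_{e_1} \sigma_{e_2} (1 - \rho_{e_1 e_2})}
#' where \eqn{\sigma} is a clone's standard deviation of mean infectivity
#' (or resistance) across the era columns and \eqn{\rho} the correlation
#' between two clones' era profiles. It is zero when all finite-variance
#' clones are pairwise perfectly correlated (parallel reaction norms) and
#' grows when clone profiles cross - the clone-level signature of
#' specialism FSD. Standard deviations use the population form
#' (denominator n); pairs where either clone has zero variance contribute
#' nothing (their correlation is undefined).
#'
#' @param clone_era_means numeric matrix, clones x eras (>= 2 clones,
#'   >= 2 era columns; the canonical design has columns past, present,
#'   future).
#' @return non-negative scalar.
#' @export
inconsistency <- function(clone_era_means) {
  m <- as.matrix(clone_era_means)
  if (ncol(m) < 2) stop("need at least 2 era columns", call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 clones", call. = FALSE)
  ne <- ncol(m)
  mu <- rowMeans(m)
  dev <- m - mu
  sdev <- sqrt(rowSums(dev^2) / ne) # population-form sd across eras
  total <- 0
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      if (sdev[i] == 0 || sdev[j] == 0) next
      rho <- sum(dev[i, ] * dev[j, ]) / (ne * sdev[i] * sdev[j])
      total <- total + sdev[i] * sdev[j] * (1 - rho)
    }
  }
  total
}

#' Clone-by-era mean matrices and inconsistency over a tensor
#'
#' For each population and each interior focal time, averages each phage
#' clone's infectivity against bacteria pooled from the past, present and
#' future eras (and symmetrically each bacteria clone's resistance = 1 -
#' infection against past/present/future phages), then computes the
#' inconsistency statistic on each matrix.
#'
#' @param tensor a `cross_infection_tensor`.
#' @param focal_times interior focal transfers to use (default: all
#'   interior times of the design).
#' @return `data.table` with columns `population`, `treatment`,
#'   `focal_time`, `inconsistency_infectivity`,
#'   `inconsistency_resistance`.
#' @export
inconsistency_profile <- function(tensor, focal_times = NULL) {
  stopifnot(inherits(tensor, "cross_infection_tensor"))
  times <- sort(unique(tensor$phage_time))
  if (is.null(focal_times)) focal_times <- times[-c(1, length(times))]
  out <- list()
  for (popn in unique(tensor$population)) {
    sub <- tensor[tensor$population == popn]
    trt <- sub$treatment[1]
    for (tf in focal_times) {
      er <- eras_for_focal_time(times, tf)
      era_of <- function(tv) ifelse(tv < tf, "past",
                                    ifelse(tv > tf, "future", "present"))
      # phage clones sampled at the focal time vs bacteria eras
      ph <- sub[sub$phage_time == tf]
      mi <- tapply(ph$infected, list(ph$phage_clone, era_of(ph$bacteria_time)),
                   mean)
      mi <- mi[, c("past", "present", "future"), drop = FALSE]
      # bacteria clones at the focal time vs phage eras (resistance)
      ba <- sub[sub$bacteria_time == tf]
      mr <- tapply(1 - ba$infected,
                   list(ba$bacteria_clone, era_of(ba$phage_time)), mean)
      mr <- mr[, c("past", "present", "future"), drop = FALSE]
      out[[length(out) + 1]] <- data.table::data.table(
        population = popn, treatment = trt, focal_time = tf,
        inconsistency_infectivity = inconsistency(mi),
        inconsistency_resistance = inconsistency(mr))
    }
  }
  data.table::rbindlist(out)
}
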