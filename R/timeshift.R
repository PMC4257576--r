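#' Time shift between phage and bacteria sampling transfers
#'
#' The time shift of an assay is the bacteria sampling transfer minus the
#' phage sampling transfer: phage from transfer 4 against bacteria from
#' transfer 10 gives a shift of +6. Under arms-race dynamics (ARD) average
#' infectivity declines with time shift (phages do better against past
#' hosts than future ones).
#'
#' @param phage_time,bacteria_time sampling transfer numbers.
#' @return signed integer shift(s), `bacteria_time - phage_time`.
#' @export
compute_time_shift <- function(phage_time, bacteria_time) {
  bacteria_time - phage_time
}

#' Mean infectivity per population and time pair
#'
#' Averages the binary outcomes over the full clone-by-clone panel within
#' each (population, phage time, bacteria time) cell: with 20 phage and 20
#' bacteria clones each cell averages 400 assays.
#'
#' @param tensor a `cross_infection_tensor`.
#' @return a `data.table` with columns `population`, `treatment`,
#'   `phage_time`, `bacteria_time`, `mean_infectivity`, `n`.
#' @export
mean_infectivity <- function(tensor) {
  stopifnot(inherits(tensor, "cross_infection_tensor"))
  infected <- NULL # NSE note for R CMD check
  tensor[, .(mean_infectivity = mean(infected), n = .N),
         by = c("population", "treatment", "phage_time", "bacteria_time")]
}

#' Fit the ARD time-shift model to a treatment's mean-infectivity table
#'
#' Linear model of mean infectivity on continuous phage time and
#' continuous time shift, with population blocks and population-by-
#' covariate interactions, fitted per treatment. The treatment-level
#' time-shift effect is tested against the population x time-shift
#' interaction stratum, giving an F statistic on (1, n_pop - 1) degrees of
#' freedom; with six populations this is the F(1,5) shape. One
#' independent slope per population is also returned, with its own
#' t-test p-value, and per-population significance decisions after
#' sequential Bonferroni (Holm) correction. A significantly negative
#' treatment slope is the ARD signature.
#'
#' Covariates are centred before the interaction fit for conditioning.
#'
#' @param table a mean-infectivity table from [mean_infectivity()].
#' @param treatment which treatment label to fit (default: all rows).
#' @param alpha significance level for the Holm decisions.
#' @return a `time_shift_fit` list: `slope` (treatment-level), `F`,
#'   `df`, `p_value`, and a `per_population` data.frame with `slope`,
#'   `p_value`, `significant`.
#' @export
fit_time_shift_model <- function(table, treatment = NULL, alpha = 0.05) {
  tb <- data.table::as.data.table(table)
  if (!is.null(treatment)) {
    keep <- tb$treatment %in% treatment
    tb <- tb[keep, ]
  }
  if (nrow(tb) == 0) stop("no rows for the requested treatment", call. = FALSE)
  tb$shift <- compute_time_shift(tb$phage_time, tb$bacteria_time)
  if (length(unique(tb$population)) < 2)
    stop("need >= 2 populations", call. = FALSE)
  if (length(unique(tb$shift)) < 3)
    stop("need >= 3 distinct time shifts", call. = FALSE)

  pop <- factor(tb$population)
  pt <- tb$phage_time - mean(tb$phage_time)
  sh <- tb$shift - mean(tb$shift)
  y <- tb$mean_infectivity

  fit <- stats::lm(y ~ pop + pt + sh + pop:pt + pop:sh)
  av <- stats::anova(fit)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased))
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)

  ms_shift <- av["sh", "Mean Sq"]
  ms_err <- av["pop:sh", "Mean Sq"]
  df1 <- av["sh", "Df"]
  df2 <- av["pop:sh", "Df"]
  Fstat <- ms_shift / ms_err
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  per_pop <- do.call(rbind, lapply(split(tb, pop), function(d) {
    f <- stats::lm(mean_infectivity ~ phage_time + shift, data = d)
    sm <- summary(f)$coefficients
    data.frame(population = d$population[1],
               slope = sm["shift", "Estimate"],
               p_value = sm["shift", "Pr(>|t|)"])
  }))
  rownames(per_pop) <- NULL
  per_pop$significant <- sequential_bonferroni(per_pop$p_value, alpha)

  structure(list(
    slope = mean(per_pop$slope),
    F = unname(Fstat), df = c(df1, df2), p_value = unname(pval),
    per_population = per_pop, alpha = alpha,
    treatment = if (is.null(treatment)) unique(tb$treatment) else treatment),
    class = "time_shift_fit")
}

#' @export
print.time_shift_fit <- function(x, ...) {
  cat(sprintf("time-shift fit [%s]: slope = %.4f, F(%d,%d) = %.3f, p = %.4g\n",
              paste(x$treatment, collapse = "+"), x$slope,
              x$df[1], x$df[2], x$F, x$p_value))
  cat(sprintf("  populations with significant slope (Holm, alpha = %g): %d/%d\n",
              x$alpha, sum(x$per_population$significant),
              nrow(x$per_population)))
  invisible(x)
}

#' Range-FSD two-way ANOVA for one population
#'
#' Mean infectivity against phage time and bacteria time as categorical
#' factors over the fully crossed time design (one mean per cell, so the
#' interaction is the residual stratum). The main-effect mean squares
#' estimate the strength of range fluctuating-selection dynamics (FSD) for
#' infectivity (phage time) and resistance (bacteria time); each is
#' F-tested against the interaction mean square. Because directional
#' escalation also inflates these mean squares, range FSD is flagged only
#' when a main effect is significant *and* the population's time-shift
#' slope is not (`slope_significant` argument).
#'
#' @param table mean-infectivity rows for a single population.
#' @param slope_significant was this population's time-shift slope
#'   significant? (used only for the interpretation flag).
#' @param alpha significance level.
#' @return a `range_fsd_result` list: `ms_phage_time`,
#'   `ms_bacteria_time`, `ms_interaction`, F tests per main effect, and
#'   `range_fsd` flags for infectivity and resistance.
#' @export
range_fsd_anova <- function(table, slope_significant = FALSE, alpha = 0.05) {
  tb <- data.table::as.data.table(table)
  if (length(unique(tb$population)) != 1)
    stop("pass one population at a time", call. = FALSE)
  np <- length(unique(tb$phage_time)); nb <- length(unique(tb$bacteria_time))
  if (nrow(tb) != np * nb)
    stop("time design is not fully crossed/balanced", call. = FALSE)
  fit <- stats::aov(mean_infectivity ~ factor(phage_time) +
                      factor(bacteria_time), data = tb)
  av <- summary(fit)[[1]]
  ms <- av[, "Mean Sq"]; df <- av[, "Df"]
  # residual of the additive model over a complete two-way grid is the
  # interaction stratum
  Fp <- ms[1] / ms[3]; Fb <- ms[2] / ms[3]
  p_p <- stats::pf(Fp, df[1], df[3], lower.tail = FALSE)
  p_b <- stats::pf(Fb, df[2], df[3], lower.tail = FALSE)
  structure(list(
    population = tb$population[1],
    ms_phage_time = unname(ms[1]), ms_bacteria_time = unname(ms[2]),
    ms_interaction = unname(ms[3]),
    F_phage_time = unname(Fp), F_bacteria_time = unname(Fb),
    df = unname(df),
    p_phage_time = unname(p_p), p_bacteria_time = unname(p_b),
    range_fsd_infectivity = unname(p_p < alpha && !slope_significant),
    range_fsd_resistance = unname(p_b < alpha && !slope_significant)),
    class = "range_fsd_result")
}

#' Welch's unequal-variance t-test between treatment groups
#'
#' Used to compare per-population mean squares (or inconsistency values)
#' between the high- and low-nutrient treatments; reports the
#' Welch-Satterthwaite fractional degrees of freedom. Degenerate input
#' (zero variance in both groups with equal means) returns t = 0, p = 1.
#'
#' @param values_high,values_low numeric vectors (one value per
#'   population).
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t <- function(values_high, values_low) {
  if (length(values_high) < 2 || length(values_low) < 2)
    stop("need >= 2 values per group", call. = FALSE)
  if (stats::var(values_high) == 0 && stats::var(values_low) == 0) {
    if (mean(values_high) == mean(values_low))
      return(list(t = 0, df = length(values_high) + length(values_low) - 2,
                  p_value = 1))
    return(list(t = Inf * sign(mean(values_high) - mean(values_low)),
                df = length(values_high) + length(values_low) - 2,
                p_value = 0))
  }
  ht <- stats::t.test(values_high, values_low, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Sequential Bonferroni (Holm step-down) decisions
#'
#' Orders p-values ascending, compares the i-th smallest to
#' `alpha / (m - i + 1)`, and stops at the first failure; all earlier
#' hypotheses are rejected. Decisions are monotone in p.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param alpha family-wise significance level.
#' @return logical vector of rejections, in the input order.
#' @export
sequential_bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "holm") < alpha
}
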