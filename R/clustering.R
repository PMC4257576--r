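#' Cluster clone phenotype profiles at a similarity threshold
#'
#' Groups clonal isolates into discrete phenotypic complexes from their
#' binary outcome profiles (a clone's infect/resist outcomes against every
#' enemy clone in its population's panel). The distance between two
#' profiles is the squared Euclidean distance normalised by profile
#' length - for binary data, the fraction of mismatched positions - so
#' similarity = 1 - distance lies in [0, 1] and the threshold is
#' scale-free. Profiles are merged by agglomerative clustering (average
#' linkage by default) and the tree is cut so merged clusters retain
#' linkage similarity >= the threshold (the canonical cut is 80%
#' similarity). Clustering is deterministic under input order.
#'
#' @param profiles numeric matrix, clones x panel positions, binary
#'   entries; rows are clones.
#' @param threshold similarity threshold in (0, 1]; default 0.80.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return a `phenotype_clustering` list: `labels` (cluster id per
#'   clone), `representatives` (modal profile per cluster), `threshold`,
#'   `linkage`.
#' @export
cluster_phenotypes <- function(profiles, threshold = 0.80,
                               linkage = "average") {
  m <- as.matrix(profiles)
  if (any(!m %in% c(0, 1)))
    stop("profiles must be binary", call. = FALSE)
  if (nrow(m) == 1) {
    labels <- 1L
  } else {
    d <- stats::dist(m)^2 / ncol(m) # squared Euclidean per position
    hc <- stats::hclust(d, method = linkage)
    labels <- stats::cutree(hc, h = 1 - threshold)
    # relabel clusters by lowest member index for deterministic ids
    first <- tapply(seq_along(labels), labels, min)
    labels <- as.integer(rank(first)[as.character(labels)])
  }
  reps <- do.call(rbind, lapply(split(seq_len(nrow(m)), labels),
                                function(ix) {
    round(colMeans(m[ix, , drop = FALSE]))
  }))
  structure(list(labels = labels, representatives = reps,
                 threshold = threshold, linkage = linkage),
            class = "phenotype_clustering")
}

#' @export
print.phenotype_clustering <- function(x, ...) {
  cat(sprintf("phenotype clustering: %d clones -> %d cluster(s) at %.0f%% similarity (%s linkage)\n",
              length(x$labels), max(x$labels), 100 * x$threshold, x$linkage))
  invisible(x)
}

#' Phenotype cluster frequencies through time
#'
#' Clusters one species' clones from one population across all sampling
#' times, then tabulates each cluster's frequency among the clones
#' sampled at each time and each cluster's range (mean proportion of the
#' panel its members infect, for phage, or resist, for bacteria).
#'
#' @param tensor a `cross_infection_tensor` restricted to one population.
#' @param species `"phage"` (profiles = outcomes against every bacteria
#'   clone x time) or `"bacteria"` (profiles = resistance against every
#'   phage clone x time).
#' @param threshold,linkage passed to [cluster_phenotypes()].
#' @return list with `clustering`, `frequencies` (data.table: time,
#'   cluster, frequency), and `ranges` (data.table: cluster, range).
#' @export
phenotype_frequencies <- function(tensor, species = c("phage", "bacteria"),
                                  threshold = 0.80, linkage = "average") {
  species <- match.arg(species)
  stopifnot(inherits(tensor, "cross_infection_tensor"))
  if (length(unique(tensor$population)) != 1)
    stop("pass one population at a time", call. = FALSE)
  dt <- data.table::as.data.table(tensor)
  if (species == "phage") {
    dt$clone_id <- paste(dt$phage_time, dt$phage_clone, sep = "_")
    dt$panel_id <- paste(dt$bacteria_time, dt$bacteria_clone, sep = "_")
    dt$time <- dt$phage_time
    dt$outcome <- dt$infected
  } else {
    dt$clone_id <- paste(dt$bacteria_time, dt$bacteria_clone, sep = "_")
    dt$panel_id <- paste(dt$phage_time, dt$phage_clone, sep = "_")
    dt$time <- dt$bacteria_time
    dt$outcome <- 1 - dt$infected
  }
  wide <- data.table::dcast(dt, clone_id + time ~ panel_id,
                            value.var = "outcome")
  panel_cols <- setdiff(names(wide), c("clone_id", "time"))
  m <- as.matrix(wide[, panel_cols, with = FALSE])
  cl <- cluster_phenotypes(m, threshold, linkage)
  tab <- data.table::data.table(time = wide$time, cluster = cl$labels,
                                range = rowMeans(m))
  freq <- tab[, .N, by = c("time", "cluster")]
  tot <- tab[, .N, by = "time"]
  freq <- merge(freq, tot, by = "time", suffixes = c("", "_tot"))
  freq$frequency <- freq$N / freq$N_tot
  freq <- freq[, c("time", "cluster", "frequency"), with = FALSE]
  data.table::setkeyv(freq, c("time", "cluster"))
  ranges <- tab[, .(range = mean(range)), by = "cluster"]
  data.table::setkeyv(ranges, "cluster")
  list(clustering = cl, frequencies = freq, ranges = ranges)
}
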