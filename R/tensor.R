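#' Cross-infection tensors
#'
#' A cross-infection tensor holds the complete binary infect/resist
#' outcomes of a time-shift experiment: every phage clone sampled at every
#' phage time crossed against every bacteria clone sampled at every
#' bacteria time, within each replicate population. It is stored tidily as
#' a `data.table` with columns `population`, `treatment`, `phage_time`,
#' `bacteria_time`, `phage_clone`, `bacteria_clone`, `infected` (0/1),
#' carrying class `cross_infection_tensor`.
#'
#' @param dt a data.frame/data.table in the tidy dialect above.
#' @return a validated `cross_infection_tensor`.
#' @export
as_cross_infection_tensor <- function(dt) {
  dt <- data.table::as.data.table(dt)
  validate_tensor(dt)
  data.table::setkeyv(dt, c("population", "phage_time", "bacteria_time",
                            "phage_clone", "bacteria_clone"))
  data.table::setattr(dt, "class",
                      c("cross_infection_tensor", class(dt)))
  dt
}

tensor_cols <- c("population", "treatment", "phage_time", "bacteria_time",
                 "phage_clone", "bacteria_clone", "infected")

validate_tensor <- function(dt) {
  miss <- setdiff(tensor_cols, names(dt))
  if (length(miss))
    stop("tensor is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!(dt$infected %in% c(0L, 1L)))
  if (length(bad))
    stop("non-binary outcomes at rows ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  # complete crossing within every population
  n <- dt[, .N, by = c("population", "phage_time", "bacteria_time")]
  counts <- dt[, {
    npc <- length(unique(phage_clone))
    nbc <- length(unique(bacteria_clone))
    .(expected = npc * nbc)
  }, by = c("population", "phage_time", "bacteria_time")]
  chk <- merge(n, counts, by = c("population", "phage_time", "bacteria_time"))
  gaps <- chk[chk$N != chk$expected]
  if (nrow(gaps))
    stop("incomplete clone crossing in population(s) ",
         paste(unique(gaps$population), collapse = ", "), call. = FALSE)
  dup <- anyDuplicated(dt, by = c("population", "phage_time", "bacteria_time",
                                  "phage_clone", "bacteria_clone"))
  if (dup)
    stop("duplicated assay rows (first at row ", dup, ")", call. = FALSE)
  invisible(dt)
}

#' @export
print.cross_infection_tensor <- function(x, ...) {
  cat(sprintf(
    "cross-infection tensor: %d assays, %d population(s), %d phage x %d bacteria times\n",
    nrow(x), length(unique(x$population)),
    length(unique(x$phage_time)), length(unique(x$bacteria_time))))
  cat(sprintf("  overall infection fraction: %.3f\n", mean(x$infected)))
  invisible(x)
}

#' Read / write a cross-infection tensor as tidy CSV
#'
#' The canonical dialect is comma-separated UTF-8 with a header row and
#' columns `population`, `treatment`, `phage_time`, `bacteria_time`,
#' `phage_clone`, `bacteria_clone`, `infected`; rows are ordered by
#' population, phage time, bacteria time, phage clone, bacteria clone so
#' write/read round-trips are byte-identical. Gzip-compressed files are
#' accepted transparently (by extension `.gz`).
#'
#' @param path file path (`.csv` or `.csv.gz`).
#' @return `read_tensor()` returns a validated `cross_infection_tensor`;
#'   `write_tensor()` returns `path` invisibly.
#' @export
read_tensor <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- if (grepl("\\.gz$", path)) {
    data.table::as.data.table(utils::read.csv(gzfile(path)))
  } else {
    data.table::fread(path)
  }
  as_cross_infection_tensor(dt)
}

#' @rdname read_tensor
#' @param tensor a `cross_infection_tensor`.
#' @export
write_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "cross_infection_tensor"))
  ord <- order(tensor$population, tensor$phage_time, tensor$bacteria_time,
               tensor$phage_clone, tensor$bacteria_clone)
  out <- data.table::as.data.table(tensor)[ord, tensor_cols, with = FALSE]
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "wb")
    on.exit(close(con))
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  } else {
    data.table::fwrite(out, path)
  }
  invisible(path)
}
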