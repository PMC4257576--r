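#' Load a structured configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration with
#' sections `eco` (demography and transmission), `costs` (curvature
#' exponents), `kernel` (steepness and trait bounds), `numerics`
#' (evolutionary speeds and simulator settings) and `synthetic` (the
#' synthetic community design). Every field is optional: defaults are
#' filled in, invariants are enforced by the respective constructors, and
#' unknown keys are rejected.
#'
#' @param path config file path; `NULL` or a missing/empty file yields
#'   the full default bundle.
#' @return list with `params` (an [eco_params()]), `numerics` (speeds
#'   and simulator settings), and `synthetic` (a [synthetic_config()]).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  known_sections <- c("eco", "costs", "kernel", "numerics", "synthetic")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sect <- function(s, allowed) {
    x <- raw[[s]]
    if (is.null(x)) return(list())
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", s,
                   paste(bad, collapse = ", ")), call. = FALSE)
    x
  }
  eco <- sect("eco", c("q", "b", "alpha", "a_max", "a_min",
                       "beta_max", "beta_min"))
  costs <- sect("costs", c("c_h", "c_p"))
  kernel <- sect("kernel", c("s_k", "trait_lo", "trait_hi"))
  params <- do.call(eco_params, c(eco, costs, kernel))

  num_defaults <- list(speeds = c(1, 0.5), n_strains = 51L,
                       relax_time = 200, n_events = 400,
                       mutant_frac = 1e-3, extinction_threshold = 1e-6)
  num <- sect("numerics", names(num_defaults))
  numerics <- utils::modifyList(num_defaults, num)
  if (length(numerics$speeds) != 2 || any(numerics$speeds < 0))
    stop("numerics$speeds must be two non-negative weights", call. = FALSE)

  syn <- sect("synthetic", names(formals(synthetic_config)))
  synthetic <- do.call(synthetic_config, syn)

  list(params = params, numerics = numerics, synthetic = synthetic)
}

#' Write a run manifest
#'
#' Records what a scripted analysis step did: the step name, the
#' configuration echo, every seed used, package version, input/output
#' paths and wall-clock timestamps — enough to re-run the step and
#' reproduce its outputs exactly.
#'
#' @param path output YAML path.
#' @param step short step name.
#' @param config configuration echo (any YAML-serialisable list).
#' @param seeds named or unnamed list/vector of seeds used.
#' @param inputs,outputs character vectors of file paths.
#' @param started POSIXct start time (defaults to now).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, step, config = list(), seeds = list(),
                           inputs = character(), outputs = character(),
                           started = Sys.time()) {
  manifest <- list(
    step = step,
    package_version = as.character(utils::packageVersion("coevorange")),
    seeds = seeds,
    config = config,
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    started = format(started, "%Y-%m-%d %H:%M:%S %Z"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
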