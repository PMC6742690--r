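# Run configuration, result serialization and provenance.

#' Load a run configuration
#'
#' Reads a YAML (or JSON) run configuration and validates it,
#' accumulating all validation errors before failing.  A configuration
#' has a \code{preset} (or \code{parameter_file}), optional
#' \code{solver} settings, a \code{seed}, an \code{outdir} and exactly
#' one experiment block among \code{simulate}, \code{fit},
#' \code{sensitivity}, \code{lhs}, \code{treatment}.
#'
#' @param path configuration file path.
#' @return A validated \code{t1d_config} (named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  errs <- character()
  known <- c("preset", "parameter_file", "solver", "seed", "outdir",
             "simulate", "fit", "sensitivity", "lhs", "treatment")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    errs <- c(errs, paste("unknown top-level key(s):",
                          paste(bad, collapse = ", ")))
  blocks <- intersect(c("simulate", "fit", "sensitivity", "lhs",
                        "treatment"), names(cfg))
  if (length(blocks) != 1)
    errs <- c(errs, "exactly one experiment block required (simulate/fit/sensitivity/lhs/treatment)")
  if (is.null(cfg$preset) && is.null(cfg$parameter_file))
    errs <- c(errs, "either 'preset' or 'parameter_file' required")
  if (!is.null(cfg$preset) &&
      !tolower(cfg$preset) %in% c("nod", "balbc"))
    errs <- c(errs, "preset must be 'nod' or 'balbc'")
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)))
    errs <- c(errs, "seed must be an integer")
  if (!is.null(cfg$parameter_file)) {
    p <- tryCatch(read_parameter_file(cfg$parameter_file),
                  error = function(e) conditionMessage(e))
    if (is.character(p)) errs <- c(errs, p)
  }
  if (length(errs))
    stop("invalid config ", path, ":\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "."
  structure(cfg, class = c("t1d_config", "list"))
}

#' Resolve the parameter set named by a configuration
#' @param cfg a \code{t1d_config}.
#' @return A \code{t1d_parameters} object.
#' @export
config_parameters <- function(cfg) {
  if (!is.null(cfg$parameter_file)) read_parameter_file(cfg$parameter_file)
  else mouse_preset(cfg$preset)
}

#' Write results with a checksum manifest
#'
#' Serializes a trajectory, region map, treatment map, sensitivity table
#' (CSV) or an engulfment fit (JSON) into a directory, together with a
#' \code{manifest.json} listing every file with its MD5 checksum and the
#' run metadata needed to regenerate it (parameters, seed, package
#' version).
#'
#' @param obj object to write.
#' @param dir output directory (created if missing).
#' @param meta optional named list of extra metadata.
#' @return The manifest (invisibly): list with \code{files},
#'   \code{md5}, \code{meta}.
#' @export
write_results <- function(obj, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (inherits(obj, "t1d_trajectory")) {
    f <- file.path(dir, "trajectory.csv")
    utils::write.csv(as.data.frame(obj), f, row.names = FALSE)
    files <- f
    p <- attr(obj, "parameters")
    meta <- c(meta, list(parameters = unclass(p),
                         preset = attr(p, "preset"),
                         wave = attr(obj, "wave"),
                         solver = attr(obj, "solver"),
                         flagged = attr(obj, "flagged")))
    sch <- attr(obj, "schedule")
    if (!is.null(sch))
      meta$schedule <- list(times = sch$times, doses = sch$doses)
  } else if (inherits(obj, "t1d_region_map")) {
    f <- file.path(dir, "region_map.csv")
    utils::write.csv(as.data.frame(obj), f, row.names = FALSE)
    b <- file.path(dir, "healthy_boundary.json")
    jsonlite::write_json(healthy_boundary(obj), b, auto_unbox = TRUE,
                         digits = NA)
    files <- c(f, b)
    meta <- c(meta, list(w = attr(obj, "w"), eta = attr(obj, "eta"),
                         eval_days = attr(obj, "eval_days")))
  } else if (inherits(obj, "t1d_treatment_map")) {
    f <- file.path(dir, "treatment_map.csv")
    utils::write.csv(as.data.frame(obj), f, row.names = FALSE)
    wjson <- file.path(dir, "windows.json")
    jsonlite::write_json(window_report(obj), wjson, auto_unbox = TRUE,
                         digits = NA)
    files <- c(f, wjson)
    meta <- c(meta, list(schedule_kind = attr(obj, "schedule_kind"),
                         eval_weeks = attr(obj, "eval_weeks")))
  } else if (inherits(obj, "t1d_sensitivity")) {
    f <- file.path(dir, "sensitivity.csv")
    utils::write.csv(as.data.frame(obj), f, row.names = FALSE)
    files <- f
  } else if (inherits(obj, "engulfment_fit")) {
    f <- file.path(dir, "engulfment_fit.json")
    jsonlite::write_json(
      list(g = obj$g, sigma = obj$sigma, acceptance = obj$acceptance,
           seed = obj$seed, ci90 = obj$ci90,
           chain_summary = list(
             n = nrow(obj$chain),
             g_mean = mean(obj$chain[, "g"]),
             g_sd = stats::sd(obj$chain[, "g"]))),
      f, auto_unbox = TRUE, digits = NA)
    files <- f
  } else if (is.data.frame(obj)) {
    f <- file.path(dir, "result.csv")
    utils::write.csv(obj, f, row.names = FALSE)
    files <- f
  } else stop("write_results(): unsupported object class", call. = FALSE)
  if (!length(files)) warning("empty result: manifest lists no data files")
  meta$package_version <- as.character(utils::packageVersion("t1dsim"))
  meta$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest <- list(files = basename(files),
                   md5 = unname(tools::md5sum(files)),
                   meta = meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Derive a component seed from a global seed
#'
#' Counter-based fan-out so each experiment component gets its own
#' reproducible stream: \code{seed * 1000 + counter}, kept inside the
#' 32-bit integer range.
#'
#' @param seed global integer seed.
#' @param counter component index.
#' @return Integer seed.
#' @export
component_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1000 + counter) %% .Machine$integer.max)
}
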