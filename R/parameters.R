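# Parameter registry: construction, validation, presets, YAML round-trip.

.t1d_param_names <- c(
  # macrophages
  "J", "k", "b", "c", "e1", "e2", "fM", "fMa",
  # healthy beta cells / effector kill / wave
  "alphaB", "deltaB", "Ghb", "eta", "alphaE", "betaE", "sE", "sR", "w",
  "d", "Bconv", "Qpanc", "B0",
  # dendritic cells
  "Dss", "ftD", "fD", "bDE", "bIR", "muD",
  # glucose / insulin
  "R0", "G0", "SI", "sigmaI", "GI", "deltaI",
  # T cells
  "aE", "aR", "Tnaive", "bP", "thetaD", "ram", "bE", "bR",
  "muE", "muR", "aEm")

# Parameters that may legitimately be zero (all others must be > 0 or >= 0
# according to .t1d_strictly_positive below).
.t1d_strictly_positive <- c("Qpanc", "Bconv", "Dss", "thetaD", "Ghb", "GI",
                            "B0", "deltaI")

#' Construct and validate a model parameter set
#'
#' Builds the full rate-constant registry for the twelve-compartment
#' model.  Called with no arguments it returns the packaged Balb/c
#' (non-diabetes-prone) registry; any field can be overridden by name.
#' Use \code{\link{mouse_preset}} for the strain presets, which differ
#' only in the macrophage clearance rates \code{fM} and \code{fMa}.
#'
#' @param ... named numeric overrides of individual parameters (see the
#'   packaged \code{extdata/balbc.yaml} for the field glossary and the
#'   provenance of every default).
#' @param base optional parameter list to start from instead of the
#'   packaged Balb/c registry.
#' @return An object of class \code{t1d_parameters}: a named list of the
#'   45 model constants.
#' @examples
#' p <- t1d_parameters(eta = 0.02)
#' p$eta
#' @export
t1d_parameters <- function(..., base = NULL) {
  if (is.null(base)) base <- mouse_preset("balbc")
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("t1d_parameters(): overrides must be named", call. = FALSE)
    bad <- setdiff(names(over), .t1d_param_names)
    if (length(bad))
      stop("t1d_parameters(): unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    base[names(over)] <- over
  }
  validate_parameters(base)
}

#' Validate a parameter list
#'
#' Checks completeness, numeric type, nonnegativity of all rates, and
#' strict positivity of the capacities and half-saturation constants.
#'
#' @param p named list of parameters.
#' @return \code{p}, classed as \code{t1d_parameters}, invisibly usable.
#' @export
validate_parameters <- function(p) {
  stopifnot(is.list(p))
  missing <- setdiff(.t1d_param_names, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(p), .t1d_param_names)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  vals <- unlist(p[.t1d_param_names])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all parameters must be finite numerics", call. = FALSE)
  if (any(vals < 0))
    stop("negative parameter(s): ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  zp <- .t1d_strictly_positive
  zv <- unlist(p[zp])
  if (any(zv <= 0))
    stop("parameter(s) must be strictly positive: ",
         paste(zp[zv <= 0], collapse = ", "), call. = FALSE)
  p <- p[.t1d_param_names]
  class(p) <- c("t1d_parameters", "list")
  p
}

#' Strain presets for NOD and Balb/c mice
#'
#' Loads the packaged, versioned parameter file for a mouse strain.  The
#' two presets share every rate constant except the macrophage clearance
#' rates \code{fM} (resting) and \code{fMa} (activated), which are
#' impaired in the diabetes-prone NOD strain; the dendritic-cell
#' clearance rates are scaled once from the healthy (Balb/c) activated
#' macrophage rate and shared by both strains.
#'
#' @param name \code{"nod"} or \code{"balbc"} (case-insensitive).
#' @return A \code{t1d_parameters} object with attributes \code{preset}
#'   (the strain name) and \code{wave_on} (default wave flag from the
#'   preset file).
#' @export
mouse_preset <- function(name = c("nod", "balbc")) {
  name <- match.arg(tolower(name), c("nod", "balbc"))
  path <- system.file("extdata", paste0(name, ".yaml"), package = "t1dsim",
                      mustWork = TRUE)
  read_parameter_file(path)
}

#' Read a parameter file
#'
#' Parses a flat YAML (or JSON) parameter file with blocks
#' \code{preset}, \code{wave_on}, \code{parameters} and (optionally)
#' \code{provenance}, validating that the parameter keys are exactly the
#' model symbols.  Unknown keys are rejected.
#'
#' @param path file path.
#' @return A validated \code{t1d_parameters} object with attributes
#'   \code{preset}, \code{wave_on} and \code{provenance}.
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("preset", "wave_on", "parameters",
                               "provenance"))
  if (length(bad))
    stop("unknown top-level key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(raw$parameters))
    stop("parameter file has no 'parameters' block: ", path, call. = FALSE)
  p <- validate_parameters(lapply(raw$parameters, as.numeric))
  attr(p, "preset")     <- raw$preset %||% "custom"
  attr(p, "wave_on")    <- isTRUE(raw$wave_on)
  attr(p, "provenance") <- raw$provenance
  p
}

#' Write a parameter file
#'
#' Serializes a parameter set (plus preset name, wave flag and provenance
#' strings) to YAML so that \code{\link{read_parameter_file}} round-trips
#' it losslessly.
#'
#' @param p a \code{t1d_parameters} object.
#' @param path output file path (\code{.yaml}).
#' @return \code{path}, invisibly.
#' @export
write_parameter_file <- function(p, path) {
  preset <- attr(p, "preset") %||% "custom"
  wave_on <- isTRUE(attr(p, "wave_on"))
  prov <- attr(p, "provenance")
  p <- validate_parameters(p)
  out <- list(preset = preset, wave_on = wave_on,
              parameters = unclass(p)[.t1d_param_names])
  if (!is.null(prov)) out$provenance <- prov
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
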