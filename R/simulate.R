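# Integration of the full model: initial conditions, impulsive tolerogenic-DC
# dosing, glucose-threshold event detection, outcome classification.

#' Construct a tolerogenic-DC dose schedule
#'
#' Timed impulse additions of tolerogenic dendritic cells.  Doses are
#' given in cells (whole-injection counts); at administration each dose
#' is converted to a concentration jump \code{dose / Qpanc} on the
#' \code{tD} compartment.
#'
#' @param times_days injection times, days; strictly increasing.
#' @param doses_cells injected cell counts (> 0); recycled to the length
#'   of \code{times_days}.  Doses outside the studied range
#'   \code{[1e4, 5e6]} trigger a warning.
#' @return An object of class \code{t1d_dose_schedule}.
#' @examples
#' dose_schedule(25 * 7, 2e5)                      # one injection at 25 wk
#' dose_schedule(28 + 7 * 0:3, rep(5e5, 4))        # weekly x 4 from 4 wk
#' @export
dose_schedule <- function(times_days, doses_cells) {
  stopifnot(length(times_days) >= 1)
  doses_cells <- rep_len(doses_cells, length(times_days))
  if (any(diff(times_days) <= 0))
    stop("dose times must be strictly increasing", call. = FALSE)
  if (any(doses_cells <= 0))
    stop("doses must be positive", call. = FALSE)
  if (any(doses_cells < 1e4 | doses_cells > 5e6))
    warning("dose outside the studied range [1e4, 5e6] cells")
  structure(list(times = as.numeric(times_days),
                 doses = as.numeric(doses_cells),
                 target = "tD"),
            class = "t1d_dose_schedule")
}

#' Default initial state
#'
#' Equilibrated starting point at birth (t = 0): the wave-free system is
#' integrated for 50 days with the healthy beta-cell mass frozen at its
#' full value \code{B0} (on the pre-natal time axis, so the effector
#' avidity ramp sits at its basal level), and the terminal state is taken
#' as the initial condition.  During this pre-natal equilibration the
#' DC-driven T-cell expansion terms (\code{bP}, \code{bE}, \code{bR}) are
#' held at zero: the neonatal adaptive compartment is present at its
#' homeostatic level but has not yet undergone antigen-driven expansion.
#' This yields strain-specific resting levels for the macrophage,
#' glucose/insulin and dendritic-cell compartments; in particular the
#' impaired-clearance (NOD) preset starts with more necrotic debris and
#' immunogenic DCs than the Balb/c preset.
#'
#' @param p a \code{\link{t1d_parameters}} object.
#' @param equil_days length of the equilibration run, days.
#' @return Named state vector (see \code{\link{t1d_state_names}}).
#' @export
default_initial_state <- function(p, equil_days = 50) {
  p <- validate_parameters(p)
  pn <- p
  pn$bP <- 0; pn$bE <- 0; pn$bR <- 0      # pre-natal: no antigen expansion
  seed <- c(M = p$J / p$c, Ma = 0, B = p$B0, Ba = 0, Bn = 0,
            G = 100, I = 10, D = 0, tD = 0, E = 0, R = 0, Em = 0)
  out <- deSolve::lsoda(
    y = seed, times = c(-equil_days, 0), func = t1d_rhs, parms = pn,
    wave = FALSE, freeze_B = TRUE,
    rtol = 1e-8, atol = .t1d_atol(p), hmax = 1)
  st <- stats::setNames(pmax(as.numeric(out[nrow(out), t1d_state_names]), 0),
                        t1d_state_names)
  st[["Em"]] <- 0                          # no memory T cells at birth
  st
}

# Per-state absolute tolerances: B is O(mg), glucose O(100), cell
# compartments span 1e4..1e6 cells/ml.
.t1d_atol <- function(p) {
  c(M = 1e-2, Ma = 1e-2, B = 1e-10, Ba = 1e-4, Bn = 1e-4,
    G = 1e-8, I = 1e-8, D = 1e-4, tD = 1e-4, E = 1e-4, R = 1e-4, Em = 1e-4)
}

#' Simulate the model
#'
#' Stiff integration of the twelve-compartment system with optional
#' impulsive tolerogenic-DC dosing.  At each dose time the integrator
#' halts, \code{tD} jumps by \code{dose / Qpanc}, and integration
#' restarts.  If an injection pushes \code{D + tD} above the pancreatic
#' DC capacity \code{Dss} a warning is emitted; the overshoot is
#' transient (the resident-pool engulfment term turns negative above
#' capacity and pulls \code{tD} back below \code{Dss}).
#'
#' @param p a \code{\link{t1d_parameters}} object (e.g. from
#'   \code{\link{mouse_preset}}).
#' @param wave logical; include the neonatal apoptotic wave (its scale is
#'   the parameter \code{w}).
#' @param schedule optional \code{\link{dose_schedule}}.
#' @param horizon_days integration horizon, days.
#' @param init initial state; defaults to
#'   \code{\link{default_initial_state}(p)}.
#' @param dt output sampling interval, days.
#' @param rtol,hmax solver controls (relative tolerance, maximum step).
#' @return A \code{t1d_trajectory}: a \code{data.frame} with columns
#'   \code{time_days}, the 12 states, and the derived ratios
#'   \code{ratio_RE}, \code{ratio_tDD}, \code{ratio_BaBn} (denominator
#'   floored at 1e-9 cells/ml for reporting only).  Attributes carry the
#'   parameters, schedule, solver settings and a \code{flagged} field for
#'   integration failures.
#' @export
simulate_t1d <- function(p, wave = TRUE, schedule = NULL,
                         horizon_days = 280, init = NULL, dt = 0.25,
                         rtol = 1e-8, hmax = 1) {
  p <- validate_parameters(p)
  stopifnot(horizon_days > 0)
  if (is.null(init)) init <- default_initial_state(p)
  init <- init[t1d_state_names]
  if (any(init < 0) || init[["D"]] + init[["tD"]] > p$Dss + 1e-6)
    stop("initial state violates nonnegativity or D + tD <= Dss",
         call. = FALSE)
  times <- sort(unique(c(seq(0, horizon_days, by = dt), horizon_days)))
  events <- NULL
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "t1d_dose_schedule"))
    if (any(schedule$times >= horizon_days))
      stop("dose times must lie inside the horizon", call. = FALSE)
    events <- list(data = data.frame(
      var = "tD", time = schedule$times,
      value = schedule$doses / p$Qpanc, method = "add"))
    times <- sort(unique(c(times, schedule$times)))
  }
  out <- deSolve::lsoda(
    y = init, times = times, func = t1d_rhs, parms = p, wave = wave,
    rtol = rtol, atol = .t1d_atol(p), hmax = hmax, events = events,
    maxsteps = 1e5)
  diagn <- attributes(out)$istate
  df <- as.data.frame(out)
  names(df)[1] <- "time_days"

  # integration health: completed horizon, finite, no materially negative
  # states (tolerance-scale undershoot is accepted, never clamped)
  scale <- pmax(apply(abs(df[t1d_state_names]), 2, max, na.rm = TRUE), 1)
  flagged <- max(df$time_days, na.rm = TRUE) < horizon_days - 1e-8 ||
    any(!is.finite(as.matrix(df[t1d_state_names]))) ||
    any(sweep(df[t1d_state_names], 2, -1e-6 * scale, "<"))
  if (!is.null(schedule)) {
    after <- vapply(schedule$times, function(tt) {
      i <- which.min(abs(df$time_days - tt))
      df$D[i] + df$tD[i]
    }, numeric(1))
    if (any(after > p$Dss * (1 + 1e-9)))
      warning("injection pushed D + tD above the DC capacity Dss; ",
              "the overshoot decays through the resident-pool term")
  }
  floor9 <- function(x) pmax(x, 1e-9)
  df$ratio_RE   <- df$R / floor9(df$E)
  df$ratio_tDD  <- df$tD / floor9(df$D)
  df$ratio_BaBn <- df$Ba / floor9(df$Bn)
  structure(df,
            class = c("t1d_trajectory", "data.frame"),
            parameters = p, wave = wave, schedule = schedule,
            solver = list(method = "lsoda", rtol = rtol,
                          atol = .t1d_atol(p), hmax = hmax, dt = dt),
            flagged = flagged)
}

#' @export
print.t1d_trajectory <- function(x, ...) {
  cat(sprintf(
    "<t1d_trajectory> %d samples over %.1f days (preset %s, wave %s)%s\n",
    nrow(x), max(x$time_days),
    attr(attr(x, "parameters"), "preset") %||% "custom",
    if (isTRUE(attr(x, "wave"))) "on" else "off",
    if (isTRUE(attr(x, "flagged"))) " [FLAGGED]" else ""))
  cat(sprintf("  terminal glucose %.1f mg/dl, terminal B %.3f mg\n",
              x$G[nrow(x)], x$B[nrow(x)]))
  invisible(x)
}

#' First upward glucose threshold crossing
#'
#' Locates the first time glucose rises through a threshold, refining
#' between trajectory samples by linear interpolation.
#'
#' @param traj a \code{t1d_trajectory}.
#' @param threshold glucose threshold, mg/dl (250 marks overt diabetes).
#' @return Crossing time in weeks, or \code{NA_real_} if the trajectory
#'   never crosses.
#' @export
detect_threshold_crossing <- function(traj, threshold = 250) {
  g <- traj$G
  t <- traj$time_days
  up <- which(g[-length(g)] < threshold & g[-1] >= threshold)
  if (!length(up)) return(NA_real_)
  i <- up[1]
  # linear refinement inside the bracketing sample interval
  tc <- t[i] + (threshold - g[i]) * (t[i + 1] - t[i]) / (g[i + 1] - g[i])
  tc / 7
}

#' Classify a long-run outcome
#'
#' Region classification over clearance-rate space:
#' \describe{
#'   \item{III}{diabetic: glucose at the evaluation time >= threshold.}
#'   \item{II}{recovered: below threshold at evaluation but with an
#'     earlier hyperglycemic episode (an upward crossing).}
#'   \item{I}{never-diabetic: below threshold throughout.}
#' }
#'
#' @param traj a \code{t1d_trajectory}.
#' @param threshold diabetic glucose threshold, mg/dl.
#' @param eval_weeks evaluation time, weeks; the trajectory horizon must
#'   reach it.
#' @return A list of class \code{t1d_outcome}: \code{region} (\code{"I"},
#'   \code{"II"} or \code{"III"}), \code{first_crossing} (weeks or
#'   \code{NA}), \code{terminal_glucose} (mg/dl at \code{eval_weeks}) and
#'   \code{eval_time} (weeks).
#' @export
classify_outcome <- function(traj, threshold = 250, eval_weeks = 1000 / 7) {
  eval_days <- eval_weeks * 7
  if (max(traj$time_days) < eval_days - 1e-6)
    stop("trajectory horizon shorter than the evaluation time",
         call. = FALSE)
  Geval <- stats::approx(traj$time_days, traj$G, xout = eval_days)$y
  cross <- detect_threshold_crossing(traj, threshold)
  region <- if (Geval >= threshold) "III"
            else if (!is.na(cross) && cross <= eval_weeks) "II"
            else "I"
  structure(list(region = region,
                 first_crossing = cross,
                 terminal_glucose = Geval,
                 eval_time = eval_weeks),
            class = "t1d_outcome")
}

#' Integrate to steady state
#'
#' Runs the system in chunks until the largest relative state derivative
#' falls below \code{tol} (1/day, relative to each state's scale) or the
#' horizon is exhausted.
#'
#' @param p a \code{\link{t1d_parameters}} object.
#' @param wave logical; include the apoptotic wave.
#' @param horizon_days maximum integration time.
#' @param tol relative-derivative convergence tolerance.
#' @param init optional initial state.
#' @return Named terminal state with attributes \code{converged}
#'   (logical) and \code{time_days} (when the run stopped).
#' @export
steady_state <- function(p, wave = TRUE, horizon_days = 2000, tol = 1e-8,
                         init = NULL) {
  p <- validate_parameters(p)
  if (is.null(init)) init <- default_initial_state(p)
  state <- init[t1d_state_names]
  t0 <- 0
  chunk <- 250
  converged <- FALSE
  while (t0 < horizon_days) {
    t1 <- min(t0 + chunk, horizon_days)
    out <- deSolve::lsoda(y = state, times = c(t0, t1), func = t1d_rhs,
                          parms = p, wave = wave, rtol = 1e-9,
                          atol = .t1d_atol(p), hmax = 1,
                          maxsteps = 5e5)
    state <- stats::setNames(as.numeric(out[nrow(out), t1d_state_names]),
                             t1d_state_names)
    t0 <- t1
    d <- unlist(t1d_rhs(t0, state, p, wave = wave))
    rel <- abs(d) / pmax(abs(state), 1e-3)
    if (t0 > 100 && max(rel) < tol) { converged <- TRUE; break }
  }
  attr(state, "converged") <- converged
  attr(state, "time_days") <- t0
  state
}
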