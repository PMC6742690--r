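# In-silico studies: one-at-a-time sensitivity, stratified clearance-rate
# sweeps with outcome region maps, and treatment dose-by-timing sweeps.

#' One-at-a-time clearance-rate sensitivity
#'
#' Perturbs parameters individually (default: both macrophage clearance
#' rates jointly, the model's decisive pair) by a fixed fraction up and
#' down, and reports the percent change in glucose relative to the
#' unperturbed run at the requested weeks.  Both runs include the
#' apoptotic wave and share solver settings.
#'
#' @param p a \code{\link{t1d_parameters}} object.
#' @param parameters character vector of parameter names to perturb;
#'   names may be grouped with \code{"+"} (e.g. \code{"fM+fMa"}) to
#'   perturb jointly.
#' @param fraction perturbation fraction (0.05 = five percent).
#' @param weeks evaluation weeks.
#' @param wave logical; include the apoptotic wave.
#' @return \code{data.frame} with columns \code{parameter},
#'   \code{direction} (\code{"+5\%"}-style), \code{week},
#'   \code{glucose}, \code{glucose_base} and \code{percent_change}
#'   (100 * (G_perturbed - G_base)/G_base); failed runs appear with
#'   \code{NA} glucose.
#' @export
oat_sensitivity <- function(p, parameters = "fM+fMa", fraction = 0.05,
                            weeks = c(20, 25, 30, 35, 40), wave = TRUE) {
  p <- validate_parameters(p)
  horizon <- max(weeks) * 7 + 14
  base <- simulate_t1d(p, wave = wave, horizon_days = horizon, dt = 0.5)
  gb <- stats::approx(base$time_days, base$G, xout = weeks * 7)$y
  out <- list()
  for (par in parameters) {
    nm <- strsplit(par, "+", fixed = TRUE)[[1]]
    for (dir in c(1, -1)) {
      pp <- p
      for (n1 in nm) pp[[n1]] <- pp[[n1]] * (1 + dir * fraction)
      gpert <- rep(NA_real_, length(weeks))
      tr <- tryCatch(simulate_t1d(validate_parameters(pp), wave = wave,
                                  horizon_days = horizon, dt = 0.5),
                     error = function(e) NULL)
      if (!is.null(tr) && !isTRUE(attr(tr, "flagged")))
        gpert <- stats::approx(tr$time_days, tr$G, xout = weeks * 7)$y
      out[[length(out) + 1]] <- data.frame(
        parameter = par,
        direction = sprintf("%+.0f%%", 100 * dir * fraction),
        week = weeks, glucose = gpert, glucose_base = gb,
        percent_change = 100 * (gpert - gb) / gb)
    }
  }
  structure(do.call(rbind, out), class = c("t1d_sensitivity", "data.frame"))
}

#' Stratified clearance-rate sample
#'
#' Draws a stratified (Latin hypercube style) sample for the two
#' macrophage clearance rates: each marginal range is split into
#' \code{n_bins} subintervals of equal probability with exactly one
#' uniform draw per subinterval, and the two stratified marginals are
#' fully crossed, giving \code{n_bins^2} pairs.
#'
#' @param n_bins number of subintervals per parameter.
#' @param seed integer seed.
#' @param fM_range,fMa_range sampling intervals, ml cell^-1 day^-1.  The
#'   defaults are the studied ranges \code{[0.062, 3.1]e-4} for
#'   \code{fM} and \code{[0.062, 1.2]e-4} for \code{fMa}.
#' @return \code{data.frame} with columns \code{fM}, \code{fMa}
#'   (\code{n_bins^2} rows) and attributes \code{fM_draws},
#'   \code{fMa_draws} (the stratified marginals).
#' @export
lhs_sample <- function(n_bins = 50, seed = 1,
                       fM_range = c(0.062e-4, 3.1e-4),
                       fMa_range = c(0.062e-4, 1.2e-4)) {
  stopifnot(n_bins >= 1, fM_range[2] > fM_range[1],
            fMa_range[2] > fMa_range[1])
  set.seed(seed)
  strat <- function(range) {
    edges <- seq(range[1], range[2], length.out = n_bins + 1)
    stats::runif(n_bins, edges[-(n_bins + 1)], edges[-1])
  }
  fM <- strat(fM_range)
  fMa <- strat(fMa_range)
  grid <- expand.grid(fM = fM, fMa = fMa, KEEP.OUT.ATTRS = FALSE)
  structure(grid, fM_draws = fM, fMa_draws = fMa)
}

#' Outcome region map over clearance-rate combinations
#'
#' Simulates every (fM, fMa) pair to the evaluation time and classifies
#' the outcome into regions I (never diabetic), II (hyperglycemic
#' episode, recovered) and III (diabetic), for given wave scale and
#' basal effector activity.
#'
#' @param pairs \code{data.frame} with columns \code{fM}, \code{fMa}
#'   (e.g. from \code{\link{lhs_sample}}).
#' @param p base parameter set (clearance rates are overridden per
#'   pair).
#' @param w wave scale (0 switches the wave off).
#' @param eta basal effector kill strength.
#' @param eval_days evaluation time, days.
#' @param threshold diabetic glucose threshold, mg/dl.
#' @return A \code{t1d_region_map}: \code{data.frame} with the pair
#'   columns plus \code{region}, \code{terminal_glucose},
#'   \code{first_crossing} and \code{failed} (solver failures are
#'   flagged, not dropped).
#' @export
clearance_heatmap <- function(pairs, p = mouse_preset("nod"), w = 0.75,
                              eta = p$eta, eval_days = 1000,
                              threshold = 250) {
  p <- validate_parameters(p)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pi <- t1d_parameters(base = p, fM = pairs$fM[i], fMa = pairs$fMa[i],
                         w = w, eta = eta)
    rec <- tryCatch({
      tr <- simulate_t1d(pi, wave = w > 0, horizon_days = eval_days,
                         dt = 1)
      oc <- classify_outcome(tr, threshold = threshold,
                             eval_weeks = eval_days / 7)
      data.frame(region = oc$region, terminal_glucose = oc$terminal_glucose,
                 first_crossing = oc$first_crossing,
                 failed = isTRUE(attr(tr, "flagged")))
    }, error = function(e)
      data.frame(region = NA_character_, terminal_glucose = NA_real_,
                 first_crossing = NA_real_, failed = TRUE))
    res[[i]] <- rec
  }
  out <- cbind(pairs, do.call(rbind, res))
  structure(out, w = w, eta = eta, eval_days = eval_days,
            class = c("t1d_region_map", "data.frame"))
}

#' Healthy-boundary extraction from a gridded region map
#'
#' Marches an (fM, fMa) grid along fixed fMa rows and returns, per row,
#' the largest fM classified diabetic (region III) and the smallest fM
#' that is not -- bracketing the healthy boundary between regions III
#' and II/I.
#'
#' @param map a \code{t1d_region_map}.
#' @return \code{data.frame} with columns \code{fMa}, \code{fM_lo}
#'   (last diabetic), \code{fM_hi} (first non-diabetic); rows that are
#'   entirely one region give \code{NA} on the empty side.
#' @export
healthy_boundary <- function(map) {
  stopifnot(inherits(map, "t1d_region_map"))
  rows <- split(map, map$fMa)
  out <- lapply(rows, function(r) {
    r <- r[order(r$fM), ]
    dia <- r$region == "III" & !is.na(r$region)
    data.frame(fMa = r$fMa[1],
               fM_lo = if (any(dia)) max(r$fM[dia]) else NA_real_,
               fM_hi = if (any(!dia)) min(r$fM[!dia]) else NA_real_)
  })
  do.call(rbind, unname(out))
}

#' Treatment dose-by-start-time sweep
#'
#' Simulates single (or four-weekly fractionated) tolerogenic-DC
#' injections over a grid of doses and daily start times in the
#' diabetes-prone model, evaluating each run at a fixed week against the
#' diabetic glucose threshold and recording the log regulatory/effector
#' ratio.
#'
#' @param p parameter set (typically the NOD preset), wave on.
#' @param doses injected cell counts.
#' @param start_days injection start times, days.
#' @param schedule_kind \code{"single"} or \code{"weekly4"} (total dose
#'   split into four equal weekly injections).
#' @param eval_weeks evaluation time, weeks.
#' @param threshold diabetic glucose threshold, mg/dl.
#' @param quiet suppress per-run dose warnings.
#' @return A \code{t1d_treatment_map}: \code{data.frame} with columns
#'   \code{dose}, \code{start_day}, \code{glucose_eval},
#'   \code{effective} (glucose below threshold at evaluation),
#'   \code{log_RE} (log10 R/E at evaluation) and \code{failed}.
#' @export
treatment_sweep <- function(p, doses = c(2e5, 2e6),
                            start_days = seq(7, 315, by = 7),
                            schedule_kind = c("single", "weekly4"),
                            eval_weeks = 85, threshold = 250,
                            quiet = TRUE) {
  p <- validate_parameters(p)
  schedule_kind <- match.arg(schedule_kind)
  horizon <- eval_weeks * 7 + 7
  init <- default_initial_state(p)
  grid <- expand.grid(dose = doses, start_day = start_days,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sch <- if (schedule_kind == "single")
      dose_schedule(grid$start_day[i], grid$dose[i])
    else dose_schedule(grid$start_day[i] + 7 * 0:3, rep(grid$dose[i] / 4, 4))
    rec <- tryCatch({
      tr <- withCallingHandlers(
        simulate_t1d(p, wave = TRUE, schedule = sch,
                     horizon_days = horizon, dt = 1, init = init),
        warning = function(w) if (quiet) invokeRestart("muffleWarning"))
      g <- stats::approx(tr$time_days, tr$G, xout = eval_weeks * 7)$y
      re <- stats::approx(tr$time_days, pmax(tr$ratio_RE, 1e-12),
                          xout = eval_weeks * 7)$y
      data.frame(glucose_eval = g, effective = g < threshold,
                 log_RE = log10(re), failed = isTRUE(attr(tr, "flagged")))
    }, error = function(e)
      data.frame(glucose_eval = NA_real_, effective = NA,
                 log_RE = NA_real_, failed = TRUE))
    res[[i]] <- rec
  }
  out <- cbind(grid, do.call(rbind, res))
  structure(out, schedule_kind = schedule_kind, eval_weeks = eval_weeks,
            class = c("t1d_treatment_map", "data.frame"))
}

#' Windows of opportunity per dose
#'
#' Collapses a treatment map into maximal runs of consecutive effective
#' start times per dose, with the dose-row category used in the dosing
#' taxonomy: \code{no-window}, \code{single-late}, \code{double}
#' (two distinct windows) or \code{single-long} (one window opening in
#' the first half of the sweep).
#'
#' @param map a \code{t1d_treatment_map}.
#' @return List with \code{windows} (\code{data.frame}: dose,
#'   window_start_day, window_end_day) and \code{categories}
#'   (\code{data.frame}: dose, n_windows, category).
#' @export
window_report <- function(map) {
  stopifnot(inherits(map, "t1d_treatment_map"))
  win <- list(); cat_ <- list()
  for (d in sort(unique(map$dose))) {
    sub <- map[map$dose == d, ]
    sub <- sub[order(sub$start_day), ]
    eff <- !is.na(sub$effective) & sub$effective
    r <- rle(eff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- which(r$values)
    if (length(k))
      win[[length(win) + 1]] <- data.frame(
        dose = d, window_start_day = sub$start_day[starts[k]],
        window_end_day = sub$start_day[ends[k]])
    nw <- length(k)
    span <- range(sub$start_day)
    category <- if (nw == 0) "no-window"
      else if (nw >= 2) "double"
      else if (sub$start_day[starts[k[1]]] <= span[1] + diff(span) / 2)
        "single-long"
      else "single-late"
    cat_[[length(cat_) + 1]] <- data.frame(dose = d, n_windows = nw,
                                           category = category)
  }
  list(windows = if (length(win)) do.call(rbind, win) else
         data.frame(dose = numeric(), window_start_day = numeric(),
                    window_end_day = numeric()),
       categories = do.call(rbind, cat_))
}

#' Critical transition times of a dose's effectiveness
#'
#' Scans start times at one-day resolution (refining an initial coarse
#' sweep around sign changes) and reports the earliest effective start
#' time and, if the window closes again, the first subsequent
#' ineffective start time.
#'
#' @param p parameter set (NOD preset, wave on).
#' @param dose injected cells.
#' @param coarse_by coarse scan step, days.
#' @param span scanned start-time range, days.
#' @param eval_weeks,threshold evaluation settings.
#' @return List with \code{first_effective_week} and
#'   \code{first_ineffective_week} (NA if the window never opens or
#'   never closes inside the span).
#' @export
critical_transitions <- function(p, dose, coarse_by = 7,
                                 span = c(7, 315), eval_weeks = 85,
                                 threshold = 250) {
  p <- validate_parameters(p)
  init <- default_initial_state(p)
  eff <- function(day) {
    tr <- suppressWarnings(simulate_t1d(
      p, wave = TRUE, schedule = dose_schedule(day, dose),
      horizon_days = eval_weeks * 7 + 7, dt = 1, init = init))
    stats::approx(tr$time_days, tr$G, xout = eval_weeks * 7)$y < threshold
  }
  days <- seq(span[1], span[2], by = coarse_by)
  e <- vapply(days, eff, logical(1))
  refine_up <- function(lo, hi) {        # first TRUE in (lo, hi]
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (eff(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  refine_down <- function(lo, hi) {      # first FALSE in (lo, hi]
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (!eff(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  first_eff <- NA_real_
  first_ineff <- NA_real_
  k <- which(e)
  if (length(k)) {
    first_eff <- if (k[1] == 1) days[1] else
      refine_up(days[k[1] - 1], days[k[1]])
    k2 <- which(!e & seq_along(e) > k[1])
    if (length(k2))
      first_ineff <- refine_down(days[k2[1] - 1], days[k2[1]])
  }
  list(first_effective_week = first_eff / 7,
       first_ineffective_week = first_ineff / 7)
}
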