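# Reduced phagocytosis-assay model and engulfment-rate estimation.
#
# In the assay a phagocyte population P (macrophages, mature DCs or
# immature DCs) is mixed 1:1 with apoptotic cells C(0) = P.  Each
# phagocyte engulfs with a single clearance rate gP regardless of prior
# cargo; Pe(t) counts phagocytes that have engulfed at least once:
#   dC/dt  = -gP * P * C,          C(0)  = P
#   dPe/dt =  gP * (P - Pe) * C,   Pe(0) = 0
# with closed forms C(t) = P exp(-gP P t) and
# Pe(t) = P (1 - exp(exp(-gP P t) - 1)).

#' Closed-form solution of the assay model
#'
#' @param t time, hours (vectorized).
#' @param gP engulfment rate, ml cell^-1 hour^-1.
#' @param P phagocyte count (= initial apoptotic count), cells/ml.
#' @return \code{data.frame} with columns \code{t}, \code{C}
#'   (remaining apoptotic cells) and \code{Pe} (phagocytes that have
#'   engulfed).  As \code{t} grows, \code{Pe/P} saturates at
#'   \code{1 - exp(-1)}, independent of \code{gP}.
#' @export
assay_closed_form <- function(t, gP, P) {
  stopifnot(all(t >= 0), gP >= 0, P >= 0)
  x <- exp(-gP * P * t)
  data.frame(t = t, C = P * x, Pe = P * (1 - exp(x - 1)))
}

#' Percent phagocytosis
#'
#' The assay readout: \code{rho = Pe / P * 100}.
#'
#' @param Pe engulfed-phagocyte count, cells/ml.
#' @param P total phagocyte count, cells/ml.
#' @return Percent in \code{[0, 100]}.
#' @export
percent_phagocytosis <- function(Pe, P) 100 * Pe / P

#' Generate a synthetic phagocytosis time course
#'
#' Draws noisy percent-phagocytosis observations from the closed-form
#' assay model: Gaussian observation error on the percent scale, clipped
#' to \code{[0, 100]}.
#'
#' @param gP true engulfment rate, ml cell^-1 hour^-1.
#' @param P phagocyte count, cells/ml.
#' @param times observation times, hours.
#' @param noise_sd observation noise SD, percent points.
#' @param seed integer seed.
#' @param cell_type label carried in the result.
#' @return An \code{assay_data} object: \code{data.frame} with columns
#'   \code{cell_type}, \code{time_h}, \code{percent}, and attribute
#'   \code{P}.
#' @export
generate_synthetic_assay <- function(gP, P, times = seq(0.1, 4, by = 0.1),
                                     noise_sd = 2, seed = 1,
                                     cell_type = "macrophage") {
  stopifnot(gP > 0, P > 0, all(times >= 0), noise_sd >= 0)
  set.seed(seed)
  rho <- percent_phagocytosis(assay_closed_form(times, gP, P)$Pe, P)
  obs <- pmin(pmax(rho + stats::rnorm(length(times), 0, noise_sd), 0), 100)
  structure(data.frame(cell_type = cell_type, time_h = times,
                       percent = obs),
            P = P, class = c("assay_data", "data.frame"))
}

#' Read assay data from CSV
#'
#' Expects columns \code{cell_type}, \code{time_h}, \code{percent}; the
#' phagocyte count is passed separately (the assay reports percentages).
#'
#' @param path CSV file path.
#' @param P phagocyte count, cells/ml.
#' @return An \code{assay_data} object.
#' @export
read_assay_csv <- function(path, P) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "time_h", "percent")
  if (!all(need %in% names(d)))
    stop("assay CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(d$percent < 0 | d$percent > 100) || any(d$time_h < 0))
    stop("assay data out of range (percent in [0,100], time_h >= 0)",
         call. = FALSE)
  structure(d[need], P = P, class = c("assay_data", "data.frame"))
}

# Gaussian log-likelihood of percent observations under rate g, noise sd
.assay_loglik <- function(g, sigma, data, P) {
  mu <- percent_phagocytosis(assay_closed_form(data$time_h, g, P)$Pe, P)
  sum(stats::dnorm(data$percent, mu, sigma, log = TRUE))
}

#' Fit an engulfment rate by Metropolis MCMC
#'
#' Maximum-likelihood estimation of the assay engulfment rate \code{gP}
#' (and the observation noise SD, estimated jointly) using a Metropolis
#' random walk on the log scale under flat priors within bounds.  Only
#' observations up to \code{t_max} hours enter the likelihood: near the
#' saturation plateau the percent-phagocytosis no longer depends on the
#' rate, so the transient (default first hour) identifies \code{gP}.
#'
#' @param data an \code{assay_data} object (or data.frame with
#'   \code{time_h}, \code{percent}).
#' @param P phagocyte count, cells/ml; defaults to the \code{P}
#'   attribute of \code{data}.
#' @param t_max fitting window, hours.
#' @param n_steps number of MCMC steps.
#' @param seed integer seed.
#' @param g_bounds bounds of the flat prior on \code{gP}; default spans
#'   two orders of magnitude either side of a coarse grid-search
#'   initializer.
#' @param step proposal SD on the log scale, tuned for 20-40 percent
#'   acceptance at the default.
#' @return An \code{engulfment_fit}: list with \code{g} (MLE, the
#'   maximum-posterior sample), \code{sigma}, \code{chain} (matrix of
#'   samples), \code{acceptance}, \code{seed}, \code{ci90} (central 90
#'   percent interval of the chain).
#' @export
fit_engulfment_mcmc <- function(data, P = attr(data, "P"), t_max = 1,
                                n_steps = 20000, seed = 1,
                                g_bounds = NULL, step = 0.25) {
  d <- data[data$time_h <= t_max & data$time_h > 0, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 time points inside the fitting window",
         call. = FALSE)
  if (all(d$percent == 0))
    stop("degenerate assay data: all percents zero", call. = FALSE)
  if (is.null(P)) stop("phagocyte count P required", call. = FALSE)
  sat <- 100 * (1 - exp(-1))
  if (all(abs(d$percent - sat) < 1)) {
    warning("assay data sit at the saturation plateau; ",
            "the rate is unidentifiable from these times")
  }
  # coarse grid initializer
  if (is.null(g_bounds)) {
    grid <- 10^seq(-9, -2, by = 0.25) / P * 1e5   # scale-free-ish sweep
    ll <- vapply(grid, function(g) .assay_loglik(g, 5, d, P), 1)
    g0 <- grid[which.max(ll)]
    g_bounds <- c(g0 / 100, g0 * 100)
  } else {
    g0 <- sqrt(prod(g_bounds))
  }
  set.seed(seed)
  g <- g0
  sigma <- max(stats::sd(d$percent) / 2, 0.5)
  lp <- .assay_loglik(g, sigma, d, P)
  chain <- matrix(NA_real_, n_steps, 3,
                  dimnames = list(NULL, c("g", "sigma", "loglik")))
  acc <- 0L
  for (i in seq_len(n_steps)) {
    gp <- g * exp(stats::rnorm(1, 0, step))
    sp <- sigma * exp(stats::rnorm(1, 0, step / 2))
    if (gp >= g_bounds[1] && gp <= g_bounds[2] && sp > 1e-3 && sp < 50) {
      lpp <- .assay_loglik(gp, sp, d, P)
      # Metropolis on log-parameters: symmetric proposal in log space
      # needs the Jacobian ratio (gp*sp)/(g*sigma)
      if (log(stats::runif(1)) < lpp - lp + log(gp / g) + log(sp / sigma)) {
        g <- gp; sigma <- sp; lp <- lpp; acc <- acc + 1L
      }
    }
    chain[i, ] <- c(g, sigma, lp)
  }
  accr <- acc / n_steps
  if (accr < 0.05) warning("MCMC acceptance below 5%; chain may not mix")
  burn <- seq_len(floor(n_steps / 5))
  post <- chain[-burn, , drop = FALSE]
  best <- post[which.max(post[, "loglik"]), ]
  structure(list(g = unname(best["g"]), sigma = unname(best["sigma"]),
                 chain = post, acceptance = accr, seed = seed,
                 ci90 = unname(stats::quantile(post[, "g"],
                                               c(0.05, 0.95)))),
            class = "engulfment_fit")
}

#' @export
print.engulfment_fit <- function(x, ...) {
  cat(sprintf(
    "<engulfment_fit> g = %.4g ml/cell/h (90%% CI %.3g-%.3g), sigma = %.2f, acceptance %.0f%%\n",
    x$g, x$ci90[1], x$ci90[2], x$sigma, 100 * x$acceptance))
  invisible(x)
}

#' Scale mouse DC clearance rates from assay rate ratios
#'
#' The full-model DC clearance rates are obtained by assuming the
#' human-assay ratios of DC-to-macrophage engulfment rates carry over to
#' the mouse: \code{fD = (gD/gMa) fMa} and \code{ftD = (gtD/gMa) fMa},
#' where \code{fMa} is the healthy-strain activated-macrophage clearance
#' rate.  The default ratios are the canonical fitted constants
#' \code{gD/gMa = 5.49e-2} and \code{gtD/gMa = 3.82e-1}.
#'
#' @param fMa activated-macrophage clearance rate, ml cell^-1 day^-1.
#' @param ratio_D,ratio_tD rate ratios; either the defaults or ratios
#'   from \code{\link{fit_engulfment_mcmc}} fits
#'   (\code{gD/gMa}, \code{gtD/gMa}).
#' @return Named list with \code{fD} and \code{ftD} (ml cell^-1 day^-1).
#' @examples
#' scale_rates(3.1e-4)
#' @export
scale_rates <- function(fMa, ratio_D = 5.49e-2, ratio_tD = 3.82e-1) {
  stopifnot(fMa > 0, ratio_D > 0, ratio_tD > 0)
  list(fD = ratio_D * fMa, ftD = ratio_tD * fMa)
}
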