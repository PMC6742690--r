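# Auxiliary kinetic functions and the full ODE right-hand side.
#
# State ordering (fixed everywhere in the package):
#   M, Ma  resting / activated macrophages        [cells/ml]
#   B      healthy beta-cell mass                 [mg]
#   Ba, Bn apoptotic / necrotic beta cells        [cells/ml]
#   G      blood glucose                          [mg/dl]
#   I      insulin                                [muU]
#   D, tD  immunogenic / tolerogenic dendritic cells [cells/ml]
#   E, R, Em effector / regulatory / memory T cells  [cells/ml]

#' Names of the twelve model state variables, in canonical order
#' @export
t1d_state_names <- c("M", "Ma", "B", "Ba", "Bn", "G", "I",
                     "D", "tD", "E", "R", "Em")

#' Saturating glucose response
#'
#' Hill-type (coefficient 2) saturating response used both for
#' glucose-dependent beta-cell growth and for glucose-stimulated insulin
#' secretion: \code{G^2 / (G^2 + Ghalf^2)}.
#'
#' @param G glucose concentration, mg/dl (nonnegative).
#' @param Ghalf half-maximum glucose level, mg/dl (positive).
#' @return Fraction in \code{[0, 1]}, strictly increasing in \code{G}.
#' @examples
#' k1(100, 100)   # 0.5 at the half-max
#' @export
k1 <- function(G, Ghalf) {
  if (any(G < 0) || any(Ghalf <= 0))
    stop("k1(): G must be >= 0 and Ghalf > 0", call. = FALSE)
  G2 <- G * G
  G2 / (G2 + Ghalf * Ghalf)
}

#' Effector-driven beta-cell apoptosis response
#'
#' Saturating effector T-cell kill term, down-modulated by regulatory
#' T cells: \code{(sE*E)^2 / (1 + (sE*E)^2 + (sR*R)^2)}.  Increasing in
#' \code{E}, decreasing in \code{R}, bounded in \code{[0, 1)}.
#'
#' @param E,R effector / regulatory T-cell concentrations, cells/ml.
#' @param sE,sR effector / regulatory scaling factors, ml/cell.
#' @return Fraction in \code{[0, 1)}.
#' @export
k2 <- function(E, R, sE, sR) {
  if (any(E < 0) || any(R < 0))
    stop("k2(): E and R must be >= 0", call. = FALSE)
  e2 <- (sE * E)^2
  r2 <- (sR * R)^2
  e2 / (1 + e2 + r2)
}

#' Time-dependent effector T-cell kill rate
#'
#' Ramp in effector avidity against beta cells,
#' \code{eta_e(t) = eta + 2*eta*(1 + tanh(alphaE*(t - betaE)))}:
#' monotone nondecreasing, from \code{eta} (early life) to \code{5*eta}
#' (late), passing through \code{3*eta} at \code{t = betaE}.
#'
#' @param t age, days.
#' @param eta basal kill strength, 1/day.
#' @param alphaE ramp steepness, 1/day.
#' @param betaE ramp midpoint, days.
#' @return Kill rate, 1/day.
#' @export
eta_e <- function(t, eta, alphaE, betaE) {
  eta + 2 * eta * (1 + tanh(alphaE * (t - betaE)))
}

#' Neonatal apoptotic wave
#'
#' Transient developmental surge of beta-cell apoptosis during weaning,
#' \code{W(B, t) = 0.1 * w * B * exp(-((t - 9) / 9)^2)}: peaks at 9 days
#' of age at 10 percent of the current beta-cell mass per day (for
#' \code{w = 1}).
#'
#' @param B healthy beta-cell mass, mg (nonnegative).
#' @param t age, days (nonnegative).
#' @param w dimensionless wave scale (0 switches the wave off).
#' @return Beta-cell mass loss rate, mg/day.
#' @export
apoptotic_wave <- function(B, t, w) {
  if (any(B < 0) || any(t < 0))
    stop("apoptotic_wave(): B and t must be >= 0", call. = FALSE)
  0.1 * w * B * exp(-((t - 9) / 9)^2)
}

#' Right-hand side of the twelve-compartment model
#'
#' Time derivative of the full pancreatic-compartment system: macrophages,
#' beta cells (healthy in mg; apoptotic/necrotic in cells/ml, converted
#' with the factor \code{Bconv/Qpanc}), glucose and insulin, dendritic
#' cells with a shared resident pool \code{iD = Dss - D - tD}, and
#' effector/regulatory/memory T cells.
#'
#' In the signature used by \pkg{deSolve}: returns
#' \code{list(derivatives)}.
#'
#' @param t time, days.
#' @param state named numeric vector in the order of
#'   \code{\link{t1d_state_names}}.
#' @param p a \code{\link{t1d_parameters}} object (or plain named list).
#' @param wave logical; include the apoptotic wave term?
#' @param freeze_B logical; hold the healthy beta-cell mass constant
#'   (used when equilibrating initial conditions).
#' @return \code{list} with the twelve derivatives, as expected by
#'   \code{\link[deSolve]{lsoda}}.
#' @export
t1d_rhs <- function(t, state, p, wave = TRUE, freeze_B = FALSE) {
  if (any(!is.finite(state)))
    stop("t1d_rhs(): non-finite state at t = ", t, call. = FALSE)
  M  <- state[["M"]];  Ma <- state[["Ma"]]
  B  <- state[["B"]];  Ba <- state[["Ba"]]; Bn <- state[["Bn"]]
  G  <- state[["G"]];  I  <- state[["I"]]
  D  <- state[["D"]];  tD <- state[["tD"]]
  E  <- state[["E"]];  R  <- state[["R"]];  Em <- state[["Em"]]

  conv  <- p$Bconv / p$Qpanc               # mg -> cells/ml
  etat  <- eta_e(t, p$eta, p$alphaE, p$betaE)
  K1g   <- k1(max(G, 0), p$Ghb)
  K2er  <- k2(max(E, 0), max(R, 0), p$sE, p$sR)
  Wv    <- if (wave) apoptotic_wave(max(B, 0), max(t, 0), p$w) else 0

  engulf <- p$fM * M + p$fMa * Ma + p$ftD * (p$Dss - D) + p$fD * D

  dM  <- p$J + (p$k + p$b) * Ma - p$c * M - p$fM * M * Ba - p$fM * M * Bn -
    p$e1 * M * (M + Ma)
  dMa <- p$fM * M * Ba + p$fM * M * Bn - p$k * Ma - p$e2 * Ma * (M + Ma)

  dB  <- if (freeze_B) 0 else
    p$alphaB * K1g * B - p$deltaB * B - etat * K2er * B - Wv

  dBa <- conv * (p$deltaB * B + etat * K2er * B + Wv) - p$d * Ba - engulf * Ba
  dBn <- p$d * Ba - engulf * Bn

  dG  <- p$R0 - (p$G0 + p$SI * I) * G
  dI  <- p$sigmaI * k1(max(G, 0), p$GI) * B - p$deltaI * I

  iD  <- p$Dss - D - tD
  dD  <- p$ftD * Bn * iD + p$ftD * Bn * tD - p$bDE * E * D - p$muD * D
  dtD <- p$ftD * Ba * iD - p$ftD * Bn * tD - p$bIR * R * tD - p$muD * tD

  dE  <- p$aE * (p$Tnaive - E) + p$bP * D * E / (p$thetaD + D) -
    p$ram * E + p$bE * D * Em - p$muE * E * R
  dR  <- p$aR * (p$Tnaive - R) + p$bP * tD * R / (p$thetaD + tD) -
    p$ram * R + p$bR * tD * Em - p$muR * E * R
  dEm <- p$ram * (E + R) - (p$aEm + p$bE * D + p$bR * tD) * Em

  list(c(dM, dMa, dB, dBa, dBn, dG, dI, dD, dtD, dE, dR, dEm))
}
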