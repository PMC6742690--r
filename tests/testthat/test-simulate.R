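# Integration, dosing impulses, event detection and outcome classes.

test_that("a dose is an impulse of exactly dose/Qpanc on the tD compartment", {
  p <- mouse_preset("nod")
  init <- default_initial_state(p)
  dose <- 2e5
  tr <- suppressWarnings(
    simulate_t1d(p, wave = FALSE, schedule = dose_schedule(10, dose),
                 horizon_days = 12, dt = 0.01, init = init))
  tr0 <- simulate_t1d(p, wave = FALSE, horizon_days = 12, dt = 0.01,
                      init = init)
  # first sample after the impulse; the pulse already decays at a few
  # percent per 0.01 day through pool pull-back and removal
  i <- which.min(abs(tr$time_days - 10.01))
  i0 <- which.min(abs(tr0$time_days - 10.01))
  expect_equal(tr$tD[i] - tr0$tD[i0], dose / p$Qpanc, tolerance = 5e-2)
  # and immediately before it the two runs are identical
  j <- which.min(abs(tr$time_days - 9.99))
  expect_equal(tr$tD[j], tr0$tD[j], tolerance = 1e-9)
})

test_that("dose schedules validate times, positivity and the studied range", {
  expect_error(dose_schedule(c(10, 10), 2e5), "strictly increasing")
  expect_error(dose_schedule(10, -1), "positive")
  expect_warning(dose_schedule(10, 5e3), "studied range")
  s <- dose_schedule(c(10, 17, 24, 31), 5e4)
  expect_length(s$doses, 4)
})

test_that("threshold crossing is located within a sample step on a constructed trajectory", {
  tr <- structure(data.frame(time_days = seq(0, 300, 0.5)),
                  class = c("t1d_trajectory", "data.frame"))
  tstar <- 171.3
  tr$G <- 100 + 200 / (1 + exp(-(tr$time_days - tstar) / 5))
  # G(tstar) = 200 crosses 250 where logistic = 0.75: tstar + 5*log(3)
  expected <- (tstar + 5 * log(3)) / 7
  expect_equal(detect_threshold_crossing(tr, 250), expected,
               tolerance = 0.01)
  tr$G <- rep(89, nrow(tr))
  expect_true(is.na(detect_threshold_crossing(tr, 250)))
})

test_that("outcome classes follow the region definitions", {
  mk <- function(g) structure(
    data.frame(time_days = seq(0, 1000, 1), G = g),
    class = c("t1d_trajectory", "data.frame"))
  tt <- seq(0, 1000, 1)
  # never crosses -> I
  oc1 <- classify_outcome(mk(rep(100, 1001)), eval_weeks = 1000 / 7)
  expect_identical(oc1$region, "I")
  # crosses then recovers -> II
  g2 <- 100 + 300 * exp(-((tt - 300) / 80)^2)
  oc2 <- classify_outcome(mk(g2), eval_weeks = 1000 / 7)
  expect_identical(oc2$region, "II")
  expect_false(is.na(oc2$first_crossing))
  # ends high -> III, and a boundary tie counts as diabetic
  g3 <- 100 + 0.45 * tt
  oc3 <- classify_outcome(mk(g3), eval_weeks = 1000 / 7)
  expect_identical(oc3$region, "III")
  g4 <- rep(250, 1001)
  expect_identical(classify_outcome(mk(g4), eval_weeks = 100)$region, "III")
  expect_error(classify_outcome(mk(rep(1, 1001)), eval_weeks = 300),
               "horizon")
})

test_that("states stay nonnegative and the DC pool stays within capacity over 1000 days", {
  for (nm in c("nod", "balbc")) {
    p <- mouse_preset(nm)
    tr <- simulate_t1d(p, wave = TRUE, horizon_days = 1000, dt = 1)
    expect_false(attr(tr, "flagged"))
    states <- as.matrix(as.data.frame(tr)[t1d_state_names])
    scale <- pmax(apply(abs(states), 2, max), 1)
    expect_true(all(t(states) > -1e-6 * scale))
    expect_true(all(tr$D + tr$tD <= p$Dss * (1 + 1e-6)))
  }
})

test_that("crossing time is stable under solver tolerance refinement", {
  p <- mouse_preset("nod")
  t1 <- detect_threshold_crossing(
    simulate_t1d(p, wave = TRUE, horizon_days = 240, dt = 0.25))
  t2 <- detect_threshold_crossing(
    simulate_t1d(p, wave = TRUE, horizon_days = 240, dt = 0.25,
                 rtol = 5e-9, hmax = 0.5))
  expect_false(is.na(t1))
  expect_lt(abs(t1 - t2) * 7, 0.1)          # < 0.1 day
})

test_that("identical inputs give bit-identical trajectories", {
  p <- mouse_preset("balbc")
  tr1 <- simulate_t1d(p, wave = TRUE, horizon_days = 100, dt = 0.5)
  tr2 <- simulate_t1d(p, wave = TRUE, horizon_days = 100, dt = 0.5)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
})

test_that("glucose-insulin subsystem reproduces the algebraic steady state with frozen beta mass", {
  p <- mouse_preset("balbc")
  for (B in c(0.4, p$B0)) {
    pp <- p; pp$B0 <- B
    # independent algebraic root: R0 = (G0 + SI * sigmaI*K1(G,GI)*B/deltaI) * G
    f <- function(G) p$R0 -
      (p$G0 + p$SI * p$sigmaI * k1(G, p$GI) * B / p$deltaI) * G
    Gstar <- stats::uniroot(f, c(1, 600), tol = 1e-12)$root
    st <- c(M = 0, Ma = 0, B = B, Ba = 0, Bn = 0, G = 150, I = 0,
            D = 0, tD = 0, E = 0, R = 0, Em = 0)
    out <- deSolve::lsoda(st, times = c(0, 400), t1d_rhs, parms = pp,
                          wave = FALSE, freeze_B = TRUE,
                          rtol = 1e-10, atol = 1e-10)
    expect_equal(unname(out[2, "G"]), Gstar, tolerance = 1e-6)
  }
})

test_that("with the immune system silenced, beta mass settles at the closed-form balance", {
  p0 <- mouse_preset("balbc")
  p <- t1d_parameters(base = p0, aE = 0, aR = 0, ram = 0, bP = 0,
                      bE = 0, bR = 0)
  # B* solves alphaB*K1(G*,Ghb) = deltaB with the glucose subsystem:
  # K1(G*) = deltaB/alphaB gives G*; then I* from the glucose balance
  # and B* = I* deltaI / (sigmaI K1(G*, GI)).
  r <- p$deltaB / p$alphaB
  Gstar <- p$Ghb * sqrt(r / (1 - r))
  Istar <- (p$R0 / Gstar - p$G0) / p$SI
  Bstar <- Istar * p$deltaI / (p$sigmaI * k1(Gstar, p$GI))
  st <- c(M = p$J / p$c, Ma = 0, B = p$B0, Ba = 0, Bn = 0, G = 100,
          I = 10, D = 0, tD = 0, E = 0, R = 0, Em = 0)
  out <- deSolve::lsoda(st, times = c(0, 4000), t1d_rhs, parms = p,
                        wave = FALSE, rtol = 1e-10, atol = 1e-8)
  expect_equal(unname(out[2, "G"]), Gstar, tolerance = 1e-4)
  expect_equal(unname(out[2, "B"]), Bstar, tolerance = 1e-3)
})

test_that("steady_state glucose is stable under horizon extension", {
  p <- mouse_preset("balbc")
  ss1 <- steady_state(p, wave = FALSE, horizon_days = 1500)
  ss2 <- steady_state(p, wave = FALSE, horizon_days = 2500)
  expect_true(is.logical(attr(ss1, "converged")))
  expect_true(all(ss1 >= 0))
  expect_lt(abs(ss1[["G"]] - ss2[["G"]]) / ss2[["G"]], 1e-3)
})
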