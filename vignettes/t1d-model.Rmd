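---
title: "A single-compartment immune model of type 1 diabetes initiation and tolerogenic-DC vaccination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A single-compartment immune model of type 1 diabetes initiation and tolerogenic-DC vaccination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dsim)
```

## The model

`t1dsim` simulates the initiation of autoimmune (type 1) diabetes in a
single well-mixed pancreatic compartment with twelve state variables:
resting and activated macrophages $M, M_a$ (cells/ml); healthy
$\beta$-cell mass $B$ (mg); apoptotic and necrotic $\beta$ cells
$B_a, B_n$ (cells/ml); glucose $G$ (mg/dl); insulin $I$ ($\mu$U);
immunogenic and tolerogenic dendritic cells $D, tD$ (cells/ml); and
effector, regulatory and memory T cells $E, R, E_m$ (cells/ml).

The mechanistic core is the *clearance hypothesis*: dying $\beta$ cells
are engulfed by macrophages and dendritic cells; apoptotic cells that
are cleared slowly decay (rate $d$) into necrotic cells.  Apoptotic
cargo turns a resident DC tolerogenic; necrotic cargo turns it
immunogenic.  Tolerogenic DCs drive regulatory T cells, immunogenic DCs
drive effector T cells, and effectors kill healthy $\beta$ cells
through the saturating response
$$K_2(E, R) = \frac{(s_E E)^2}{1 + (s_E E)^2 + (s_R R)^2},$$
scaled by an age-dependent avidity ramp
$\eta_e(t) = \eta + 2\eta(1 + \tanh(\alpha_e (t - \beta_e)))$, which
rises from $\eta$ to $5\eta$ around $\beta_e$ days.  A neonatal
*apoptotic wave* $W(B,t) = 0.1\,w\,B\,e^{-((t-9)/9)^2}$ peaks at 9 days
of age at 10% of the $\beta$ mass per day (for $w = 1$; the default
scale is $w = 0.75$).  Glucose and insulin follow the classical
two-compartment kinetics with constant glucose production $R_0$,
insulin-independent clearance $G_0 G$, insulin-dependent clearance
$S_I I G$, and $\beta$-mass-proportional insulin secretion.

Mouse strains differ *only* in the two macrophage clearance rates:
the control strain (Balb/c preset) clears at
$f_M = 1.2\times10^{-4}$, $f_{Ma} = 3.1\times10^{-4}$ ml/cell/day,
while the diabetes-prone NOD preset is impaired roughly twelve-fold
and sits close to the healthy boundary of the clearance-rate plane.
DC clearance rates are shared by the strains and scaled from the
healthy activated-macrophage rate with the assay-derived ratios
$f_D = 5.49\times10^{-2} f_{Ma}$ and
$f_{tD} = 3.82\times10^{-1} f_{Ma}$.

## The bistable race

The model has two attractors.  In the healthy state regulatory T cells
are abundant, $K_2 \approx 0$, and glucose settles at 89 mg/dl.  In the
diseased state the $\beta$ mass is destroyed, glucose settles at
$R_0/G_0 = 539$ mg/dl, and the immune compartment relaxes to an
effector-biased homeostatic state whose residual kill pressure keeps
any regrowing $\beta$ cells suppressed.

Which attractor is reached is decided by a race in the first weeks of
life.  At birth the adaptive compartment is antigen-inexperienced:
the pre-natal equilibration holds the DC-driven expansion terms at zero
and starts the memory pool empty, leaving a naive state in which the
homeostatic effector level exceeds the (mutually suppressed) regulatory
level.  The apoptotic wave floods the compartment with dying cells; in
an impaired-clearance mouse enough of them become necrotic to saturate
the immunogenic-DC channel, and the effector pool expands before the
regulatory pool can.  Mutual suppression ($\mu_E E R$, $\mu_R E R$)
then locks the winner in.  With healthy clearance rates (either strain)
or without the wave (any strain) the necrotic channel stays quiet, the
effector pool decays, and regulatory cells proliferating on the
tolerogenic-DC signal take over.  The effector avidity ramp converts
the NOD+wave stand-off into overt disease: glucose crosses the 250
mg/dl diagnostic threshold at 24.2 weeks of age in the packaged
registry.

## Parameters

The packaged registries (`inst/extdata/nod.yaml`, `balbc.yaml`) carry a
provenance string per constant.  Three blocks are standard-literature
values: the macrophage turnover block ($J = 5\times10^4$, $k = 0.4$,
$b = 0.09$, $c = 0.1$, $e_{1,2} = 10^{-8}$, $d = 0.5$), the
glucose-insulin block (rescaled so that a 2 mg mouse $\beta$ mass
yields the healthy 89 mg/dl steady state, and $R_0/G_0$ equals the
539 mg/dl insulin-free level), and the assay-ratio DC clearances.  The
T-cell/DC interaction block is not reported in the primary literature
at this granularity; its constants were calibrated numerically, in the
order: glucose steady states first, then the 24.3-week onset, with the
sensitivity and treatment behaviours used as held-out checks.  The
calibration targets a knife-edge: the NOD preset must become diabetic
*only* in the presence of the wave, which pins the suppression
asymmetry $\mu_R/\mu_E \approx 10$ and places the NOD clearance rates
about 4% below the healthy boundary (so a 5% improvement in clearance
rescues the mouse, while a 5% impairment does not measurably worsen
it -- and the robust Balb/c preset is insensitive to either).

Numerical choices: `deSolve::lsoda` with relative tolerance $10^{-8}$,
per-state absolute tolerances (the $\beta$ mass is $O(1)$ mg while cell
pools reach $10^6$/ml), and a 1-day maximum step so the 9-day wave is
never skipped.  Negative states are never clamped; any state below
$-10^{-6}$ of its scale flags the run.  Threshold crossings are located
by linear interpolation on 0.25-day output, which is three orders of
magnitude finer than the reported precision.  Ratios ($R/E$, $tD/D$,
$B_a/B_n$) floor their denominators at $10^{-9}$ cells/ml for reporting
only, never in the dynamics.

## Dosing

Tolerogenic-DC vaccination is an impulse: at each scheduled time the
integrator halts and $tD$ jumps by (dose cells)$/Q_{panc}$.  We do not
truncate the injected pulse at the resident capacity $D_{ss}$: every
studied dose ($10^4$ to $5\times10^6$ cells) exceeds the capacity of a
0.17 ml compartment, so truncation would erase the dose-response that
the treatment studies measure.  The equations are self-correcting --
above capacity the resident-pool engulfment term reverses sign and the
overshoot decays within days -- and no state can go negative;
`simulate_t1d()` warns when an injection exceeds the capacity.
Injected cells gain no extra engulfment function while the pool is
over capacity, and obey the same death and removal dynamics as native
tolerogenic DCs.

A dose succeeds by converting the memory pool: the reactivation flux
$b_R \, tD \, E_m$ turns memory cells into regulators while the pulse
lasts.  Because the mutual-suppression terms conserve
$\mu_R E - \mu_E R$ exactly, a pulse flips the system only if the
delivered regulatory boost exceeds $(\mu_R/\mu_E) E(t)$ -- treatment
windows therefore track the ratio of the memory reservoir to the
current effector load, and successful treatments show
$\log(R/E) > 0$ at evaluation while failures show the opposite.

## What the packaged registry reproduces, and what it does not

Reproduced at the reported precision: the healthy (89 mg/dl) and
diseased (539 mg/dl) glucose steady states; diabetes onset of the
untreated NOD+wave mouse at 24.2 weeks; no 250 mg/dl crossing within
40 weeks for NOD-without-wave or Balb/c; Balb/c glucose insensitivity
(< 0.01%) to 5% clearance perturbations; a bounded (< 1%) response to
clearance impairment in the NOD mouse at week 40.

Reproduced qualitatively but not at the reported numbers: a 5% increase
in NOD clearance rates rescues the mouse, but in this registry the
rescue is complete by week 40 (an 81% glucose reduction rather than the
reported 60% partial recovery).  Tolerogenic-DC dosing is
time-and-dose dependent -- no dose rescues a week-4 start, the low dose
fails at week 10 while late starts can still be rescued -- and the
low-dose window opens just after diabetes onset (26.1 weeks vs the
reported 24.86).  But the high-dose map is non-monotone here: a brief
effective window around weeks 2-3.5 (a large pulse tips the still
unresolved birth race), a long ineffective stretch until about week 22
(the suppression asymmetry forced by the strain discrimination makes
mid-course effector loads too high for any memory-backed pulse), and
effectiveness again thereafter; and the low-dose window does not close
within the studied 45-week start range because the post-collapse state
is too easy to flip.  These are properties of this calibration, not of
the interface; a registry with the unpublished supplementary constants
can be dropped into the YAML files without code changes.

## The synthetic assay and what passing tests show

The engulfment-rate fitting path is exercised end-to-end on synthetic
phagocytosis time courses generated from the reduced assay model
(closed forms $C(t) = P e^{-g_P P t}$,
$P_e(t) = P(1 - e^{e^{-g_P P t} - 1})$) plus Gaussian observation noise
on the percent scale, clipped to $[0, 100]$.  This emulates the
*structure* of a real co-culture assay -- 1:1 phagocyte-to-apoptotic
ratio, percent-phagocytosis readout, saturation at $1 - e^{-1}$ -- but
not its biological error sources (plate effects, counting error,
heterogeneous phagocyte activity).  Parameter-recovery and coverage
tests therefore validate the estimator, not any claim about real
cells.  Fitting uses only the first hour of the time course: at the
plateau the readout is rate-independent, so later points carry no
information about $g_P$.  The Metropolis sampler walks
$(\log g_P, \log \sigma)$ jointly under flat bounded priors (four
orders of magnitude around a grid-search initializer) with the
log-scale Jacobian included in the acceptance ratio; the default step
gives 20-40% acceptance, and chains under 5% acceptance warn.

## Problem sizes

Test-suite and acceptance runs use the study's own horizons (40-week
natural-history runs, 2000-day steady states, 85-week treatment
evaluations) but coarse start-time grids refined by bisection around
the transitions (about sixty 85-week runs per dose), and a reduced
replicate count (60) for the MCMC coverage study.  The full
2,500-combination stratified clearance sweep at three wave scales and
two $\eta$ values, and the full daily-by-$10^4$-cell treatment map,
are exposed through `lhs_sample()`/`clearance_heatmap()` and
`treatment_sweep()` and the command-line tool, with strides chosen by
the caller.

## Known limitations

Single compartment only: no spleen or lymph-node trafficking, no
pharmacokinetics of the injected cells, no $\beta$-cell viability or
ER-stress axis, no delay between DC contact and T-cell commitment.  The
model omits post-natal $\beta$-mass growth, so the wave bites deeper
than in growing animals.  The diseased steady state is maintained by
residual effector pressure rather than glucose toxicity; interventions
that merely lower glucose do not move the system between attractors.
The strain window of the calibrated registry is narrow (a few percent
in $\mu_R$), which is a faithful reflection of the bistable boundary
the study places the NOD mouse on, but it means registry edits should
re-verify the four strain-by-wave scenarios.
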