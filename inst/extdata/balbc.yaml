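preset: balbc
wave_on: true
parameters:
  J: 5.0e+4
  k: 0.4
  b: 0.09
  c: 0.1
  e1: 1.0e-8
  e2: 1.0e-8
  fM: 1.2e-4
  fMa: 3.1e-4
  alphaB: 0.035
  deltaB: 0.01667
  Ghb: 93.3424
  eta: 0.011
  alphaE: 0.03
  betaE: 149.0
  sE: 6.0e-5
  sR: 1.0e-5
  w: 0.75
  d: 0.5
  Bconv: 8.2e+5
  Qpanc: 0.17
  B0: 2.0
  Dss: 2.5e+4
  ftD: 1.1842e-4
  fD: 1.7019e-5
  bDE: 6.0e-6
  bIR: 2.0e-6
  muD: 0.5
  R0: 864.0
  G0: 1.603
  SI: 0.72
  sigmaI: 8570.0
  GI: 141.421356
  deltaI: 432.0
  aE: 0.01
  aR: 0.01
  Tnaive: 1.0e+5
  bP: 0.5
  thetaD: 2000.0
  ram: 0.05
  bE: 1.0e-8
  bR: 1.5e-7
  muE: 3.0e-7
  muR: 3.233e-6
  aEm: 0.003
provenance:
  J: "resting-macrophage influx; macrophage turnover block of the Copenhagen-style clearance model"
  k: "activated-macrophage deactivation rate; macrophage block"
  b: "activated-macrophage recruitment of resting macrophages; macrophage block"
  c: "resting-macrophage egress; macrophage block"
  e1: "resting-macrophage crowding coefficient; macrophage block"
  e2: "activated-macrophage crowding coefficient; macrophage block"
  fM: "Balb/c resting-macrophage clearance of dying beta cells; healthy-strain value at the top of the studied sampling range"
  fMa: "Balb/c activated-macrophage clearance of dying beta cells; healthy-strain value at the top of the studied sampling range"
  alphaB: "beta-cell glucose-dependent growth ceiling; calibrated jointly with deltaB and Ghb to the 89 mg/dl healthy glucose steady state"
  deltaB: "beta-cell natural death rate (~60-day turnover)"
  Ghb: "half-max glucose of the beta-cell growth response; calibrated so growth balances natural death at 89 mg/dl"
  eta: "basal effector kill strength; calibrated to diabetes onset near week 24 in the impaired-clearance strain"
  alphaE: "steepness of the effector avidity ramp; calibrated with betaE to the late-rise glucose shape"
  betaE: "midpoint (days) of the effector avidity ramp; calibrated to the 250 mg/dl crossing at ~24.3 weeks"
  sE: "effector scaling in the kill saturation response; calibrated so the post-collapse immune state keeps beta mass suppressed"
  sR: "regulatory scaling in the kill saturation response"
  w: "apoptotic-wave scale (model default 0.75)"
  d: "apoptotic-to-necrotic decay of uncleared beta cells"
  Bconv: "beta cells per milligram of islet mass (cell-count based conversion)"
  Qpanc: "pancreas volume, ml"
  B0: "healthy beta-cell mass at birth, mg"
  Dss: "total pancreatic dendritic-cell capacity"
  ftD: "tolerogenic/immature DC clearance = 3.82e-1 x Balb/c fMa (assay rate-ratio scaling)"
  fD: "immunogenic DC clearance = 5.49e-2 x Balb/c fMa (assay rate-ratio scaling)"
  bDE: "DC removal by effector T cells; calibrated to the post-wave effector decline"
  bIR: "tolerogenic-DC removal by regulatory T cells"
  muD: "dendritic-cell death rate (2-day tissue lifetime)"
  R0: "basal glucose production; glucose-insulin kinetics block, scaled so the insulin-free glucose level is 539 mg/dl"
  G0: "insulin-independent glucose clearance; glucose-insulin kinetics block"
  SI: "insulin sensitivity; glucose-insulin kinetics block"
  sigmaI: "maximal insulin secretion per mg beta mass; rescaled to the ~2 mg mouse beta-cell mass"
  GI: "half-max glucose of insulin secretion; glucose-insulin kinetics block"
  deltaI: "insulin clearance rate; glucose-insulin kinetics block"
  aE: "effector naive-compartment homeostasis rate; calibrated (T-cell race)"
  aR: "regulatory naive-compartment homeostasis rate; calibrated (T-cell race)"
  Tnaive: "naive T-cell reference level"
  bP: "maximal DC-driven T-cell proliferation rate"
  thetaD: "DC half-saturation of T-cell proliferation; calibrated (T-cell race)"
  ram: "activated-to-memory conversion rate; calibrated (memory reservoir build-up)"
  bE: "memory reactivation to effectors by immunogenic DCs"
  bR: "memory reactivation to regulators by tolerogenic DCs; calibrated (dose-response of tolerogenic-DC injections)"
  muE: "suppression of effectors by regulators; calibrated (bistable race)"
  muR: "suppression of regulators by effectors; calibrated to the strain-discrimination window"
  aEm: "memory T-cell death rate; calibrated (memory reservoir persistence)"
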