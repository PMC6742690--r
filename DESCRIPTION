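Package: t1dsim
Title: Single-Compartment Immune Model of Type 1 Diabetes Initiation and
    Tolerogenic Dendritic Cell Vaccination in Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the initiation of autoimmune (type 1) diabetes in
    diabetes-prone NOD and control Balb/c mice with a twelve-compartment
    nonlinear ordinary differential equation model of the pancreas:
    resting and activated macrophages, healthy, apoptotic and necrotic
    beta cells, glucose, insulin, immunogenic and tolerogenic dendritic
    cells, and effector, regulatory and memory T cells.  Impaired
    macrophage clearance of apoptotic beta cells, together with a neonatal
    apoptotic wave, tips the bistable system into a diabetic state.  The
    package provides stiff integration with impulsive tolerogenic-DC
    dosing, glucose-threshold event detection and outcome classification;
    a reduced phagocytosis-assay model with Metropolis MCMC estimation of
    dendritic-cell engulfment rates; one-at-a-time sensitivity analysis;
    stratified (Latin hypercube style) clearance-rate sweeps with outcome
    region maps; and dose-by-start-time treatment sweeps that locate
    windows of opportunity for tolerogenic-DC vaccination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
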