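Package: trapcycle
Title: Kinetics and Conformational Dynamics of the Sequential ATPase Cycle
    of the Mitochondrial Hsp90 Chaperone TRAP1
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to model and analyse the asymmetric, sequential two-step
    ATPase cycle of a homodimeric Hsp90-family chaperone (TRAP1). Provides
    first-order kinetic fitting for FRET closure, phosphate-release and
    single-turnover assays (exponential fits with optional linear terms, Hill
    titrations, initial-rate extraction, phosphate-sensor calibration with a
    detector-linearity cap, NADH-coupled rate conversion); a binomial
    dimer-exchange model that solves mixed wild-type/mutant activity tables
    for the heterodimer activity; a finite-state-machine simulator of the
    dimer cycle (closure with random buckling, obligatory hydrolysis by the
    buckled protomer, asymmetry flip, second hydrolysis, reopening) with
    exact stochastic (Gillespie) and deterministic master-equation engines
    and protomer-specific variants; water occupancy, fractional residence and
    dwell-time analysis around the two ATP pockets of aligned trajectories;
    two-Gaussian decomposition of DEER distance distributions into
    buckled/straight conformer populations; and seeded synthetic-data
    generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    deSolve,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
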