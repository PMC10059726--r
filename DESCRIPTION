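Package: endpointr
Title: End-Point Binding Free Energy Toolkit (MM/PBSA and MM/GBSA)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-point (MM/PBSA and MM/GBSA) binding free-energy estimation
    for host-guest complexes, supporting both the single-trajectory and
    three-trajectory realizations and an interior-dielectric-constant scan
    with an exact decomposition of the dielectric-dependent response.
    Includes AMBER-style molecular-mechanics energies with analytic
    gradients, generalized Born (OBC) polar solvation, a finite-difference
    linearized Poisson-Boltzmann reference solver, Shrake-Rupley solvent
    accessible surface area, rigid-rotor/harmonic-oscillator entropy from
    normal-mode analysis, term-by-term force-field parameter-set comparison,
    ranking quality metrics (RMSE, mean signed error, Kendall tau,
    Pearlman predictive index), readers and writers for a JSON topology
    schema, a subset of the AMBER prmtop format, multi-model PDB and XYZ
    trajectories, and a seeded synthetic host-guest fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
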