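Package: psdcrowd
Title: Monte Carlo Simulation of Receptor Diffusion in a Crowded
    Post-Synaptic Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lattice Monte Carlo simulator of AMPA-receptor lateral
    diffusion on a toroidal membrane crowded with static post-synaptic
    density (PSD) molecules that act as elastic obstacles and, optionally,
    as non-covalent binding sites with exponential unbinding kinetics.
    Provides ensemble mean-squared-displacement analysis, estimation of
    the anomalous diffusion exponent, apparent diffusion coefficient
    distributions, confined-diffusion (Kusumi) model fitting, closed-form
    residence-time and crowding calculators, and reproducible protocols
    for crowding sweeps, PSD trapping, binding-fraction sweeps, and
    activity-dependent stimulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
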