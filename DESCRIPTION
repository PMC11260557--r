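Package: dynoccam
Title: Dynamic Occupancy Models for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-season (dynamic) occupancy analysis of
    camera-trap data: independence filtering of photo streams, detection
    history construction, covariate standardization and design-matrix
    assembly with interaction terms, a marginalized hidden-Markov
    likelihood for initial occupancy, colonization, extirpation and
    detection with a site-level detection random effect, Hamiltonian
    Monte Carlo posterior sampling with convergence diagnostics, and
    derived occupancy dynamics (trajectories, turnover, rates of change,
    decline proportions, stable-state occupancy) on prediction grids.
    Includes a synthetic-data generator that emulates seasonal paired-camera
    surveys for end-to-end testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
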