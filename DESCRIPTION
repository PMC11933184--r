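Package: graftflow
Title: Lumped-Parameter Coronary Bypass Graft Hemodynamics and Uncertainty
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop zero-dimensional (lumped-parameter) simulation of the
    systemic and pulmonary circulation with a three-layer intramyocardial
    perfusion bed supplied through a bypass graft carrying an optional
    Young-Tsai stenosis element.  Computes the transit-time flow measurement
    (TTFM) patency metrics (mean flow, pulsatility index, diastolic/systolic
    ratio, diastolic filling percentage, diastolic resistance index) from
    simulated or beat-annotated clinical-style waveforms, and quantifies their
    parametric uncertainty via Morris elementary-effects screening and
    regression-based polynomial chaos expansion with Sobol indices.  Includes
    an iterative coronary autoregulation experiment and a seeded synthetic
    clinical-cohort generator with robust cohort comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
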