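Package: srnakin
Title: Kinetics and Inference for Ribosome-Modulated Small RNA Silencing
Version: 0.1.0
Authors@R:
    person("Dana", "Keren", email = "dana.keren@example.org",
           role = c("aut", "cre"))
Description: Quantitative framework for the modulation of bacterial small-RNA
    (sRNA) silencing by ribosome binding at the target 5'UTR. Implements a
    three-state kinetic model with coarse-grained effective rates, closed-form
    and numeric steady states, fold-repression (efficacy) response curves, a
    linear-noise-approximation covariance layer with an exact Gillespie
    simulator as oracle, synthetic generators for plate-reader, flow-cytometry
    and rifampicin-chase qPCR data, the matching estimators (GFP-vs-OD slopes,
    CV-squared noise with autofluorescence correction, efficiency-corrected
    delta-delta-Cq half-life fits), and an inference pipeline that classifies
    ribosome-sRNA competition versus recruitment and tests the anomalous-noise
    signature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
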