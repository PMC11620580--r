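Package: filacol
Title: Off-Lattice Simulation and Likelihood-Free Inference of Filamentous
    Yeast Colony Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An off-lattice agent-based model of filamentous Saccharomyces
    cerevisiae colony growth, in which elliptical sated and pseudohyphal
    cells bud from prescribed sites under a five-parameter stochastic
    decision tree. Provides rasterization of colonies to binary masks,
    three image-derived morphology statistics (radius ratio, filamentous
    area ratio, and skeleton-based sub-branch count), and approximate
    Bayesian computation with Metropolis-Hastings steps (ABC-MCMC) to
    infer the budding parameters from replicate colony images, with
    proposal-covariance and tolerance tuning and effective-sample-size
    diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
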