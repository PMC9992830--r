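Package: mobfield
Title: Spatiotemporal Ancestry Interpolation and Mobility Estimation for
    Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates individual-level human mobility from ancient genomic
    data. Pairwise identity-by-state distances from EIGENSTRAT genotype
    matrices are reduced to ancestry components by classical
    multidimensional scaling; the components are interpolated through space
    and time with an anisotropic Gaussian-process (kriging) model with
    nugget; per-sample Bayesian similarity probability surfaces are derived
    in past time slices; and maximum-probability "mobility vectors" are
    summarised, with Monte-Carlo resampling of age uncertainty, into
    regional diachronic mobility curves. A synthetic-data module simulates
    spatially structured populations with migration events so the full
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
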