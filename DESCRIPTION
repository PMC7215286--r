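Package: ndimap
Title: Bayesian Neighborhood Disadvantage Index Models for Areal Outlet Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian hierarchical disease-mapping models for per-tract counts
    of retail outlets (or any areal event counts) with an estimated
    neighborhood disadvantage index.  Socioeconomic covariates are oriented,
    decile-scored and combined into a weighted index whose simplex weights
    carry a Dirichlet prior; the log relative risk adds unstructured,
    intrinsic conditional autoregressive (ICAR), convolution, or
    convolution-mixture random effects.  Models are fitted by an adaptive
    Metropolis-within-Gibbs sampler, compared by the deviance information
    criterion, checked with Geweke diagnostics and Moran's I screening, and
    summarized with exceedance-probability hotspot calls.  Includes a
    synthetic lattice data generator, GeoJSON/GAL spatial input, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
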