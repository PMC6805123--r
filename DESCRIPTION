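Package: herbiscaper
Title: Hierarchical Spatial Abundance Models for Camera-Trap Counts and
    Landscape-Scale Herbivory Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a hierarchical N-mixture model for camera-trap count data in
    which observed counts are Poisson given a Negative-Binomial latent relative
    density per landscape grid cell, with log-linear covariate effects, an
    effort offset, lognormal site-level detection noise and Restricted Spatial
    Regression (Moran-basis) random effects. Inference is by blocked adaptive
    Metropolis-Hastings MCMC on the integrated likelihood (latent abundance
    summed out), with Gelman-Rubin diagnostics and posterior predictive checks.
    Downstream tools convert fitted relative-density surfaces into community
    products: biomass surfaces, abundance-weighted functional dispersion (FDis)
    on mixed traits, pairwise overlap, and hierarchical clustering on principal
    components into landscape-scale herbivory regimes ('herbiscapes'), plus
    plot-level browsing-intensity and recruitment-shift analyses linking the
    regimes to vegetation. A synthetic-data generator with the model's own
    statistical structure makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    jsonlite
Config/testthat/edition: 3
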