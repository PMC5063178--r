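Package: latentleaf
Title: Latent Shape Analysis of Grapevine Leaf Morphology and Heterochrony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics for grapevine (Vitis)
    leaf series: generalized Procrustes superimposition of 17-landmark leaf
    configurations, principal-component morphospaces ("eigenleaves"), linear
    discriminant latent shapes for species identity and shoot position,
    cross-collection developmental staging, and heterochrony indices
    (relative developmental stage and relative leaf number, per-vine means,
    per-species deviation tests, and the correlation with the first tendril
    node). Includes supporting rank statistics with false discovery rate
    control, correlation-distance hierarchical clustering with newick
    export, and a synthetic shoot generator with full ground truth for
    validating the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
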