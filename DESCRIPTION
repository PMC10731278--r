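Package: ecotol
Title: Multi-Trait Comprehensive Evaluation of Heavy-Metal Tolerance in
    Fungal Ecotypes and Mycorrhizal Seedlings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks the cadmium tolerance of genotypes (fungal ecotypes,
    mycorrhizal seedlings, or any replicated multi-trait screen) by the
    fuzzy membership-function comprehensive-evaluation procedure: stress
    resistance coefficients from paired control/stress measurements,
    column-wise min-max membership functions, principal-component
    comprehensive indices with variance-contribution weights, weighted and
    unweighted comprehensive D scores, hierarchical tolerance classing,
    and cross-level Pearson association with an exact small-sample t test.
    Includes metal transfer and bioconcentration factors, relative
    expression by the delta-delta-Ct method, a synthetic phenotype
    generator with known latent tolerance for validation, and a
    reproducible end-to-end pipeline driven by a single configuration
    file.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
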