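Package: dmetpool
Title: Meta-Analysis of Drug-Metabolizing Enzyme Abundance and PBPK Input
    Derivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools study-level protein abundance data for drug-metabolizing
    enzymes and transporters (DMET) across laboratories: fixed- and
    random-effects summary estimates with Cochran's Q, the method-of-moments
    between-study variance, H2 and I2 heterogeneity indices, sample-size
    weighted means, three alternative pooled percent-coefficient-of-variation
    estimators, and lognormal (geometric) confidence intervals suitable for
    forest plots. Pooled abundances feed a well-stirred-liver in vitro-in vivo
    extrapolation (IVIVE) chain that back-calculates unbound intrinsic hepatic
    clearance from systemic clearance, partitions it across enzyme isoforms,
    and derives microsomal intrinsic clearance and Vmax values for
    physiologically based pharmacokinetic (PBPK) models, together with scale
    factors for inter-laboratory variability bounds and for paediatric and
    hepatically impaired populations. Includes a synthetic study-level data
    generator with known ground truth for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    metafor,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
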