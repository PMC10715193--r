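Package: cogscaling
Title: Power-Law Scaling of Functional Gene Categories Across Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the abundance of COG functional
    categories scales with the total number of functional annotations in a
    genome. Builds organism-by-category count matrices from per-protein
    annotation tables, fits power laws by ordinary least squares on
    log-transformed data with 95 percent confidence intervals, detects
    single breakpoints with a continuous two-segment model selected by a
    residual-sum-of-squares reduction criterion, quantifies phylum-level
    deviations from domain-level exponents with Z-statistic scores,
    provides a category-shuffle permutation null that conserves
    per-organism and per-category totals, relates patristic distances
    between phyla to scaling-exponent divergence, and includes a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
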