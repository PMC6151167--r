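Package: zdiv
Title: Z-Chromosome Versus Autosome Diversity and Divergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Windowed population-genomic diversity and divergence statistics
    (nucleotide diversity, Hudson's FST, dXY, da, Tajima's D) with
    genotype-quality filtering and hemizygous-Z handling, block-jackknife
    uncertainty and permutation Mantel tests, a structured-coalescent
    simulator with recombination, piecewise population size change,
    two-population splits with migration and Z-specific scaling, and the
    Z/A ratio analysis used to detect reduced effective migration on the
    Z chromosome. Includes a synthetic-study generator that emits VCFs and
    sample maps from known demographic truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
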