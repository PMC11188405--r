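Package: sysgenet
Title: Systems Genetics of Quantitative Traits in Doubled Haploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end systems-genetics toolkit for doubled haploid (DH)
    mapping populations: composite interval mapping of phenotypes with
    permutation-derived significance thresholds, weighted gene co-expression
    network construction (soft thresholding, topological overlap, module
    detection, eigengenes), module-trait association, QTL mapping of module
    eigengenes (network QTL), genome-wide eQTL scanning with cis/trans
    classification, and colocalization-based prioritization of candidate
    causal genes. Includes two-colour microarray preprocessing (MA-lowess and
    quantile normalization, intensity filtering, replicate averaging,
    differential expression) and a fully parameterised synthetic-study
    generator with ground truth for power and recovery analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
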