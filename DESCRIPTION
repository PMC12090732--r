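Package: symbiocor
Title: Co-Expression and Ordination Analysis of Host-Endosymbiont
    Meta-Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-level meta-transcriptomic analysis of an arthropod host
    carrying two intracellular bacterial symbionts in single-infected and mixed
    cultures. Provides library-size standardization by rarefaction, symbiont/host
    read-proportion comparisons, Shannon expression-diversity analysis, all-pairs
    Spearman correlation networks with permutation p-values and signed-edge
    summaries, distance-based redundancy analysis (dbRDA) with permutation tests
    and forward selection, ANOSIM and SIMPER group comparisons, nonparametric
    differential expression with FDR control, per-pathway partial dbRDA effect
    matrices with K-means clustering, and a negative-binomial synthetic data
    generator that plants known correlation, fold-change and pathway structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
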