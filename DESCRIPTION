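Package: mitoscreen
Title: In-Silico Discovery Toolkit for Mitotic Kinase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for the in-silico arm of a mitotic kinase
    inhibitor discovery campaign: connectivity-map style transcriptomic
    matching (weighted Kolmogorov-Smirnov enrichment) and Tanimoto
    fingerprint similarity for mechanism-of-action inference, kinome
    selectivity scores from percent-of-control competition-binding panels,
    derivation of an anchor-correlated active-mitosis gene signature scored
    per patient by single-sample GSEA, median-split survival screens for
    synthetic-lethal partners of an anchor kinase, and Chou-Talalay
    median-effect combination-index analysis of drug pairs. Synthetic-data
    generators plant known ground truth (latent mitotic activity, survival
    interactions, binding hits, fingerprint families, Loewe interaction)
    so every statistic can be validated by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
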