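Package: dsinet
Title: Differential SHAP Interaction Networks for Two-Condition Multi-Omics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable multi-omics analysis of paired-condition (control vs
    drought) studies: multi-kernel BLUP with feature-coefficient back-projection
    and SVD latent maps, random-forest importance screening, a linear mixed model
    GWAS baseline, exact TreeSHAP attribution of per-condition tree models, and
    differential SHAP-interaction network inference with permutation-null
    Z-scores, empirical p-values and bootstrap edge-stability filtering. Includes
    a synthetic two-condition multi-omics generator with known ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    xgboost,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
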