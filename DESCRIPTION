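Package: gangliaDE
Title: Neuron-Enriched Comparative Transcriptomics of Sensory Ganglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing bulk RNA-seq profiles of
    FACS-enriched sensory neuron populations, modelled on a dorsal root
    ganglion (DRG) versus trigeminal ganglion (TG) design with unbalanced
    replication. Provides FPKM normalization and replicate-based
    presence/absence calls, a negative-binomial Wald differential expression
    test with median-of-ratios size factors, moment dispersion estimation
    with trend shrinkage and Benjamini-Hochberg correction, classification
    of significant genes into upregulated, ganglion-exclusive, not-expressed
    and non-neuronal categories against a pure-neuron reference set,
    cross-dataset and cross-species concordance statistics (rank
    correlation, presence agreement, trend concordance, fold-threshold
    counts, standardized heatmap matrices), closed-form and Monte-Carlo
    power calculations for two-group RNA-seq designs, and a
    negative-binomial count simulator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
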