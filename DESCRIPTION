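Package: arrestomics
Title: Multi-Modal Analysis of Ribosome Depletion and Stress-Response
    Activation During Prolonged Cell-Cycle Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for studies of prolonged cell-cycle
    arrest in budding yeast: single-sample gene-set enrichment (ssGSEA)
    projection of induced and repressed environmental-stress-response (ESR)
    gene sets from TPM expression matrices; ribosomal proteome-fraction
    quantification from TMT peptide reports with Mascot-score and
    isolation-interference filtering; biochemical ribosome-to-protein
    ratios; Coulter-histogram mean cell volume by the half-maximal-count
    rule with exponential growth references; GEM nanoparticle diffusion
    estimation from time-averaged mean-square displacement; and
    colony-count viability normalization. A coupled synthetic-data
    generator with a latent arrest-strength trajectory produces all five
    modalities with known ground truth so every stage is testable by
    parameter recovery, and a pipeline driver joins the modalities and
    reports cross-modality correlations such as ESR strength versus cell
    size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    ggplot2
Config/testthat/edition: 3
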