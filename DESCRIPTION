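Package: ifnscore
Title: Interferon-Stimulated Gene Scores and Multi-Omics Association Analysis for Trisomy 21 Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying interferon (IFN) pathway hyperactivity in
    whole-blood transcriptomes of trisomy 21 (T21) cohorts and relating it to
    plasma proteomics, immunoassay cytokine panels, metabolomics, immune-cell
    composition and clinical co-occurring conditions. Implements signature
    selection for interferon-stimulated genes (ISGs), composite z-score IFN
    scores referenced to euploid controls, platform-specific preprocessing
    (extreme-outlier fences, immunoassay fit-range handling, metabolite median
    normalization, covariate adjustment), association screens (Spearman,
    log2-scale linear models, beta regression on compositional cell
    frequencies, preranked gene set enrichment), unsupervised stratification
    (subsampled consensus clustering, Gower distance with PAM and silhouette
    selection, condition enrichment), and a longitudinal on/off JAK-inhibitor
    case analysis. A seeded synthetic multi-omics cohort generator with a
    latent IFN-activity variable makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    limma,
    withr
Config/testthat/edition: 3
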