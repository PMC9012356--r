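Package: mcpratio
Title: Standardized T1w/T2w Ratio Biomarker for the Middle Cerebellar Peduncle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the standardized T1w/T2w (sT1w/T2w) ratio pipeline for
    quantifying degeneration of the middle cerebellar peduncle (MCP) from paired
    T1-weighted and T2-weighted brain MRI, together with the diagnostic
    evaluation statistics used to assess it as a biomarker for separating the
    cerebellar subtype of multiple system atrophy (MSA-C) from spinocerebellar
    ataxias (SCA3, SCA6) and controls. Includes a synthetic multi-contrast brain
    phantom generator with a probabilistic MCP atlas, desk-scale bias-field
    correction, rigid registration, brain masking and tissue segmentation,
    atlas-based ROI median extraction, ICV-normalized MCP volumetry, and a
    statistics layer covering ROC/AUC with DeLong inference, closest-to-corner
    cutoffs, exact binomial confidence intervals and tests, intraclass
    correlation, Grubbs outlier screening, and covariate-adjusted group
    comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
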