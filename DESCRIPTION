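Package: nichefate
Title: Spatial Niche Quantification for Glucocorticoid-Sensitive Fibroblast States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-definition spatial transcriptomics of
    fibrotic lung disease: rank-based (UCell-style) gene-signature scoring of
    8 um grid spots, per-sample percentile classification of
    glucocorticoid-sensitive spots with threshold sensitivity scans and
    donor-level bootstrap confidence intervals, cell-type proximity and
    kernel-density geometry, donor-level nonparametric statistics
    (Kruskal-Wallis, Dunn, Wilcoxon, Cliff's delta, Spearman with bootstrap),
    and stage-resolved niche dynamics in organising pneumonia. Includes a
    seeded synthetic cohort generator emulating the donor/ROI/spot hierarchy
    and clustered lesion niches so the full pipeline is testable without
    tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    MASS,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
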