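Package: epimetab
Title: Serum 1H-NMR Metabolomics Workflow for Drug-Response Profiling in Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometrics workflow for 1D 1H-NMR serum metabolomics
    cohorts with three classes (healthy controls, drug-responder and
    drug-resistant epilepsy patients): a seeded synthetic-spectrum generator
    parameterized by per-class metabolite concentration distributions, fixed-width
    spectral binning with exclusion windows, percent total-area normalization,
    Pareto scaling, PCA outlier screening (Hotelling T2), two-class OPLS-DA with
    cross-validated Q2, permutation testing with R2/Q2 intercept diagnostics,
    CV-ANOVA, S-plot and VIP discriminant selection, TSP-referenced targeted
    quantification, and a Mann-Whitney/Holm-Bonferroni univariate screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
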