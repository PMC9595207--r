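Package: traffiq
Title: Quantitative Analysis of High-Content GLUT4/TfR Trafficking Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Downstream statistics for high-content imaging screens of
    insulin-stimulated GLUT4 and transferrin-receptor (TfR) translocation in
    adipocytes, starting from per-cell measurement tables: lipid-scatter
    gating of adipocytes, anchored cross-plate normalization of single-cell
    intensities, fold-over-basal / fold-over-control / min:max summaries,
    three-parameter Hill dose-response (EC50/IC50) and one-phase association
    kinetics fitting with AIC-based shared-versus-independent model
    comparison, single-cell density and population-shift metrics, siRNA
    knockdown-screen summarization, and bait-versus-IgG AP-MS differential
    enrichment with two-step (conditional + downshifted-normal) imputation
    and MAD-based insulin-regulation calls. Seeded synthetic-data generators
    with ground truth emulate the assay's statistical structure for testing
    and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
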