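Package: nmrchemo
Title: Chemometrics Toolkit for 1H-NMR Metabolic Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable workflow for clinical 1H nuclear magnetic resonance
    (NMR) metabolomics: spectral ingestion (JCAMP-DX, Bruker processed
    directories, TSV matrices), region exclusion, total-area and probabilistic
    quotient normalization, variable scaling, NIPALS principal components
    analysis with Hotelling T-squared outlier exclusion and re-projection,
    two-class OPLS-DA with test-set prediction and cross-validated Q2,
    statistical total correlation spectroscopy (STOCSY), consensus multiblock
    PCA over user-defined chemical-shift blocks, cross-correlation reference
    pattern matching with shift tolerance, per-class box statistics, and a
    synthetic multi-class spectrum simulator with known ground truth so the
    entire pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
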