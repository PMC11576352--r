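# nmrchemo

A chemometrics toolkit for clinical ¹H-NMR metabolic phenotyping, written
for biomedical scientists who need a scriptable, reproducible counterpart to
interactive spectral-analysis suites. A cohort of 1D spectra on a shared
chemical-shift grid is an *n* × *p* matrix **X**; the package covers the full
path from instrument files to validated multivariate models:

- **Ingestion** — JCAMP-DX (AFFN and SQZ/DIF/DUP compressed), Bruker
  processed directories (`procs`/`1r`), TSV spectral matrices and annotation
  tables; linear-interpolation alignment of mixed sources onto one ppm grid.
- **Preprocessing** — region exclusion (e.g. residual water 4.55–4.90 ppm),
  total-area and probabilistic quotient (PQN) normalization, mean-center /
  unit-variance / Pareto scaling, with full provenance of applied factors.
- **PCA** — NIPALS with explained variance, Hotelling *T*² outlier limits
  (`T²ᵢ = Σₐ t²ᵢₐ/λₐ` against the F-distribution ellipse bound), and the
  interactive exclude → refit → re-project workflow.
- **OPLS-DA** — one predictive plus *k* orthogonal components
  (`w ∝ Xᵀy`, `w_o ∝ p − (wᵀp)w`), test-set prediction by sign of
  `ŷ = q·t_pred`, stratified cross-validated `Q² = 1 − PRESS/Σy²`, and a
  predictive-vs-orthogonal loading table for biomarker reading.
- **STOCSY** — statistical total correlation spectroscopy: Pearson
  correlation and covariance of a driver variable against the whole
  spectrum; resonances of one molecule correlate near 1.
- **Multiblock (consensus) PCA** — per-block scaling and `1/√p_b` weighting
  over user-defined ppm blocks; super scores, super weights, block loadings.
- **Pattern matching** — lag-scanned Pearson correlation of a reference
  template against every spectrum with a user-defined threshold, counting
  and ranking the samples that contain a metabolite; iterable with STOCSY.
- **Box statistics** — per-variable five-number summaries by class, and
  placement of an individual sample within its group.
- **Simulator** — multi-class cohorts from Lorentzian peak-list compounds
  with log-uniform concentrations, class multipliers, coherent shift jitter
  and additive noise; full ground truth for every validation in the package.

## Worked example

Simulate a 60-sample, two-class cohort in which glycine is a two-fold
biomarker, preprocess, and model it:

```r
library(nmrchemo)

cfg <- sim_config(n_classes = 2, n_per_class = 30,
                  biomarkers = list(glycine = c(1, 2)),
                  conc_range = list(glycine = c(0.8, 1.25)),
                  noise_sd = 0.02, seed = 7)
ds <- simulate_dataset(cfg)
#> <sim_dataset> 60 samples (2 classes) x 1000 variables, seed 7

pr <- preprocess(ds$matrix, excluded_regions = water_region(),
                 normalization = "pqn", scaling = "pareto")
pca <- fit_pca(pr$matrix, n_components = 2, center = FALSE)
hotelling_outliers(pca)
#> <outlier_report> limit 6.528 (alpha 0.05): 2 flagged
#>   sample_010, sample_034

opls <- fit_oplsda(pr$matrix, ds$annotations$class, n_orth = 1, center = FALSE)
opls
#> <oplsda_model> class1 (-1) vs class2 (+1), 1 orthogonal component(s)
#> R2X(pred) 0.069  R2X(orth) 0.120  R2Y 0.844
cross_validate_oplsda(pr$matrix, ds$annotations$class, n_orth = 1,
                      folds = 7, seed = 7, center = FALSE)$q2
#> [1] 0.696

ld <- loading_decomposition(opls)
head(ld[order(ld$rank), c("ppm", "p_pred", "rank")], 3)
#>          ppm    p_pred rank
#> 621 3.563063 0.3982780    1
#> 622 3.554054 0.3690421    2
#> 620 3.572072 0.2592997    3
```

Reading the output: two samples exceed the 95% Hotelling limit and could be
excluded and re-projected with `refit_excluding()`; the OPLS-DA model
explains 84% of the class variable (R²Y) with a cross-validated Q² of 0.70;
and the top-ranked predictive loadings sit at 3.55–3.57 ppm — the simulated
glycine singlet at 3.56 ppm, i.e. the model recovers the planted biomarker.
A STOCSY at 2.54 ppm (`stocsy(pr$matrix, 2.54)`) shows its highest
off-driver correlation (r = 0.99) at the other citrate resonance, as
expected for two signals of one molecule.

The same stages run from the shell through the thin CLI wrapper:

```sh
Rscript inst/cli/nmrchemo.R simulate --out out/ --seed 7
Rscript inst/cli/nmrchemo.R pca --in out/matrix.tsv --out out/ --components 2
Rscript inst/cli/nmrchemo.R run --config analysis.json --out out/
```

Every run writes TSV/JSON artifacts, a resolved-config copy and an MD5
manifest; identical seeded configurations reproduce identical hashes.

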