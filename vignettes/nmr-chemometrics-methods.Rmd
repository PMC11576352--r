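---
title: "Methods: chemometrics for 1H-NMR metabolic phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometrics for 1H-NMR metabolic phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrchemo)
```

`nmrchemo` is a scriptable workflow for clinical ^1^H-NMR metabolomics. A
cohort of one-dimensional spectra, sampled on a shared chemical-shift (ppm)
grid, is treated as an $n \times p$ matrix $X$: $n$ samples, $p$ spectral
variables. The package covers ingestion from common instrument formats,
preprocessing, unsupervised and supervised latent-variable modeling,
statistical spectroscopy, pattern matching, descriptive univariate
statistics, and a simulator that generates cohorts with known ground truth
so every stage can be validated without patient data. This vignette explains
the models, their assumptions, the tunable parameters, and the numerical
choices made where the design was genuinely open.

## Spectral ingestion

Spectra are read from JCAMP-DX files (`read_jcamp()`; AFFN ordinates and the
SQZ/DIF/DUP compressed ASDF form with per-line Y checkpoints; PAC and
NTUPLES dialects are rejected with an explanatory message), from Bruker
processed directories (`read_bruker()`; int32 `1r` values scaled by
$2^{NC\_proc}$, ppm axis descending from `OFFSET` over `SW_p/SF` in `SI`
points), or from a plain TSV matrix (`read_tsv_matrix()`; header `sample_id`
followed by ppm values, numbers printed with 17 significant digits so the
round-trip is bit-lossless). The canonical ppm orientation is descending,
the NMR display convention; ascending inputs are reversed on read.

Mixed-source spectra are placed on one grid by `align_to_grid()` using
linear interpolation. Grid points outside a spectrum's range are zero-filled
with a warning rather than extrapolated: extrapolation would invent signal
at the spectrum edges, while zero is the correct baseline value for regions
that were never observed. Raw free-induction-decay processing (apodization,
Fourier transform, phasing) is out of scope; inputs are assumed to be
processed real spectra.

## Preprocessing

The pipeline order is fixed: **region exclusion → normalization → variable
scaling**. Exclusion runs first so that removed signal — typically the
residual water band, for which `water_region()` supplies the conventional
4.55–4.90 ppm window — can never influence the dilution-factor estimates.
No region is removed unless explicitly requested.

Two normalizations are provided, the field standards for urine and plasma:

* **Total area** (`normalize_total_area()`): each row is divided by
  `row_sum / area_target` (default target 100).
* **Probabilistic quotient** (`normalize_pqn()`): after an internal
  total-area step (which makes quotients scale-free), the reference is the
  element-wise median spectrum; each sample's dilution factor is the median
  of its variable-wise quotients against that reference. PQN assumes that
  most variables differ between samples mainly by dilution; when
  compositional variation is large relative to dilution the factor estimate
  degrades gracefully toward the total-area estimate.

Scaling options are mean-centering, unit-variance (autoscaling) and Pareto
(centered values divided by $\sqrt{s_j}$, damping the dominance of intense
peaks). All standard deviations use the $n-1$ denominator, consistent with
the score-variance and cross-validation formulas elsewhere. Zero-variance
columns cannot be scaled and are dropped with a warning rather than imputed.
Every applied factor (dilution divisors, centers, scales) is recorded in the
returned object, so the processed matrix is exactly reproducible from the
raw one — a property the test suite asserts to $10^{-12}$.

## PCA with interactive outlier handling

`fit_pca()` implements NIPALS, the chemometrics workhorse: per component,
the score vector is seeded with the column of maximal variance and the
iteration $p = X^\top t / (t^\top t)$ (normalized), $t = X p$ repeats until
the relative change of $t$ falls below the tolerance; the component is then
deflated, $X \leftarrow X - t p^\top$. Loading signs are fixed so the entry
of largest magnitude is positive, making plots and tests reproducible.

NIPALS is power iteration, and its convergence rate is governed by the
ratio of successive eigenvalues. The defaults are `tol = 1e-13` and
`max_iter = 1e5`: empirically, looser settings (e.g. $10^{-10}$ and a few
hundred iterations) leave visible errors on matrices whose leading
eigenvalues nearly tie, while the chosen settings reproduce a truncated SVD
to better than $10^{-9}$ on hundreds of random matrices at negligible cost
for the problem sizes this package targets.

Outliers are flagged with Hotelling's $T^2$: per sample
$T^2_i = \sum_a t_{ia}^2 / \lambda_a$ with $\lambda_a$ the per-component
score variance, against the F-distribution limit
$\frac{A(n-1)(n+1)}{n(n-A)} F_{1-\alpha}(A,\, n-A)$ (default
$\alpha = 0.05$). The interactive exclude–refit–re-project loop of the
graphical workflow is captured by `refit_excluding()`: the model is refit on
the retained samples and the excluded ones are projected back into it
($T_{new} = X_{new} P$ after applying the stored centers and scales), so the
impact of a removal can be judged in the new score space. Missing values are
not supported; the NIPALS extension that skips them is deliberately deferred.

## OPLS-DA

`fit_oplsda()` separates two classes, coded $y \in \{-1, +1\}$ (the
lexicographically larger label is $+1$). For each of the `n_orth` orthogonal
components the algorithm computes the PLS weight $w \propto X^\top y$, the
loading $p$ of the corresponding score, and the orthogonal weight
$w_o \propto p - (w^\top p)\,w$ — the part of the loading not aligned with
the predictive direction; the matrix is deflated by the orthogonal component
$t_o p_o^\top$. The single predictive component is then extracted from the
deflated matrix, with y-loading $q = y^\top t / (t^\top t)$. With
`n_orth = 0` the model is exactly the first PLS1 component, an identity the
tests assert to $10^{-10}$.

Prediction (`predict_oplsda()`) maps a test sample through the stored
centers/scales, strips each orthogonal component in fit order, and
thresholds $\hat y = q\,t_{pred}$ at zero; an exact tie is assigned the
lexicographically first label. Predictive ability is estimated by
`cross_validate_oplsda()`: stratified k-fold (default 7, the chemometrics
convention; folds are dealt round-robin within class after a seeded
shuffle), $Q^2 = 1 - PRESS / \sum y_i^2$. The $\{-1,+1\}$ coding keeps
$\sum y_i^2$ equal to the centered sum of squares for balanced designs.
Multi-class problems are handled one-vs-rest by fitting one binary model per
class and assigning the argmax $\hat y$; a true multi-Y OPLS is out of
scope. The number of orthogonal components is never auto-selected — users
choose it and can sweep it, reporting $Q^2$ per value.

`loading_decomposition()` tabulates, per variable, the predictive loading,
the orthogonal loadings and the rank by $|p_{pred}|$; on simulated cohorts
the rank-1 variable falls on the designated biomarker's tallest peak.

## STOCSY and intensity ranking

`stocsy()` correlates the intensity at a driver variable (chosen by ppm and
snapped to the nearest grid point) against every variable across samples.
Resonances of the same molecule have strictly proportional intensities and
correlate near 1, which is what makes the correlation trace useful for
structural assignment; the covariance trace (always $r \cdot s_d \, s_j$)
retains lineshape-like intensity meaning, which is why STOCSY is by default
run on the normalized but *unscaled* matrix. Correlation is Pearson, as in
the original formulation; zero-variance columns receive correlation 0 by
convention. `rank_variables()` orders variables by median, mean or maximum
intensity with ties broken by descending ppm, giving a deterministic answer
to "which signals are most abundant".

## Consensus multiblock PCA

`fit_mbpca()` models user-defined, non-overlapping ppm blocks, each with its
own scaling and a weight (default $1/\sqrt{p_b}$) that prevents wide,
intense regions from swamping small ones — the dynamic-range motivation for
block modeling. The consensus iteration (CPCA-W) alternates block loadings
$p_b \propto X_b^\top t_T$, block scores $t_b = X_b p_b$, super weights
$w_T \propto T_{blk}^\top t_T$ and the super score $t_T = T_{blk} w_T$, then
deflates every block by the super score. With this normalization scheme the
two unit-norm steps cancel, and the iteration is algebraically a power
iteration on the concatenated weighted matrix; the super scores therefore
coincide with plain PCA scores of that concatenation (asserted to $10^{-6}$
against an SVD oracle), while the block-level quantities — super weights,
block scores/loadings, per-block explained variance — provide the
interpretation layer that plain PCA lacks. Unassigned grid regions are
simply unused.

## Reference-pattern matching with shift tolerance

`extract_reference()` takes an analyst-chosen window (at least 5 points)
from a clean, high-intensity spectrum and stores the mean-subtracted trace
as a template. `compass_match()` scans every sample over integer lags
$\ell \in [-L, +L]$ and scores each lag by the Pearson correlation between
the template and the shifted window. Pearson correlation is used rather
than unnormalized cross-correlation deliberately: it is invariant to the
per-sample affine intensity transforms caused by dilution and receiver gain,
so the threshold (default 0.8, user-adjustable) expresses pure shape
agreement, and abundance is reported separately as the matched-window
maximum intensity, by which samples are ranked. Ties between lags go to the
smallest $|\ell|$, then the negative lag. Sub-grid alignment is deferred;
the lag range should cover the expected chemical-shift jitter (±0.005 ppm is
a typical default for urine).

`compass_stocsy_iterate()` closes the loop with statistical spectroscopy:
the matched subset is STOCSY-driven at the template's apex, surfacing the
molecule's other resonances, and the template is refined as the mean of the
lag-aligned matched windows. On noise-free data the iteration reaches a
fixed point immediately; on real data a few iterations sharpen the match
set.

## Univariate box statistics

`box_stats()` reports min, Q1, median, Q3 and max per variable, per class or
cohort-wide. Quantiles use linear interpolation of order statistics (R's
type 7) — no convention is universal, so one is fixed and documented for
cross-implementation reproducibility. `locate_sample()` places one sample
within its group at a chosen variable; the percentile is the sample's
midrank within the group divided by the group size,
$(\#\{x < v\} + (\#\{x = v\} + 1)/2)/n$, which handles ties
deterministically and gives exactly 1 for a unique group maximum, and the
IQR flag is $q_1 \le v \le q_3$. Hypothesis testing is deliberately absent:
this module is descriptive.

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates multi-class cohorts from compound templates
(`compound_spec()`: explicit peak lists with Lorentzian lineshapes —
explicit lists rather than structure-based spectral prediction, which is a
research problem in its own right and unnecessary for exercising the
pipeline). Per sample $i$ of class $g$ and compound $c$:

$$\mathrm{conc}_{i,c} = \mathrm{base}_c \times \mathrm{mult}_{g,c}, \qquad
  \mathrm{base}_c \sim \mathrm{LogUniform}(l_c, h_c)$$

$$x_i(\nu) = \sum_c \mathrm{conc}_{i,c} \sum_k I_{c,k}\,
  \frac{(w_c/2)^2}{(\nu - \mu_{c,k} - \delta_i)^2 + (w_c/2)^2}
  + \varepsilon_i(\nu)$$

with a single per-sample shift offset $\delta_i \sim N(0, \sigma_\delta)$
(pH and ionic-strength shifts move related resonances coherently; per-peak
jitter is deliberately off) and i.i.d. Gaussian noise. One seed drives all
randomness and is recorded in the annotations; equal seeds give bit-identical
datasets.

Default conditions, chosen once as realistic for urine-like cohorts: base
concentrations log-uniform over $[0.5, 2]$ (biological concentrations span
multiples, and multiplicative class effects match how biomarker
"concentration ranges" behave); shift jitter 0.001 ppm; noise 0.01 intensity
units against peak apexes of order 1; a 9.5–0.5 ppm grid of 1000 points.
The default linewidth is 0.02 ppm FWHM: the simulator emits decimated grids
(~0.002–0.02 ppm per point, versus ~0.0004 for a 32k acquisition), and a
line must span several grid points to be representable at all — 0.02 ppm
corresponds to a moderately line-broadened processed spectrum and satisfies
that sampling requirement on every grid the package ships.

Two further design points. First, in validation cohorts for supervised
models, the designated biomarker is given a *tight* within-class base range
($[0.8, 1.25]$) while other compounds keep the 4-fold spread: a
multiplicative effect of 2 then separates the class-conditional
distributions (an effect of ~5 standard deviations on the log scale),
whereas a 2-fold effect on a 4-fold within-class spread would leave classes
genuinely overlapping and no classifier could reach perfect held-out
accuracy. Second, `presence_count` lets a compound occur in an exact number
of randomly chosen samples, which is what pattern-matching validation needs
(a Bernoulli presence model only controls the count in expectation).

The simulator deliberately omits baseline and phase artifacts, J-coupling
fine structure, peak-shape deviations from Lorentzian, and correlated
(1/f-like) noise. Tests that pass on simulated cohorts therefore demonstrate
the correctness of the algorithms under the stated generative model, not
robustness to every artifact of real spectra.

## Pipeline and problem sizes

`run_pipeline()` chains the stages through plain TSV/JSON files — every
intermediate inspectable, every run accompanied by a resolved-config copy
and an MD5 manifest; identical configurations reproduce identical hashes. A
thin command-line wrapper (`inst/cli/nmrchemo.R`) exposes each stage as a
subcommand and delegates to the same functions, so CLI and library results
are identical. Unknown configuration keys are rejected by name: silently
ignored typos are a classic source of irreproducible analyses.

The validation suite and the acceptance script run cohorts of 60–120
samples on grids of 300–4000 points, with 20-replicate loops for the
stochastic properties — sizes chosen so the full validation completes in
seconds on a single core while still exercising every code path at
realistic dimensionality. All tolerances quoted above (e.g. $10^{-8}$
against the SVD oracle, $10^{-12}$ for brute-force correlation oracles) are
asserted by the test suite as written.

## Known limitations

* Two-class OPLS-DA with one-vs-rest multiclass; no multi-Y OPLS, S-plots,
  VIP scores or permutation p-values.
* No missing-value support in the latent-variable models.
* No peak alignment (icoshift-style), binning, baseline correction, or
  absolute quantification by peak integration.
* JCAMP support covers the common Bruker-exported dialect; JEOL and NTUPLES
  formats and 2D NMR are out of scope.
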