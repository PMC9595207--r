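---
title: "Models and methods behind traffiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind traffiq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

traffiq implements the downstream statistics of a high-content imaging
assay of endogenous GLUT4 (and transferrin receptor, TfR) translocation to
the plasma membrane of adipocytes: the pipeline starts from per-cell
measurement tables produced by upstream segmentation and ends at EC50s,
half-times, knockdown effect sizes and AP-MS interactome calls. This
vignette is the package's account of its models, assumptions, numerical
choices and limitations. Every empirical claim here is one the test suite
or `scripts/acceptance.R` computes; nothing is quoted from elsewhere.

## The single-cell assay model

One row of a cell table is one segmented cell with surface-GLUT4 and
surface-TfR antibody intensities (arbitrary fluorescence units, AFU), a
lipid-scatter score, and bookkeeping identifiers (plate, well, field). The
analysis assumes, and the generator `simulate_plate()` emulates:

* **Lognormal per-cell noise.** Single-cell surface intensities are
  strictly positive and right-skewed, so per-cell variation is modelled as
  a multiplicative lognormal factor with mean exactly 1 and coefficient of
  variation `cell_cv` (default 0.35, a typical single-cell spread for this
  kind of stain). Additive read noise, when enabled, is half-normal so
  intensities stay non-negative.
* **Plate batch effects.** One multiplicative gain (lognormal across
  plates, SD 0.1 on the log scale) and one additive offset (normal, SD 2
  AFU on a basal scale of 100) per plate. This is deliberately the minimal
  structure the anchored normalization below is designed to remove; the
  tests verify exact removal.
* **A fibroblast subpopulation.** Differentiation is never complete; a
  default 10% of cells (the assay's own acceptance bar is at least 90%
  differentiated) are fibroblasts/necrotic cells that draw from the basal
  intensity distribution regardless of insulin and from a low lipid-scatter
  distribution (mean 0.2 vs 0.9 for adipocytes, SD 0.1).
* **Poisson cell counts** per well, with knockdown conditions able to scale
  the expectation (cytotoxic siRNAs).
* **Dose and time structure.** The true adipocyte well mean is a
  three-parameter Hill function of insulin dose; inhibitors and
  insulin-resistance agents scale the insulin-stimulated *increment* by
  `IC50 / (IC50 + dose)`; kinetics follow a one-phase association
  `S(t) = S0 + (Splateau - S0)(1 - 2^{-t/t_{1/2}})`, parameterized by the
  half-time so presets can carry published half-times directly.

The per-channel lognormal factors of a cell are drawn independently; real
cells correlate channels through cell size and focus, which the generator
does not emulate. Passing tests therefore certify the *statistics* of the
pipeline, not image-level realism.

### Presets

`preset()` returns configurations whose generating parameters equal
characteristic published values for this assay (insulin EC50 0.860 nM;
GLUT4 half-times 7.5 / 9.5 min at 100 / 1 nM insulin; inhibitor IC50s
GDC0941 8 nM, MK2206 183 nM, GSK23344 289 nM, GDC0068 121 nM; chronic
insulin 0.17 nM and TNF 0.18 ng/ml against the 1 nM response; basal TfR
35% and basal GLUT4 6.5% of the insulin maximum; TfR half-time 3 min vs
GLUT4 9 min), so that the full pipeline run on generated data should
recover them. The generator's defaults *are* the study conditions: for the
dose-response presets, two plates of four replicate wells per condition at
~550 cells/well (about 2000 gated adipocytes per dose) reproduce a
realistic screening scale while keeping the whole acceptance run around a
minute on one CPU; these sizes are stated here as the package's choice of
problem scale.

One deliberate deviation: the `fig4d` preset sets `plate_offset_sd = 0`.
Percent-of-maximum ratios are not invariant to an additive offset, and the
experiment that motivates this preset reads background-corrected
intensities; the generator therefore treats background subtraction as an
upstream given for that design. Gains cancel in the ratio and are left on.

## Gating and QC

Adipocytes are separated from fibroblasts/necrotic cells on the
lipid-scatter feature. The default gate is an exact two-class
minimum-within-class-variance split (Otsu's criterion on the sorted
values, no histogram binning), trained on control wells only so that
treatment effects cannot bias the threshold, then applied everywhere.
Whether gating should be global or per-plate is not dictated by the assay
description; global-from-controls is the default and `per_plate = TRUE` is
available. A fixed threshold is supported for reproducibility. Wells with
fewer than `min_cells` gated adipocytes are excluded by `well_qc()` before
any statistics.

## Anchored cross-plate normalization

For plate $i$ with control-basal median $med0_i$ and control-100 nM median
$med100_i$ (medians over gated cells pooled across that plate's control
wells — cells, not per-well medians), and cross-plate anchors
$maxmed0 = \max_i med0_i$, $maxmed100 = \max_i med100_i$:

$$X^{norm}_i = (X_i - med0_i)\,\frac{maxmed100 - maxmed0}{med100_i - med0_i} + maxmed0$$

is the unique linear map sending each plate's control medians onto the
common anchors. Because a plate's gain and offset enter both the cell
values and that plate's anchors, the map removes them exactly; the tests
assert control medians land on the anchors to 1e-9 relative error and that
the between-plate variance of control medians is numerically zero.
The transform is idempotent and invariant to plate relabelling (a maximum
is order-free). Plates whose control medians are not strictly increasing
(`med100 <= med0`) are rejected as non-responsive rather than silently
flipped. After the linear map, log2 values are attached; cells with
non-positive normalized intensity are excluded from the log2 column with a
reported count instead of being floored — flooring would pile mass into
the left tail of the single-cell histograms, and surfacing the count lets
either convention be compared.

Summary scalings on top of the normalized scale: fold over basal, fold
over non-targeting control (stratified by insulin dose and cell line),
min:max percent (basal control to 0%, 100 nM control to 100%, no
clamping), and the per-cell surface/total reporter ratio.

## Dose-response and kinetic fits

The three-parameter Hill model fixes the slope at 1 — the standard
three-parameter agonist model, and no slope is reported for this assay; a
free-slope variant exists but is not the default. Both the Hill and the
one-phase association models are linear in their asymptote parameters once
the nonlinear parameter (EC50/IC50 or rate) is fixed, so fitting profiles
the residual sum of squares over the nonlinear parameter on a log scale —
a grid multistart at the observed doses/times (extended 64-fold beyond the
observed range), then a bracketed 1-D minimization to tolerance 1e-10 —
with the asymptotes solved by linear least squares at each candidate. This
makes the fit deterministic, immune to start-point luck, and exact on
noise-free data (verified to 1e-6 in the tests). Standard errors come from
the numerical Jacobian at the optimum; the half-time SE uses the delta
method on $t_{1/2} = \ln 2 / k$. An optimum stuck at the extended-grid
boundary, or an all-constant response, is flagged `converged = FALSE`
rather than silently returned. Fitting operates on per-dose summaries
(well means), not single cells, mirroring how such curves are reported;
`condition_means()` treats wells as the unit of replication throughout.

Model comparison uses $AIC = n\ln(RSS/n) + 2k$ with $k$ the number of
mean-model parameters, summed over datasets for independent fits and
computed on pooled residuals for the shared-parameter fit (per-dataset
Bottom/Top, one common EC50/IC50). AICc is available by flag but AIC is
the default. The mean squared residual is floored at machine epsilon so
the comparison stays decidable on noise-free data, where the true
structure is always preferred. With very few points per dataset the
sampling variability of per-dataset RSS can flip the verdict even when the
truth is shared; the comparison is intended for designs with replicate
wells per dose.

Whether curves should be fitted per experiment and averaged, or fitted to
pooled summaries, is left to the caller: the fitting functions accept any
summary table, and the comparison operation covers the shared-vs-
independent question directly.

## Population statistics and the screen

Density curves use a Gaussian kernel with Silverman's rule-of-thumb
bandwidth by default; a common bandwidth and grid should be supplied when
curves are overlaid. Estimation refuses fewer than 50 cells or degenerate
(constant) input. The population shift metric
$(\tilde{x}_{cond} - \tilde{x}_{basal}) / (\tilde{x}_{max} -
\tilde{x}_{basal})$ on medians locates a condition between the basal (0)
and insulin (1) control populations and is invariant to common affine
transforms — so it reads identically on raw or normalized scales.

The knockdown screen summarizes each readout (GLUT4 surface, TfR surface,
nuclei per field, droplet count, mean droplet area) as well-level means,
then condition mean ± SD over wells and fold over the non-targeting
control within each stratum. Well-level SDs are reported because cell-level
SDs would understate between-well error. Inference is a deliberately
simple, clearly labelled substitute for mixed-model post hoc machinery: a
two-sided Welch test of target wells against stratum control wells,
BH-adjusted across targets within readout and stratum. Cross-cell-line
comparisons regress one line's per-target effects on the other's by
ordinary least squares (per-target means by default).

## AP-MS interactome scoring

The bait-vs-IgG pipeline follows the standard label-free workflow exactly:

1. **Filter**: drop Reverse / Potential contaminant / Only identified by
   site rows, and rows with fewer than two quantified values in the bait
   pulldowns. The quantification clause is ambiguous between "in every
   bait condition" and "across all bait samples"; both are implemented and
   the per-condition reading is the default (a protein solidly quantified
   in basal pulldowns alone is kept).
2. **log2 + median normalization**: per-sample median centring with the
   grand median added back, preserving the pooled scale.
3. **IgG averaging**: replicate $r$ of the basal and insulin IgG controls
   are averaged into one control per replicate, removing IgG-driven
   between-condition variance; a missing partner is carried forward (the
   handling is not dictated anywhere, so the count of carried values is
   surfaced).
4. **Two-step imputation**: conditions with at least two quantified
   replicates have their remaining missing values drawn from a normal with
   the replicates' mean and SD; remaining missing values *in the IgG
   controls only* are drawn per sample from a downshifted normal (mean −
   1 SD, 0.6 SD) resembling the sample's low tail — the left-censored
   (MNAR) assumption. Draw order is documented (proteins in row order,
   conditions in design order, then IgG columns) and scoped to a single
   seeded generator, so runs are bit-reproducible and unit tests can
   replay individual draws.
5. **Testing**: per condition, log2FC = mean(bait) − mean(IgG) and a
   Student's (pooled-variance) two-sample t test — the common default in
   proteomics practice; Welch by flag — restricted to proteins complete
   after imputation, with BH adjustment per condition (pooled adjustment
   by flag).
6. **MAD classification**: with $\Delta$ = log2FC(insulin) −
   log2FC(basal) across all tested proteins and raw (unscaled) MAD — no
   1.4826 consistency constant — a protein is insulin-regulated when
   $|\Delta| > 2\,MAD$, log2FC $> 2$ (in at least one condition, by
   default), and adjusted $p \le 0.05$ in that same condition. Whether
   $\Delta$ should be signed or folded is unstated; signed
   insulin − basal is used.

The generator `simulate_ipms()` plants truth: a fraction of proteins are
bait interactors (+4 log2 by default), a subset of those gain an insulin
delta (+3 log2), and every value is independently censored with
probability $\mathrm{logit}^{-1}(slope \cdot (midpoint - x))$ — steepness
parameterization, so an infinitely steep slope with the midpoint below all
intensities yields no missingness. Nonspecific background binding gets a
larger replicate SD (0.8 log2) than specific bait signal (0.3 log2),
reflecting the well-documented irreproducibility of nonspecific binders in
pulldowns. This heteroscedasticity matters for the MAD rule: on a
homoscedastic Gaussian $\Delta$, the raw 2·MAD threshold sits at 1.35
standard deviations and passes ~18% of any null set regardless of noise
scale — the rule only has a low false-label rate because constitutive
interactors are more reproducible than the background that sets the MAD.
That observation is a genuine limitation of 2·MAD cutoffs worth keeping in
mind with real data.

## Numerical and degenerate-input conventions

* Even-count medians are midpoint means (R's default), used for anchors.
* `EC50`/`IC50`/half-time optimization is on the log scale; tolerance
  1e-10; extended-bracket edge hits flag non-convergence.
* Zero-variance responses, empty populations, degenerate anchors,
  missing control wells (named plate), unknown preset/condition names
  (named well), all-identical scatter, sub-50-cell densities, and
  sub-3-protein MAD calls raise immediate errors instead of propagating.
* All generator and imputation randomness is scoped with
  `withr::with_seed`: no global RNG state is disturbed, and identical
  seeds are bit-identical.

## Known limitations

* The generator works at the per-cell table level; segmentation errors,
  illumination fields, focus drift and channel crosstalk are out of scope.
* Per-cell intensity families beyond the lognormal (e.g. heavy-tailed
  mixtures from staining artefacts) are not modelled; the gating and
  normalization results on real data should be inspected via the reported
  thresholds, anchors and exclusion counts.
* The screen's Welch/BH inference is a substitute for, not a reproduction
  of, mixed-effects post hoc analyses.
* Real interactome lists for a given bait require the corresponding
  deposited proteomics data; the interactome module here is validated on
  synthetic truth only.
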