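---
title: "Quantifying glymphatic function and PVS burden: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glymphatic function and PVS burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphkit)
```

`glymphkit` implements an imaging-to-statistics chain for studying
perivascular waste clearance (the glymphatic system) in cerebral small vessel
disease: the DTI-ALPS index from diffusion MRI, quantitative perivascular
space (PVS) volume fractions from structural MRI, and the statistical layer
linking both to cognition. This vignette explains each model, the parameters
that matter, what the synthetic generators do and do not emulate, and the
design decisions taken where the methodology is genuinely open.

## The DTI-ALPS model

Diffusion MRI measures water displacement along chosen gradient directions.
At the level of the lateral-ventricle body, three tissue orientations
coexist in a useful geometry: projection fibers run head–foot (z),
association fibers run front–back (y), and the perivascular spaces around
the deep medullary veins run left–right (x), perpendicular to both tracts.
Water moving along perivascular channels therefore raises the x-axis
diffusivity in both fiber regions without a confounding fiber contribution,
motivating

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx}^{proj}, D_{xx}^{assoc})}
                       {\mathrm{mean}(D_{yy}^{proj}, D_{zz}^{assoc})}.$$

An index of 1 means no preferential perivascular diffusion; values well
above 1 indicate freer perivascular water movement, read as a proxy of
glymphatic function. The index is dimensionless and invariant to a common
rescaling of all four diffusivities (tested as a property).

**Tensor estimation.** `fit_tensors()` solves
$\ln(S/S_0) = -b\, g^\top D g$ per voxel. $S_0$ is the mean of all
$b = 0$ volumes (averaging reduces noise when several reference volumes are
acquired). The default estimator is weighted log-linear least squares with
weights equal to the squared predicted signal — the standard correction for
the heteroscedasticity introduced by the log transform — with plain OLS
available; on noiseless data the two coincide exactly. Negative eigenvalues
(possible under noise) are clamped to zero only for FA and color-FA; the raw
tensor is retained because the ALPS ratio uses raw diagonal diffusivities.
Voxels with non-positive signal are flagged, given a zero tensor, and
excluded from ROI averages.

**ROI protocol.** Clinical practice places two 5-mm diameter spherical ROIs
manually on the color-FA map, by multiple raters with consensus. Rater
behaviour cannot be emulated; the reproducible interface is a coordinate
table (world mm, RAS), and `sphere_roi()` selects every voxel whose center
falls within the radius. Rater agreement on repeated measurements is the
domain of `icc_absolute_agreement()`. Diagonal diffusivities are taken in
the native image axes — the acquisition is assumed axis-aligned, as when
reading values off a color-FA map — and no tensor reorientation is applied.
The pipeline default analyses the left hemisphere only (the common
convention in right-handed cohorts), but every operation is
hemisphere-agnostic.

**Diffusion phantoms.** `make_dwi_phantom()` renders rectilinear region
layouts with known tensors through the forward model
$S = S_0 e^{-b g^\top D g}$, plus channel-wise Rician noise
($\sigma = S_0/\mathrm{SNR}$) matching magnitude-MR statistics. Fiber-block
eigenvalues default to canonical white-matter values
$(1.7, 0.3, 0.3)\times10^{-3}$ mm²/s. Two layouts matter for testing:

* `"alps"` — projection block along z, association block along y, isotropic
  background: the anatomical geometry. With axisymmetric tensors every ALPS
  input equals the perpendicular eigenvalue and the index is exactly 1; the
  `pvs_dxx` argument raises the x-axis diffusivity of both blocks to plant a
  glymphatic signal.
* `"alps_oracle"` — both blocks carry the principal axis along x, so the
  full pipeline (fit → ROI → extract → ratio) must return exactly
  $\lambda_\parallel/\lambda_\perp = 5.667$. This is the arithmetic oracle
  used in the acceptance tests; the noiseless fit inverts the generator to
  below $10^{-9}$ mm²/s.

The default gradient scheme is 64 directions at b = 1000 s/mm² on a
spherical Fibonacci lattice plus five b = 0 volumes, mirroring a common
clinical protocol. The phantoms do not simulate eddy currents, motion,
susceptibility or anatomy; those corrections are upstream of this package's
scope and its inputs are assumed preprocessed and co-registered.

## PVS quantification

PVS are dark on T1w and bright on T2w. Dividing the two (after denoising)
yields the enhanced PVS contrast image, on which PVS are dark tubes on a
bright background — a geometry made for Hessian-based tubularity filtering.

**Non-local means** (`nlm_filter()`): each voxel is replaced by a weighted
average of search-window candidates, with weights decaying in the patch-mean
squared difference after subtracting the expected noise term $2\sigma^2$.
The noise SD is estimated from pseudo-residuals against the six-neighbour
mean (robust MAD), so the filter adapts to the image's noise level without a
tuning parameter; `h = 0` disables filtering. Being a convex combination,
the output cannot leave the input intensity range.

**EPC** (`compute_epc()`): the ratio is formed as filter-then-divide, with
the denominator floored at `eps` and such voxels masked out, so no
infinities are produced.

**Frangi vesselness** (`frangi_vesselness()`): per scale $\sigma$, the
Hessian of the Gaussian-smoothed image is scale-normalized by $\sigma^2$ and
its eigenvalues sorted by absolute value, $|\lambda_1| \le |\lambda_2| \le
|\lambda_3|$. Dark tubes require $\lambda_2, \lambda_3 > 0$; where the gate
passes, the response combines plate discrimination
($R_A = |\lambda_2|/|\lambda_3|$, weight $\alpha$), blob discrimination
($R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$, weight $\beta$) and
structureness ($S$, the Hessian Frobenius norm, weight $c$); the map is the
maximum over scales, bounded in [0, 1]. Defaults: $\alpha = \beta = 0.5$
(the filter's canonical values), scales {0.5, 1, 1.5, 2} mm spanning PVS
calibers, and adaptive $c$ = half the maximum Frobenius norm per scale,
which tracks image contrast. A numerical floor zeroes the response when the
maximum Hessian norm is negligible relative to the intensity scale
(otherwise adaptive $c$ would rescale floating-point noise on flat volumes
into spurious response). The eigensolver is a closed-form trigonometric
solution for symmetric 3×3 fields, verified against `eigen()`.

**Segmentation and volume fraction.** `segment_pvs()` thresholds the
vesselness map inside a region mask and removes 26-connected components
below a minimum size; 26-connectivity preserves thin oblique tubes that
touch only diagonally. The threshold (0.1) and minimum cluster (3 voxels)
are calibration constants fixed once against the standard tube phantom
(below) and exposed in the configuration. `pvs_volume_fraction()` divides
each region's PVS volume by the whole-brain GM+WM volume (×100); this
whole-brain denominator removes inter-individual brain-size effects and is
the default reading of a regionally unqualified "gray + white matter
volume". Because it is ambiguous whether a region-local denominator could be
intended, a `denominator = "region"` option is provided without asserting
either convention. With the shared denominator, the basal-ganglia aggregate
(caudate + putamen + pallidum + amygdala) satisfies exact additivity of
volume fractions, which is tested.

**Structural phantoms.** `make_pvs_phantom()` renders tubes as finite
cylinders voxelized by the center-of-voxel rule (a voxel belongs to the tube
iff its center lies inside the cylinder — the simplest consistent rule, and
the one the brute-force test oracle implements independently). The standard
test phantom uses elongated tubes (radii 1–2 mm, lengths 6–8 mm, 30%
intensity contrast, Gaussian noise at 5% of background) inside a synthetic
box atlas of twelve nucleus regions; short stubs were deliberately avoided
because a 2-mm cylinder is closer to a blob than a tube and is not what the
filter is designed to detect. At 1-mm resolution the center-of-voxel rule
systematically over-counts thin-tube volume (the voxelized cross-section of
a 1-mm radius tube is 5 mm² against π mm² analytic); the voxelizer is
therefore tested for convergence to the analytic volume under grid
refinement rather than against a fixed analytic bound at coarse resolution.
Gaussian (not Rician) noise is used for the structural channels, adequate at
structural-image SNR. The atlas is purely synthetic geometry: it carries no
anatomical shape, no bias fields, and no partial-volume gradients, so
passing phantom tests demonstrates correctness of the operators, not
clinical segmentation accuracy on real anatomy.

## The statistical layer

**Z-scoring** (`zscore_cognition()`): each raw test score is standardized
against the healthy-control subgroup mean and sample SD (n−1 denominator,
the standard choice for reference-group standardization); domains derived
from timed tests (TMT-A → processing speed, TMT-B → executive function) are
multiplied by −1 after standardization so higher always means better. The
construction forces HC mean 0 and SD 1 exactly — a useful invariant, tested
as such.

**Group comparisons** (`group_compare()`): per-group Shapiro–Wilk (α = 0.05)
and Levene on medians decide between one-way ANOVA and Kruskal–Wallis;
categorical variables use Pearson chi-square *without* continuity
correction — verified by reproducing a published baseline table's p-value
(0.7150 for 19/40 vs 61/120 male counts) through independent 2×2 arithmetic.
Pairwise p-values are Bonferroni-multiplied and capped at 1.

**Partial correlation** (`partial_correlation()`): both variables are
residualized on the covariates (OLS with intercept) and the residuals
correlated; $t = r\sqrt{df/(1-r^2)}$ with $df = n - 2 - k$. This
residualized form is algebraically identical to the inverse-correlation
definition and is checked against an explicit projection-matrix oracle to
$10^{-12}$. FDR control (`fdr_adjust()`) is Benjamini–Hochberg within
declared families; which tests share a family (e.g. ALPS-vs-PVS versus
ALPS-vs-cognition) is analysis configuration, not something the method can
decide, so families are explicit arguments.

**ICC** (`icc_absolute_agreement()`): single-measure, two-way model,
absolute agreement, from the row/column/error mean squares, with the
standard F-based confidence interval using Satterthwaite degrees of freedom.
Rejects missing cells rather than imputing.

**Mediation** (`mediate()`): three OLS fits give the paths — $a$ (X→M),
$b$ and $c'$ (M and X in the full outcome model), $c$ (total) — and with a
shared covariate set the identity $c = c' + ab$ holds to machine precision
(asserted at $10^{-10}$). Inference on $ab$ uses a subject-level
nonparametric bootstrap, 5000 replicates by default, with a percentile
interval: the simplest defensible reading of "bootstrap CI", with BCa
available as an option. Covariates are binary-coded 0/1 (male = 1) to fix
sign conventions. The mediated proportion $100\,ab/c$ is reported only under
consistent mediation (same sign of $ab$ and $c$); it is uninterpretable and
returned as `NA` otherwise. Exposure, mediator and outcome scales are the
caller's: both unstandardized (default) and standardized (`standardize =
TRUE`) paths are available, because reported unstandardized indirect effects
depend on whether volume fractions enter as fractions or percentages and no
single convention can be asserted. One caveat worth knowing: exact
proportionality between mediator and exposure makes the model unidentifiable
(the full design matrix loses rank), so a literally noise-free mediator is
rejected as collinear rather than "solved".

**Cohort generator.** `make_cohort()` draws three groups (defaults 40/52/68
— healthy controls and CSVD with/without mild cognitive impairment, the
scale of a typical single-center cohort) and builds the mediator and outcome
from the linear structural model
$M = \alpha_M[g] + aX + w_M^\top Z + \varepsilon_M$,
$Y = \alpha_Y[g] + c'X + bM + w_Y^\top Z + \varepsilon_Y$ with X = putamen
PVS volume fraction, M = ALPS index, Y = MoCA. Group intercepts are solved
so the marginal group means land on the effect model (ALPS 1.39/1.29/1.23
with SDs 0.14/0.11/0.11; MoCA 25.98/25.25/19.82; demographics and
risk-factor prevalences at published group rates). Since per-subject
distributions are never published, the regional PVS means and the path
coefficients are generator parameters chosen once for realism (defaults
a = −0.15 per %VF, b = 6 MoCA per ALPS unit, c′ = −2, noise SDs 0.08 and
2.5), giving covariate-adjusted correlations of roughly −0.2 (ALPS vs
putamen-PVS) and +0.3 (ALPS vs MoCA) — small-to-moderate effects of the
size seen in clinical cohorts. With `effect_model = NULL` the generator
reduces to the bare structural equations, which is what the exact algebraic
tests use. The generator is bit-reproducible under its seed.

## Numerical choices and problem sizes

Tolerances follow the quantity's conditioning: exact identities (OLS
decomposition, BH versus brute force, residualized correlation) are asserted
at $10^{-10}$–$10^{-12}$; noiseless phantom inversions at $10^{-9}$ mm²/s;
stochastic recoveries at the sampling error of their design (e.g. planted
indirect effect within 5% at n = 2000 with noise SDs sized so the
between-seed spread is ~1%). The default test and acceptance runs use
phantom grids of 16³–32³ voxels, a 40×40×32 structural atlas, cohorts of
160–2000 subjects, 1000-replicate bootstraps and a 200-repeat null-coverage
simulation — sizes chosen so the whole suite completes in a few minutes
while leaving each check's statistical resolution far finer than its
assertion. The coverage check accepts 90–99% where 95% is nominal,
reflecting the binomial spread of 200 repeats.

## Known limitations

* ROI placement is coordinate-driven; no automated atlas-based placement.
* No preprocessing: eddy/motion correction, bias-field correction, brain
  extraction, registration and tissue segmentation are assumed done.
* PVS quantification targets subcortical nuclei; cortical and
  centrum-semiovale PVS are out of scope (reliable cortical PVS
  quantification remains technically hard at conventional resolution).
* Single-mediator models only; no moderated or multiple mediation, no
  missing-data imputation.
* Phantom realism is deliberately limited (uniform backgrounds, box atlas,
  no scanner artifacts): the generators validate operators, not clinical
  performance.
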