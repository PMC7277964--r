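---
title: "Methods: CT lung densitometry, GAP staging and feature ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT lung densitometry, GAP staging and feature ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungdens)
```

# The measurement model

Lung attenuation on CT is expressed in Hounsfield units: air is about
−1000 HU, water 0 HU, dense bone roughly +2000 HU. Aerated lung sits
around −850 HU; fibrotic remodelling (reticulation, ground glass,
honeycombing walls) moves tissue towards soft-tissue densities, while
emphysema moves it towards pure air. Densitometry therefore summarises
disease burden through the distribution of HU values over the segmented
lung.

`lungdens` represents that distribution as an integer-binned histogram:
1-HU bins from −1024 to +200 inclusive (1225 bins), with voxel HU
rounded half-away-from-zero to its bin. The lower bound −1024 is treated
as universal — values below it are clipped at load time — while the
*upper* bound of what counts as "lung volume" is an analysis parameter,
not a data property. Three conventional upper thresholds are supported,
−200, 0 and +200 HU, because the literature's index definitions disagree
on this point and the choice changes every percentage denominator. All
indices are computed at each threshold so their sensitivity to it can be
inspected directly.

On the histogram restricted to [−1024, *U*]:

* **NL%** — fraction in [−950, −701] HU;
* **PFF%** — 100 − fraction in [−1024, −700] HU;
* **HAA%** — fraction strictly above −200 HU (integer bins ≥ −199);
* **LAA%** — fraction strictly below −960 HU (bins ≤ −961);
* **HAA_A%** — fraction in [−600, −250] HU;
* moments — mean (MLD), median, variance, skewness and excess kurtosis
  m₄/m₂² − 3.

Two definitional points deserve emphasis, since both are genuine
ambiguities in the densitometry literature and the package resolves them
deliberately:

* **PFF% is a complement.** The *non-fibrotic* fraction is the mass in
  [−1024, −700]; the pulmonary fibrosis fraction is 100 minus it. The
  name of the index, its well-replicated *negative* correlation with
  FVC/DLco, and the typical reported magnitudes (PFF ≈ 20–30% where
  NL ≈ 60–70%) all force this reading. The raw non-fibrotic fraction is
  also returned (`nonfibrotic_pct`) so nothing is hidden.
* **Kurtosis is excess kurtosis.** Among the competing kurtosis
  conventions the package uses the fourth standardised moment minus 3,
  anchored by the property that it is zero for a perfectly normal
  distribution. Low kurtosis indicates a broadened, multi-modal
  histogram — more severe disease.

Band boundaries are kept exactly as printed in their source definitions,
inclusive on integer bins; in particular the 1-HU gap between NL's −701
and the non-fibrotic band's −700 is preserved rather than smoothed, and
strict inequalities map to the adjacent integer bin (("< −960" → bins
≤ −961, "> −200" → bins ≥ −199). HAA% is identically zero at the
−200 HU threshold — its band lies wholly outside the lung volume there —
and is reported as such rather than dropped, except in correlation
matrices where a constant column is meaningless.

# Segmentation

Lungs are isolated by region growing: the connected set of voxels with
HU in [−1024, +200] reachable from seed points, under 6-connectivity
(face adjacency) by default. Face adjacency is the conventional choice
on anisotropic CT grids because diagonal adjacency lets masks leak
through one-voxel barriers. The growth primitive is a multi-source flood
fill vectorised over the whole frontier, validated against an
independent fixed-point dilation oracle on hundreds of random grids.

Seeds are discovered automatically: voxels below −400 HU that are *not*
connected to a lateral face of the grid (ambient air) form candidate
components; the centroids of the up to two largest — each at least 30
voxels and at least 20% of the largest, so airway remnants are never
mistaken for a second lung — are the seeds. The superior face is
excluded from the ambient-air flood because the airway opening would
otherwise leak the ambient label into the lungs through the trachea.

The trachea is removed with the same machinery: a small (< 3 cm²
in-plane) near-air (< −900 HU) component in the most superior slices is
tracked slice-by-slice towards the lung bases and the tracked voxels are
subtracted; tracking stops when the cross-section grows by more than a
factor of 3 from one slice to the next, which is where the airway opens
into the lungs at the carina. If no candidate exists the mask is
returned unchanged with a warning — removal is idempotent. Finally,
`refine_mask()` drops connected components smaller than a minimum size
(default: the voxel count of 2 mL) and fills interior holes slice-wise.
This refinement stands in for the manual correction step a thoracic
radiologist would perform interactively; a user-supplied mask bypasses
the whole chain.

The region-growing parameters (seeds, connectivity, post-processing) are
module decisions documented here, not properties of the data; the
defaults were fixed once and are exposed (`region_grow_params()`,
`remove_trachea()` arguments) rather than tuned per-volume.

# GAP staging

The Gender–Age–Physiology index is computed from frozen constants:
female 0 / male 1; age ≤ 60 → 0, 61–65 → 1, > 65 → 2; FVC %predicted
≥ 75 → 0, 50–74 → 1, < 50 → 2; DLco %predicted ≥ 55 → 0, 36–54 → 1,
≤ 35 → 2, unable to perform → 3. Points 0–3, 4–5 and 6–8 map to stages
1, 2 and 3. `NA` in the DLco column of a clinical table encodes "unable
to perform". Mortality-probability estimates are out of scope.

# The statistical layer

Whether a densitometric index is *useful* is judged by regressing a
clinical severity measure on it, one index at a time, and comparing
maximized log-likelihoods:

* **Poisson GLM, log link**, response = GAP points (0–8), one
  explanatory index. GAP points are a small non-negative integer score,
  which is what makes the Poisson approximation serviceable; the
  response can be switched to GAP stage (1–3), since the literature is
  ambiguous about which was intended, but points is the default as the
  higher-resolution variable.
* **Gamma GLM, log link**, responses FVC or DLco %predicted — strictly
  positive and continuous, with the log link the conventional cure for
  convergence problems. These are deliberately plain fixed-effect GLMs:
  with one observation per patient and no grouping factor, no random
  effect is identifiable, so a mixed-model formulation would reduce to
  exactly these outputs (β, SE on the log scale, exp(β), p, log-lik).

Fitting is iteratively reweighted least squares (`stats::glm`) with
deviance tolerance 1e-8 and at most 100 iterations. Reported p-values
are Wald tests of the slope (the conventional GLM summary; a
likelihood-ratio p-value is also returned as `p_lrt`). No
multiple-testing correction is applied: raw p < 0.05 is the working
significance convention of the analyses this package supports, and the
log-likelihood ranking, not the p-value, is the primary comparison. For
the gamma family the log-likelihood is evaluated at the
maximum-likelihood shape, profiled given the fitted means (on which the
IRLS coefficients do not depend), so reported log-likelihoods are full
ML quantities comparable against direct numerical maximization — the
test suite verifies agreement to 1e-5 on small datasets for both
families. Two fits are flagged as carrying distinct information only
when their log-likelihoods differ by at least 1 point
(`rank_by_loglik()`).

# The synthetic-data generator

No suitable public cohort couples volumetric thin-section CT with
spirometry at the scale this pipeline targets, so the package ships a
generator whose defaults *are* its study conditions, fixed once:

**Phantoms** (`generate_phantom()`): a 96 × 96 × 64 grid at 3 mm
spacing (a full 32-phantom cohort segments in minutes on one CPU), an
elliptic-cylinder soft-tissue body (HU ~ N(+40, 20)), two ellipsoidal
lungs, and a trachea open to the top of the grid. Lung voxels carry
tissue labels — normal ~ N(−850, 60); fibrotic ~ N(−300, 150) truncated
at +200; emphysematous ~ N(−990, 12) truncated at −1024 — placed by
thresholding a smoothed Gaussian random field at empirical quantiles, so
lesions are spatially blobby rather than i.i.d. salt-and-pepper and the
marginal label counts are exact. Because every component distribution is
known, all band fractions and moments have closed-form binned ground
truth (`mixture_true_features()`), computed at the same half-integer bin
edges the histogram uses.

One geometric element is deliberately non-physiological: a thin dense
shell (~ +400 HU) at the pleural interface around each lung, and a dense
airway wall. Soft tissue at +40 HU lies *inside* the segmentation band
[−1024, +200], so no connectivity argument could stop region growing at
a soft-tissue lung boundary; in patients that role is played by the
chest wall and mediastinal anatomy plus a radiologist's oversight. The
shell gives the band a barrier so that automatic segmentation is
testable against exact ground truth. By default the trachea is sealed
from the lungs (two interior air components → two seeds); an attached
variant (`trachea_attached = TRUE`) joins trachea, main bronchi and both
lungs into one air space to exercise carina-stop trachea removal.

The phantoms do **not** emulate scanner noise, reconstruction kernels,
partial-volume gradients (an optional Gaussian blur exists but is off by
default, and ground truth is defined pre-blur), vessels, airways beyond
the trachea, or gravity-dependent density gradients. Passing phantom
tests therefore demonstrates correctness of the *algorithms* —
segmentation connectivity, binning, band arithmetic, moment estimation —
not robustness to acquisition physics.

**Cohorts** (`generate_cohort()`): n = 32 patients by default, male
skewed ~ 26:32, ages ~ N(68.3, 6.5) truncated to [55, 82], per-patient
fibrosis fraction f ~ Beta(14, 30) (mean ≈ 0.32) and emphysema fraction
~ Beta(2, 38). Lung function is generated from the index the analysis
assumes matters: FVC ~ Gamma with mean exp(3.8386 + 0.010·NL%) and shape
25, DLco ~ Gamma with mean exp(3.1656 + 0.015·NL%) and shape 20, chosen
so that cohort means land near a realistic fibrosis cohort (FVC ≈ 89%,
DLco ≈ 63% at NL ≈ 65%). These calibration anchors are realism targets
only; no test asserts them as outputs. `simulate_gap_cohort()`
additionally draws GAP ~ Poisson(exp(3.7 − 0.04·NL%)) for
parameter-recovery and ranking studies, with small independent
measurement noise (SD 0.5 percentage points; a tenth of that for
kurtosis) on the observed feature columns.

# Numerical choices and degenerate inputs

* Voxel HU is stored as doubles; rounding to bins is half-away-from-zero
  for reproducibility across float dialects.
* The binned median is the first bin at which the cumulative fraction
  reaches one half.
* A histogram with a single occupied bin has undefined kurtosis and
  skewness; this is an error naming the features, not a silent NaN.
* An empty mask, an empty restricted histogram, a non-integer Poisson
  response, a non-positive gamma response, and a seed outside the HU
  band are all fatal with messages naming the offending record.
* Zero-variance features produce `NA` rows in correlation matrices with
  a warning.
* Near-perfect gamma fits (residual dispersion below 1e-9) use the
  asymptotic shape solution 1/(2s) instead of a root search.

# File formats and scope

Volumes and masks are read and written as NIfTI (masks as uint8 0/1
with the parent affine; spacing must be set before the transform when
writing, a quirk of the NIfTI metadata model). DICOM *calibration* —
stored value × rescale slope + intercept, then the −1024 clip — is
exposed as `hu_calibrate()`, but reading DICOM series directories is out
of scope for this package; convert to NIfTI first. Texture/GLCM
radiomics, lobe segmentation, airway trees beyond the trachea,
multi-energy CT and kernel harmonisation are likewise out of scope.

# Validation problem sizes

The shipped validation suite uses: 500 random grids up to 12³ for the
flood-fill oracle; toy datasets of n ≤ 12 for the GLM likelihood
oracles; 20 phantoms for threshold monotonicity; 4–5 full-pipeline
phantoms for Dice and ±1.5% band-fraction recovery; and 200 simulated
32-patient cohorts for the ranking and slope-recovery study. One caveat
is worth stating plainly: the ±2·SE Wald interval for the Poisson slope
at n = 32 covers the generating value in about 94.8% of replicates (not
the nominal ≈ 95.4%), a textbook small-sample shortfall of the normal
approximation, so a ≥ 95%-of-200 coverage check sits on a knife edge by
construction.

# Known limitations

* Segmentation inherits the band's physics: with an upper bound of
  +200 HU, only out-of-band structures stop growth, so volumes whose
  lungs touch ambient air through in-band paths (severe chest-wall
  defects, scans cropped through the lung) need a supplied mask.
* The trachea tracker assumes the superior-most slices contain the
  airway; apex-cropped scans fall back to the unchanged-mask path.
* GLM rankings compare single-feature models only; no joint or
  penalised models are fitted.
* The generator's tissue HU distributions are stylised; absolute
  phantom index values should not be read as clinical reference ranges.
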