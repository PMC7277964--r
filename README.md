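# lungdens

Quantitative CT lung densitometry for idiopathic pulmonary fibrosis (IPF)
and other fibrosing interstitial lung diseases, in R.

Visual scoring of high-resolution CT (HRCT) in IPF is slow and
operator-dependent. Densitometric analysis replaces it with reproducible
numbers: isolate the lung parenchyma, histogram its attenuation values in
Hounsfield units (HU), and summarize the histogram with a handful of
indices that track disease severity and correlate with lung function
(FVC and DLco, % predicted). `lungdens` implements that pipeline
end-to-end for radiology and pulmonology researchers, together with the
statistical layer used to decide *which* index carries the most
information, and a synthetic phantom generator so every stage can be
validated without patient data.

## What it computes

**Segmentation.** Lungs are isolated by region growing over voxels with
HU in [−1024, +200] from automatically discovered seeds; the trachea and
main bronchi are removed by tracking the small near-air cross-section
down from the most superior slices until it opens at the carina. Small
components are dropped and interior holes filled. An externally supplied
mask can replace all of this.

**Densitometry.** From the 1-HU-binned attenuation histogram of the
segmented lung, restricted to [−1024, *U*] for each upper lung-volume
threshold *U* ∈ {−200, 0, +200} HU:

| Index | Definition |
|---|---|
| NL% | volume fraction in [−950, −701] HU (normally attenuated lung) |
| PFF% | 100 − %[−1024, −700] (pulmonary fibrosis fraction, complement of the non-fibrotic fraction) |
| HAA% | fraction above −200 HU (bins ≥ −199); identically 0 at *U* = −200 |
| LAA% | fraction below −960 HU (bins ≤ −961) |
| HAA_A% | fraction in [−600, −250] HU |
| kurtosis | excess kurtosis m₄/m₂² − 3 (0 for a normal distribution) |
| skewness, MLD, median, variance | remaining histogram moments |

**GAP staging.** The Gender–Age–Physiology index (0–8 points, stages
1–3) from sex, age, FVC and DLco.

**Model comparison.** Poisson GLMs (log link) of GAP points on each
index, ranked by maximized log-likelihood — two models are treated as
carrying distinct information only when they differ by ≥ 1 point of
log-likelihood — plus gamma log-link GLMs of FVC and DLco on NL%, and
per-threshold Pearson correlation matrices of the indices.

## Worked example

```r
library(lungdens)

# a synthetic thorax with 30% fibrotic / 5% emphysematous lung tissue
ph   <- generate_phantom(phantom_spec(fibrosis_fraction = 0.3,
                                      emphysema_fraction = 0.05, seed = 42))
mask <- segment_lungs(ph$volume)
mask
#> seg_mask: 96 x 96 x 64 grid, 75488 voxels set

compute_features(build_histogram(ph$volume, mask), -200)
#> feature_set (upper threshold -200 HU):
#>   nl_pct       66.70 %
#>   pff_pct      24.54 %
#>   haa_pct       0.00 %
#>   laa_pct       7.71 %
#>   haa_a_pct    19.74 %
#>   kurtosis  -0.161  skewness   1.128  MLD  -739.1 HU
```

About two thirds of this phantom's lung volume is normally attenuated
(NL% 66.7) and a quarter falls outside the non-fibrotic band (PFF%
24.5); the mildly negative excess kurtosis reflects the broadened
histogram that fibrotic tissue produces. Both match the phantom's
analytic ground truth (`ph$true_features`) to within a fraction of a
percentage point.

On a simulated 32-patient cohort, the statistical layer reproduces the
familiar reporting layout — gamma models of lung function on NL%:

```r
co <- generate_cohort(cohort_spec(seed = 42))
gamma_report(co$features)
#>        response threshold feature   beta exp_beta      se p_value log_lik
#> 1  fvc_pct_pred      -200  nl_pct 0.0117     1.01 0.00498 0.01833    -135
#> 2  fvc_pct_pred       200  nl_pct 0.0117     1.01 0.00447 0.00888    -134
#> 3 dlco_pct_pred      -200  nl_pct 0.0127     1.01 0.00444 0.00434    -123
#> 4 dlco_pct_pred       200  nl_pct 0.0118     1.01 0.00402 0.00331    -123
```

Each additional percentage point of normally attenuated lung multiplies
expected FVC by exp(β) ≈ 1.01 — about 1% higher lung function — with
p < 0.02 throughout. `poisson_report()` and `rank_by_loglik()` produce
the analogous GAP-response comparison across all indices and thresholds,
and `run_pipeline()` orchestrates everything from NIfTI volumes (or a
simulated cohort) to CSV/JSON reports. A thin command-line front-end
lives at `inst/scripts/lungdens-cli.R`.

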