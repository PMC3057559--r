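---
title: "Facial metrics, BMI and TaeEum-type classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial metrics, BMI and TaeEum-type classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasangface)
```

## The problem

Sasang constitutional medicine (SCM) classifies people into four
constitutional types — TaeYang, SoYang (SY), TaeEum (TE) and SoEum (SE) —
with distinct physical and physiological tendencies. The TE type is
strongly associated with higher body mass index, and facial shape carries
additional signal: TE faces tend to be squarer (lower cheek-to-jaw width
ratio) and, in men, wider. `sasangface` implements the quantitative
pipeline behind this kind of study: landmark-based facial metrics, their
comparison across types, their correlation with BMI, and a binary
logistic classifier for the TE type selected by exhaustive BIC-based
Bayesian model averaging. Because the original photographs of such
cohorts are not redistributable, the package also ships a synthetic
generator calibrated to the published group summary statistics, so every
stage of the pipeline is testable end to end.

## The landmark scheme and its conventions

All metrics are computed from 20 manually placed 2-D points per face:
midline points P1 (top of forehead) and P2 (chin), cheekbone extremes
P3/P4, jaw (gonion) points P5/P6, the fWHR height endpoints P7 (brow
midline) and P8 (upper lip midline), eye corners P9–P12 (outer then
inner), pupil centers P13/P14, and six eyebrow points P9p–P14p directly
above P9–P14 (`p` is an ASCII stand-in for the prime glyph, which is
hostile to file formats). The published point scheme is a figure rather
than a machine-readable table, and it does not label which point is
which; the mapping above is this package's documented convention,
shipped as data in `landmark_scheme()` so users can inspect it. The
reading of P13/P14 as pupil centers is inferred from the lower-face
definition referencing "two pupils" together with the 14-plus-6-primed
point budget; it is a convention, not a fact recoverable from the
source figure.

Coordinates follow the image convention: x grows rightward, y grows
downward, and a "vertical" distance is `|dy|`. Photographic protocols
align heads so that the pupil line is horizontal, which is what makes
`|dy|` the right reading of "distance between horizontal lines". All
metric computation is done in millimetres; pixel input requires an
explicit mm-per-pixel scale, because published eye sizes and eyebrow
heights are in mm while the original scale factor is not stated.

## The seven metrics

With `d(·,·)` Euclidean distance and `a` the vertical distance from the
chin line to the pupil line:

* **PAR** (perimeter-to-area ratio, 1/mm): closed perimeter of the
  lower-face polygon P3–P5–P2–P6–P4–P3 divided by its shoelace area.
  The closing edge P4–P3 is included: the polygon is described as
  running "through P3, P5, P2, P6, P4, and P3", which implies closure.
  The area is the absolute shoelace value, so vertex orientation can
  never flip its sign; a self-intersecting polygon is rejected with a
  diagnostic rather than silently measured.
* **WHR** = d(P3,P4) / d(P7,P8): facial width-to-height ratio.
* **CJWR** = d(P3,P4) / d(P5,P6): cheek-to-jaw width ratio.
* **eye size** = (d(P9,P10) − d(P11,P12)) / 2 in mm. The defining
  sentence ("distance between P9 and P10 minus the distance between P11
  and P12 divided by two") is ambiguous about parenthesization. The
  literal right-associative reading, d(P9,P10) − d(P11,P12)/2, gives
  ~60 mm on plausible faces, while published values are 28–33 mm; the
  chosen reading — half of (outer span minus inner span), i.e. the mean
  single-eye width — reproduces the published scale and is the
  anatomically meaningful quantity.
* **LF/FH** = a / d(P1,P2): lower-face to face-height ratio.
* **FW/LFH** = d(P3,P4) / a: face width to lower-face height.
* **EH mean**: mean of the six Euclidean distances d(Pk, Pkp), k = 9…14.
  These are full Euclidean distances, not vertical components, because
  the defining text says "distance between P9 to P9′" without
  qualification.

The dimensionless ratios are invariant under uniform scaling and
translation; PAR scales as 1/s and the two mm-valued metrics as s under
a scale factor s — properties the test suite checks explicitly.
Test–retest reliability of repeated landmarking is summarised as a
per-metric coefficient of variation (100·SD/mean across repeats,
min–max over subjects), the same summary used in landmarking
reliability reports.

## The synthetic generator and its calibration

The generator emulates the study design: 12 groups (3 types × 2 sexes ×
2 age decades) with the published per-group sizes, means and SDs for BMI
and all seven metrics. Each group is sampled from a multivariate normal.
Normality per type is consistent with how such data are reported
(mean (SD)) and analysed (ANOVA); it is an assumption, not an inference
from raw data.

The published correlations between BMI and each metric are *pooled*
within sex × age across the three types. Pooling mixes two sources of
covariance: the between-type separation of group means, and the
within-type correlation ρ_w. The calibration solves the moment identity

    r_pooled = (cov_between + ρ_w · Σ_g w_g σ_Bg σ_Mg) / (σ_B^tot σ_M^tot)

for ρ_w, where w_g are group-size weights, cov_between is the
size-weighted covariance of the group means, and total variances are
within + between. `calibrate_within_correlation()` inverts this exactly;
`implied_pooled_correlation()` is the forward form, and the two are
inverses to machine precision. A single ρ_w shared by the three types of
a stratum is the minimal sufficient assumption — published pooled values
cannot identify three separate within-type correlations. Metric–metric
within-type correlations are unknowable from the published summaries and
default to zero; if a user supplies a configuration that is not positive
definite, it is repaired to the nearest positive-definite correlation
matrix with a warning. Because the true within-type dependence structure
of the original cohort is unknowable, parameter-recovery tests treat the
calibrated generative model — not the unavailable study data — as ground
truth: passing them shows the pipeline recovers what this model encodes,
not that the model captures every feature of real faces.

The geometry-level generator goes one step further down: for each
sampled metric vector it synthesizes a full 20-point landmark set whose
computed metrics match the sampled values to a relative tolerance of
1e-6. A template face fixes the proportions the seven metrics leave
unconstrained (vertical placement of cheeks and jaw within the lower
face, inner-eye span relative to cheek width, pupil positions); widths,
heights and eye spans are then solved from the ratio targets, and the
overall mm scale is pinned by PAR, which for a shape-similar polygon
scales exactly as one over size. The solver iterates deformation and
re-measurement until every metric is within tolerance, erroring with the
offending metric if it cannot converge. The template itself is a
synthetic construction (shipped as
`inst/extdata/synthetic_template_landmarks.csv`), not a measured face.

## Correlation comparisons

Pearson correlations use the usual t-test with n−2 degrees of freedom.
Two independent correlations are compared on the Fisher scale:
z = atanh(r), Var(z) ≈ 1/(n−3), standardized difference
(z1 − z2)/√(1/(n1−3) + 1/(n2−3)), two-sided normal p. The 1/(n−3)
variance is the standard choice; two-sided p-values reproduce every
recomputable published comparison after rounding to two decimals,
whereas one-sided values do not. One published cell prints 2.43 where a
p-value belongs; that value equals the z statistic of its comparison
(the corresponding p is ≈ 0.015), an apparent typesetting slip that the
package documents and does not use as a reference value.

## Group comparisons

One-way ANOVA across the three types is followed by Duncan's multiple
range test for the letter display (a > b > c by descending mean; groups
sharing a letter are not separated). Ordered spans of p means are tested
against q(α_p, p, df)·√(MSE/n_h) with Duncan's protection level
α_p = 1 − (1 − α)^(p−1); a span inside a retained non-significant span
is never declared significant. Studentized-range quantiles come from R's
numerically integrated `qtukey`/`ptukey`, which match published q-tables
to two decimals. Group sizes are unbalanced, and the original software's
handling of that is unstated; this implementation uses the harmonic-mean
n, the textbook convention, so letters on other software may differ
marginally in borderline cells. Note Duncan's design trades family-wise
error for power: with three identically distributed groups at α = 0.05
the chance of a spurious separation is ≈ 1 − (1 − α)² ≈ 10%, which is
the method's intended behaviour, not a defect.

## The TE classifier

TE vs non-TE is modelled by binary logistic regression (IRLS via
`stats::glm.fit`, log-likelihood tolerance 1e-10), with Wald standard
errors from the inverse observed information. Odds ratios are reported
per the published comparison units (1 for BMI, eye size and eyebrow
height; SD-like units 0.002, 0.14, 0.05, 0.02 and 0.06 for PAR, WHR,
CJWR, LF/FH and FW/LFH). With 8 candidate predictors (BMI plus seven
metrics), all 2^8 = 256 subsets are fitted; each model m gets weight
proportional to exp(−BIC_m/2), the BIC approximation to its marginal
likelihood under a uniform model prior. The parsimonious model is the
BIC minimiser; per-predictor inclusion probabilities are the summed
weights of models containing the predictor. Subsets that separate or
fail to converge are excluded from the averaging, with a warning and
renormalized weights.

Discrimination is the c statistic, computed by the rank-based
Mann–Whitney estimator with ties counted one half — identical to the
trapezoidal ROC area, which the tests verify against a brute-force
pairwise oracle. Internal validation is leave-one-out cross-validation
at a probability threshold of 0.5; the published account names only
"cross-validation", so leave-one-out and the 0.5 threshold are
documented assumptions here. LOOCV folds that separate fall back to a
ridge-stabilized Newton fit (penalty 1e-4 on non-intercept terms) so a
single pathological fold cannot abort validation.

The four published stratum-specific equations are stored verbatim in
`te_equations()` and evaluated by `predict_te()` in their published sign
convention, probability = 1/(1 + e^x) — note this is the *reversed*
logistic convention, so negative BMI coefficients inside x mean higher
BMI raises the TE probability. Internal fits use the standard convention
and are never silently mixed with the published one. One published
inconsistency is worth recording: the model-averaged per-0.05-CJWR fold
changes (0.37, 0.56, 0.3, 0.46 across strata) do not equal
exp(−0.05·b_CJWR) of the printed equations (0.63, 0.44, 0.71, 0.55).
These are plausibly posterior-averaged versus single-model coefficients;
the package treats the printed equations as the contract and does not
use the fold-change set as a reference.

## Numerical choices and problem sizes

* Geometry synthesis tolerance 1e-6 relative, maximum 50 iterations.
* Logistic convergence 1e-10 on the log-likelihood, 100 iterations;
  separation flagged when fitted probabilities pin at 0/1 or the
  information matrix is numerically singular (reciprocal condition
  below 1e-12).
* BIC weights are computed after subtracting the minimum BIC, so
  exponentiation never underflows to an all-zero weight vector.
* The test suite exercises the calibrated generator at the published
  group sizes (230 subjects per sex × age stratum) for classifier
  recovery, 2×10^4–10^5 pooled samples for moment-convergence checks,
  200 replicate fits for c-statistic averages and 100 replicates for
  LOOCV averages — sizes at which the Monte Carlo error of each
  averaged quantity is comfortably below the tolerance used to judge
  it.

## Limitations

* The landmark semantics are a documented convention; if the original
  operators' point assignments differed, metric values on real
  photographs would shift accordingly. The mapping is configurable at
  the `landmark_set` level.
* The generator reproduces first and second moments and the pooled
  BMI–metric correlations, but real faces have metric–metric
  dependence, non-Gaussian tails and measurement error that it does not
  model. Passing recovery tests therefore validates the statistical
  machinery, not the biology.
* Exact published regression coefficients, ANOVA p-values and AUCs from
  the original cohort are not reproducible without the original data;
  the package pins the exactly recomputable quantities (Fisher-z
  comparisons, equation identities) and recovers the rest in
  distribution via the calibrated generator.
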