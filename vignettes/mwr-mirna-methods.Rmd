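---
title: "Methods: bilateral MWR thermogram scoring and miRNA panel risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral MWR thermogram scoring and miRNA panel risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwrisk)
```

## The measurement model

One examination records 44 temperatures in degrees Celsius: at points 0-9
of each breast, an infrared reading of the skin (`ir`) and a passive
microwave reading of the internal tissue (`mw`), plus two body reference
points T1/T2 on both channels. `mwrisk` stores these as a `thermogram`
and partitions them into six named groups (right/left/reference, per
channel) before any scoring. Temperatures are kept as exact doubles
throughout scoring; rounding to 0.1 degC happens only at display time.
Scoring refuses incomplete examinations — there is no imputation, because
a missing point would silently bias every maximum-based statistic below.
The plausibility window (default 20-45 degC) is a configurable sanity
screen, wide enough for any in-vivo surface or core reading.

## Bilateral statistics

The physiological premise: a proliferative focus is warmer than the
surrounding gland and breaks the left-right symmetry of the temperature
field. Two statistics capture this.

**Focal heating, Qmax.** Pool the 20 breast temperatures of a channel
(reference points excluded — they track the body, not the gland), and
take `max - mean`; Qmax is the larger of the two channels' values. It is
translation-invariant (a warm day shifts max and mean together) and
non-negative by construction.

**Asymmetry, k_int / k_skin / R.** Per channel, the largest absolute
left-right difference over the ten symmetric point pairs, with the argmax
point recorded. When both channels peak at the same point — the typical
picture over a single focus — R is their sum. When they peak at different
points, the larger coefficient is kept and the *other* sensor's
difference at that same point is added, so R always combines evidence
from both channels at one location. Ties are deterministic: argmax ties
break to the lowest point index, and a `k_int == k_skin` tie between
channels breaks toward the internal channel (the microwave reading is the
deeper, more specific signal).

The printed formulations of the asymmetry coefficients are left-minus-
right maxima; the package defaults to absolute differences so a
right-sided focus scores identically to a left-sided one (breast swap is
an exact invariance of the default scoring, enforced by tests). The
signed variant remains available via `sign_convention = "signed"` for
sensitivity analyses.

**Classification.** `Qmax > 2.0` and `R > 2.5` (strictly) suggest
malignancy; both strictly below suggest a benign process. The thresholds
define only strict regimes, so exact equality — and any one-sided
exceedance — is reported `ambiguous` rather than silently absorbed into
either class.

One pooled-mean formulation in the source material mixes channels for
the internal mean; the package averages both breasts' internal
temperatures, mirroring the skin-channel mean, which is the only reading
consistent with "average internal temperature of the breast tissue".

## The feature space

For classification the package exposes a fixed 74-dimensional vector:
per-point internal gradients `T_mw - T_ir` for each breast (a
near-surface focus locally *reduces* the gradient), signed left-right
asymmetry vectors per channel (signed, so a model can learn sidedness),
then min/max/mean/range aggregates of those four vectors and of the four
raw breast groups — the range ("oscillation") of a gland's skin
temperatures captures spread, the max captures hot areas — and finally
Qmax and R. The exact aggregate list is a versioned package choice (the
underlying feature families are described qualitatively in the source
material; the full list is not recoverable), declared in
`default_config()` and `feature_names()`. Reference points are excluded
by default and can be appended with `include_reference = TRUE`.

## The stand-in risk classifier

The production-scale classifier behind this screening program was a
weight-agnostic neural network tuned by an evolutionary strategy on a
private database of 4377 low-risk and 535 high-risk patients; neither
the architecture search nor the database is reproducible at desk scale,
and re-implementing that cited machinery is out of scope here. `mwrisk`
instead ships a deliberately small, fully reproducible stand-in:
ridge-regularized logistic regression (`glmnet`, fixed `lambda = 0.01`
for determinism — no cross-validated lambda, which would introduce
fold-randomness) or a single-hidden-layer perceptron (`nnet`, 5 hidden
units, `decay = 0.01`, seeded initialization). Features are standardized
with training-set statistics; the roughly 8:1 class imbalance is handled
by inverse-frequency observation weights; a seeded stratified 80/20
split yields the held-out F1/precision/recall stored in `training_meta`.
Models serialize to JSON (coefficients, or the MLP weight vector plus
its layer sizes) and predict identically after a round-trip; the forward
pass is reimplemented from the stored weights so a serialized model has
no runtime dependency on the fitting package.

The classifier's acceptance property — held-out F1 at or above 0.9 on
the default 560-patient synthetic cohort, averaged over 5 seeds — is a
property of the *generator* being learnable, an analog of (not a
reproduction of) the production model's cross-validated 0.933.

## The synthetic generator

No raw temperatures or cohort data are published, so the generator
encodes the *conceptual* high-risk signatures: skin temperature spread
above 2 degC, an area of significantly elevated temperature, a reduced
skin-internal gradient over it, and high inter-breast asymmetry at
symmetric points.

* Healthy profile: i.i.d. Gaussian temperatures per point, skin around
  31.5 degC, internal around 34.5 degC, sd 0.25 degC. These baselines
  are invented stand-ins placed mid-physiological-range; with them the
  expected skin range of 10 draws is about 0.8 degC (below the 2 degC
  signature) and both asymmetry coefficients stay far below threshold.
* High-risk profile: the same field plus a focus — `focus_delta_int`
  (default 3.0 degC) added to the internal channel over the focus point
  and its ring neighbors (up to 3 points), and `focus_delta_int -
  focus_gradient_reduction` (default 3.0 - 1.0 = 2.0 degC) to the skin
  above it. The gradient reduction models the shallow-tumor picture
  (and, crudely, partial capsule masking); it is an additive offset, not
  a physics simulation. Focus point and side are drawn uniformly when
  unspecified.

Calibration under the published thresholds is a tested regression
surface: healthy draws classify benign in at least 95% of 200 seeded
examinations, high-risk draws escape benign in at least 90%. Panel
concentrations are log-normal around the published normal-range
geometric means; a high-risk draw displaces each marker by its
clinically observed pathology/norm fold along the marker's risk
direction. What the generator does *not* emulate: spatial correlation
between neighboring points, bilateral physiological asymmetries
(vasculature, nipple warming), device noise structure, demographic
covariates, or any correlation between a patient's thermogram and panel.
Passing tests therefore demonstrate the pipeline's correctness and the
profiles' separability — not clinical performance on real data.

## The miRNA oncopanel

Eight circulating markers, each with a risk direction: miR-155,
miR-199a-3p, miR-222-3p and miR-21-5p are oncogenic (up is risk);
let-7a-5p, miR-196a-2, miR-106a-5p and miR-137 are protective (down is
risk). The fold change `pathology / norm` is computed exactly and
reported rounded half-up to one decimal (clinical reporting convention;
banker's rounding would turn 0.25 into 0.2). Scoring converts the fold
into a magnitude of change *along the risk direction* — the fold itself
for oncogenic markers, its reciprocal for protective ones, and 1 when
the change points the protective way — then bands it: below 1.5 scores
0, 1.5-2 scores 1 (slight), 2-5 scores 2 (moderate), 5 and above scores
3 (significant). The printed bands overlap at their boundaries; the
package uses half-open bands with boundaries assigned upward, exposed in
configuration. The direction-aware reading is the only one consistent
with panels that flag five-fold *drops* of protective markers as
increased risk.

Panels arriving as categorical expression labels ("Norm", "Slight
increase", "Pronounced increase—3", ...) are scored by label directly.
When a row carries both a label and concentrations the label wins — it
is the clinician's integrated call, and published label tables are known
to disagree with the corresponding concentration tables (markers with
folds of 7.1 and 5.0 labeled "Norm"); the package implements both paths
and does not attempt to reconcile that conflict. Marker names are
normalized across the spelling variants found in the wild (`Hsa-`,
`Has-`, `Micro-`, case); the table spelling "miR-196a-3p" is treated as
a variant of miR-199a-3p, since the eight-marker panel definition lists
miR-199a-3p and carries miR-196a-2 separately.

The per-marker scores sum to the panel risk factor (0-24). The low/high
cutoff defaults to 5: the published anchors are a sum of 3 "typical of
low risk" and 7 "typical of high risk", so the cutoff is interpolated
between them and exposed in configuration.

## Fusing the three readings

The `assess()` decision table codifies the clinical workflow narrative
rather than any stated formal rule, and is deliberately simple and
total:

| MWR class | classifier | panel | overall |
|---|---|---|---|
| malignant_suspected | any | high or absent | high_risk_refer |
| malignant_suspected | any | low | discordant_review |
| ambiguous | any | high | high_risk_refer |
| ambiguous | any | low or absent | elevated_recommend_mirna |
| benign | high | high | high_risk_refer |
| benign | high | absent | elevated_recommend_mirna |
| benign | high | low | benign_monitor (follow-up note) |
| benign | low or absent | high | elevated_recommend_mirna |
| benign | low or absent | low or absent | benign_monitor |

Two rows (benign + classifier high + panel high; benign + classifier
low + panel high) are not pinned down by the narrative; they are filled
so that adding a high panel category never downgrades the overall level
(a tested monotonicity invariant). The rationale trace records every
threshold comparison for auditability; the ">85% probability" language
attached to a malignant MWR picture is echoed as text only and never
computed — no calibration data exist for it.

## Numerical and scale choices

Comparisons inside scoring use exact floating arithmetic; no epsilon is
applied at the decision thresholds because the ambiguous class already
absorbs the boundary. Test and acceptance problem sizes — 1,000 random
examinations for the R-statistic oracle check, 200 seeded draws per
calibration rate, and 5 seeds of the 560-patient cohort for the
classifier property — are the package's chosen trade-off between
statistical resolution and a test suite that runs in well under a
minute; all are driven by explicit seeds.

## Known limitations

The decision thresholds and band edges are taken as given, not
re-estimated; the synthetic cohorts cannot validate clinical
sensitivity/specificity; the fusion table is a codified narrative, not a
learned policy; and the panel's concentration-to-label conflict in the
published example means the two scoring paths can legitimately disagree
on real exports — the package surfaces both rather than averaging them.
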