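---
title: "Methods: MRI scoring and diagnostic evaluation for pernicious placenta previa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRI scoring and diagnostic evaluation for pernicious placenta previa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pppscore)
```

## The clinical problem and the score

Pernicious placenta previa (PPP) — placenta previa overlying a previous
cesarean scar — is the setting in which placenta accreta spectrum (PAS)
disorders are most dangerous. PAS is graded by the depth of villous
invasion: placental adhesion (PA, superficial myometrium), placental
implantation (PI, deep myometrium) and placenta percreta (PP, through the
serosa, sometimes into the bladder). Distinguishing these grades before
cesarean delivery drives blood-product preparation, surgical staffing and
hysterectomy planning.

The score implemented here combines ten T2-weighted MRI signs (placental
position, uterine bulge, parenchymal heterogeneity, T2-dark intraplacental
bands, abnormal intraplacental vascularity, abnormal placental-bed
vascularization, loss of the T2-hypointense interface, bladder-wall
interruption, penetrating implantation, myometrial thinning/interruption)
with one clinical item, the number of previous cesarean deliveries. Each
MRI item scores 0/1/2 by severity; the cesarean item scores 1 or 2 because
a cesarean history is an inclusion criterion, so 0 is not representable.
The total score is the plain sum, range 1–22. We deliberately reject, and
never impute, cohorts with missing or out-of-range items: the score is
defined only on complete 11-item readings.

An open reading-protocol question is whether "suspected" (1-point) findings
should ever be collapsed into definite (2-point) findings. We keep the
three-level coding throughout: collapsing is a strictly coarser reading
that can only lose discrimination, and a user who wants it can recode the
item columns before scoring.

## Dichotomies, ROC and cutoff selection

Because PAS severity is ordinal, the diagnostic question is asked three
ways: A, no-PAS vs any PAS; B, no-PAS/PA vs PI/PP; C, PP vs the rest.
For each dichotomy we build the empirical ROC curve (one operating point
per distinct score, positivity rule *score ≥ cutoff*) and take the area
under it by the trapezoidal rule, which on discrete data equals the
tie-corrected Mann–Whitney concordance — a property the test suite checks
against a brute-force pairwise oracle.

Cutoffs are chosen by maximizing the Youden index over the midpoints
between consecutive distinct observed scores, plus one candidate below the
minimum and one above the maximum. On integer scores this yields
half-integer boundaries (e.g. 5.5 / 11.5 / 15.5), matching how such
boundary values are conventionally reported and how pROC places
thresholds. Ties in the Youden index are broken toward the *smaller*
cutoff, i.e. toward higher sensitivity: in a screening context a missed
deep invasion is costlier than a false alarm. Because candidate midpoints
move under monotone rescaling of the scores while the induced
classifications do not, the selected confusion table is invariant to
strictly monotone transforms — also property-tested.

The AUC confidence interval uses a stratified percentile bootstrap
(resampling within each label class, so no resample is one-class), default
2000 replicates, default seed 20220811, 2.5/97.5 percentiles. A bootstrap
was chosen over the DeLong interval because it makes no asymptotic
normality assumption at these group sizes (26–77 per class); either would
be defensible. The bootstrap is bit-reproducible under a fixed seed and
restores the caller's RNG state.

## The metric suite and reconstruction from printed rates

From a 2×2 confusion table we report sensitivity, specificity, PPV, NPV,
Youden index (= sens + spec − 1 exactly), likelihood ratios
LR+ = sens/(1 − spec) and LR− = (1 − sens)/spec, accuracy, and unweighted
Cohen's kappa computed directly from observed and chance agreement.
Undefined ratios (0/0) are reported as `NA`, never silently 0 or 1, and
LR+ is `+Inf` when specificity is 1 with nonzero sensitivity. Reporting
rounds half-away-from-zero at 3 decimals (the convention of clinical
tables); all internal computation is full precision.

Published diagnostic tables usually print rates, not counts.
`reconstruct_confusion()` inverts printed sensitivity/specificity against
known group margins by nearest-integer rounding, which recovers the unique
integer table consistent with the printed rates whenever one exists; a
printed rate farther than half a 3-dp print unit from every achievable
count ratio triggers a warning. Kappas recomputed from such reconstructed
tables can differ from originally printed kappas by up to ~0.01 because
the upstream software rounded at a different stage; the package treats
agreement within ±0.01 as the attainable fidelity for that statistic.

## The synthetic cohort generator

No patient-level data are distributed, so the generator exists to give
every downstream stage a realistic, fully specified input. It emulates the
published per-class structure: class sizes 30/77/60/26 (193 patients),
per-class total-score summaries (means 5.6/9.4/12.8/15.5, SDs
2.5/2.9/2.5/3.5, ranges 3–13/5–19/6–20/9–21) and per-class blood-loss
medians and ranges 225 (100–3700), 600 (200–6000), 1500 (300–7000),
3000 (400–6300) ml.

**Items.** Each item is drawn independently from a class-conditional
probability triplet; the draw is rejected until the total lies inside the
class's published score range. Item-level independence is a deliberate
simplification: only total-score summaries are published, and any
correlation structure would be invented. The cesarean-item probabilities
are not free parameters — they are the published once/twice-or-more counts
per class. The ten MRI triplets per class were calibrated once by Monte
Carlo so the post-rejection total-score mean sits within ±0.5 points of
the published mean. A structural note on spread: 11 independent items
bounded in {0,1,2} (cesarean in {1,2}) cap the total-score SD at
√10.25 ≈ 3.2 before truncation, so the percreta class's published SD of
3.5 is not attainable under independence; its calibrated SD (≈2.75 after
range truncation) is the ceiling, and consumers should not expect
synthetic percreta scores to be as dispersed as the real ones.

**Blood loss.** The published medians sit far from the midpoint of their
log-ranges (e.g. 225 within 100–3700), so a single symmetric log-normal
cannot honor the median and span the range at once. We use a two-piece
(split) log-normal: with probability ½ the draw falls on each side of the
median, each side a half log-normal whose 99.5th percentile is the
corresponding published bound, with rejection beyond it. The median is
exact by construction, the range is hard, and empirical medians recover
the configured values to Monte-Carlo error (checked at ±5%).

**Demographics.** Age and neonatal weight are Gaussian with the published
class means/SDs; gestational age uses the same split mechanism around the
published class medians, clipped to the 28–39-week inclusion window;
previa type is Bernoulli with the published complete-previa proportions.
These columns exist so the ANOVA/exact-test stages have realistic inputs;
no between-column dependence is modelled, and blood loss is independent of
the score given class (no within-class association is published).

**What passing tests show.** Calibration tests demonstrate that the
generator reproduces the published *summaries*; they cannot demonstrate
that the pipeline would reproduce the published per-patient ROC results
(AUCs 0.920/0.885/0.855 and boundaries 5.5/11.5/15.5), which depend on the
unavailable raw data and on item correlations the generator does not
model. Those printed values are therefore used only as reconstruction
inputs, never as simulation targets.

**Determinism and problem sizes.** Every generator entry point either
takes the config's seed (`generate_cohort()`) or uses the caller's RNG
state (`sample_features()`, `sample_blood_loss()`); the default seed is
20220811. Calibration checks in the tests use 2,000–10,000 patients per
class and 50 replicate cohorts of 193 — sizes at which Monte-Carlo error
is a fraction of each tolerance while the whole suite stays fast. A
replicate-level check that each 193-patient cohort's class means land
within ±0.6 points would be mis-specified at these sizes (for the
percreta class, n = 26 with SD ≈ 2.8 gives a per-run standard error of
≈0.55, so even a perfectly calibrated generator lands outside ±0.6 almost
30% of the time); the suite instead checks unbiasedness of the pooled
means across 50 seeds and recovery at large n.

## Group comparisons

Blood loss across the four classes uses the tie-corrected Kruskal–Wallis
test; pairwise contrasts use the Wilcoxon rank-sum normal approximation
with tie and continuity corrections (exact enumeration adds nothing at
group sizes 26–77) with Bonferroni adjustment by default — configurable,
including `"none"`, since published pairwise stars rarely name an
adjustment. Continuous demographics use classical equal-variance one-way
ANOVA; the degenerate all-equal-within case is reported explicitly
(F = ∞, p = 0 for separated means; p = 1 when nothing varies).
Categorical class-by-category tables use the Freeman–Halton exact test
(the r×c generalization of Fisher's test, by exact network enumeration),
with all-zero rows/columns dropped first so empty categories cannot change
the result, and an explicit enumeration bound (total ≤ 500, ≤ 16 cells)
beyond which the test refuses rather than approximates. P-values below
1e-16 are formatted as "<1e-16" rather than printed with spurious digits.

## Numerical choices and limitations

* Half-integer cutoff candidates make the ≥ vs > positivity choice
  immaterial on integer scores; we use ≥.
* Rounding for display is half-away-from-zero at 3 dp; tests compare at
  that rounding where printed values are the reference, at full precision
  everywhere else.
* Rejection sampling enforces published score ranges rather than
  reshaping the distribution — the simplest mechanism honoring both the
  moments and the bounds; an infeasible window raises an error after a
  bounded attempt count instead of looping.
* The generator cannot (and does not try to) emulate reader disagreement,
  item correlations, or the association between score and blood loss
  within a class.
* Exact reproduction of published kappas and AUCs is out of reach without
  the per-patient data; the package's fidelity claims are limited to what
  the reconstruction arithmetic and the calibration tolerances stated
  above can support.
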