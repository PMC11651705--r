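---
title: "Biomarker-guided treatment assignment and trial simulation for acromegaly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker-guided treatment assignment and trial simulation for acromegaly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acropred)
```

## The problem

Medical therapy of acromegaly conventionally starts every patient on a
first-generation somatostatin receptor ligand (fgSRL: octreotide LAR or
lanreotide) and escalates by trial and error, although fgSRLs normalize
IGF-1 in only about half of patients. Several pretreatment biomarkers
predict fgSRL response: strong GH suppression in the short acute octreotide
test (sAOT), a T2-hypointense tumor signal on MRI, and tumor E-cadherin
immunopositivity in operated patients. `acropred` implements a decision
rule that turns those biomarkers into a first-line assignment — fgSRL
monotherapy, pegvisomant monotherapy, or their combination — together with
the machinery needed to study such a rule end to end: a dose-titration
state machine on the 3-month visit grid, a synthetic cohort generator that
emulates a two-arm trial population, and the endpoint analyses (control
proportions with Fisher's exact test, Kaplan–Meier and Cox time-to-control,
ROC, counterfactual policy evaluation, sample size).

## The decision rule

All GH values are first harmonized onto a common reference immunoassay
scale by registered affine calibrations (`harmonize_gh()`); the sAOT
cutoffs are defined on that scale only.

The sAOT classifier (`classify_saot()`) uses GH measured 2 h after 100 µg
subcutaneous octreotide (GH~2h~) and the percent decrease from baseline
(%∇GH):

* GH~2h~ < 2.7 ng/mL → **responder** (GH~2h~ prevails over a discordant
  drop);
* GH~2h~ ≥ 2.7 and drop > 50% → **partial responder**;
* GH~2h~ ≥ 2.7 and drop ≤ 50% → **non-responder**.

`assign_personalized()` then maps biomarkers to first-line therapy. For
treatment-naive patients: responders receive fgSRL monotherapy at medium
dose; partial responders with a T2-hypointense tumor receive fgSRLs plus
pegvisomant; all other predicted non-responders receive pegvisomant
monotherapy, unless MRI shows cavernous sinus invasion, in which case the
combination is used so that a tumor-directed drug is retained. For
postsurgical patients the rule is driven by E-cadherin (positive → fgSRL
monotherapy, negative → pegvisomant monotherapy); when tissue was
insufficient for immunostaining, the presurgical branch applies.
`assign_standard()` encodes the guideline comparator: fgSRLs for everyone,
with other drugs only after demonstrated failure.

Two cells of the rule are not fully pinned down by its published
description and were fixed here as package design choices, recorded in each
assignment's `rationale` trace:

* a partial responder *without* T2 hypointensity is treated as a predicted
  non-responder (the hypointense signal is stated as a requirement for the
  combination), hence pegvisomant monotherapy barring sinus invasion;
* the sinus-invasion override (combination instead of pegvisomant alone) is
  applied to every naive predicted non-responder, including that inferred
  partial-responder cell, since the stated motivation — keep a
  tumor-directed component when the tumor invades the cavernous sinus —
  applies equally there.

Boundary conventions: GH~2h~ exactly 2.7 ng/mL goes to the percent-drop
branch, and a drop of exactly 50% to the non-responder class; cutoff
exactness favors the cautious path.

## Titration

`titrate()` advances one scheduled visit at a time (90-day grid, 365-day
horizon). IGF1-SDS at or below the control threshold (2.0 SDS by default)
freezes the state and records the event day. Above the titration trigger
(2.5 SDS) doses escalate in order: fgSRL medium → maximal; then the
personalized arm adds or up-titrates pegvisomant in 0.5 mg/kg/week steps to
a 1.5 mg/kg/week ceiling, while the standard arm waits six months at
maximal fgSRL dose before escalating modality (default to the
combination — a configurable policy hook, since the comparator protocol
leaves the choice to clinical judgment). Cabergoline 1 mg/week may join
fgSRLs for minor IGF-1 elevations (2.5–3 SDS); it is an optional flag with
adoption probability 0 by default so the engine stays deterministic.
Requests beyond the pegvisomant ceiling set a flag rather than erroring.

## The synthetic cohort generator

`generate_cohort()` emulates the population of a 68-patient two-arm trial
(32 personalized, 36 standard by default). What it reproduces:

* **Marginals.** Arm-specific baselines: age (truncated normal 52 ± 15 /
  56 ± 14 y on 18–80), sex ratio, BMI, largest tumor diameter (17 ± 8 /
  16 ± 8 mm, truncated), Knosp grade, T2-hypointense fraction (56%/33%),
  postsurgical fraction (28%/28%). Skewed hormone variables — baseline GH,
  GH~2h~, IGF1-SDS — follow a *two-piece log-normal* matched exactly to the
  configured median and both quartiles (e.g. GH~2h~ 1.3 (0.3–2.2) vs 1.6
  (0.4–3.3) ng/mL), because the published summaries have asymmetric IQRs on
  the log scale that a single log-normal cannot match.
* **Coupling.** A Gaussian copula links age, tumor size, baseline GH,
  GH~2h~ and IGF1-SDS; the latent GH~2h~–size correlation of 0.58 yields a
  Spearman rank correlation near 0.56, matching the observed association of
  sAOT GH~2h~ with tumor diameter and volume, and age–IGF1-SDS is set to
  −0.43.
* **Response truth.** Each patient's probability of control under
  fgSRL-only therapy is keyed on the sAOT *response stratum*: concordant
  responders (GH~2h~ < 2.7 **and** drop > 50%) 0.87, discordant responders
  0.05, partial responders 0.05, non-responders 0.02; pegvisomant-containing
  regimens control with probability 0.72 regardless of stratum. The
  concordance split extends the plain class-conditional coupling: it is
  what makes the two arms' observed control rates (≈78% personalized vs
  ≈53% standard) jointly attainable, since the exact Table-of-baselines
  margins put 82%/69% of the arms below the 2.7 ng/mL cutoff — a single
  shared responder probability would leave the standard arm far above 53%.
  The numbers solve the two-arm system analytically at the generator's own
  stratum fractions and are deliberate calibration, not estimates; all are
  config keys. Second-line rescue (control after modality escalation of a
  first-line failure) defaults to probability 0, reflecting how rarely late
  escalation achieved control within the follow-up window; it is likewise
  configurable.
* **Trajectories.** Controlled patients draw a time-to-control
  (fgSRL: 150 ± 94 / 158 ± 88 days per arm; pegvisomant-containing: 260 ±
  90 days) snapped *up* to the next scheduled visit; their IGF1-SDS
  trajectory stays above the control threshold before the event visit and
  below it from the event on, so `classify_outcome()` recovers the
  generating truth exactly. Uncontrolled patients decline toward a plateau
  above the threshold, about half of them by more than 50% (partial
  responders).
* **Assay provenance.** Each record carries a center assay identifier and
  raw-scale GH values obtained by inverting the calibration (restricted to
  assays whose intercept keeps the raw value non-negative), so
  harmonization is exercised on read-back.
* **Missing tissue.** One third of postsurgical records lose their
  E-cadherin result (`inject_missingness()`), sending personalized-arm
  patients to the presurgical fallback.

What it does **not** emulate: dose–response feedback (the titration
machinery does the bookkeeping, but the drawn truth — not the achieved
dose — determines control), adverse events and exclusions, center effects,
comorbidity co-occurrence (flags would be independent), and measurement
error in IGF1-SDS beyond trajectory noise. Passing tests therefore
demonstrate the internal consistency of the rule, the generator and the
analyses — not clinical performance on real patients.

## Endpoint analysis

* `fisher_exact()` — two-sided exact test on the arm × control table
  (p = 1 with a flag on a zero margin).
* `km_curve()` / `cox_hr()` — product-limit curve of remaining
  uncontrolled, and the arm hazard ratio adjusted for age and sex from a
  proportional-hazards fit. Ties are handled by the Breslow approximation:
  event times sit on a coarse 90-day grid, so ties are pervasive; this is
  the simplest defensible choice and a documented limitation.
* `roc_auc()` — rank-based concordance AUC with lower GH~2h~ oriented
  toward control, and a seeded bootstrap percentile interval.
* `counterfactual_control_arm()` — applies the personalized rule to
  standard-arm patients: where it would also pick fgSRL monotherapy the
  observed outcome carries over; where it would pick a
  pegvisomant-containing regimen the predicted outcome is the configured
  efficacy (expectation mode) or a seeded draw. A prediction is *valid*
  when the predicted class agrees with the observed fgSRL control status;
  *overtreated* patients would have received pegvisomant although fgSRLs
  alone controlled them.
* `sample_size_two_proportions()` / `inflate_recruitment()` — the standard
  normal-approximation two-proportion design formula plus loss-to-follow-up
  inflation (`ceiling(n_min * (1 + loss))`), e.g. a design minimum of 66
  inflated by 15% gives a recruitment target of 76.

Numerical conventions: never-controlled patients are censored at the
365-day horizon and enter time-to-control summaries at 365; the control
threshold defaults to 2.0 SDS (the conventional normality bound — distinct
from the 2.5 SDS titration trigger; both are config keys); quantiles of
time-to-control use the default type-7 definition.

## Reproducibility and problem sizes

All stochastic steps take explicit seeds; `run_pipeline()` derives
per-stage seeds from one root seed, and a fixed seed yields byte-identical
cohort files and reports. The package's own validation uses problem sizes
chosen to keep Monte-Carlo error well inside the assertion bands: marginal
and coupling recovery at 10,000 patients per arm, arm-rate calibration at
1,000 per arm (binomial standard error ≈ 1.3–1.6 points against ±3-point
bands), Cox coverage over 100 replicates at 500 per arm, and exhaustive
enumeration for the exact test (all 2×2 tables with total ≤ 24) and the
decision table (every biomarker state).

```{r example}
run <- run_pipeline(cohort_config(), seed = 42)
run$result
```

## Known limitations

* The IGF-1 reference table shipped with the package is synthetic (the
  clinical SDS calculator's internals are not public); any table with the
  same columns can be substituted.
* The published Passing–Bablok calibration coefficients are configuration,
  not re-derived from paired measurements.
* The hazard ratio implied by the generator's time-to-control model is
  milder than headline trial reports, because the two arms share most of
  their event-time distribution and differ mainly in the controlled
  fraction; the generator calibrates proportions, not the full joint
  time-to-event law.
* Cabergoline and surgery referral are recorded as flags, not modeled as
  outcome-modifying interventions; pasireotide is out of scope.
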