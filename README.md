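# acropred

Biomarker-guided treatment assignment and trial simulation for acromegaly.

Acromegaly — chronic growth-hormone excess from a pituitary adenoma — is
conventionally treated by starting every patient on a first-generation
somatostatin receptor ligand (fgSRL) and escalating by trial and error,
although fgSRLs control only about half of patients. Pretreatment
biomarkers predict fgSRL response: GH suppression in the short acute
octreotide test (sAOT), T2-hypointense tumor signal on MRI, and tumor
E-cadherin immunopositivity after surgery. `acropred` is for
endocrinologists and trial statisticians who want to study a decision rule
built on those biomarkers: it implements the rule itself, the dose
titration that follows it, a synthetic two-arm cohort generator with the
statistical structure of such a trial population, and the endpoint
analyses.

## The rule

GH values are harmonized to a reference immunoassay by registered affine
calibrations (`harmonized = slope × raw + intercept`); the sAOT cutoffs
live on that scale. With GH<sub>2h</sub> the GH value 2 h after 100 µg
subcutaneous octreotide and %∇GH the percent decrease from baseline:

| sAOT result | Extra condition | First-line therapy |
|---|---|---|
| GH<sub>2h</sub> < 2.7 ng/mL (responder) | — | fgSRL monotherapy |
| GH<sub>2h</sub> ≥ 2.7, drop > 50% (partial) | T2-hypointense | fgSRL + pegvisomant |
| predicted non-responder (otherwise) | cavernous sinus invasion | fgSRL + pegvisomant |
| predicted non-responder (otherwise) | no invasion | pegvisomant monotherapy |

Postsurgical patients are assigned by E-cadherin instead (positive →
fgSRL, negative → pegvisomant; tissue unavailable → the presurgical rules
above). The comparator `assign_standard()` gives everyone fgSRLs first.
Doses titrate every 3 months while IGF1-SDS stays above 2.5, and hormonal
control is declared when IGF1-SDS normalizes (≤ 2.0 SDS by default).

## Worked example

```r
library(acropred)

classify_saot(10, 4)
#> sAOT: basal 10.00 ng/mL, 2h 4.00 ng/mL (drop 60.0%) -> PARTIAL_RESPONDER

p <- patient_record("P1", "PERSONALIZED", "NAIVE", age = 48, sex = "M",
                    bmi = 28, baseline_gh = 10, baseline_igf1_sds = 6.5,
                    saot = classify_saot(10, 4),
                    geometry = tumor_geometry(18, 15, 13, "HYPOINTENSE", 2L))
assign_personalized(p)
#> FGSRL_PLUS_PEGV (fgSRL medium, PEGV 0.5 mg/kg/wk)
#>   rules: naive_branch -> saot_partial+T2_hypointense->combo

run <- run_pipeline(cohort_config(), seed = 42)
run$result
#> PERSONALIZED n= 32 controlled= 22 (69%)  time-to-control median 270 (180-365) d
#> STANDARD     n= 36 controlled= 17 (47%)  time-to-control median 365 (180-365) d
#> Fisher exact (controlled x arm): p = 0.08949
#> Cox HR (personalized vs standard, age/sex-adjusted): 1.41 (0.71-2.79)
#> GH_2h AUC for control (naive patients): 78.1% (64.2%-89.8%)
```

The pipeline generated a 68-patient cohort (32 personalized, 36 standard),
assigned first-line therapy per arm, titrated doses over the 90/180/270/365
day visits, and classified outcomes. In this draw 69% of the personalized
arm reached hormonal control against 47% of the standard arm; at this
sample size the exact test does not reach 0.05 (p = 0.089), the adjusted
hazard ratio of 1.41 favors the personalized arm, and GH<sub>2h</sub>
discriminates eventual control among naive patients with an AUC of 78%. At
the generator's calibration the long-run arm control rates sit near 78%
and 53%; single trial-sized draws scatter around them, which is precisely
the sampling behavior the simulator is for.

The methods vignette
(`vignettes/personalized-acromegaly-trial.Rmd`) documents the model,
the calibration choices and their rationale, and what the synthetic cohort
does and does not emulate.

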