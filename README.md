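# ddacc — deformable dose accumulation for adaptive prostate radiotherapy

`ddacc` compares three prostate radiotherapy strategies by the total dose
they actually deliver over a fractionated course (20 × 3 Gy):

* **refPlan** — the static pre-treatment reference plan (clinical intent);
* **conv-IGRT** — conventional image guidance: one plan, corrected daily
  by a translation-only couch shift found by rigid registration;
* **OA-MRgRT** — online-adaptive MR-guided radiotherapy: the plan is
  re-optimized on each day's anatomy.

The comparison uses **deformable dose accumulation (DDA)**: each
fraction's anatomy is registered to the first fraction, the fraction dose
is mapped along the resulting displacement field by direct dose mapping
(trilinear sampling at the displaced point, no energy rescaling), and the
mapped doses are summed. Accumulated distributions are evaluated by
dose–volume parameters (CTV D50%, D98%; rectum/bladder/urethra Dmax;
rectum and bladder V56Gy, from DVHs at 0.01 Gy bins) against the planning
objectives

    CTV D50% >= 60 Gy, CTV D98% >= 57 Gy, OAR Dmax <= 61.0 Gy,
    rectum V56Gy < 13.5 %, bladder V56Gy < 18.0 %

and by Lyman–Kutcher–Burman NTCP, with voxelwise EQD2
(`D·(d + α/β)/(2 + α/β)`, uniform fractionation), the gEUD power mean
`(mean EQD2^(1/n))^n`, and the logistic

    NTCP = 1 / (1 + exp(-(gEUD - TD50) / (m·TD50)))

for bladder incontinence G2+ (α/β = 1.5 Gy, TD50 = 108.9 Gy, m = 0.24,
n = 0.02) and rectum late toxicity G2+ (α/β = 3.0 Gy, TD50 = 80.8 Gy,
m = 0.15, n = 0.12). Arms are compared pairwise with exact two-sided
Wilcoxon signed-rank tests, Bonferroni correction (k = 3), and paired
Cohen's d.

Because the underlying clinical images are not public, the package ships
a seeded **synthetic pelvis cohort generator** (10 patients × 20
fractions, 2 mm grid) with ground-truth per-fraction deformation fields —
prostate drift, bladder filling, rectum volume change — so that every
pipeline stage (registration, dose warping, accumulation, DVH/NTCP,
statistics) can be validated against a known answer. See the methods
vignette (`vignettes/dose-accumulation-methods.Rmd`) for the models,
parameters and design decisions.

Intended users: medical-physics researchers prototyping or validating
dose-accumulation workflows, and anyone needing a self-contained, tested
DDA reference implementation with an honest synthetic ground truth.

## Worked example

One patient at the study conditions (2 mm grid, 20 × 3 Gy; about 90 s):

```r
library(ddacc)

p <- phantom_params()
case <- generate_patient_case(p, patient_seed = 7L)

# reference plan meets every planning objective by construction
chk <- check_objectives(extract_dvps(case$ref_dose, case$ref_structures))
chk[, c("objective", "value", "limit", "pass")]
#>      objective      value limit pass
#> 1      CTV_D50 61.7505357  60.0 TRUE
#> 2      CTV_D98 60.5024901  57.0 TRUE
#> 3  rectum_Dmax 60.1139574  61.0 TRUE
#> 4 bladder_Dmax 60.5000000  61.0 TRUE
#> 5 urethra_Dmax 60.5000000  61.0 TRUE
#> 6   rectum_V56  0.6628003  13.5 TRUE
#> 7  bladder_V56  1.6184404  18.0 TRUE

# accumulate both adaptive arms into the fraction-1 frame using the
# phantom's ground-truth fields (the oracle path; method = "dir" runs the
# demons registration surrogate instead)
acc <- accumulate_case(case, method = "gt")
acc$oa
#> <accumulated_dose:OA-MRgRT> frame fraction1, max 63.34 Gy

s1 <- case$fractions[[1]]$structures
dose_at_volume(compute_dvh(acc$oa$dose, s1$CTV), 98)    # CTV D98, Gy
#> [1] 60.55173
dose_at_volume(compute_dvh(acc$conv$dose, s1$CTV), 98)
#> [1] 60.53507
dmax(acc$conv$dose, s1$rectum)                          # rectum Dmax, Gy
#> [1] 60.33782

# NTCP of the accumulated OA dose for the bladder endpoint
ntcp_from_dose(acc$oa$dose, s1$bladder, n_fractions = p$n_fractions,
               params = lkb_presets("bladder"))
#> <ntcp> bladder incontinence G2+: gEUD-EQD2 = 70.48 Gy, NTCP = 0.1869
```

The numbers mean: the synthetic reference plan covers the CTV (median
dose 61.8 Gy, near-minimum D98% 60.5 Gy) while every organ-at-risk
constraint holds; this patient's systematic posterior drift is small
(3.8 mm), so after accumulating the daily doses both strategies keep CTV
D98% above 57 Gy and the rectum below its maximum-dose limit, and the
accumulated bladder dose corresponds to a ~19 % modelled risk of
grade-2+ incontinence (the logistic is evaluated far below
TD50 = 108.9 Gy). Patients with larger drift violate the rectum
maximum-dose objective under conv-IGRT but not under daily re-planning.

The full cohort analysis and report:

```r
res <- run_cohort_analysis(phantom_params(), method = "gt")  # ~6 min
rep <- build_report(res$dvps, res$ntcp)
print(rep)          # medians (range), attainment %, NTCP summaries
write_report(rep, "report/")   # CSVs + plain-text summary
```

On the default cohort the report reproduces the qualitative clinical
finding: daily re-planning meets all organ-at-risk objectives in every
patient, the translation-only arm violates the rectum maximum-dose
objective in a subset of patients, and both maintain CTV D98% ≥ 57 Gy
everywhere.

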