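# iscr

Immunoscore-style scoring of tumor-infiltrating lymphocytes (TILs) in
early breast cancer, and the full association analysis against
pathological complete response (pCR) after neoadjuvant chemotherapy.

## What it does and for whom

Digital pathology can count CD3+ (total T cell) and CD8+ (cytotoxic
T cell) densities, in cells/mm², separately in the **center of the tumor
(CT)** and in a band around the **invasive margin (IM)**. The Immunoscore
for Clinical Research (ISCR) turns those four densities into a 0–4 score:
each density is dichotomized at a cohort-derived cut-off and the score is
the number of high marker–compartment pairs,

    ISCR = #{ k : x_k > θ_k },   k ∈ {CD3-CT, CD8-CT, CD3-IM, CD8-IM},

with tiers Low (0–1), Intermediate (2), High (3–4), a binary grouping
(0–2 vs 3–4), and a CT-only biopsy variant (0–2). Cut-offs θ_k are chosen
per marker–compartment by maximizing the Youden index
J = sensitivity + specificity − 1 on the ROC curve against pCR, with a
strict `density > θ` high call.

The package is aimed at biostatisticians and translational researchers
who want this pipeline as tested, scriptable code: compartment geometry
and density estimation from cell coordinates, ROC/Youden cut-off
derivation, scoring, and the association battery (Pearson chi-square,
Fisher exact by hypergeometric/Freeman–Halton enumeration, Mann–Whitney
U, odds ratios, PPV/NPV with exact Clopper–Pearson intervals, univariate
logistic regression by IRLS). Because the 103-patient reference cohort
was never deposited, the package ships its printed aggregate contingency
tables as fixtures (`reference_tables()`) and provides synthetic slide
and cohort generators with the same statistical structure, so every stage
is testable end to end.

## Worked example

pCR rates by ISCR tier, recomputed from the packaged reference tables:

```r
library(iscr)
fx <- reference_tables()
proportions_from_table(fx$tables$iscr_tier_pcr)
#>          group  n events   fraction percent
#> 1         High 36     25 0.69444444      69
#> 2 Intermediate  8      4 0.50000000      50
#> 3          Low 31      2 0.06451613       6
```

High-ISCR patients respond at 69%, low at 6% — the core association the
score is built to expose. The full pipeline on a synthetic cohort:

```r
co <- generate_cohort(synthetic_params(), seed = 7)
rep <- run_pipeline(co)
rep
#> ISCR report: 103 patients (75 with evaluable IM), pCR 49%
#>
#> Cut-offs (Youden):
#>      key threshold sensitivity specificity    auc n_used polarity_warning
#> 1 cd3_ct     878.6      0.8400      0.7170 0.8396    103            FALSE
#> 2 cd8_ct     259.4      0.8400      0.7170 0.8423    103            FALSE
#> 3 cd3_im     896.6      0.9412      0.6341 0.8042     75            FALSE
#> 4 cd8_im     682.7      0.6471      0.8780 0.8329     75            FALSE
#>
#> ISCR distribution (IM-present):
#>  score count percent
#>      0    19      25
#>      1    14      19
#>      2     8      11
#>      3    11      15
#>      4    23      31
#>
#> Binary ISCR (0-2 vs 3-4) logistic: OR 27.22 (95% CI 7.91-93.68), Wald p 1.61e-07
#> pCR by tier: Low 6%, Intermediate 50%, High 82%
```

Each marker gets its own Youden cut-off with the two denominators the
analysis tracks throughout (all 103 patients for CT, the 75 with an
evaluable margin for IM); the binary ISCR odds ratio is wide at n = 103,
as expected — `parameter_recovery_check(n = 2000)` shows the pipeline
concentrating around the programmed truth at larger n.

The methods vignette (`vignettes/iscr-methods.Rmd`) documents the model,
the conventions (strict cut-off calls, closed regions, tie-breaks,
rounding), the generator's calibration and its limitations.

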