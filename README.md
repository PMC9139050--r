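# neutroclust

Data-driven neutrophil-count phenotyping for non-cystic-fibrosis
bronchiectasis cohorts.

Blood neutrophils drive much of the tissue damage in bronchiectasis, and a
single blood count is one of the cheapest candidate biomarkers for splitting
a cohort into clinically distinct phenotypes. `neutroclust` implements the
full analysis for researchers working with patient-registry tables: it
discovers a neutrophil cut-off by sweeping candidate thresholds with the
Mann–Whitney U test on the FACED and E-FACED severity indices, selects the
operating threshold under joint-significance and cluster-balance
constraints, and then characterizes the resulting above-/below-threshold
clusters — two-group comparison tables with significance stars and subgroup
exclusions, mild/moderate/severe category histograms, pairwise Pearson
correlation matrices, and confounder-adjusted logistic models of severe
disease (FACED ≥ 5, E-FACED ≥ 7) with Wald intervals.

At its core are three table-driven severity-score calculators and one
statistic. For a candidate threshold *t* the cohort splits into groups
*A(t)* = {neutrophils ≥ *t*} and *B(t)*, and the sweep records the
two-sided Mann–Whitney p-value of

> U = Σᵢ∈A Σⱼ∈B [ 1(sᵢ > sⱼ) + ½·1(sᵢ = sⱼ) ]

for s = FACED and s = E-FACED, exactly (permutation-equivalent rank-sum
enumeration) for small tie-free splits and by tie-corrected normal
approximation otherwise. Eligible thresholds have both p-values below α and
at least a `min_fraction` share of patients in the smaller cluster; the
shipped selection rules are `most_balanced` (published rationale),
`highest_significant`, and `min_p` (the classical minimum-p cut-point rule,
the one that recovers a planted change-point). The adjusted association is a
logistic model `severe ~ cluster + confounders` fitted by IRLS, with the
confounder list fixed to PA colonization, Charlson index, leukocytes,
% lymphocytes, % eosinophils, platelets, CRP, fibrinogen, total protein,
albumin and ESR.

Because registry data are not redistributable, the package ships a
synthetic-cohort generator (`generate_cohort()`) whose marginals are
calibrated to a published 1034-patient registry cohort and which plants a
step effect at a configurable neutrophil threshold — every stage of the
pipeline is testable end to end without external data.

## Worked example

```r
library(neutroclust)

cohort <- generate_cohort(cohort_config(n_patients = 1034, seed = 7))
scored <- score_cohort(cohort)                     # FACED / E-FACED / BSI
scan   <- scan_thresholds(scored, grid_step = 10, alpha = 0.05)
thr    <- select_threshold(scan, strategy = "min_p")
thr
#> [1] 5010
assignment <- dichotomize(scored, thr)
table(assignment$cluster)
#>      below      above unassigned
#>        695        339          0
```

The generator plants its effect at 4990 cells/µL; the sweep recovers 5010
and splits the cohort 695/339 — two clusters of the same shape as the
published 697/337. The characterization table then reads:

```r
format_comparison(comparison_table(scored, assignment))
#>   variable        below       above              p stars
#> 1 age             67.0 (15.0) 71.6 (14.6) 2.62e- 6 ***
#> 2 faced           2.1 (1.4)   2.8 (1.6)   2.55e-13 ***
#> 3 efaced          3.0 (1.8)   4.1 (1.8)   1.09e-22 ***
#> 4 pa_colonization 158 (22.7)  112 (33.0)  3.98e- 4 ***
#> 5 dlco_pct        85.6 (21.3) 74.7 (22.4) 8.81e-13 ***
#> 6 crp             2.6 (7.9)   5.9 (18.8)  1.01e- 4 ***
```

Above-threshold patients are older, score worse on every severity index,
are more often PA-colonized, diffuse worse and are more inflamed — mean (SD)
for continuous rows, N (%) for binary rows, stars at p < 0.05/0.01/0.001.
Finally, cluster membership predicts severe disease after full confounder
adjustment:

```r
fit <- adjusted_association(scored, assignment, "FACED")
fit$terms[fit$terms$term == fit$exposure, ]
#>   term                estimate    se    or ci_lo ci_hi        p
#> 1 above_thresholdTRUE     1.43 0.433  4.18  1.79  9.78 0.000957
```

i.e. an adjusted odds ratio of 4.2 (95% CI 1.8–9.8) for FACED ≥ 5 in the
above-threshold cluster. `run_pipeline(pipeline_config(...))` chains all of
the above, writes every table as CSV plus a JSON manifest, and is
byte-for-byte reproducible from (config, seed). A thin command-line wrapper
lives at `inst/cli/neutroclust.R` (`simulate`, `score`, `scan`, `run`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
it generates the registry-calibrated 1034-patient synthetic cohort for the
given seed, executes the full pipeline (scores, sweep, selection,
characterization, adjusted models) and writes the result JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
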