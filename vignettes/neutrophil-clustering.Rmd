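---
title: "Neutrophil-count phenotype clustering: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutrophil-count phenotype clustering: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Blood neutrophilia is a hallmark of chronic airway infection, and in
non-cystic-fibrosis bronchiectasis there is long-standing interest in whether
a simple blood count can separate patients into clinically distinct
phenotypes. `neutroclust` implements one complete version of that analysis:
find a neutrophil cut-off, data-driven rather than conventional, that splits
a cohort into two clusters differing in validated severity indices, then
characterize the clusters (clinical tables, category histograms, correlation
matrices) and test whether cluster membership predicts severe disease after
adjusting for inflammation and nutrition markers.

The package is organized exactly along those stages:

1. `generate_cohort()` — synthetic registry cohorts with a planted
   threshold effect (no real registry data ship with the package);
2. `score_cohort()` — FACED (0–7), E-FACED (0–9) and BSI (0–26) severity
   indices, table-driven;
3. `scan_thresholds()` / `select_threshold()` — a Mann–Whitney U sweep over
   candidate cut-offs with significance and balance constraints;
4. `comparison_table()`, `category_histogram()`, `correlation_matrix()`,
   `adjusted_association()` — the downstream characterization;
5. `run_pipeline()` — deterministic end-to-end orchestration with a JSON
   manifest.

## Severity scores

The scoring engine is deliberately table-driven (`default_point_tables()`):
each index is a list of components, each component a banding rule over one
or two record fields. The registry study this design follows does not print
the point values; the shipped defaults transcribe the original index
publications and carry a provenance note saying exactly that. If a banding
is ever found to disagree with the originals, the correction is a config
edit, not a code change.

Two conventions deserve notice:

* **BSI maximum of 26.** We score chronic *Pseudomonas aeruginosa*
  colonization (0/3 points) and chronic colonization by other organisms
  (0/1) as two separate components, which makes the per-component maxima sum
  to 26 — consistent with the widely quoted 0–26 range and with the separate
  `pa_colonization` / `other_colonization` record fields. Readings of the
  original index that treat colonization as one three-level item sum to 25;
  under either reading every category boundary used here (mild 0–4,
  moderate 5–8, severe ≥ 9) is unaffected.
* **Missing inputs.** A component with a missing input contributes no points
  and marks the patient's total as undefined. Severity is never imputed;
  patients without a total simply drop out of score-dependent stages (the
  registry tables' varying Ns arise the same way).
* **BSI hospitalization look-back.** The original index counts admissions
  over two years; the registry variable modelled here is "hospitalizations
  for exacerbations in the previous year". The look-back is a constructor
  flag (`bsi_hospitalization_lookback`), defaulting to the previous-year
  variable.

Category boundaries are fixed by the published legend: FACED mild 0–2 /
moderate 3–4 / severe 5–7; E-FACED 0–3 / 4–6 / 7–9; BSI 0–4 / 5–8 / ≥ 9.
All boundaries are inclusive as printed.

## The threshold sweep

`scan_thresholds()` evaluates, at every candidate cut-off, the two-sided
Mann–Whitney U test comparing FACED and E-FACED totals between patients at
or above versus below the candidate. Conventions:

* the default grid runs every 10 cells/µL from the 5th to the 95th
  percentile of observed neutrophils (the source analysis never states its
  candidate set; the grid is configurable);
* the exact null distribution (a rank-sum dynamic programme, equivalent to
  full permutation of group labels) is used when `n_a * n_b <= 400` and the
  pooled sample has no ties; otherwise a normal approximation with
  tie-corrected variance and a 0.5 continuity correction;
* p-values are raw — no correction across the grid, matching the source
  analysis;
* the above cluster is inclusive of the boundary (`neutrophils >=
  threshold`), following the "≥ 4.99 × 10³ cells/µL" table convention, and
  tied values at the threshold all go above.

`select_threshold()` restricts to candidates where **both** scores separate
at `alpha` (the joint requirement is a design decision; the source describes
the two scores together without stating the rule) and where the smaller
cluster keeps at least `min_fraction` of patients (default 0.25; the
reported split was 337/1034 ≈ 33%). Three strategies are named:

* `most_balanced` (default) — the eligible candidate maximizing the smaller
  cluster, ties to the higher threshold. This mirrors the published
  rationale ("the most balanced cluster sizes") and in practice lands near
  the sample median.
* `highest_significant` — the largest eligible candidate, mirroring the
  alternative phrasing ("the highest threshold").
* `min_p` — the eligible candidate minimizing `max(p_faced, p_efaced)`,
  ties to the higher threshold. This is the classical minimum-p-value
  cut-point rule. We added it because it is the only rule of the three that
  *recovers a planted change-point*: when a step effect is planted away
  from the neutrophil median, balance always prefers the median and
  "highest" drifts to the balance boundary, while the p-value curve dips at
  the true change-point. The recovery simulations in the test suite use it.

**Selection bias.** Scanning a grid and reporting the best unadjusted p is
the textbook minimum-p bias. The package keeps the raw p-values on purpose
(that is the procedure being modelled) but the null-model simulations in the
suite bound the cost: even requiring joint significance plus balance, a
non-trivial fraction of pure-noise cohorts still yields a selected
threshold (the suite checks that most null draws select nothing). Any
threshold found this way needs external validation before clinical use.

## Two-cluster characterization

* Continuous rows: mean (SD) per cluster, pooled-variance Student's t
  (Welch by option). Degenerate zero-variance samples use the documented
  convention p = 1 (equal means) / p = 0 (unequal).
* Binary/categorical rows: N (%) with Pearson's chi-square, no Yates
  correction by default (option available); expected counts below 5 raise a
  warning that the pipeline surfaces in its manifest.
* Stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, strictly; exact p is
  always exported alongside.
* Missing data are handled pairwise: each row uses every patient
  non-missing for that variable. Exclusion re-analyses (drop COPD, drop PA
  colonization) remove flagged patients before any summary, and percent
  denominators are the post-exclusion group sizes.
* Display rounds half-up to one decimal (table style); CSV exports keep
  full precision. `percentage(337, 1034, 0)` is 33 — the analysed cohort's
  own prose truncates the same quantity to "thirty-two percent", so the
  pipeline records both the exact 32.59 and the rounded value.

Correlation matrices are pairwise complete-case Pearson (Spearman by
option, since score totals are ordinal), with the p > 0.05 entries flagged
rather than suppressed, matching the crossed-dot display convention.

## Adjusted association

`adjusted_association()` fits severe disease (FACED ≥ 5 or E-FACED ≥ 7) on
the cluster indicator plus a fixed confounder list: PA colonization,
Charlson index, total leukocytes, % lymphocytes, % eosinophils, platelets,
CRP, fibrinogen, total protein, albumin, ESR — entered simultaneously and
untransformed. The fit is our own IRLS implementation because the analysis
contract pins details a stock fit does not expose: score-based convergence
(`max |X'(y-p)| < 1e-8`, 100 iterations), step-halving so the likelihood
never decreases, complete-case counts, Wald intervals `exp(b ± 1.96·SE)`
(the published interval shapes are consistent with Wald on the log scale),
and a quasi-separation flag when any coefficient passes 15 in absolute
value — flagged fits still report estimates, with a warning. The test suite
cross-checks coefficients and standard errors against `stats::glm` and the
one-binary-covariate fit against the closed-form 2×2 odds ratio.

## The synthetic registry

The generator is a stated world, not a tuning knob. Neutrophils are
lognormal — right-skewed and strictly positive, the natural minimal choice;
the source never states a distribution. The default `meanlog = 8.317`,
`sdlog = 0.44` were derived once, analytically, so that at the 4990 cells/µL
cut-off the sub-threshold stratum has mean ≈ 3370 and SD ≈ 910 cells/µL and
≈ 32.6% of patients fall above — the three moments the registry tables pin
down. Every other variable takes its below-threshold marginal from the
published below-threshold column (age 67.1 (14.6) years, FEV₁ 78 (24)%,
PA colonization 21.5%, CRP 2.89 (8.54) mg/dL, ...) and its effect size from
the above-minus-below difference. Skewed analytes (CRP, ESR, lymphocyte and
eosinophil counts, pack-years) use gamma families matching mean and SD;
bounded physiology is clamped (e.g. FEV₁/FVC ≤ 100). Counts are Poisson;
the dyspnea grade is categorical; affected lobes are a truncated shifted
Poisson on 1–6 with mean ≈ 2.9. Leukocytes are assembled as neutrophils +
lymphocytes + eosinophils + a non-negative residual, so the additivity
invariant holds by construction. With these defaults the implied FACED means
are ≈ 2.0 below and ≈ 2.7 above threshold — close to the published
1.9 / 2.8 — *without* ever generating score totals directly: the components
are generated and the scorer does the rest, so the scorer is genuinely
exercised.

What the generator does **not** emulate, and hence what a green simulation
test cannot establish: effects are a step exactly at the planted threshold
(the dichotomized world the pipeline assumes), not a graded dose–response;
within a stratum, variables are conditionally independent (no
correlation structure beyond what the step induces); missingness is
missing-completely-at-random per variable; comorbidities are independent
flags rather than a coherent Charlson structure. Recovering the planted
threshold here says the machinery works, not that a real cohort's cut-off
is biologically meaningful.

## Numerical choices, degenerate inputs, determinism

* Exact Mann–Whitney switches to the normal path whenever ties exist, at
  any sample size; all-tied pooled samples return p = 1.
* Half-up rounding is used for all printed-style cells (base `round()`
  rounds half to even, which table formatters must not).
* Cohorts are a pure function of (config, seed); `generate_cohort()`
  restores the caller's RNG state. `run_pipeline()` writes byte-identical
  CSVs on rerun and halts cleanly, with a manifest record, when no
  threshold is eligible.
* Empty samples, single-class outcomes, rank-deficient designs, constant
  correlation inputs, zero margins and out-of-range grades all raise typed
  errors naming the offending quantity rather than propagating NaNs.

## Known limitations

The analysis is cross-sectional by construction; nothing here estimates
prognosis. The selection procedure inherits minimum-p bias (see above). The
shipped point tables must be verified against the original index
publications before any clinical use. Firth-style penalization for
separated logistic fits is not implemented; the separation flag plus warning
is the supported behaviour.
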