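---
title: "Methods: pooling SNP case-control studies with snpmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling SNP case-control studies with snpmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem

A single case-control study of a biallelic SNP reports six genotype counts:
TT/TC/CC among cases and among controls. Individually such studies are
usually underpowered and often disagree; meta-analysis pools them into a
single odds ratio (OR) per genetic contrast, with an honest account of
between-study heterogeneity. snpmeta implements that pipeline end to end
from raw counts, together with the standard companion analyses
(subgroups, leave-one-out sensitivity, funnel-plot asymmetry tests,
Hardy-Weinberg checks, power), and a simulator that generates tables with
the same generative structure for calibration experiments.

Throughout, C denotes the effect allele and T the reference allele.

## Genetic-model contrasts

Each study's 3x2 genotype table is collapsed to a 2x2 table
(a = case events, b = case non-events, c = control events,
d = control non-events) under five contrasts:

| model        | contrast          | a               | b               |
|--------------|-------------------|-----------------|-----------------|
| allele       | C vs. T           | 2·CC + TC       | 2·TT + TC       |
| dominant     | CC + TC vs. TT    | CC + TC         | TT              |
| recessive    | CC vs. TT + TC    | CC              | TC + TT         |
| homozygote   | CC vs. TT         | CC              | TT              |
| heterozygote | TC vs. TT         | TC              | TT              |

(c and d analogously from the control row.) The allele model treats the 2N
alleles of N subjects as independent observations — the convention of this
literature, but an approximation: it is exact only under
Hardy-Weinberg equilibrium in both arms, and it understates the variance
when genotypes depart from it.

**Informativeness.** A study with no events in both arms (a = c = 0) or no
non-events in both arms (b = d = 0) carries no information about the OR
under that contrast. Such studies are excluded from pooling *for that
contrast only*, before any continuity correction; the exclusion is logged.
This matters in practice: a cohort monomorphic for T contributes to no
contrast, and a cohort with no CC genotypes anywhere drops out of the
recessive and homozygote contrasts while still informing the others.

**Continuity correction.** When an informative table contains a zero cell,
0.5 is added to *all four* cells of that study (the convention of the
mainstream meta-analysis software family); other studies are untouched.
The policy is a configuration knob (`continuity = "none"` disables it) so
its influence can be probed; with `none`, a remaining zero cell makes the
per-study OR undefined and raises an error rather than silently dropping
the study.

## Pooling

Per study, the log OR is `ln(ad/bc)` with Woolf standard error
`sqrt(1/a + 1/b + 1/c + 1/d)`.

Three pooled estimators are provided:

* **Mantel-Haenszel fixed effect** (default fixed method):
  `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`; the variance of
  `ln(OR_MH)` uses the Robins-Breslow-Greenland formula. MH degrades
  gracefully with sparse cells, which is why it is the field's default for
  ORs from count data.
* **Inverse-variance fixed effect**: weights `w_i = 1/se_i^2`.
* **DerSimonian-Laird random effects**: the moment estimator
  `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` from the IV
  pass, then re-weighting by `1/(se_i^2 + tau^2)`. `tau^2` is truncated at
  zero, and no iterative (REML / Paule-Mandel) refinement is attempted;
  when `tau^2 = 0` the random-effects result coincides exactly with the
  IV fixed result, and the test suite asserts that identity.

**Heterogeneity.** Cochran's `Q = sum(w_i (theta_i - theta_IV)^2)` on
`k - 1` df, `I^2 = max(0, (Q - df)/Q) * 100`. Q is always computed with
inverse-variance weights around the *IV* fixed estimate, even when the MH
estimator reports the pooled OR — this keeps the heterogeneity assessment
(and everything downstream of it) independent of the MH/IV choice. With
`k = 1`, `df = 0` and the Q test is vacuous; `p_Q` is reported as 1.

**Model selection.** `select_model()` implements the conventional rule:
random effects when `p_Q < 0.1` **or** `I^2 > 50%`, fixed effects
otherwise. Both inequalities are strict, so the boundary values select the
fixed model. Confidence intervals are Wald intervals with
`z = qnorm(0.975) = 1.959964`; p-values are two-sided normal.

## Subgroups and sensitivity

`subgroup_analysis()` re-runs the full pipeline inside each category of a
label column (ethnicity and source of controls are first-class; any extra
column works). Two conventions exist for choosing fixed vs random within a
stratum, and the package supports both:

* `method = "inherit"` (default): every stratum uses the fixed/random
  choice made by the **overall** analysis of the same contrast. Stratum
  CIs are then directly comparable with the overall CI, and this is the
  behaviour of the mainstream software family this pipeline is modelled
  on — published subgroup tables produced with that software only
  reproduce under this convention.
* `method = "per_stratum"`: the heterogeneity rule is re-applied inside
  each stratum. Statistically defensible, but a homogeneous stratum inside
  a heterogeneous meta-analysis then switches estimator relative to the
  overall row.

Per-stratum Q, `p_Q` and `I^2` are computed from the stratum's own
effects either way and do not depend on this choice. A stratum with no
informative study is reported as empty, not an error.

`leave_one_out()` omits each informative study in turn and re-runs
pooling, including model re-selection, on the remaining `k - 1` studies.
The pooled estimate of every subset necessarily lies within the range of
the remaining per-study ORs (a property the tests check), so an omission
result far from the overall estimate flags an influential study.

## Publication-bias diagnostics

* **Egger's regression**: OLS of the standardized effect
  `theta_i / se_i` on precision `1 / se_i`; a two-sided t test on the
  intercept with `k - 2` df. Requires variation in the standard errors —
  equal `se_i` make the regressor degenerate and raise an error.
* **Begg-Mazumdar rank correlation**: Kendall's tau between
  `(theta_i - theta_hat) / sqrt(v_i - v_hat)` (fixed IV pool `theta_hat`,
  pooled variance `v_hat`) and `v_i`, with normal approximation
  `z = (P - Q) / sqrt(k(k-1)(2k+5)/18)` and a continuity correction of 1
  on `P - Q`. Ties contribute zero to the score. If some `v_i <= v_hat`
  (a small-k edge case), the standardization denominator is clamped at
  `sqrt(1e-8)` and a warning is emitted.

Both tests need `k >= 3`, are invariant to study order, and are known to
be underpowered at small k (Begg conservatively so); the simulator's
null-calibration run quantifies this.

## Hardy-Weinberg and power

`hwe_test()` is the plain Pearson chi-squared test on 1 df (one free
allele frequency, no continuity correction) of observed control genotypes
against `n(1-q)^2, 2nq(1-q), nq^2` at the observed allele frequency `q`.
Monomorphic controls are reported `assessable = FALSE` — the test is
undefined there, whatever a primary report may have printed.
`hwe_table()` recomputes the flag for every cohort and reports
disagreements with the reported flag rather than trusting it; in the
packaged dataset exactly two reported "N" flags are not reproducible (one
monomorphic cohort, one with p well above 0.05), and they are surfaced as
disagreements.

`power_analysis()` computes allele-contrast power by normal
approximation: the case allele frequency implied by
`odds_case = OR x odds_control`, the SE of the log OR from the expected
2x2 allele-count table at the given sample sizes, and
`power = Phi(|ln OR|/SE - z) + Phi(-|ln OR|/SE - z)`. At `OR = 1` this
returns exactly `alpha`. It ignores between-study heterogeneity, so for a
heterogeneous meta-analysis it is an upper bound; we therefore treat
published power claims as lower-bound checks only.

## The simulator

`simulate_study_table()` draws, per study: a control effect-allele
frequency `q ~ U(maf_law)`; control genotypes multinomial under
Hardy-Weinberg at `q`; a study log OR `ln(OR) + N(0, tau^2)`; the case
allele frequency from the odds relation; and case genotypes multinomial
under Hardy-Weinberg at that frequency. Ethnicity and source-of-control
labels are assigned round-robin so all strata are populated from
`k >= 6`.

Defaults mirror the packaged dataset's scale: `k = 14` cohorts, allele
OR 0.76 (the protective effect size the packaged analysis is powered
for), `tau = 0`, control allele frequencies on (0.10, 0.45) — the
polymorphic range observed in the packaged controls — and 100-2000
subjects per arm. What the simulator deliberately does **not** emulate:
genotype-level penetrance (cases are drawn under HWE at the shifted
allele frequency, matching the allele-contrast analysis), linkage
disequilibrium, covariates, or selective publication. Passing calibration
tests therefore demonstrates internal statistical correctness of the
estimators under the model's own assumptions, not robustness to the
messiness of real literatures.

`simulate_null_meta()` wraps replicate runs and reports empirical
rejection rates of the pooled z-test, the Q test, and both bias tests,
with binomial Monte-Carlo standard errors. The test suite runs it at
`k = 15` studies and 500 replicates for type-I error, and recovers a true
OR of 0.7-0.76 from 200 replicates of `k = 50` studies with 1000
subjects per arm — sizes chosen to make Monte-Carlo bands tight enough to
detect estimator bias while keeping the default suite quick.

## Numerical and degenerate-input choices

* Counts are validated as non-negative integers at parse time; errors
  name the row and field.
* `ethnicity` and `soc` come from closed vocabularies; unknown categories
  are rejected at parse time, unknown *columns* are kept as extra labels.
* Cohorts sharing a `study_id` (two publications in the packaged data
  each contribute two cohorts) are independent analysis units.
* `I^2` is clamped to [0, 100]; `tau^2` to [0, Inf); `p_Q = 1` at k = 1.
* Random-effects pooling refuses k < 2 (`tau^2` undefined); the auto rule
  falls back to fixed at k = 1.
* The packaged dataset's published summary estimates are reproduced by
  the acceptance tests at 2-decimal tolerance; two printed values in the
  source tables are internally inconsistent (a CI that is not
  log-symmetric about its own OR, with an incompatible p-value) and the
  corresponding assertions document the discrepancy rather than hiding
  it.

## Known limitations

* No Peto OR, risk ratio/difference scales, Hartung-Knapp variance
  adjustment, meta-regression, cumulative meta-analysis, trim-and-fill,
  or exact (mid-p) HWE tests.
* The allele contrast's independence assumption, the DL estimator's known
  downward bias in `tau^2` at small k, and Wald CIs are all retained
  deliberately to match standard practice in this literature rather than
  current methodological best practice.
* Multi-allelic markers, X-linked dosage and genotype imputation are out
  of scope.
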