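---
title: "Methods: diet scores, genetic risk, and matched-pair interaction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet scores, genetic risk, and matched-pair interaction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietGxE)
```

dietGxE analyses whether adherence to a Mediterranean-style dietary pattern
modifies the association between FTO genetic risk and obesity phenotypes in
a nested case-control design. This vignette documents the models and the
decisions behind them: what is computed, under which conventions, and what
the synthetic-data machinery does and does not establish.

## The Mediterranean diet score

Each subject's daily intakes of eight food components are first expressed
as energy densities — grams per 1000 kcal of total energy intake
(`energy_adjust()`). Energy adjustment removes the gross correlation
between absolute intake and body size/energy needs; the MUFA:SFA ratio is
dimensionless and unaffected.

One point per component is awarded relative to the *sex-specific median*
of the pooled analysis sample (`compute_medians()`, `score_mds()`):

* desirable components — vegetables, legumes, fruits+nuts, cereals, fish —
  score 1 when intake is **at or above** the median;
* undesirable components — meat & poultry, dairy — score 1 when intake is
  **below** the median (at the median scores 0);
* the MUFA:SFA ratio scores 1 only when **strictly greater** than the
  median.

The total ranges 0–8. Alcohol is not a component (the score was developed
for a population where consumption is rare and unmeasurable). The
asymmetric tie rules are intentional and exactly as stated in the score's
definition; a subject sitting exactly at every median therefore scores 5
under the default 8-component scheme (desirable ties win their point;
undesirable and ratio ties do not).

Two conventions were genuinely open and are fixed as follows:

* **Fruits and nuts form one combined component** (their energy-adjusted
  intakes are summed before the median is taken). This follows the
  original eight-component formulation in which meat and dairy are the two
  undesirable components. `combine_fruits_nuts = FALSE` keeps them
  separate (nine components) for sensitivity analyses.
* **Even-sized strata use the standard sample median** (midpoint of the
  two central order statistics).
* An **undefined ratio** (SFA intake exactly 0) is scored 1 and logged:
  the ratio grows without bound as SFA tends to 0, so the limiting value
  exceeds any finite median.

## Genotypes and the weighted genetic risk score

Genotypes enter as risk-allele dosages 0/1/2 (the risk allele is the
BMI-increasing, here minor, allele), read from a TSV matrix or a minimal
VCF (GT field, biallelic diploid records only; half-calls are missing).
Frequency tables (`genotype_frequencies()`) and the Hardy-Weinberg test
(`hwe_test()`: Pearson chi-square on 1 df, no continuity correction) are
computed per SNP and group.

The weighted score over $n$ SNPs with literature odds-ratio weights $w_i$
is

$$\mathrm{GRS} = \Big(\sum_i w_i g_i\Big)\cdot\frac{n}{\sum_i w_i},$$

which ranges 0 to $2n$ (0–12 for the six-SNP FTO panel) and makes one GRS
point correspond to one risk allele; the normalising factor cancels for any
constant dosage, so the range is weight-free. Published analyses of this
panel report only the weight **sum** (8.18), not the six individual
weights; `fto_panel()` therefore defaults to equal weights $8.18/6$ —
preserving the printed sum and range without inventing unpublished per-SNP
values — and accepts user-supplied weights. Subjects with any missing
dosage get a missing GRS (complete-case; no imputation). The GRS is split
at its sample median (`dichotomize_grs()`, ties to the high group);
per-SNP analyses use dominant (carrier) coding.

## Cohort assembly

`classify_phenotypes()` applies the study definitions: obesity BMI ≥ 30,
normal weight 18.5–24.9, abdominal obesity WC ≥ 95 cm (both sexes), high
WHR ≥ 0.8 in men and ≥ 0.9 in women. The WHR cutoffs invert the usual
convention but are implemented as printed, with overrides.

`apply_exclusions()` drops, in fixed order: recent weight change > 5 kg,
pregnancy/lactation, weight-affecting drugs, failed DNA quality, and
implausible energy reporting (reported/predicted ratio outside mean ± 3 SD
among subjects surviving the earlier rules). The predicted intake is not
pinned down by the study description; the default is a Schofield
age/sex/weight BMR equation times an activity factor
(`schofield_energy()`), and a pass-through column is accepted so the
screen is testable without endorsing any particular equation. The audit
log's per-rule counts sum exactly to input minus retained.

`match_pairs()` performs randomized greedy 1:1 matching: cases in random
order, each matched to a control sampled uniformly from unused same-sex
controls within ±5 years. The study says only that a random control was
drawn; randomized greedy is the simplest faithful reading, is seeded, and
every emitted pair provably satisfies both constraints.

`assign_quartiles()` cuts the discrete 0–8 score at the ordered 25/50/75%
positions keeping whole tie blocks together (ties resolved downward), so
quartile membership is deterministic and permutation-invariant. On a
discrete score this makes quartile sizes unequal by up to the tie-block
size — unavoidable for any deterministic quartiling of a 9-valued score.

## Association models

The contribution of the package is the likelihood machinery, written
directly rather than delegated:

* **Conditional logistic regression** (`clogit_fit()`): for a 1:1 matched
  pair with case covariates $x_1$ and control covariates $x_0$, the
  conditional likelihood contribution is
  $e^{d'\beta}/(1+e^{d'\beta})$ with $d = x_1 - x_0$. The fit is
  Newton-Raphson with step-halving; convergence at max |score| < 1e-8 or
  step norm < 1e-10, at most 50 iterations; standard errors from the
  inverse observed information. Concordant pairs contribute a constant and
  leave estimates unchanged. A covariate whose nonzero differences all
  share a sign separates the likelihood; the fit is flagged rather than
  silently returned.
* **Unconditional logistic regression** (`logit_fit()`) under the same
  convergence contract, for outcomes where matching is broken (abdominal
  obesity, high WHR).
* **Interaction testing** (`lrt_interaction()`): twice the log-likelihood
  difference between the model with and without the product term(s),
  chi-square with df = parameter difference. The headline
  parameterisation is binary genotype (carrier or high GRS) × MDS
  quartile as an ordinal 1–4 covariate — a 1-df test, matching the single
  interaction p-value reported per SNP in this literature. The 8-level
  factor (4 quartiles × 2 genotype groups, reference Q1 × non-carrier) is
  used for the OR grids (`build_groups()`, `or_report()` with Wald
  95% CIs, z = 1.96).
* **Trend tests** (`quartile_median_score()`, `trend_test()`): the
  quartile factor is replaced by the median score of each quartile as a
  continuous covariate; the p-for-trend is the Wald test on that slope,
  per genotype stratum.

Two internal cross-checks guard the likelihood code: the pair-difference
fit must agree with an intercept-free logistic fit on differences with
outcome fixed at 1 (two independent code paths to the same maximum), and
the test suite compares both fitters against the survival package and
`glm` on simulated data.

Adjustment sets follow the reported tables: conditional obesity models
adjust for education; unconditional abdominal-obesity and WHR models
adjust for education, age, sex, smoking, activity and energy.

## The synthetic cohort

No individual-level data are distributed with studies of this design, so
the generator (`simulate_cohort()`) is first-class: it defines the
conditions under which every claim about the pipeline is tested.

* **Genotypes**: dosages marginally Binomial(2, MAF) — exact HWE — at
  MAFs 0.33–0.38 matching the six FTO variants, with cross-SNP linkage
  from a Gaussian copula on the two latent per-chromosome allele draws
  (default ρ = 0.9; FTO intron-1 SNPs are tightly linked, and results
  should be robust to ρ).
* **Diet**: lognormal component intakes (locations typical of an urban
  Middle-Eastern FFQ) scaled with a lognormal energy (mean 2400, SD
  1000 kcal/day). Because intakes are continuous, each score point is
  close to a fair coin, so the derived MDS lands at mean ≈ 4, SD ≈ 1.4 —
  the published marginals — without any tuning knob.
* **Covariates**: age ≈ 34 ± 11, education ≥ 14 y at 24%, current smoking
  15%, low activity 41%; anthropometrics with enough independent variation
  that the abdominal outcomes are stochastic rather than determined by
  case status.
* **Outcomes**: per phase (3 by default), a still-non-obese subject
  becomes an incident case with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta_G G + \beta_E Q + \beta_{G\times E} GQ + \text{covariates})$.
  The latent truth is retained for recovery tests.

For calibrating the interaction test itself, a direct matched-pair
simulator (`simulate_matched_pairs()`) draws both members' covariates and
assigns case status by the conditional-on-one-case probability
$e^{\eta_1}/(e^{\eta_1}+e^{\eta_2})$. This is *exactly* the 1:1
conditional likelihood, so the conditional fit is correctly specified with
the same coefficients — the clean instrument for type-I error and
coverage studies, free of the matching and exclusion noise of the full
generator (which is exercised separately by round-trip and pipeline
tests). Problem sizes used by the shipped checks — 1000 null replicates of
500 pairs for size, 200 replicates of 5000 pairs at
$\beta_{G\times E} = -0.2$ for bias and coverage — give Monte-Carlo
standard errors of about 0.7 points on a 5% rejection rate and 1.5 points
on 95% coverage.

What passing these checks does **not** show: the generator draws
components independently given energy (real FFQ components correlate),
models no measurement error in diet or genotype, and its linked SNPs share
one exchangeable correlation rather than a realistic LD block. Parameter
recovery under the generator is evidence the *machinery* is correct, not
that any particular published odds ratio would replicate.

## Numerical and degenerate-input conventions

* Records with non-positive energy or negative intakes are rejected with
  diagnostics, not silently dropped.
* Monomorphic SNPs return a Hardy-Weinberg chi-square of 0 with a
  warning; all-zero genotype counts are an error.
* Quartiles collapse with a warning when fewer distinct values than
  cutpoints exist.
* `lrt_interaction()` treats a full-model log-likelihood more than 1e-6
  below the reduced model's as a convergence failure and errors rather
  than reporting a negative chi-square.
* All simulation entry points take explicit seeds; the pipeline derives
  per-stage sub-seeds from one master seed so stages can be re-run
  independently and reproducibly.

## Known limitations

* Per-SNP GRS weights default to equal because only their sum is
  published; analyses sensitive to weight heterogeneity need user-supplied
  weights.
* The published per-quartile mean scores (1.63/3.56/5.00/6.25) are not
  jointly attainable with the published score SD of 1.45 — the
  between-quartile variance they imply (2.96) exceeds the total variance
  (2.10) — so the quartile checks assert the attainable part (monotone
  means; upper three quartiles near the printed values).
* Exact conditional inference, Firth penalisation, robust variances and
  multiple-testing corrections are out of scope; separation is flagged,
  not repaired.
* 1:1 matching only; no multi-control or propensity matching.
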