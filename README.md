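# dietGxE

Gene–diet interaction analysis for nested case-control studies of
obesity: does adherence to a Mediterranean-style dietary pattern modify
the association between FTO genetic risk and obesity phenotypes?

The package is aimed at genetic-epidemiology analysts working with
matched case-control data. It covers the full path from raw inputs to
interaction tests:

* **Mediterranean diet score (MDS)** — energy-density adjustment
  (g/1000 kcal), pooled sex-specific median cutoffs, and the
  eight-component 0–8 adherence score (desirable components score at or
  above the median; meat/poultry and dairy score below it; the MUFA:SFA
  ratio scores strictly above it).
* **Genotype toolkit** — risk-allele dosage coding from VCF or TSV,
  allele/genotype frequency tables, Hardy–Weinberg testing (Pearson
  chi-square, 1 df), dominant coding, and the weighted genetic risk score

  GRS = (Σᵢ wᵢ gᵢ) · n / Σᵢ wᵢ,  range 0–2n (0–12 for the 6-SNP FTO panel),

  split at its sample median.
* **Cohort assembly** — phenotype definitions (BMI ≥ 30 obesity,
  18.5–24.9 normal weight, WC ≥ 95 cm abdominal obesity, sex-specific
  WHR cutoffs), an auditable exclusion cascade (including a ±3 SD
  reported/predicted energy screen), seeded randomized greedy 1:1
  matching on age (±5 y) and sex, and whole-tie-block MDS quartiles.
* **Association models** — conditional logistic regression for 1:1
  matched pairs, fitted by Newton–Raphson on within-pair covariate
  differences (the exact conditional likelihood
  exp(d'β)/(1+exp(d'β))), unconditional logistic regression by IRLS,
  1-df likelihood-ratio interaction tests (carrier × ordinal MDS
  quartile), quartile-median trend tests, OR grids with Wald 95% CIs,
  and Table-1-style descriptives.
* **Synthetic cohorts** — genotypes in HWE with copula-linked SNPs,
  lognormal intakes whose derived MDS lands at mean ≈ 4 (SD ≈ 1.4),
  phased incident obesity driven by a configurable logistic model with a
  gene–diet interaction, and a conditional-likelihood-exact matched-pair
  simulator for calibration and power studies.

## Worked example

Simulate a cohort, run the whole pipeline, and inspect the GRS × MDS
interaction:

```r
library(dietGxE)
cfg <- sim_config(n_subjects = 4000, seed = 20)
res <- run_pipeline(cfg, "out")

res$manifest$n_pairs
#> [1] 606
subset(res$obesity_interaction, snp == "GRS")
#>     snp  lr_chi2 df p_interaction
#> GRS GRS 1.437174  1     0.2305972
subset(res$obesity_or, snp == "GRS")[, c("term", "or", "ci_lo", "ci_hi")]
#>                term       or     ci_lo    ci_hi
#> GRS.1 Q2.noncarrier 1.220839 0.7738012 1.926137
#> GRS.2 Q3.noncarrier 1.400468 0.8772281 2.235806
#> GRS.3 Q4.noncarrier 1.593387 0.9294467 2.731607
#> GRS.4    Q1.carrier 1.354694 0.9112267 2.013984
#> GRS.5    Q2.carrier 1.172452 0.7707144 1.783595
#> GRS.6    Q3.carrier 1.347005 0.8712421 2.082569
#> GRS.7    Q4.carrier 1.516172 0.9420530 2.440179
```

606 age/sex-matched pairs survive the exclusion cascade and matching.
The OR grid is the 8-group design (MDS quartile × GRS group, reference
Q1 low-GRS, education-adjusted conditional model); the interaction row
is the 1-df likelihood-ratio test of high-GRS × ordinal quartile — here
non-significant, as expected for a cohort simulated without a planted
interaction. Frequency and Hardy–Weinberg tables, abdominal-obesity and
high-WHR analogues, trend tests and an audit log are written as CSVs to
the output directory together with a JSON run manifest.

The building blocks work standalone, e.g. the matched-pair odds ratio
from a discordant-pair table:

```r
d <- matrix(c(rep(1, 30), rep(-1, 10)), ncol = 1,
            dimnames = list(NULL, "exposed"))
exp(clogit_fit(d)$beta)
#>  exposed
#>        3
hwe_test(10, 10, 10)$chi2
#> [1] 3.333333
```

A command-line wrapper for the two entry points ships in
`inst/cli/dietGxE.R` (`run` and `calibrate` subcommands).

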