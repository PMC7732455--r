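# pairedLFQ

Paired longitudinal analysis of label-free plasma proteomes.

## The problem

In the first week of life the plasma proteome changes rapidly: maternal
IgG begins its first-order decay, the newborn starts synthesizing IgM
and J chain, complement components rise, and an acute-phase response
appears around day one. Quantifying these changes from label-free
quantification (LFQ) mass spectrometry is statistically awkward:
cohorts are paired (every newborn gives a day-of-life 0 baseline plus
exactly one follow-up at DOL 1, 3 or 7, to limit phlebotomy), samples
are processed in batches that shift and rescale intensities, and
low-abundance proteins go missing not at random (left-censoring).

`pairedLFQ` implements the full analysis path for such cohorts, for
proteomics analysts working from MaxQuant-style `proteinGroups` tables:

* reading MaxQuant-dialect tables (LFQ + iBAQ columns, "+"-flags, 0 =
  not quantified), with strict paired-design validation;
* contaminant/decoy/modified-only filtering and the 50% valid-value
  rule applied per comparison arm;
* empirical-Bayes location/scale batch correction that tolerates
  missing entries, with covariate protection;
* a quantile-based permutation test for global distribution differences
  between days;
* QRILC-style left-censored imputation, quarantined to PCA — imputed
  values can never reach a statistical stage (enforced by a provenance
  flag);
* paired differential abundance: per follow-up day, a linear
  mixed-effects model with a random participant intercept,

  `y = b0 + b_DOL * 1[day = d] + sex + batch + u_participant + e`,

  tested by a 1-df likelihood ratio (maximum-likelihood refits) with a
  finite-sample calibrated reference, Benjamini–Hochberg correction per
  day, and the dual significance gate q < 0.05 and |log2FC| > 0.2;
  plus Fisher's exact missingness analysis on the pre-filter matrix;
* trajectory analysis: per-participant change vs DOL0, clustered
  protein–protein correlation maps, and correlation screens against a
  target protein;
* immunoglobulin kinetics from iBAQ: subclass ratios normalized to
  IgG2, Welch comparisons against an adult reference panel, and
  apparent half-life estimation `t_half = -1/slope` from zero-intercept
  least squares of paired log2 changes on elapsed days, with a
  participant bootstrap CI;
* protein–mRNA concordance of change trajectories at the individual
  and DOL-average level (concordant: average R > 0.3).

A synthetic cohort generator (`generateCohort()`) reproduces the whole
statistical structure — paired design, trajectory classes, batch
effects, MNAR censoring, IgG decay with configurable half-lives,
coupled IgM/J-chain growth, RNA counts with tunable protein–mRNA
concordance — and emits the ground truth next to the data, so every
stage is testable without any external download.

## Worked example

```r
library(pairedLFQ)

co <- generateCohort(simConfig())      # 30 newborns, 60 samples, seed 1
co$pqe
#> ProteinQuantExperiment: 206 proteins x 60 samples
#>   missing lfq entries: 2059 (16.7%)
#>   iBAQ assay: present | imputed: FALSE
#>   samples per DOL: DOL0:30 DOL1:10 DOL3:10 DOL7:10

fl  <- filterFlags(co$pqe)
arm <- filterValidValues(fl$pqe, 7)    # DOL0-vs-DOL7 comparison arm
arm$report
#>   comparison_dol n_input n_removed_valid_value n_quantifiable
#> 1              7     206                    31            175

bc <- correctBatch(arm$pqe, covariates = "dol")
da <- callSignificance(fitPairedLMM(bc$pqe, 7))
head(da[order(da$q_value), c("protein", "log2fc", "q_value",
                             "significant", "n_used")], 3)
#>     protein log2fc  q_value significant n_used
#> 137  SP0158  0.880 2.09e-06        TRUE     10
#> 172   IGHG3 -0.936 2.09e-06        TRUE     10
#> 121  SP0142  1.305 5.55e-06        TRUE     10
sum(da$significant, na.rm = TRUE)
#> [1] 32
```

32 of 175 quantifiable proteins pass the dual gate at DOL7; IGHG3 falls
(short-half-life maternal IgG3 decaying) while IgM rises. The
immunoglobulin kinetics from the same cohort:

```r
tr <- computeChanges(co$pqe)
hl <- estimateHalfLife(tr, "IGHG1", boot_n = 2000, seed = 1)
#> IgG1 apparent half-life: 26.0 days (95% CI 18.4-43.6, n=30 pairs)

correlatePair(tr, "IGHM", "JCHAIN")
#> IgM vs J chain: R = 0.74, p = 2.7e-06
```

The half-life point estimate from a single 30-pair cohort is noisy (the
bootstrap interval shows it); across 200 replicate cohorts the
estimator's median recovery is within a few percent of the configured
truth, which is what the validation suite asserts. The IgM/J-chain
change trajectories correlate strongly because the generator couples
their per-participant growth rates — the behaviour expected when J
chain production tracks IgM secretion.

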