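---
title: "Methods: paired longitudinal analysis of label-free plasma proteomes"
author: "pairedLFQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired longitudinal analysis of label-free plasma proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedLFQ)
```

# Scope and data model

`pairedLFQ` analyses longitudinal plasma proteomes acquired by label-free
quantification (LFQ) mass spectrometry in a *paired* design: every
participant contributes a baseline sample at day of life (DOL) 0 and
exactly one follow-up sample at DOL 1, 3 or 7. The central container,
`ProteinQuantExperiment`, extends `SummarizedExperiment`: the `lfq` assay
holds log2 intensities with `NA` marking not-quantified entries (MaxQuant
emits 0 for these; the reader converts on import), an optional `ibaq`
assay holds linear-scale iBAQ values used only for between-protein
comparisons, `rowData` carries the MaxQuant quality flags and `colData`
the sample annotation. Intensities are modelled on log2 scale
throughout; iBAQ stays linear because subclass ratios are taken on
linear scale.

# Filtering

Three flag filters remove reversed decoys, potential contaminants and
groups identified only by modified peptides; a row carrying several
flags is counted once (contaminant takes precedence). The valid-value
rule keeps a protein, per comparison arm, when it is quantified in at
least 50% of the arm's DOL0 samples *and* at least 50% of its follow-up
samples. We read the "less than 50%" phrasing inclusively — exactly 50%
is kept — which maximizes retained data; the boundary matters rarely but
is pinned by a test. Filtering never creates or alters values, and no
imputation enters any statistical stage. For ordination only, a union
filter (pass in at least one arm) is applied across all samples.

# Batch correction

Samples processed on different LC columns / 96-well plates carry
location and scale artefacts. `correctBatch()` implements the familiar
empirical-Bayes location/scale adjustment: per protein, data are
standardized against an overall fit that protects biological covariates
(the pipeline protects DOL; sex is instead handled downstream in the
mixed model, because protecting many covariates in small arms invites
accidental aliasing); per-batch location `gamma` and scale `delta^2`
estimates are shrunk towards parametric priors (normal, inverse-gamma)
by iterated conditional modes (tolerance 1e-4, at most 100 iterations).
Unlike the reference implementation, every sum, mean and variance is
taken over observed entries only, so matrices with MNAR holes are
handled without imputation; proteins with fewer than two observed
entries in a batch are left unadjusted for that batch. Two deliberate
properties:

* after adjustment, each protein's grand mean over observed entries is
  restored exactly, so batch correction never relocates a protein;
* with `eb = FALSE` the method reduces to direct per-batch
  standardization, which equalizes empirical batch means exactly. With
  shrinkage on, a small per-protein residual batch difference remains
  *by design* (that is the bias-variance trade the EB prior makes); what
  correction removes completely is the systematic, across-protein batch
  shift. Tests therefore check the systematic residual, the variance
  ratio, grand-mean preservation, and exactness of the non-EB limit,
  and cross-check the EB path against the reference implementation on
  complete data.

Confounded layouts (a protected covariate aliased with batch) are
refused with the offending columns named, since correction would then
remove biology.

# Global distribution check

Before comparing groups we ask whether whole distributions differ
between DOLs, which would point at processing problems or argue for
quantile-type normalization. Each sample is summarized by 100 equally
spaced quantiles of its observed values; the statistic is the ratio of
between-group to within-group mean squared deviation of these quantile
vectors, and significance comes from label permutations with the
add-one estimator, `p = (1 + #{perm >= obs}) / (1 + n_perm)` (10000
permutations by default), so p is never 0. Permutation size is exact
under exchangeable samples; the paired design makes samples of one
participant correlated, which renders the test *conservative* (never
anticonservative) — acceptable for its role as a QC alarm. The size
calibration test therefore simulates exchangeable (subject-effect-free)
null cohorts.

# Imputation, quarantined to PCA

Statistical testing uses observed data only. For PCA, which needs a
complete matrix, missing entries are drawn in the QRILC style: per
sample, the mean and standard deviation of the complete intensity
distribution are estimated by regressing observed order statistics on
standard-normal quantiles with censoring-aware plotting positions (the
missing fraction occupies the lower tail); draws come from a normal
with that mean and `sd * tune_sigma` (default 0.3), truncated above at
the fitted distribution's `q` quantile (default 0.01). With these
defaults the truncated draws sit in a narrow band just below the 1%
quantile — the intended "signals from low-abundance proteins". Sampling
uses the inverse CDF in log space, which stays exact arbitrarily far
into the tail. The result carries an `imputed` provenance flag and
every statistical entry point refuses flagged matrices, so no imputed
value can leak into a test. PCA itself is protein-centered SVD without
unit-variance scaling (LFQ log2 intensities share a scale); scaling is
exposed as a flag, and whether the original analyses scaled is unknown
— the default is off and stated here.

# Paired differential abundance

For each follow-up day, intensity is modelled on that arm's samples as

$$y_{ij} = \beta_0 + \beta_{DOL}\,[\text{day} = d] + \text{covariates} + u_i + \varepsilon_{ij}$$

with a random participant intercept $u_i$; the reported log2 fold
change is $\beta_{DOL}$, and the test compares maximum-likelihood fits
with and without the DOL term (1 df likelihood ratio). The three
follow-up days are fit as three two-timepoint models rather than one
four-level model because each participant contributes only one
follow-up day, so a joint model would anyway decompose over disjoint
participant subsets.

Two numerical decisions matter:

* **Engine.** The default fitter maximizes the exact profile likelihood
  of the random-intercept model over the variance ratio (grid search,
  parabolic refinement in log space, one exact evaluation per protein;
  the OLS boundary is always evaluated, which is the variance-zero
  fallback). It matches `lme4::lmer` maximum likelihood to about 1e-5
  and is vectorized across proteins sharing a design, which makes
  thousand-protein simulation studies affordable; `engine = "lmer"` is
  available and the two are asserted equal in the tests.
* **Reference distribution.** In the balanced complete-pair case the
  LRT statistic is a monotone function of the paired t statistic,
  `stat = n log(1 + t^2/(n-1))`. Referring the back-transformed `t^2`
  to F(1, n−1) is exact there and remains a far better finite-sample
  reference in general: the asymptotic chi-square(1) tail is too light
  for cohorts of tens of pairs and measurably inflates the realized
  false discovery rate. The calibrated reference is the default; the
  asymptotic one is available as `p_reference = "chisq"`. With no
  covariates the coefficient equals the mean within-participant
  difference exactly, which the tests assert, and the raw paired mean
  is reported alongside the coefficient since it is unknowable which of
  the two a given published fold change denotes.

Per-day p-values are Benjamini–Hochberg adjusted across proteins
(per-day lists are the default; pooled adjustment is behind a flag),
and a protein is called significant only when q < 0.05 *and*
|log2FC| > 0.2 — both gates, always. Proteins with fewer than two
complete pairs are marked not testable. Because strict valid-value
filtering would discard proteins detected on only one day, a Fisher's
exact missingness analysis runs on the pre-filter matrix: per protein
and arm, a two-sided exact test on the 2x2 detected/undetected table.

# Trajectories, immunoglobulin kinetics, concordance

Per-participant change is `Delta = log2(follow-up) - log2(DOL0)` of the
same participant, undefined where either endpoint is missing. The
protein–protein correlation map uses pairwise-complete Pearson
correlations (entries with fewer than 6 complete pairs are undefined)
and average-linkage clustering on 1 − R with deterministic tie-breaks;
the screen against a target protein (for example an acute-phase marker)
reports the exact-t two-sided p and deliberately applies no multiplicity
correction, mirroring how such screens are usually reported — stated in
the output.

Maternal IgG decays first-order, `C(t) = C(0) 2^{-t/t_{1/2}}`, so
participant-level `Delta(t) = -t/t_{1/2}` on log2 scale with
`Delta(0) = 0` by construction. The apparent half-life estimator is
zero-intercept least squares of paired `Delta` on elapsed days,
`t_half = -1/slope`, which is exact on noise-free decay for any true
half-life and scale-invariant; a non-negative slope is flagged as no
measurable decay. The estimator form is our reconstruction — published
analyses state only the resulting value — and the participant-level
all-days variant is the default; a bootstrap over participants (2000
resamples, seeded) supplies the interval that point estimates usually
lack. iBAQ subclass ratios are normalized to IgG2 per sample (IgG3
renormalization is a consistent change of units, asserted exactly), and
newborn-versus-adult comparisons use Welch t-tests. The shipped adult
panel is synthetic (literature-like subclass ordering) and exists only
so examples and tests run without external data.

Protein–mRNA concordance correlates change-versus-DOL0 at two levels:
across individual matched samples, and across the three per-DOL mean
changes. Classification uses the DOL-average R against a 0.3 threshold,
because only that level reaches informative magnitudes; with three
points the correlation is intrinsically unstable, so the output carries
the point count instead of a p-value. RNA counts are normalized by
median-of-ratios size factors — a deliberate, documented stand-in for a
full count-model differential analysis, which is out of scope since
only `Delta` of normalized log counts is consumed.

# The synthetic cohort generator

`generateCohort()` produces the structure every stage assumes: 30
participants (10 per follow-up day, 60 samples), ~200 proteins with
log-normal baselines (log2 N(25, 2)), participant random effects (sd
0.5), residual noise (sd 0.3), trajectory classes (70% flat; 10% each
increasing, decreasing, acute-at-DOL1 with effect magnitudes uniform in
0.2–1.5 log2 — the non-flat magnitudes are calibration choices, since
no effect-size distribution is published), two batches (+0.4 log2,
scale 1.25 by default; the scale multiplies residual noise only,
matching the location/scale correction model), and logistic
left-censoring (threshold at the 0.15 intensity quantile, steepness 2
per log2 unit, giving realistic 15–25% MNAR missingness). The
immunoglobulin panel decays IgG1–4 with subclass half-lives (IgG1 at
the 21.1 d apparent value, IgG3 much shorter) and grows IgM and J chain
with a shared per-participant latent rate so their trajectories
correlate strongly. RNA counts are negative-binomial (size 50, typical
of deeply sequenced bulk RNA) around means engineered so each gene's
DOL-average change correlates with its partner protein's true change at
a configured target R — exactly orthogonalized for target 0. Defaults
emulate the study design: 7 strongly concordant gene–protein pairs and
23 clearly discordant ones among 30.

What passing tests do and do not show: the generator realizes the
model's own assumptions (Gaussian log2 intensities, additive batch
effects, logistic censoring, first-order Ig kinetics), so recovery
results demonstrate correctness of the implementation under those
assumptions — not robustness to interference, non-Gaussian tails,
shared-peptide effects, or batch-by-protein interactions found in real
LFQ data. Three-point concordance classification is only meaningful
against partner proteins with strong trajectories (|log2FC| ≳ 1);
against weak or flat proteins the DOL-average correlation is close to
noise, which is why the calibration test pairs genes with
strong-effect proteins and why real-data concordance claims deserve the
same caution.

# Problem sizes used by the validation suite

The suite recovers half-lives over 200 cohorts of 30 participants,
calibrates the null differential test on 100 cohorts of 2000 proteins
with 30 pairs per arm (the per-arm size at which the recovery band of
±0.15 log2 at residual sd 0.3 is attainable), checks the permutation
test's size over 500 exchangeable null cohorts at 200 permutations, and
verifies Fisher/BH/Pearson/PCA against exact enumeration oracles. These
sizes were chosen so each check estimates its quantity with useful
precision while the whole suite runs in minutes.

# Known limitations

Protein groups are treated as atomic; peptide-level evidence, shared
peptides and modification-site ambiguity are upstream concerns. The
batch model assumes location/scale artefacts only. The half-life
estimator assumes a common decay rate across participants and no
synthesis unless configured. Absolute concentration projection is a
multiplication by an externally supplied baseline, not a calibration
from iBAQ. The permutation QC test is conservative under the paired
design. Accession-scale reproduction of published cohort numbers
requires the deposited raw tables, which the package deliberately does
not bundle.
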