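---
title: "Methods: comorbidity subgroup discovery and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity subgroup discovery and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements,
the parameters that matter, and the design decisions taken where the
design was genuinely open.  It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The generative view of a diagnosis record

A patient's record is treated as a bag of disease-group "words".  Each
patient *d* has mixing proportions Θ_d over K latent comorbidity topics;
each topic Φ_k is a probability distribution over the V disease groups.
Each diagnosis event is generated topic-then-word.  The index disease
(asthma) is deliberately excluded from the vocabulary: it is the
stratifying label, and including it would let the model trivially separate
cases from controls rather than describe comorbidity structure.

Inference uses a hierarchical Dirichlet process so K is learnt.  The
sampler (`hdp_gibbs_run`) is a direct-assignment collapsed Gibbs sampler:
token-level topic indicators are resampled against global topic weights;
the weights themselves are resampled each sweep from
Chinese-restaurant table counts; empty topics are pruned and new topics
are born with stick-breaking weights.  Topics are extracted from the
*final* state rather than averaged across sweeps — posterior averaging of
topic matrices is ill-defined under label switching, and the ensemble plus
consensus step already averages across independent runs.

Sampler parameters, with defaults:

* `doc_concentration` (α = 1) — how strongly a record's topic mixture is
  pulled toward the corpus-level weights.
* `top_concentration` (γ = 1) — how readily brand-new topics appear.
* `topic_prior` (β = 0.05) — symmetric smoothing of topic rows; small
  values give sparse, well-separated comorbidity profiles.
* `max_iter` (500) — Gibbs sweeps; 500 converges comfortably on corpora
  of the scale used here (a few thousand records, ~20 events each), which
  we verified by the log-joint trajectory and by the insensitivity of the
  recovered topics between 300 and 500 sweeps.
* `min_topic_share` (0.002) — drops ephemeral topics holding less than
  this fraction of tokens at extraction.

No concentration values were published for the reference workflow; these
defaults are deliberate, config-exposed choices validated by the recovery
experiments below.

## Ensemble and consensus

One Gibbs run on one subsample is stochastic: topic counts and shapes vary
across runs.  The pipeline therefore fits R independent runs on random
patient subsamples (defaults: R = 10 runs of 1000 patients at desk scale,
mirroring the many-runs-on-subsamples design at a 10× smaller replicate
count) and pools all resulting topic points.  Pairwise dissimilarity
between topic points is Jensen–Shannon divergence with log base 2, so
values live in [0, 1] (the base is a convention choice; it is recorded
here and in the output metadata).

The pooled points are clustered with HDBSCAN on the precomputed divergence
matrix.  No HDBSCAN implementation ships with the R stack this package
targets, so the algorithm is implemented in full: core distances at
`min_samples` neighbors, mutual-reachability distances, a minimum spanning
tree, the single-linkage hierarchy, the condensed tree at
`min_cluster_size`, cluster stability as condensed-tree persistence
(λ = 1/distance), and excess-of-mass cluster selection with the root
cluster excluded.  `min_samples` is tied to `min_cluster_size` by default
so the method has the single knob that the stability rule describes.

A candidate subgroup counts as stable only if it encloses at least
`min_points` topic points — i.e., if essentially the same comorbidity
pattern recurred in at least that many ensemble runs.  Our desk-scale
default ties `min_points` to half the ensemble runs, the same ratio as the
reference workflow's 50-points-in-100-runs rule.  The threshold can also
be chosen by the elbow rule (`stability_elbow`): mean subgroup stability
is computed at each candidate threshold and the chosen elbow is the
interior point where the curve's increase switches from fast to slow,
operationalized as the maximum drop in discrete slope
(y_i − y_{i−1}) − (y_{i+1} − y_i).  A flat curve has no elbow; the
smallest threshold is returned with a warning.

Subgroups are summarized by per-disease five-number profiles (min, Q1,
median, Q3, max over enclosed points).  The representative vector is the
renormalized median profile; the subgroup is named after its
highest-median disease group.  Cross-cohort replication
(`match_profiles_across_cohorts`) computes Pearson correlations between
all pairs of median profiles over all V dimensions, matches greedily
one-to-one by descending correlation, and flags replication when the
correlation test survives Benjamini–Hochberg adjustment across all
candidate pairs; the greedy scheme is our choice — only the correlation
criterion itself was prescribed.

## Assignment

Individuals are assigned by expressing their normalized diagnosis
frequency vector as a nonnegative linear combination of subgroup
representatives and taking the subgroup with the largest coefficient.
The nonnegativity constraint is a design decision: mixing proportions are
inherently nonnegative, and unconstrained least squares can produce
uninterpretable negative loadings (an unconstrained mode is available via
`nonneg = FALSE`).  The count vector is normalized to sum 1 before
fitting so residuals are comparable across patients, and the argmax label
is invariant to any positive rescaling of the coefficients, so no simplex
renormalization of θ is needed before the argmax.  Ties break toward the
lowest subgroup index and are counted.  Controls are assigned with the
same representatives as cases, so every subgroup has its own control
stratum.

## Stratified association scan

QC per SNP: call rate > 0.95, MAF > 0.01, exact Hardy–Weinberg p > 10⁻⁶.
The HWE test is the exact conditional test (no mid-p), chosen over the
chi-square for robustness at low MAF; a chi-square mode exists behind a
flag.  The association model is a maximum-likelihood logistic regression
of case status on additive dosage plus covariates; missing dosages are
mean-imputed per SNP (a logged convention — the reference QC text is
silent).  The IRLS solver is compiled code because the power-matching
stage refits the same model tens of thousands of times; its estimates are
asserted equal to `stats::glm` in the test suite.  Quasi-separated or
non-converged fits are flagged and excluded rather than reported.

Independent loci are defined by greedy distance clumping (default ±1 Mb)
— no LD panel ships with the package, so r²-based definitions are out of
scope.  Significance conventions: suggestive p < 10⁻⁵, genome-wide
p < 5×10⁻⁸.  Heterogeneity of lead-SNP effects across subgroups uses
Cochran's Q with inverse-variance weights.

## Meta-analysis and replication

Fixed-effects inverse-variance pooling: β̂_F = Σwᵢβ̂ᵢ/Σwᵢ,
var(β̂_F) = 1/Σwᵢ, wᵢ = 1/se²ᵢ.  Replication is direction-aware: the
one-sided p value P(Z ≥ s·z_F) with s the discovery sign, adjusted by
Benjamini–Hochberg *across the attempted set only* and flagged at
FDR < 0.10.  An association is attemptable only if at least one
replication cohort allocated more than 100 cases to the stratum.  Cohorts
missing a SNP are dropped from that SNP's pool (LD-proxy substitution
needs external panels and is out of scope); the number of contributing
studies is recorded.  FDR is pooled across strata rather than computed
per stratum — the single-adjustment reading of the procedure.

## Power-matched comparison of subgroup and whole-group signals

Z = β̂/(σ̂/√n) scales with √n at fixed effect, with n the effective size
1/(1/n_case + 1/n_ctrl), so a subgroup Z and a whole-group Z are not
comparable.  The whole-group association is therefore re-estimated on
subsamples shrunk to the subgroup's case and control counts with the
stratum composition proportionally preserved.  Allocation uses
largest-remainder rounding (ties to the lowest stratum index) — exact
proportionality up to one unit, summing exactly to the target.  The
default replicate count is configurable; tests and the acceptance script
use R = 2000 rather than the reference 20,000 for desk-scale runtime,
which changes the resolution floor of the empirical p (2/(R+1)) but not
the operating characteristics at the FDR thresholds used.

The empirical two-tailed p doubles the smaller one-sided add-one count:
p = min(1, 2(min(#{z ≥ z_s}, #{z ≤ z_s}) + 1)/(R + 1)).  Doubling a
one-sided count was chosen over folding |Z| because it is exact for
asymmetric projected distributions; the add-one keeps p away from zero.
Candidates are subgroup associations below the suggestive threshold;
flags are Benjamini–Hochberg FDR < 0.05 across candidates.

## Differential expression and phenotype slopes

Counts are modeled per gene with a log-link negative-binomial GLM, log
size factors (median-of-ratios) as offsets, and covariates (age, sex,
ethnicity).  Dispersion is estimated per gene by maximum likelihood
(floored at 10⁻⁸) with a method-of-moments fallback — deliberately
without shrinkage-to-trend, which the simple NB-family description does
not license; at the sample sizes used (tens per arm) per-gene ML is
adequate, as the calibration tests show.  The group coefficient is
reported as log2 fold change with a two-sided Wald test; each contrast
side requires at least five samples.

Phenotypes are min-max normalized to [0, 1] before fitting so slope
estimates are comparable across phenotypes.  Per (phenotype, stratum),
a logistic regression of case status on the normalized phenotype plus
covariates yields the slope β_i; the whole-population slope β₀ is the
benchmark.  Heterogeneity is flagged by the normal contrast
z = (β_i − β₀)/√(se²_i + se²₀) with BH FDR.  This replaces an empirical
Bayes multivariate shrinkage step in the reference workflow; the normal
contrast preserves the step's intent (flag β_i deviating from β₀) and is
*conservative*, because each subgroup is a subset of the benchmark
population and the two estimates are positively correlated, making the
variance sum an over-estimate.

Distribution similarity diagnostics use the overlap of two Gaussian KDEs
(Silverman bandwidth) on a shared grid spanning both samples ±3
bandwidths, integrated by the trapezoid rule on ≥512 points: 1 for
identical distributions, 0 for disjoint ones.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated:

* Diagnosis records: V = 60 disease groups, K = 5 topics drawn from a
  symmetric Dirichlet(0.1) with a minimum pairwise JSD of 0.05 enforced by
  resampling; per-patient mixing Dirichlet(0.3) by default (0.1 for the
  separation fixture, 0.05 for the concentrated-assignment fixture);
  record lengths negative-binomial (mean 20, size 5, minimum one comorbid
  event) — overdispersed visit counts are realistic and stress the
  pipeline; event dates uniform over a five-year enrollment window.
* The asthma label has base rate 0.3 with subgroup-dependent log-odds
  offsets spread over [−0.5, 0.5].
* Genotypes: MAF uniform on [0.1, 0.5], Hardy–Weinberg sampling, and a
  logistic case model with planted (SNP, subgroup) log-odds ratios plus
  weak sex/age effects.
* Phenotypes: standard normal, with planted subgroup-specific slopes
  entering the case model on the min-max-normalized scale.
* Expression: NB counts, log-normal baselines around 100, dispersion 0.1,
  size factors in [0.7, 1/0.7], planted log2 fold changes in
  case-by-subgroup cells.

Master-seed splitting: every stochastic stage derives a child seed as
`(seed·48271 + 97·stream) mod (2³¹−1)`, so identical configurations give
byte-identical cohorts while stages stay independent.

What the generator does *not* emulate: claims-specific structure (payer
fields, procedures, prescriptions), ICD hierarchy and coding noise,
linkage disequilibrium between SNPs, population stratification,
relatedness, gene–gene correlation, and phenotype measurement artifacts.
Passing tests therefore demonstrate the statistical machinery under the
model's own assumptions, not robustness to the full messiness of claims
or biobank data.

## Problem sizes and numerical conventions

Tests and the acceptance script use desk-scale sizes chosen to make the
statistical properties sharp while completing quickly: subgroup-recovery
experiments use 2000-patient cohorts with 10 ensemble runs of 1000
patients (20 seeds); association calibration uses 200 null SNPs at
n = 2000; the power-matching experiment places ~3000 individuals in the
focal stratum (a 15000-person cohort over five equal subgroups), where a
planted subgroup-specific ln OR of 0.4 is reliably suggestive while a
homogeneous effect of the same size is not flagged; differential
expression uses 20-gene panels with ~40 samples per arm across 20 seeds
and a 500-gene null panel.  Degenerate inputs fail loudly and early:
zero-token corpora, all-zero count vectors, constant phenotypes,
zero-variance KDE samples, non-positive standard errors and unparseable
dates are all explicit errors naming the offending constraint, not NaN
propagation.
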