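# endotyper

Discovering disease subgroups ("endotypes") from diagnosis records, and
characterizing them genetically and phenotypically.

Large claims databases record which diagnoses co-occur in the same person.
For a heterogeneous index disease such as asthma, the pattern of comorbid
diagnoses carries information about the underlying disease mechanism:
patients whose records are dominated by psychiatric, cardiovascular or
musculoskeletal comorbidities may represent biologically distinct subgroups
that respond differently to treatment.  `endotyper` implements a complete,
testable pipeline that turns raw dated ICD codes into such subgroups and
then asks whether the subgroups differ genetically and phenotypically.

## The method

1. **Preprocessing** (`records`): per-day deduplication of codes, asthma
   labeling from the ICD-9-CM range 493.00–493.99 and ICD-10-CM range
   J45.0–J45.998, cohort filters (age 15–70, at least one comorbid
   diagnosis), and the patient × disease-group count matrix
   *W<sub>d,n</sub>*.
2. **Topic modeling** (`topics`): a hierarchical Dirichlet process topic
   model fitted by collapsed Gibbs sampling treats each patient's record as
   a document over disease-group "words"; a topic Φ<sub>k</sub> is a
   probability distribution over disease groups (a comorbidity pattern) and
   the number of topics is inferred.  The model is run as an ensemble over
   random patient subsamples.
3. **Consensus** (`consensus`): pooled topic points are clustered by
   HDBSCAN on their pairwise Jensen–Shannon divergences (base 2, range
   [0, 1]); a cluster of topic points is a *subgroup* only if it recurs
   across enough ensemble runs (the "minimum cluster points" stability
   rule, selectable by an elbow criterion on mean cluster stability).  Each
   subgroup is summarized by per-disease five-number profiles.
4. **Assignment** (`assign`): any individual — case or control — is
   assigned to the subgroup with the largest coefficient in the nonnegative
   least-squares decomposition of their diagnosis frequency vector over the
   subgroup representatives (the estimate of Θ<sub>d,k</sub>).
5. **Stratified GWAS** (`gwas`): within each subgroup, logistic regression
   of case status on additive allele dosage with covariates, after SNP QC
   (call rate > 0.95, MAF > 0.01, exact HWE p > 10⁻⁶); distance-based
   clumping to independent lead SNPs; Cochran's Q for effect-size
   heterogeneity across subgroups; Benjamini–Hochberg FDR.
6. **Meta-analysis** (`meta`): fixed-effects inverse-variance pooling
   across replication cohorts, β̂_F = Σwᵢβ̂ᵢ / Σwᵢ with wᵢ = 1/se²ᵢ and
   var(β̂_F) = 1/Σwᵢ, with direction-aware one-sided replication p values
   and FDR < 0.10.
7. **Power matching** (`powerproj`): a subgroup Z score cannot be compared
   with the whole-group Z because Z = β̂/(σ̂/√n) scales with √n (with n the
   effective size 1/(1/n_case + 1/n_ctrl)).  The whole-group association is
   therefore re-estimated on stratified subsamples shrunk to the subgroup's
   case/control sizes; the observed subgroup Z is tested against the
   empirical distribution of projected Z scores (two-tailed, add-one), FDR
   < 0.05.
8. **Downstream** (`downstream`): negative-binomial GLM differential
   expression with median-of-ratios size factors and Wald tests;
   phenotype-slope scans on min-max-normalized phenotypes with a
   benchmark-deviation test against the whole-group slope; kernel-density
   overlap diagnostics.

A synthetic-data module (`synth`) generates seeded cohorts with known
ground truth — Dirichlet-mixed multinomial diagnosis records, HWE
genotypes with planted subgroup-specific log-odds ratios, phenotypes with
planted slopes, NB counts with planted log2 fold changes — so every stage
is testable without access to claims or biobank data.

## Worked example

```r
library(endotyper)

cfg <- synth_config(seed = 42, n_patients = 2000, vocab_size = 60,
                    n_topics = 5, dirichlet_doc_conc = 0.1)
topics  <- generate_topics(cfg)                    # planted comorbidity patterns
sim     <- generate_diagnosis_records(cfg, topics)
mapping <- demo_code_mapping(cfg$vocab_size)
W       <- build_count_matrix(apply_cohort_filters(sim$corpus), mapping)

pts  <- run_ensemble(W, hdp_config(ensemble_runs = 10, subsample_size = 1000,
                                   max_iter = 500, seed = 42))
cons <- hdbscan_consensus(pts, min_points = 5)
length(cons$subgroups)
#> [1] 5
round(sapply(cons$subgroups, function(s)
  min(apply(topics, 1, js_divergence, q = s$representative))), 3)
#> [1] 0.006 0.016 0.006 0.006 0.006
```

Ten subsampled HDP runs produce ~60 topic points; consensus clustering
recovers exactly the five planted comorbidity patterns, each within
Jensen–Shannon divergence 0.02 of its planted counterpart.  Closed-form
spot checks:

```r
js_divergence(c(1, 0), c(0.5, 0.5))   #> 0.3112781
effective_n(100, 300)                 #> 75
cochran_q(c(0.1, 0.3), c(0.1, 0.1))$Q #> 2
```

The whole pipeline can also be driven from a single YAML configuration via
`run_pipeline("config.yaml")`, which writes each stage's TSV outputs and a
JSON run manifest, and skips the rerun when nothing changed.

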