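# Synthetic cohort generator with known ground truth.
#
# Emulates the statistical structure the pipeline assumes: multinomial
# diagnosis records drawn from K latent comorbidity topics with Dirichlet
# mixing, Hardy-Weinberg biallelic genotypes with subgroup-specific log-odds
# effects on a binary asthma label, quantitative phenotypes with
# subgroup-specific slopes on asthma risk, and negative-binomial expression
# counts with planted log2 fold changes.

#' Configuration for the synthetic cohort generator
#'
#' The defaults define the desk-scale study conditions used throughout the
#' package's tests: a vocabulary of 60 comorbid disease groups, five latent
#' comorbidity topics, overdispersed record lengths, and a 30% asthma base
#' rate so stratified case-control scans have cases to work with.
#'
#' @param seed master seed; all stage seeds derive from it via a fixed
#'   splitting rule, so identical configurations give identical cohorts.
#' @param n_patients number of patients.
#' @param vocab_size number of comorbid disease groups V (the index disease,
#'   asthma, is excluded from the vocabulary).
#' @param n_topics number of latent comorbidity topics K.
#' @param dirichlet_topic_conc symmetric Dirichlet concentration for topic
#'   rows over the vocabulary; small values give sparse, well-separated
#'   topics.
#' @param dirichlet_doc_conc symmetric Dirichlet concentration for per-patient
#'   topic proportions; small values concentrate each patient on one topic.
#' @param record_length_mean,record_length_dispersion negative-binomial mean
#'   and size for the number of diagnosis events per patient (minimum 1).
#' @param asthma_base_rate marginal probability of the asthma label.
#' @param asthma_subgroup_logodds optional length-K vector of per-subgroup
#'   shifts (log-odds) of the asthma rate; defaults to an even spread over
#'   `[-0.5, 0.5]` so the label rate differs across subgroups.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range minor-allele-frequency interval, within (0, 0.5].
#' @param planted_effects list of `list(snp, subgroup, ln_or)` entries;
#'   `subgroup = "all"` plants a homogeneous effect.
#' @param n_phenotypes number of quantitative phenotypes.
#' @param planted_slopes list of `list(phenotype, subgroup, slope)` entries
#'   (slope of asthma log-odds per unit of the min-max-normalized phenotype).
#' @param n_genes,nb_dispersion expression-panel size and NB dispersion
#'   (variance = mu + dispersion * mu^2).
#' @param planted_l2fc list of `list(gene, subgroup, l2fc)` entries.
#' @param n_cohorts number of cohorts for multi-cohort generation.
#' @param window_start,window_end enrollment window for event dates.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_patients = 2000L,
                         vocab_size = 60L,
                         n_topics = 5L,
                         dirichlet_topic_conc = 0.1,
                         dirichlet_doc_conc = 0.3,
                         record_length_mean = 20,
                         record_length_dispersion = 5,
                         asthma_base_rate = 0.3,
                         asthma_subgroup_logodds = NULL,
                         n_snps = 200L,
                         maf_range = c(0.1, 0.5),
                         planted_effects = list(),
                         n_phenotypes = 4L,
                         planted_slopes = list(),
                         n_genes = 200L,
                         nb_dispersion = 0.1,
                         planted_l2fc = list(),
                         n_cohorts = 2L,
                         window_start = as.Date("2008-01-01"),
                         window_end = as.Date("2012-12-31")) {
  stopifnot_scalar_prob(asthma_base_rate, "asthma_base_rate")
  if (n_topics < 1L) stop("n_topics must be >= 1", call. = FALSE)
  if (vocab_size < n_topics) stop("vocab_size must be >= n_topics", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (dirichlet_topic_conc <= 0 || dirichlet_doc_conc <= 0) {
    stop("Dirichlet concentrations must be positive", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (is.null(asthma_subgroup_logodds)) {
    asthma_subgroup_logodds <- if (n_topics == 1L) 0 else
      seq(-0.5, 0.5, length.out = n_topics)
  }
  stopifnot(length(asthma_subgroup_logodds) == n_topics)
  for (pe in planted_effects) {
    if (pe$snp > n_snps) stop("planted snp index exceeds n_snps", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    vocab_size = as.integer(vocab_size), n_topics = as.integer(n_topics),
    dirichlet_topic_conc = dirichlet_topic_conc,
    dirichlet_doc_conc = dirichlet_doc_conc,
    record_length_mean = record_length_mean,
    record_length_dispersion = record_length_dispersion,
    asthma_base_rate = asthma_base_rate,
    asthma_subgroup_logodds = asthma_subgroup_logodds,
    n_snps = as.integer(n_snps), maf_range = maf_range,
    planted_effects = planted_effects,
    n_phenotypes = as.integer(n_phenotypes), planted_slopes = planted_slopes,
    n_genes = as.integer(n_genes), nb_dispersion = nb_dispersion,
    planted_l2fc = planted_l2fc, n_cohorts = as.integer(n_cohorts),
    window_start = window_start, window_end = window_end
  )
  class(cfg) <- "synth_config"
  cfg
}

# Stream indices for the seed-splitting rule (one per stochastic stage).
.synth_streams <- c(topics = 1L, records = 2L, genotypes = 3L,
                    phenotypes = 4L, expression = 5L, cohorts = 6L)

#' Disease-group code for a vocabulary index
#'
#' Synthetic diagnosis codes use an ICD-9-CM-style "NNN.NN" layout in the
#' 101-400 block, well away from the asthma range 493.00-493.99.
#' @param g 1-based group index.
#' @keywords internal
synth_group_code <- function(g) {
  sprintf("%03d.%02d", 101L + (g - 1L) %/% 100L, (g - 1L) %% 100L)
}

#' Generate well-separated topic distributions
#'
#' Draws `n_topics` rows from a symmetric Dirichlet over the vocabulary and
#' resamples until every pair of rows differs by Jensen-Shannon divergence
#' greater than `min_jsd`, so the planted topics are identifiable.
#'
#' @param cfg a [synth_config()].
#' @param min_jsd minimum pairwise JSD enforced between topic rows.
#' @param max_attempts resampling budget before giving up.
#' @return a `n_topics x vocab_size` matrix with rows on the simplex.
#' @export
generate_topics <- function(cfg, min_jsd = 0.05, max_attempts = 500L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(child_seed(cfg$seed, .synth_streams[["topics"]]))
  K <- cfg$n_topics; V <- cfg$vocab_size
  for (attempt in seq_len(max_attempts)) {
    phi <- t(vapply(seq_len(K), function(k) {
      rdirichlet_one(rep(cfg$dirichlet_topic_conc, V))
    }, numeric(V)))
    if (K == 1L) return(phi)
    d <- pairwise_divergence(phi)
    if (min(d[upper.tri(d)]) > min_jsd) return(phi)
  }
  stop(sprintf(
    paste0("could not draw %d topics over %d diseases with pairwise ",
           "Jensen-Shannon divergence > %g after %d attempts; ",
           "lower dirichlet_topic_conc or min_jsd"),
    K, V, min_jsd, max_attempts), call. = FALSE)
}

#' Generate dated diagnosis records from latent comorbidity topics
#'
#' Per patient: topic proportions `theta ~ Dirichlet(alpha)`, a record length
#' from a negative binomial (minimum one comorbid event), and each diagnosis
#' drawn topic-then-disease.  Events receive dates uniform over the
#' enrollment window.  The asthma label is drawn with a subgroup-dependent
#' rate, and asthma cases additionally receive an asthma code event (493.00),
#' which downstream preprocessing excludes from the comorbidity vocabulary.
#'
#' @param cfg a [synth_config()].
#' @param topics a `K x V` simplex matrix, e.g. from [generate_topics()].
#' @param id_prefix prefix for patient identifiers.
#' @return a list with `corpus` (a `diagnosis_corpus`, see [records]) and
#'   `truth` (a `synth_truth` with the planted parameters).
#' @export
generate_diagnosis_records <- function(cfg, topics, id_prefix = "P") {
  stopifnot(inherits(cfg, "synth_config"),
            is.matrix(topics), ncol(topics) == cfg$vocab_size)
  if (!all(apply(topics, 1L, is_simplex))) {
    stop("topic rows must lie on the simplex", call. = FALSE)
  }
  set.seed(child_seed(cfg$seed, .synth_streams[["records"]]))
  n <- cfg$n_patients; K <- nrow(topics); V <- cfg$vocab_size

  theta <- t(vapply(seq_len(n), function(i) {
    rdirichlet_one(rep(cfg$dirichlet_doc_conc, K))
  }, numeric(K)))
  subgroup <- max.col(theta, ties.method = "first")

  n_events <- pmax(1L, stats::rnbinom(n, mu = cfg$record_length_mean,
                                      size = cfg$record_length_dispersion))
  # Asthma label with subgroup-dependent rate around the base rate.
  lp <- stats::qlogis(cfg$asthma_base_rate) + cfg$asthma_subgroup_logodds[subgroup]
  asthma <- stats::rbinom(n, 1L, stats::plogis(lp)) == 1L

  patient_id <- sprintf("%s%05d", id_prefix, seq_len(n))
  sex <- stats::rbinom(n, 1L, 0.5)
  window_days <- as.integer(cfg$window_end - cfg$window_start)
  age_at_start <- stats::runif(n, 16, 69)
  birth_year <- as.integer(format(cfg$window_start, "%Y")) -
    as.integer(floor(age_at_start))

  total <- sum(n_events)
  pid_col <- rep(patient_id, n_events)
  z <- integer(total); w <- integer(total)
  idx <- 1L
  for (i in seq_len(n)) {
    m <- n_events[i]
    zi <- sample.int(K, m, replace = TRUE, prob = theta[i, ])
    wi <- vapply(zi, function(k) {
      sample.int(V, 1L, prob = topics[k, ])
    }, integer(1L))
    z[idx:(idx + m - 1L)] <- zi
    w[idx:(idx + m - 1L)] <- wi
    idx <- idx + m
  }
  dates <- cfg$window_start + sample.int(window_days + 1L, total, replace = TRUE) - 1L
  events <- data.frame(
    patient_id = pid_col,
    date = dates,
    code = synth_group_code(w),
    code_system = "ICD-9-CM",
    stringsAsFactors = FALSE
  )
  # Asthma cases carry an asthma code event on a date inside the window.
  case_ids <- patient_id[asthma]
  if (length(case_ids)) {
    asthma_events <- data.frame(
      patient_id = case_ids,
      date = cfg$window_start +
        sample.int(window_days + 1L, length(case_ids), replace = TRUE) - 1L,
      code = "493.00",
      code_system = "ICD-9-CM",
      stringsAsFactors = FALSE
    )
    events <- rbind(events, asthma_events)
  }
  events <- events[order(events$patient_id, events$date, events$code), ]
  rownames(events) <- NULL

  patients <- data.frame(
    patient_id = patient_id, sex = sex, birth_year = birth_year,
    asthma = asthma, stringsAsFactors = FALSE
  )
  corpus <- new_diagnosis_corpus(patients, events)
  truth <- structure(list(
    true_topics = topics, true_theta = theta, true_subgroup = subgroup,
    true_snp_effects = cfg$planted_effects, true_slopes = cfg$planted_slopes,
    true_l2fc = cfg$planted_l2fc, seed = cfg$seed
  ), class = "synth_truth")
  list(corpus = corpus, truth = truth)
}

#' Generate Hardy-Weinberg genotypes with planted subgroup-specific effects
#'
#' Per SNP the minor-allele frequency is uniform over `maf_range` and
#' genotypes are Binomial(2, maf), i.e. Hardy-Weinberg proportions.  The
#' asthma label is regenerated from a logistic model whose linear predictor
#' contains the planted (SNP, subgroup) log-odds-ratio terms plus weak sex
#' and age covariate effects, so the genotype table and label are mutually
#' consistent for association testing.
#'
#' @param cfg a [synth_config()].
#' @param truth a `synth_truth` carrying the subgroup labels.
#' @return a list with `dosages` (n_patients x n_snps integer matrix),
#'   `case` (logical), `covariates` (data.frame with sex, age), `maf`
#'   (length n_snps), and `snp_info` (chrom/pos/ref/alt).
#' @export
generate_genotypes <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  for (pe in cfg$planted_effects) {
    if (pe$snp > cfg$n_snps) stop("planted snp index exceeds n_snps", call. = FALSE)
  }
  set.seed(child_seed(cfg$seed, .synth_streams[["genotypes"]]))
  n <- length(truth$true_subgroup); m <- cfg$n_snps
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  dosages <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)

  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 16, 69)
  lp <- rep(stats::qlogis(cfg$asthma_base_rate), n) +
    0.1 * sex + 0.1 * (age - mean(age)) / stats::sd(age)
  for (pe in cfg$planted_effects) {
    hit <- if (identical(pe$subgroup, "all")) rep(TRUE, n) else
      truth$true_subgroup == pe$subgroup
    lp[hit] <- lp[hit] + pe$ln_or * dosages[hit, pe$snp]
  }
  case <- stats::rbinom(n, 1L, stats::plogis(lp)) == 1L
  snp_info <- data.frame(
    chrom = "1",
    pos = seq_len(m) * 100000L,  # 100 kb spacing, one synthetic chromosome
    id = sprintf("snp%04d", seq_len(m)),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  list(dosages = dosages, case = case,
       covariates = data.frame(sex = sex, age = age), maf = maf,
       snp_info = snp_info)
}

#' Generate quantitative phenotypes with subgroup-specific asthma slopes
#'
#' Phenotypes are standard normal; the asthma label is drawn from a logistic
#' model whose linear predictor adds the planted subgroup-specific slopes
#' applied to the min-max-normalized phenotype values, matching how the
#' phenotype-slope scan will analyse them.
#'
#' @inheritParams generate_genotypes
#' @return list with `phenotypes` (n x n_phenotypes matrix), `case`
#'   (logical), `covariates` (sex, age).
#' @export
generate_phenotypes <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  set.seed(child_seed(cfg$seed, .synth_streams[["phenotypes"]]))
  n <- length(truth$true_subgroup)
  ph <- matrix(stats::rnorm(n * cfg$n_phenotypes), nrow = n,
               dimnames = list(NULL, sprintf("pheno%02d", seq_len(cfg$n_phenotypes))))
  lp <- rep(stats::qlogis(cfg$asthma_base_rate), n)
  for (ps in cfg$planted_slopes) {
    x <- minmax_normalize(ph[, ps$phenotype])
    hit <- truth$true_subgroup == ps$subgroup
    lp[hit] <- lp[hit] + ps$slope * (x[hit] - 0.5)
  }
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 16, 69)
  case <- stats::rbinom(n, 1L, stats::plogis(lp)) == 1L
  list(phenotypes = ph, case = case,
       covariates = data.frame(sex = sex, age = age))
}

#' Generate a negative-binomial expression count matrix
#'
#' Counts are NB with mean `baseline * 2^(l2fc * indicator) * size_factor`,
#' where the indicator marks asthma cases in the planted subgroup.  Baselines
#' are log-normal around 100 counts and per-sample size factors emulate
#' sequencing-depth variation.
#'
#' @inheritParams generate_genotypes
#' @param case optional logical vector of asthma labels for the expression
#'   samples; defaults to a fresh draw at the configured base rate.
#' @return list with `counts` (genes x samples integer matrix),
#'   `size_factors_true`, `case`, `covariates` (age, sex, ethnicity).
#' @export
generate_expression_counts <- function(cfg, truth, case = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  set.seed(child_seed(cfg$seed, .synth_streams[["expression"]]))
  n <- length(truth$true_subgroup); G <- cfg$n_genes
  if (is.null(case)) case <- stats::rbinom(n, 1L, cfg$asthma_base_rate) == 1L
  baseline <- exp(stats::rnorm(G, log(100), 1))
  sf <- exp(stats::runif(n, log(0.7), log(1 / 0.7)))
  l2fc_mat <- matrix(0, nrow = G, ncol = n)
  for (pf in cfg$planted_l2fc) {
    hit <- case & truth$true_subgroup == pf$subgroup
    l2fc_mat[pf$gene, hit] <- pf$l2fc
  }
  mu <- outer(baseline, sf) * 2^l2fc_mat
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = G,
                   dimnames = list(sprintf("gene%04d", seq_len(G)),
                                   sprintf("S%05d", seq_len(n))))
  list(counts = counts, size_factors_true = sf, case = case,
       covariates = data.frame(
         age = stats::runif(n, 16, 69),
         sex = stats::rbinom(n, 1L, 0.5),
         ethnicity = sample(c("A", "B", "C"), n, replace = TRUE,
                            prob = c(0.6, 0.25, 0.15))
       ))
}

#' Generate several cohorts sharing the same latent topics
#'
#' Each cohort is an independent draw of patients from the same topic matrix,
#' with a cohort-specific child seed and disjoint patient-id prefixes.
#'
#' @param cfg a [synth_config()] with `n_cohorts >= 2`.
#' @return list of `list(corpus, truth)` entries of length `n_cohorts`.
#' @export
generate_multi_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_cohorts < 2L) stop("n_cohorts must be >= 2", call. = FALSE)
  topics <- generate_topics(cfg)
  lapply(seq_len(cfg$n_cohorts), function(j) {
    cfg_j <- cfg
    cfg_j$seed <- child_seed(cfg$seed, .synth_streams[["cohorts"]] * 100L + j)
    generate_diagnosis_records(cfg_j, topics, id_prefix = sprintf("C%d_P", j))
  })
}

#' Write / read the ground-truth object as JSON
#'
#' @param truth a `synth_truth`.
#' @param path output path.
#' @return `path`, invisibly (`read_truth` returns the `synth_truth`).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  obj <- list(
    true_topics = unname(truth$true_topics),
    true_theta = unname(truth$true_theta),
    true_subgroup = truth$true_subgroup,
    true_snp_effects = truth$true_snp_effects,
    true_slopes = truth$true_slopes,
    true_l2fc = truth$true_l2fc,
    seed = truth$seed
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  relist_planted <- function(x) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) return(list())
    if (is.data.frame(x)) return(lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])))
    x
  }
  structure(list(
    true_topics = as.matrix(obj$true_topics),
    true_theta = as.matrix(obj$true_theta),
    true_subgroup = as.integer(obj$true_subgroup),
    true_snp_effects = relist_planted(obj$true_snp_effects),
    true_slopes = relist_planted(obj$true_slopes),
    true_l2fc = relist_planted(obj$true_l2fc),
    seed = as.integer(obj$seed)
  ), class = "synth_truth")
}

#' Write the synthetic cohort to the pipeline's on-disk formats
#'
#' Emits the diagnosis TSV (patient_id, date, code, code_system), the
#' code-to-group mapping TSV, a patient metadata TSV, and (when genotypes are
#' given) a VCF v4.2 plus covariate TSV.
#'
#' @param sim result of [generate_diagnosis_records()].
#' @param dir output directory, created if missing.
#' @param cfg the [synth_config()] used.
#' @param geno optional result of [generate_genotypes()].
#' @return named character vector of written paths.
#' @export
write_synth_cohort <- function(sim, dir, cfg, geno = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    diagnoses = file.path(dir, "diagnoses.tsv"),
    mapping = file.path(dir, "mapping.tsv"),
    patients = file.path(dir, "patients.tsv"),
    truth = file.path(dir, "truth.json")
  )
  ev <- sim$corpus$events
  ev$date <- format(ev$date, "%Y-%m-%d")
  utils::write.table(ev, paths[["diagnoses"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(demo_code_mapping(cfg$vocab_size), paths[["mapping"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$corpus$patients, paths[["patients"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth(sim$truth, paths[["truth"]])
  if (!is.null(geno)) {
    paths <- c(paths, vcf = file.path(dir, "genotypes.vcf"),
               covariates = file.path(dir, "covariates.tsv"))
    write_vcf(geno$dosages, geno$snp_info,
              sample_ids = sim$corpus$patients$patient_id, path = paths[["vcf"]])
    cov <- cbind(patient_id = sim$corpus$patients$patient_id,
                 geno$covariates, case = as.integer(geno$case))
    utils::write.table(cov, paths[["covariates"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}

#' Demo code-to-disease-group mapping
#'
#' One synthetic ICD-9-CM-style code per disease group; group indices are
#' 1-based.
#'
#' @param vocab_size number of groups.
#' @return data.frame with columns code, group_index, label.
#' @export
demo_code_mapping <- function(vocab_size) {
  data.frame(
    code = synth_group_code(seq_len(vocab_size)),
    group_index = seq_len(vocab_size),
    label = sprintf("disease_group_%03d", seq_len(vocab_size)),
    stringsAsFactors = FALSE
  )
}
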