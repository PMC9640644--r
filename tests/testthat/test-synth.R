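test_that("topic generation is deterministic, simplex-valued and separated", {
  cfg <- synth_config(seed = 7L, vocab_size = 60L, n_topics = 5L)
  t1 <- generate_topics(cfg)
  t2 <- generate_topics(cfg)
  expect_identical(t1, t2)
  expect_equal(rowSums(t1), rep(1, 5), tolerance = 1e-9)
  d <- pairwise_divergence(t1)
  expect_gt(min(d[upper.tri(d)]), 0.05)

  single <- generate_topics(synth_config(seed = 1L, n_topics = 1L,
                                         vocab_size = 10L))
  expect_equal(dim(single), c(1L, 10L))
  expect_equal(sum(single), 1, tolerance = 1e-12)

  # impossible separation fails with a message naming the constraint
  expect_error(
    generate_topics(synth_config(seed = 1L, n_topics = 4L, vocab_size = 4L,
                                 dirichlet_topic_conc = 1000),
                    min_jsd = 0.5, max_attempts = 5L),
    "Jensen-Shannon")
})

test_that("diagnosis records follow the mixed-topic generative model", {
  cfg <- synth_config(seed = 11L, n_patients = 400L)
  topics <- generate_topics(cfg)
  sim <- generate_diagnosis_records(cfg, topics)
  sim2 <- generate_diagnosis_records(cfg, topics)
  expect_identical(sim, sim2)

  expect_equal(rowSums(sim$truth$true_theta), rep(1, 400), tolerance = 1e-9)
  # every patient has at least one non-asthma code
  ev <- sim$corpus$events
  comorbid <- !is_asthma_code(ev$code, ev$code_system)
  expect_setequal(unique(ev$patient_id[comorbid]),
                  sim$corpus$patients$patient_id)
  # dates inside the enrollment window
  expect_true(all(ev$date >= cfg$window_start & ev$date <= cfg$window_end))
})

test_that("tiny doc concentration concentrates patients on one topic", {
  cfg <- synth_config(seed = 5L, n_patients = 500L, dirichlet_doc_conc = 1e-3)
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  frac <- mean(apply(sim$truth$true_theta, 1, max) > 0.99)
  expect_gt(frac, 0.95)
})

test_that("aggregate word frequencies converge to the topic mixture", {
  cfg <- synth_config(seed = 9L, n_patients = 5000L, vocab_size = 60L)
  topics <- generate_topics(cfg)
  sim <- generate_diagnosis_records(cfg, topics)
  ev <- sim$corpus$events
  ev <- ev[!is_asthma_code(ev$code, ev$code_system), ]
  codes <- sprintf("%03d.%02d", 101L + (seq_len(60) - 1L) %/% 100L,
                   (seq_len(60) - 1L) %% 100L)
  emp <- tabulate(match(ev$code, codes), 60)
  emp <- emp / sum(emp)
  expected <- colMeans(sim$truth$true_theta %*% topics)
  expect_lt(sum(abs(emp - expected)) / 2, 0.02)  # total variation
})

test_that("genotypes are HWE draws and null SNPs show no association", {
  cfg <- synth_config(seed = 13L, n_patients = 2000L, n_snps = 200L)
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  geno <- generate_genotypes(cfg, sim$truth)
  expect_true(all(geno$dosages %in% 0:2))

  # HWE exact-test p values approximately uniform under the truth
  hwe_p <- vapply(seq_len(200), function(j) {
    g <- geno$dosages[, j]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(hwe_p, "punif"))$p.value, 0.01)

  # no planted effect: allele-frequency Z between cases and controls modest
  z <- vapply(seq_len(200), function(j) {
    g <- geno$dosages[, j]
    f1 <- mean(g[geno$case]) / 2; f0 <- mean(g[!geno$case]) / 2
    f <- mean(g) / 2
    v <- f * (1 - f) / 2 * (1 / sum(geno$case) + 1 / sum(!geno$case))
    (f1 - f0) / sqrt(v)
  }, numeric(1))
  expect_true(all(abs(z) < 4))

  bad <- synth_config(seed = 1L, n_snps = 10L)
  bad$planted_effects <- list(list(snp = 11L, subgroup = 1L, ln_or = 0.3))
  expect_error(generate_genotypes(bad, sim$truth), "snp index")
})

test_that("phenotype generator plants recoverable subgroup slopes", {
  # null slope centers on zero
  cfg0 <- synth_config(seed = 3L, n_patients = 3000L)
  sim0 <- generate_diagnosis_records(cfg0, generate_topics(cfg0))
  ph0 <- generate_phenotypes(cfg0, sim0$truth)
  expect_equal(nrow(ph0$phenotypes), 3000L)
  fit0 <- glm(ph0$case ~ minmax_normalize(ph0$phenotypes[, 1]),
              family = binomial())
  expect_lt(abs(coef(fit0)[2]), 3 * summary(fit0)$coefficients[2, 2])

  # planted positive slope recovered with the right sign across seeds
  hits <- vapply(1:15, function(s) {
    cfg <- synth_config(seed = s, n_patients = 3000L,
                        planted_slopes = list(list(phenotype = 1L,
                                                   subgroup = 2L, slope = 2)))
    sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
    ph <- generate_phenotypes(cfg, sim$truth)
    idx <- sim$truth$true_subgroup == 2L
    fit <- glm(ph$case[idx] ~ minmax_normalize(ph$phenotypes[, 1])[idx],
               family = binomial())
    coef(fit)[2] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("expression counts are NB with working size-factor scaling", {
  cfg <- synth_config(seed = 21L, n_patients = 200L, n_genes = 100L)
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  ex <- generate_expression_counts(cfg, sim$truth)
  expect_true(all(ex$counts >= 0))
  expect_true(all(ex$counts == round(ex$counts)))
  # null l2fc: case/control mean ratio near 1 after depth normalization
  norm <- sweep(ex$counts, 2, ex$size_factors_true, "/")
  ratio <- rowMeans(norm[, ex$case, drop = FALSE]) /
    rowMeans(norm[, !ex$case, drop = FALSE])
  expect_lt(abs(median(ratio) - 1), 0.1)
})

test_that("multi-cohort generation shares topics across disjoint patients", {
  cfg <- synth_config(seed = 17L, n_patients = 600L, n_cohorts = 3L)
  cohorts <- generate_multi_cohorts(cfg)
  expect_length(cohorts, 3L)
  ids <- lapply(cohorts, function(ch) ch$corpus$patients$patient_id)
  expect_equal(length(unique(unlist(ids))), sum(lengths(ids)))
  expect_identical(cohorts[[1]]$truth$true_topics,
                   cohorts[[2]]$truth$true_topics)
  # per-cohort empirical profiles agree because the topics are shared
  prof <- vapply(cohorts, function(ch) {
    mp <- demo_code_mapping(cfg$vocab_size)
    class(mp) <- c("code_mapping", class(mp))
    W <- build_count_matrix(ch$corpus, mp)
    colSums(W) / sum(W)
  }, numeric(cfg$vocab_size))
  expect_gt(cor(prof[, 1], prof[, 2]), 0.9)
})

test_that("ground truth round-trips losslessly through JSON", {
  cfg <- synth_config(seed = 2L, n_patients = 50L,
                      planted_effects = list(list(snp = 3L, subgroup = 1L,
                                                  ln_or = 0.4)))
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  path <- tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  expect_no_error(jsonlite::read_json(path))
  back <- read_truth(path)
  expect_equal(back$true_topics, unname(sim$truth$true_topics))
  expect_equal(back$true_theta, unname(sim$truth$true_theta))
  expect_identical(back$true_subgroup, sim$truth$true_subgroup)
  expect_equal(rowSums(back$true_topics), rep(1, cfg$n_topics),
               tolerance = 1e-9)
  expect_equal(back$true_snp_effects[[1]]$ln_or, 0.4)
})
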