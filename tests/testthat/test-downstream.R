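test_that("median-of-ratios size factors match the worked example", {
  c1 <- c(10, 100, 40, 7)
  m <- cbind(s1 = c1, s2 = 2 * c1)
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- cbind(a = c1, b = c1, c = c1)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  set.seed(3)
  big <- matrix(rnbinom(500 * 6, mu = 50, size = 5) + 1L, ncol = 6)
  sf2 <- size_factors(big)
  expect_equal(exp(mean(log(sf2))), 1, tolerance = 1e-9)
  # invariant to gene order
  expect_equal(size_factors(big[sample(nrow(big)), ]), sf2)

  sparse <- rbind(c(0, 5), c(5, 0))
  expect_error(size_factors(sparse), "pseudo-reference")
})

test_that("NB differential expression recovers a planted fold change", {
  recovered <- vapply(1:8, function(s) {
    cfg <- synth_config(seed = 200L + s, n_patients = 80L, n_genes = 30L,
                        nb_dispersion = 0.1, asthma_base_rate = 0.5,
                        planted_l2fc = list(list(gene = 1L, subgroup = 1L,
                                                 l2fc = 1.0)))
    sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
    truth <- sim$truth
    # contrast: cases in subgroup 1 vs non-asthma controls
    ex <- generate_expression_counts(cfg, truth)
    grp <- ex$case & truth$true_subgroup == 1L
    sel <- grp | !ex$case
    de <- nb_glm_de(ex$counts[, sel], grp[sel],
                    covariates = ex$covariates[sel, ])
    de$l2fc[1]
  }, numeric(1))
  expect_gte(mean(abs(recovered - 1) <= 0.3), 0.85)
})

test_that("null genes give uniform Wald p values", {
  cfg <- synth_config(seed = 301L, n_patients = 60L, n_genes = 400L,
                      nb_dispersion = 0.1, asthma_base_rate = 0.5)
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  ex <- generate_expression_counts(cfg, sim$truth)
  de <- nb_glm_de(ex$counts, ex$case)
  p <- de$wald_p[de$converged]
  expect_gt(length(p), 350)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_lte(sum(de$fdr < 0.1, na.rm = TRUE), 0.05 * nrow(de))
})

test_that("permuting labels destroys a planted signal", {
  cfg <- synth_config(seed = 302L, n_patients = 80L, n_genes = 60L,
                      asthma_base_rate = 0.5,
                      planted_l2fc = list(list(gene = 1L, subgroup = 1L,
                                               l2fc = 2.0)))
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  ex <- generate_expression_counts(cfg, sim$truth)
  grp <- ex$case & sim$truth$true_subgroup == 1L
  sel <- grp | !ex$case
  de <- nb_glm_de(ex$counts[, sel], grp[sel])
  expect_lt(de$fdr[1], 0.05)            # signal present before permutation
  set.seed(77)
  de_perm <- nb_glm_de(ex$counts[, sel], sample(grp[sel]))
  expect_lte(sum(de_perm$fdr < 0.1, na.rm = TRUE), 0.05 * nrow(de_perm))
})

test_that("min-max normalization is exact, idempotent and order-preserving", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x), x)
  set.seed(4)
  y <- rnorm(50)
  expect_equal(order(minmax_normalize(y)), order(y))
  expect_error(minmax_normalize(rep(3, 5)), "constant")
})

test_that("slope scan estimates per-stratum slopes against the benchmark", {
  cfg <- synth_config(seed = 44L, n_patients = 3000L,
                      planted_slopes = list(list(phenotype = 1L,
                                                 subgroup = 2L, slope = 3)))
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  ph <- generate_phenotypes(cfg, sim$truth)
  slopes <- phenotype_slope_scan(ph$phenotypes, ph$case,
                                 sim$truth$true_subgroup,
                                 covariates = ph$covariates)
  expect_true("any-CDs" %in% slopes$stratum)
  s21 <- slopes$slope[slopes$stratum == "2" & slopes$phenotype == "pheno01"]
  expect_gt(s21, 0)
  # doubling the raw phenotype changes nothing after normalization
  ph2 <- ph$phenotypes; ph2[, 1] <- 2 * ph2[, 1]
  slopes2 <- phenotype_slope_scan(ph2, ph$case, sim$truth$true_subgroup,
                                  covariates = ph$covariates)
  expect_equal(slopes2$slope, slopes$slope, tolerance = 1e-9)

  dev <- benchmark_deviation_test(slopes)
  expect_true(all(c("deviation_z", "fdr") %in% names(dev)))
  # identical slope and benchmark give z = 0, p = 1
  fake <- data.frame(phenotype = "x", stratum = c("any-CDs", "1"),
                     slope = c(0.4, 0.4), se = c(0.1, 0.1),
                     converged = TRUE, stringsAsFactors = FALSE)
  d0 <- benchmark_deviation_test(fake)
  expect_equal(d0$deviation_z, 0)
  expect_equal(d0$deviation_p, 1)
})

test_that("deviation testing is calibrated and detects planted heterogeneity", {
  # homogeneous slopes: few flags (conservative bound)
  flags <- vapply(1:10, function(s) {
    cfg <- synth_config(seed = 400L + s, n_patients = 2500L,
                        planted_slopes = list(list(phenotype = 1L,
                                                   subgroup = 1L, slope = 1),
                                              list(phenotype = 1L,
                                                   subgroup = 2L, slope = 1),
                                              list(phenotype = 1L,
                                                   subgroup = 3L, slope = 1),
                                              list(phenotype = 1L,
                                                   subgroup = 4L, slope = 1),
                                              list(phenotype = 1L,
                                                   subgroup = 5L, slope = 1)))
    sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
    ph <- generate_phenotypes(cfg, sim$truth)
    sl <- phenotype_slope_scan(ph$phenotypes, ph$case,
                               sim$truth$true_subgroup)
    mean(benchmark_deviation_test(sl, alpha_fdr = 0.05)$heterogeneous)
  }, numeric(1))
  expect_lte(mean(flags), 0.05)

  # strong subgroup-specific slope flagged
  hits <- vapply(1:10, function(s) {
    cfg <- synth_config(seed = 500L + s, n_patients = 3000L,
                        planted_slopes = list(list(phenotype = 1L,
                                                   subgroup = 2L, slope = 6)))
    sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
    ph <- generate_phenotypes(cfg, sim$truth)
    sl <- phenotype_slope_scan(ph$phenotypes, ph$case,
                               sim$truth$true_subgroup)
    dev <- benchmark_deviation_test(sl)
    any(dev$heterogeneous[dev$stratum == "2" & dev$phenotype == "pheno01"])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("KDE overlap behaves as a bounded similarity", {
  set.seed(15)
  a <- rnorm(400)
  expect_gte(kde_overlap(a, a), 0.99)
  expect_lte(kde_overlap(a, a + 100), 0.01)
  b <- rnorm(5000); c <- rnorm(5000)
  ov <- kde_overlap(b, c)
  expect_gt(ov, 0.95)                        # analytic overlap is 1
  expect_equal(kde_overlap(b, c), kde_overlap(c, b), tolerance = 1e-12)
  expect_lte(ov, 1)
  expect_error(kde_overlap(rep(1, 10), a), "degenerate")
  expect_error(kde_overlap(1, a), "two points")
})
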