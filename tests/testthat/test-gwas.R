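test_that("SNP QC computes call rate, MAF and exact HWE", {
  # perfect HWE proportions at 50/50 alleles
  g_hwe <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_equal(hwe_exact_test(25, 50, 25, method = "chisq"), 1)

  # allele frequency 3/8 from dosages (0,0,1,2)
  qc <- snp_qc(cbind(s1 = c(0L, 0L, 1L, 2L)), call_rate_min = 0,
               maf_min = 0, hwe_p_min = 0)
  expect_equal(qc$maf, 3 / 8)

  # 10% missing fails the 0.95 call-rate filter
  g_miss <- c(rep(0L, 90), rep(NA_integer_, 10))
  qc2 <- snp_qc(cbind(a = g_miss, b = g_hwe))
  expect_equal(qc2$call_rate, c(0.9, 1))
  expect_false(qc2$qc_pass[1])
  expect_true(qc2$qc_pass[2])

  # monomorphic SNP: MAF 0, fails the MAF filter without error
  qc3 <- snp_qc(cbind(mono = rep(0L, 50)))
  expect_equal(qc3$maf, 0)
  expect_false(qc3$qc_pass)
})

test_that("exact HWE test matches full enumeration on a small table", {
  # brute-force conditional distribution for n = 5, minor allele count 4
  n <- 5L; nb <- 4L
  hets <- c(0L, 2L, 4L)
  prob <- vapply(hets, function(h) {
    hb <- (nb - h) / 2
    exp(h * log(2) - lfactorial(n - h - hb) - lfactorial(h) - lfactorial(hb))
  }, numeric(1))
  prob <- prob / sum(prob)
  for (i in seq_along(hets)) {
    h <- hets[i]
    p_exp <- sum(prob[prob <= prob[i] + 1e-15])
    got <- hwe_exact_test(n - h - (nb - h) / 2, h, (nb - h) / 2)
    expect_equal(got, p_exp, tolerance = 1e-9)
  }
})

test_that("the IRLS fit agrees with stats::glm", {
  set.seed(6)
  n <- 400
  x <- rnorm(n); sexv <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + 0.6 * x - 0.2 * sexv))
  X <- cbind(1, x, sexv)
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ x + sexv, family = binomial())
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separated)

  # complete separation is flagged, not fatal
  ys <- as.integer(x > 0)
  fit_sep <- fit_logistic(cbind(1, x), ys)
  expect_true(fit_sep$separated)
})

test_that("the null scan has calibrated type-I error", {
  cfg <- synth_config(seed = 31L, n_patients = 2000L, n_snps = 200L)
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  geno <- generate_genotypes(cfg, sim$truth)
  assoc <- logistic_scan(geno$dosages, geno$case, geno$covariates)
  expect_true(all(abs(assoc$z - assoc$beta / assoc$se) < 1e-9))
  frac <- mean(assoc$p < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("a planted common effect is detected with high power", {
  hits <- vapply(1:10, function(s) {
    cfg <- synth_config(seed = 100L + s, n_patients = 3000L, n_snps = 5L,
                        planted_effects = list(list(snp = 1L, subgroup = "all",
                                                    ln_or = 0.4)))
    sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
    geno <- generate_genotypes(cfg, sim$truth)
    assoc <- logistic_scan(geno$dosages, geno$case, geno$covariates)
    assoc$p[1] < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("flipping case/control labels negates the effect estimate", {
  cfg <- synth_config(seed = 33L, n_patients = 1000L, n_snps = 3L)
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  geno <- generate_genotypes(cfg, sim$truth)
  a <- logistic_scan(geno$dosages, geno$case, geno$covariates)
  b <- logistic_scan(geno$dosages, !geno$case, geno$covariates)
  expect_equal(a$beta, -b$beta, tolerance = 1e-6)
})

test_that("the scan refuses an underpowered stratum", {
  cfg <- synth_config(seed = 34L, n_patients = 150L, n_snps = 3L)
  sim <- generate_diagnosis_records(cfg, generate_topics(cfg))
  geno <- generate_genotypes(cfg, sim$truth)
  expect_error(logistic_scan(geno$dosages, geno$case, geno$covariates,
                             min_cases = 100L), "cases")
})

test_that("distance clumping matches brute-force lead selection", {
  set.seed(12)
  n <- 50
  assoc <- data.frame(snp = sprintf("s%02d", 1:n), stratum = "any-CDs",
                      beta = rnorm(n), se = 1,
                      p = 10^-runif(n, 0, 10),
                      stringsAsFactors = FALSE)
  pos <- data.frame(snp = assoc$snp, chrom = "1",
                    pos = sort(sample.int(5e6, n)))
  leads <- clump_independent(assoc, pos, window_bp = 5e5, p_threshold = 1e-3)
  # brute force: iteratively take best p, drop neighbors
  remaining <- which(assoc$p < 1e-3)
  expected <- character(0)
  while (length(remaining)) {
    top <- remaining[which.min(assoc$p[remaining])]
    expected <- c(expected, assoc$snp[top])
    remaining <- remaining[abs(pos$pos[remaining] - pos$pos[top]) > 5e5]
  }
  expect_setequal(leads$snp, expected)

  # two significant SNPs 10 kb apart collapse to one lead
  a2 <- data.frame(snp = c("a", "b"), stratum = "x", beta = c(1, 1),
                   se = c(0.1, 0.1), p = c(1e-10, 1e-9))
  p2 <- data.frame(snp = c("a", "b"), chrom = "1", pos = c(1e6, 1.01e6))
  expect_equal(nrow(clump_independent(a2, p2, window_bp = 1e6,
                                      p_threshold = 5e-8)), 1L)
  # nothing significant, nothing returned
  expect_equal(nrow(clump_independent(a2, p2, p_threshold = 1e-12)), 0L)
})

test_that("Cochran's Q matches the worked example and is shift-invariant", {
  q <- cochran_q(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(q$Q, 2, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  expect_equal(q$p, 0.1573, tolerance = 1e-4)

  expect_equal(cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3))$Q, 0)
  expect_equal(cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3))$p, 1)

  set.seed(7)
  b <- rnorm(4); s <- runif(4, 0.05, 0.2)
  expect_equal(cochran_q(b, s)$Q, cochran_q(b + 5, s)$Q, tolerance = 1e-9)
  expect_error(cochran_q(c(0.1), c(0.1)), "two strata")
  expect_error(cochran_q(c(0.1, 0.2), c(0.1, 0)), "positive")
})

test_that("BH adjustment reproduces the hand-worked step-up values", {
  expect_equal(bh_fdr(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.0266666666666667, 0.04), tolerance = 1e-12)
  expect_equal(bh_fdr(0.03), 0.03)
  p <- c(0.9, 0.04, 0.2, 0.001)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 0)), "in \\(0, 1\\]")
})
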