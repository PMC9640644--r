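# Subgroup-stratified case-control association scan: SNP QC, additive-dosage
# logistic regression, distance-based clumping to independent loci, Cochran's
# Q heterogeneity, and Benjamini-Hochberg FDR.

#' Per-SNP quality control
#'
#' Computes call rate, minor allele frequency and an exact Hardy-Weinberg
#' test from the control of each SNP's dosage column; `qc_pass` requires
#' call rate > 0.95, MAF > 0.01 and HWE p > 1e-6 (all three jointly, so the
#' filters are order-independent).
#'
#' @param dosages n x m matrix of allele dosages in \{0, 1, 2, NA\}.
#' @param call_rate_min,maf_min,hwe_p_min QC thresholds.
#' @return data.frame: snp, call_rate, maf, hwe_p, qc_pass.
#' @export
snp_qc <- function(dosages, call_rate_min = 0.95, maf_min = 0.01,
                   hwe_p_min = 1e-6) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  snp <- colnames(dosages)
  if (is.null(snp)) snp <- sprintf("snp%04d", seq_len(m))
  call_rate <- colMeans(!is.na(dosages))
  out <- data.frame(snp = snp, call_rate = call_rate,
                    maf = NA_real_, hwe_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g <- dosages[, j]
    g <- g[!is.na(g)]
    if (!length(g)) next
    af <- mean(g) / 2
    out$maf[j] <- min(af, 1 - af)
    out$hwe_p[j] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  out$qc_pass <- out$call_rate > call_rate_min &
    !is.na(out$maf) & out$maf > maf_min &
    !is.na(out$hwe_p) & out$hwe_p > hwe_p_min
  rownames(out) <- NULL
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the p
#' value sums the probabilities of all heterozygote counts no more likely
#' than the observed one (no mid-p correction).  A chi-square mode is
#' available for comparison.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @param method "exact" (default) or "chisq".
#' @return p value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb, method = c("exact", "chisq")) {
  method <- match.arg(method)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  n_b <- n_ab + 2L * n_bb       # minor allele count (orientation-free below)
  if (n_b > n) n_b <- 2L * n - n_b
  if (method == "chisq") {
    p <- (n_ab + 2 * n_bb) / (2 * n)
    e <- c(n * (1 - p)^2, 2 * n * p * (1 - p), n * p^2)
    o <- c(n_aa, n_ab, n_bb)
    if (any(e == 0)) return(1)
    stat <- sum((o - e)^2 / e)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  if (n_b == 0L) return(1)
  # Possible heterozygote counts share the parity of the minor allele count.
  het <- seq.int(n_b %% 2L, n_b, by = 2L)
  het <- het[(n_b - het) %% 2L == 0L & (n_b - het) / 2L + het <= n]
  # log P(het | allele counts) up to a constant
  lp <- vapply(het, function(h) {
    hom_b <- (n_b - h) / 2
    hom_a <- n - h - hom_b
    h * log(2) - lgamma(hom_a + 1) - lgamma(h + 1) - lgamma(hom_b + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(het == n_ab)
  if (!length(obs)) return(NA_real_)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Logistic regression fit (maximum likelihood, IRLS)
#'
#' Thin wrapper over the compiled iteratively-reweighted-least-squares
#' solver; equivalent to `glm(family = binomial())` (asserted in the test
#' suite) but fast enough for the resampling stages.
#'
#' @param X design matrix including the intercept column.
#' @param y 0/1 response.
#' @return list: beta, se, z, p, converged, separated.
#' @export
fit_logistic <- function(X, y) {
  res <- .logistic_irls_cpp(as.matrix(X), as.numeric(y))
  beta <- as.numeric(res$beta)
  se <- as.numeric(res$se)
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       converged = isTRUE(res$converged), separated = isTRUE(res$separated))
}

#' Case-control association scan within one stratum
#'
#' Per SNP, a logistic model of the binary label on additive allele dosage
#' (0/1/2) plus covariates; the Wald beta (ln OR), SE, Z and p value are
#' reported.  Missing dosages are mean-imputed per SNP.  Fits that do not
#' converge or are quasi-separated are flagged and carry NA statistics.
#'
#' @param dosages n x m dosage matrix for the stratum's individuals.
#' @param case logical/0-1 vector.
#' @param covariates data.frame of covariates (numeric; e.g. sex, age,
#'   genetic PCs), or NULL.
#' @param stratum label recorded in the output (e.g. a subgroup id or
#'   "any-CDs").
#' @param qc optional output of [snp_qc()]; only `qc_pass` SNPs are scanned.
#' @param min_cases minimum cases (and controls) required (default 100).
#' @return data.frame of class `assoc_records`: snp, stratum, beta, se, z,
#'   p, n_case, n_ctrl, converged.
#' @export
logistic_scan <- function(dosages, case, covariates = NULL,
                          stratum = "any-CDs", qc = NULL, min_cases = 100L) {
  dosages <- as.matrix(dosages)
  case <- as.integer(case)
  n_case <- sum(case == 1L); n_ctrl <- sum(case == 0L)
  if (n_case < min_cases || n_ctrl < min_cases) {
    stop(sprintf("stratum '%s' has %d cases / %d controls; need >= %d of each",
                 stratum, n_case, n_ctrl, min_cases), call. = FALSE)
  }
  snp_names <- colnames(dosages)
  if (is.null(snp_names)) snp_names <- sprintf("snp%04d", seq_len(ncol(dosages)))
  keep <- seq_len(ncol(dosages))
  if (!is.null(qc)) keep <- which(qc$qc_pass)
  C <- if (is.null(covariates)) NULL else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  }
  rows <- lapply(keep, function(j) {
    g <- dosages[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    X <- cbind(1, g, C)
    fit <- fit_logistic(X, case)
    ok <- fit$converged && !fit$separated
    data.frame(snp = snp_names[j], stratum = stratum,
               beta = if (ok) fit$beta[2] else NA_real_,
               se = if (ok) fit$se[2] else NA_real_,
               z = if (ok) fit$z[2] else NA_real_,
               p = if (ok) fit$p[2] else NA_real_,
               n_case = n_case, n_ctrl = n_ctrl, converged = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assoc_records", class(out))
  out
}

#' Reduce associations to independent lead SNPs by distance clumping
#'
#' Greedy: take the most significant remaining SNP below `p_threshold`,
#' suppress every SNP within `window_bp` of it, repeat.  Deterministic (p
#' ties broken by position).
#'
#' @param assoc `assoc_records` for one stratum.
#' @param positions named base-pair positions (per `assoc$snp`) or a
#'   data.frame with snp/chrom/pos.
#' @param window_bp suppression half-window (default 1 Mb).
#' @param p_threshold significance cutoff (default genome-wide 5e-8).
#' @return subset of `assoc` holding the lead SNPs.
#' @export
clump_independent <- function(assoc, positions, window_bp = 1e6,
                              p_threshold = 5e-8) {
  if (is.data.frame(positions)) {
    pos <- positions$pos[match(assoc$snp, positions$snp)]
    chrom <- positions$chrom[match(assoc$snp, positions$snp)]
  } else {
    pos <- unname(positions[assoc$snp])
    chrom <- rep("1", nrow(assoc))
  }
  cand <- which(!is.na(assoc$p) & assoc$p < p_threshold)
  leads <- integer(0)
  cand <- cand[order(assoc$p[cand], pos[cand])]
  while (length(cand)) {
    top <- cand[1L]
    leads <- c(leads, top)
    cand <- cand[!(chrom[cand] == chrom[top] &
                     abs(pos[cand] - pos[top]) <= window_bp)]
  }
  out <- assoc[sort(leads), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cochran's Q heterogeneity test across strata
#'
#' `Q = sum w_i (beta_i - beta_F)^2` with `w_i = 1/se_i^2` and `beta_F` the
#' inverse-variance-weighted mean; p from chi-square with k - 1 df.
#'
#' @param betas,ses effect sizes and standard errors over k >= 2 strata.
#' @return list: Q, df, p.
#' @export
cochran_q <- function(betas, ses) {
  stopifnot(length(betas) == length(ses))
  if (length(betas) < 2L) stop("need at least two strata", call. = FALSE)
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  beta_f <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - beta_f)^2)
  df <- length(betas) - 1L
  list(Q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param pvalues p values in (0, 1].
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
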