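# Subgroup-conditioned downstream characterization: negative-binomial
# differential expression, phenotype-slope heterogeneity against the
# whole-group benchmark, and kernel-density distribution-overlap
# diagnostics.

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth normalizers: each sample's counts are divided
#' by the per-gene geometric-mean reference, and the size factor is the
#' median of those ratios over genes expressed in every sample.  Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts gene x sample count matrix.
#' @return positive numeric vector, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) {
    stop(paste0("no gene has all-positive counts; a pseudo-reference over ",
                "expressed genes would be needed for data this sparse"),
         call. = FALSE)
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lc)                     # log geometric means
  sf <- exp(apply(lc - ref, 2L, stats::median))
  sf / exp(mean(log(sf)))
}

# Per-gene NB dispersion by maximum likelihood (log-link mean fixed by the
# fitted GLM); method-of-moments fallback when optimization fails.
nb_dispersion_ml <- function(y, mu, floor = 1e-8) {
  mom <- max(floor, (stats::var(y) - mean(mu)) / mean(mu)^2)
  nll <- function(log_disp) {
    size <- 1 / exp(log_disp)
    -sum(stats::dnbinom(y, mu = mu, size = size, log = TRUE))
  }
  opt <- tryCatch(
    stats::optimize(nll, interval = log(c(floor, 100))),
    error = function(e) NULL)
  if (is.null(opt)) mom else max(floor, exp(opt$minimum))
}

#' Negative-binomial GLM differential expression
#'
#' Per gene: a log-link negative-binomial GLM of counts on the contrast
#' indicator plus covariates, with log size factors as offsets and the
#' dispersion estimated per gene by maximum likelihood (floored at 1e-8).
#' The contrast coefficient is reported as a log2 fold change and tested
#' with a two-sided Wald test; Benjamini-Hochberg FDR is computed over the
#' converged genes.
#'
#' @param counts gene x sample matrix of nonnegative integers.
#' @param group logical/0-1 contrast indicator per sample (e.g. asthma case
#'   in the focal subgroup vs the chosen reference samples).
#' @param covariates data.frame of per-sample confounders (age, sex,
#'   ethnicity, ...) or NULL.
#' @param sf size factors; computed from `counts` when NULL.
#' @param min_group minimum samples required on each side (default 5).
#' @return data.frame of class `de_results`: gene, l2fc, se_l2fc, wald_p,
#'   fdr, converged.
#' @export
nb_glm_de <- function(counts, group, covariates = NULL, sf = NULL,
                      min_group = 5L) {
  counts <- as.matrix(counts)
  group <- as.integer(group)
  if (sum(group == 1L) < min_group || sum(group == 0L) < min_group) {
    stop(sprintf("each contrast side needs >= %d samples", min_group),
         call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  off <- log(sf)
  df <- data.frame(group = group)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  X <- stats::model.matrix(~ ., data = df)
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(nrow(counts)))
  ln2 <- log(2)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    fit <- tryCatch({
      # Poisson start for the mean structure, then ML dispersion, then the
      # NB fit at that dispersion for the Wald statistics.
      f0 <- stats::glm.fit(X, y, offset = off, family = stats::poisson())
      disp <- nb_dispersion_ml(y, pmax(f0$fitted.values, 1e-8))
      fam <- MASS::negative.binomial(theta = 1 / disp)
      f1 <- stats::glm.fit(X, y, offset = off, family = fam)
      if (!f1$converged) stop("no convergence")
      list(f1 = f1, disp = disp)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(gene = genes[i], l2fc = NA_real_, se_l2fc = NA_real_,
                        wald_p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    f1 <- fit$f1
    mu <- f1$fitted.values
    w <- mu / (1 + fit$disp * mu)          # NB log-link Fisher weights
    info <- crossprod(X * sqrt(w))
    gi <- match("group", colnames(X))
    se <- tryCatch(sqrt(diag(chol2inv(chol(info))))[gi],
                   error = function(e) NA_real_)
    b <- f1$coefficients[["group"]]
    z <- b / se
    data.frame(gene = genes[i], l2fc = b / ln2, se_l2fc = se / ln2,
               wald_p = 2 * stats::pnorm(-abs(z)),
               converged = is.finite(z), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- out$converged & !is.na(out$wald_p)
  out$fdr[ok] <- stats::p.adjust(out$wald_p[ok], method = "BH")
  class(out) <- c("de_results", class(out))
  out
}

#' Min-max normalization to [0, 1]
#'
#' @param values numeric vector with `max > min`.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_normalize <- function(values) {
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) stop("constant vector cannot be min-max normalized",
                             call. = FALSE)
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Phenotype-slope scan across subgroups
#'
#' For each phenotype and each stratum, fits a logistic regression of the
#' asthma label on the min-max-normalized phenotype plus covariates within
#' the stratum's members; the whole-population ("any-CDs") slope is fitted
#' as the per-phenotype benchmark.  Normalization uses the whole-population
#' range so slopes are on a common scale.
#'
#' @param phenotypes n x P numeric matrix (column names = phenotype names).
#' @param case asthma indicator per individual.
#' @param subgroup integer subgroup label per individual.
#' @param covariates data.frame of covariates or NULL.
#' @param min_per_arm minimum cases and controls per stratum fit (default
#'   30 at desk scale).
#' @return data.frame of class `slope_results`: phenotype, stratum
#'   ("any-CDs" or the subgroup id), slope, se, converged.
#' @export
phenotype_slope_scan <- function(phenotypes, case, subgroup,
                                 covariates = NULL, min_per_arm = 30L) {
  phenotypes <- as.matrix(phenotypes)
  pnames <- colnames(phenotypes)
  if (is.null(pnames)) pnames <- sprintf("pheno%02d", seq_len(ncol(phenotypes)))
  case <- as.integer(case)
  C <- if (is.null(covariates)) NULL else
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  strata <- c(list(`any-CDs` = seq_along(case)),
              split(seq_along(case), subgroup))
  rows <- list()
  for (ph in seq_along(pnames)) {
    x <- minmax_normalize(phenotypes[, ph])
    for (s in names(strata)) {
      idx <- strata[[s]]
      ok_size <- sum(case[idx] == 1L) >= min_per_arm &&
        sum(case[idx] == 0L) >= min_per_arm
      if (!ok_size) next
      X <- cbind(1, x[idx], if (!is.null(C)) C[idx, , drop = FALSE])
      fit <- fit_logistic(X, case[idx])
      ok <- fit$converged && !fit$separated
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = pnames[ph], stratum = s,
        slope = if (ok) fit$beta[2] else NA_real_,
        se = if (ok) fit$se[2] else NA_real_,
        n = length(idx), converged = ok, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("slope_results", class(out))
  out
}

#' Deviation of subgroup slopes from the whole-group benchmark
#'
#' For each (phenotype, subgroup) pair, the deviation of the subgroup slope
#' from the any-CDs benchmark is tested as a normal contrast,
#' `z = (beta_i - beta_0) / sqrt(se_i^2 + se_0^2)`, with two-sided p and
#' Benjamini-Hochberg FDR across all pairs.  Because each subgroup is a
#' subset of the benchmark population the two estimates are positively
#' correlated, which makes this variance sum an over-estimate — the test is
#' conservative.
#'
#' @param slopes `slope_results` from [phenotype_slope_scan()], containing
#'   the "any-CDs" benchmark rows.
#' @param alpha_fdr flag threshold (default 0.05).
#' @return data.frame: phenotype, stratum, slope, benchmark, deviation_z,
#'   deviation_p, fdr, heterogeneous.
#' @export
benchmark_deviation_test <- function(slopes, alpha_fdr = 0.05) {
  bench <- slopes[slopes$stratum == "any-CDs" & slopes$converged, ]
  if (nrow(bench) == 0L) stop("no any-CDs benchmark slopes found", call. = FALSE)
  sub <- slopes[slopes$stratum != "any-CDs" & slopes$converged, ]
  j <- match(sub$phenotype, bench$phenotype)
  keep <- !is.na(j)
  sub <- sub[keep, ]; j <- j[keep]
  out <- data.frame(
    phenotype = sub$phenotype, stratum = sub$stratum,
    slope = sub$slope, se = sub$se,
    benchmark = bench$slope[j], se_benchmark = bench$se[j],
    stringsAsFactors = FALSE)
  out$deviation_z <- (out$slope - out$benchmark) /
    sqrt(out$se^2 + out$se_benchmark^2)
  out$deviation_p <- 2 * stats::pnorm(-abs(out$deviation_z))
  out$fdr <- stats::p.adjust(out$deviation_p, method = "BH")
  out$heterogeneous <- out$fdr < alpha_fdr
  rownames(out) <- NULL
  out
}

#' Overlap of two kernel density estimates
#'
#' Gaussian KDE with Silverman's bandwidth for each sample on a shared grid
#' spanning both ranges plus three bandwidths; the overlap is the
#' trapezoid-rule integral of the pointwise minimum, 1 for identical
#' distributions and 0 for completely separated ones.
#'
#' @param sample_a,sample_b numeric samples with at least two points each.
#' @param n_grid grid resolution (>= 512).
#' @return overlap in [0, 1].
#' @export
kde_overlap <- function(sample_a, sample_b, n_grid = 1024L) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("need at least two points per sample", call. = FALSE)
  }
  if (stats::sd(sample_a) == 0 || stats::sd(sample_b) == 0) {
    stop("degenerate (zero-variance) sample", call. = FALSE)
  }
  n_grid <- max(512L, n_grid)
  bw_a <- stats::bw.nrd0(sample_a)
  bw_b <- stats::bw.nrd0(sample_b)
  lo <- min(min(sample_a) - 3 * bw_a, min(sample_b) - 3 * bw_b)
  hi <- max(max(sample_a) + 3 * bw_a, max(sample_b) + 3 * bw_b)
  fa <- stats::density(sample_a, bw = bw_a, from = lo, to = hi, n = n_grid)
  fb <- stats::density(sample_b, bw = bw_b, from = lo, to = hi, n = n_grid)
  y <- pmin(fa$y, fb$y)
  dx <- diff(fa$x)
  min(1, sum((y[-1] + y[-length(y)]) / 2 * dx))
}
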