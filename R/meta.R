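# Fixed-effects inverse-variance meta-analysis across replication cohorts
# with direction-aware one-sided replication testing.

#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' The merged effect is the weighted average of the study effects with
#' weights equal to the reciprocal squared standard errors, and the merged
#' variance is the reciprocal of the summed weights.
#'
#' @param betas study effect sizes (ln OR).
#' @param ses positive standard errors, same length.
#' @return list of class `meta_result`: beta_f, var_f, se_f, z_f,
#'   k_studies.
#' @export
ivw_meta <- function(betas, ses) {
  if (length(betas) == 0L) stop("no studies to pool", call. = FALSE)
  stopifnot(length(betas) == length(ses))
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  beta_f <- sum(w * betas) / sum(w)
  var_f <- 1 / sum(w)
  structure(list(beta_f = beta_f, var_f = var_f, se_f = sqrt(var_f),
                 z_f = beta_f / sqrt(var_f), k_studies = length(betas)),
            class = "meta_result")
}

#' One-sided replication test with an expected direction
#'
#' An association replicates only if the effect direction matches the
#' discovery analysis, so the replication p value is the one-sided normal
#' tail probability in the discovery direction,
#' `P(Z >= sign * z_F)`.
#'
#' @param meta a `meta_result` (or list with `z_f`).
#' @param discovery_sign +1 or -1, the discovery effect direction.
#' @return one-sided p value.
#' @export
replication_p <- function(meta, discovery_sign) {
  if (!discovery_sign %in% c(-1, 1)) {
    stop("discovery_sign must be -1 or +1", call. = FALSE)
  }
  stats::pnorm(discovery_sign * meta$z_f, lower.tail = FALSE)
}

#' Replication flags across a set of attempted associations
#'
#' Computes the direction-aware one-sided p value for each attempted
#' association, adjusts across all of them with Benjamini-Hochberg, and
#' flags replication at `alpha_fdr` (default 0.10).
#'
#' @param metas list of `meta_result`.
#' @param discovery_signs vector of +/-1 discovery directions.
#' @param alpha_fdr FDR level (default 0.10).
#' @return data.frame: beta_f, se_f, z_f, one_sided_p, fdr, replicated.
#' @export
replication_test <- function(metas, discovery_signs, alpha_fdr = 0.10) {
  stopifnot(length(metas) == length(discovery_signs))
  p1 <- mapply(replication_p, metas, discovery_signs)
  out <- data.frame(
    beta_f = vapply(metas, `[[`, numeric(1), "beta_f"),
    se_f = vapply(metas, `[[`, numeric(1), "se_f"),
    z_f = vapply(metas, `[[`, numeric(1), "z_f"),
    k_studies = vapply(metas, `[[`, integer(1), "k_studies"),
    expected_sign = discovery_signs,
    one_sided_p = p1
  )
  out$fdr <- stats::p.adjust(pmax(out$one_sided_p, .Machine$double.xmin),
                             method = "BH")
  out$replicated <- out$fdr < alpha_fdr
  out
}

#' Which associations are eligible for a replication attempt?
#'
#' An association is attemptable iff at least one replication cohort
#' allocated more than `min_cases` asthma cases to the stratum.
#'
#' @param case_counts matrix or data.frame of case counts, associations in
#'   rows, cohorts in columns.
#' @param min_cases threshold (default 100).
#' @return logical vector over the rows.
#' @export
eligibility_filter <- function(case_counts, min_cases = 100L) {
  m <- as.matrix(case_counts)
  apply(m, 1L, function(x) any(x > min_cases, na.rm = TRUE))
}

#' Meta-analyse per-cohort association tables
#'
#' Joins per-cohort `assoc_records` by (snp, stratum); cohorts missing a
#' SNP (or with a non-converged fit) are dropped from that SNP's pool, with
#' the number of contributing studies recorded.
#'
#' @param cohort_assocs list of `assoc_records` data.frames.
#' @param discovery `assoc_records` providing the expected direction.
#' @param alpha_fdr FDR level for replication (default 0.10).
#' @param min_cases eligibility threshold on per-cohort case counts.
#' @return data.frame with snp, stratum, meta columns and replication flags;
#'   ineligible associations carry `attempted = FALSE`.
#' @export
meta_analyse <- function(cohort_assocs, discovery, alpha_fdr = 0.10,
                         min_cases = 100L) {
  key <- function(d) paste(d$snp, d$stratum, sep = "\r")
  dkey <- key(discovery)
  rows <- list(); metas <- list(); signs <- numeric(0)
  attempted <- logical(nrow(discovery))
  for (i in seq_len(nrow(discovery))) {
    per <- lapply(cohort_assocs, function(a) {
      j <- match(dkey[i], key(a))
      if (is.na(j) || !isTRUE(a$converged[j]) || is.na(a$beta[j])) NULL
      else a[j, ]
    })
    per <- per[!vapply(per, is.null, logical(1))]
    n_cases <- vapply(per, function(x) x$n_case, numeric(1))
    attempted[i] <- length(per) > 0 && any(n_cases > min_cases)
    if (!attempted[i]) next
    metas[[length(metas) + 1L]] <- ivw_meta(
      vapply(per, function(x) x$beta, numeric(1)),
      vapply(per, function(x) x$se, numeric(1)))
    signs <- c(signs, sign(discovery$beta[i]))
    rows[[length(rows) + 1L]] <- i
  }
  out <- discovery[c("snp", "stratum")]
  out$attempted <- attempted
  out$beta_f <- out$se_f <- out$z_f <- out$one_sided_p <- out$fdr <- NA_real_
  out$k_studies <- NA_integer_
  out$replicated <- FALSE
  if (length(metas)) {
    rep <- replication_test(metas, signs, alpha_fdr)
    idx <- unlist(rows)
    out$beta_f[idx] <- rep$beta_f
    out$se_f[idx] <- rep$se_f
    out$z_f[idx] <- rep$z_f
    out$k_studies[idx] <- rep$k_studies
    out$one_sided_p[idx] <- rep$one_sided_p
    out$fdr[idx] <- rep$fdr
    out$replicated[idx] <- rep$replicated
  }
  out
}
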