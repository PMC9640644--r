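# Power-matched comparison of subgroup vs whole-group association strength:
# the whole-group Z score is re-estimated ("projected") at the subgroup's
# sample size by stratified subsampling, and the subgroup Z is tested
# against the empirical projected distribution.

#' Effective sample size of a case-control comparison
#'
#' `1 / (1/n_case + 1/n_ctrl)` — the harmonic composition through which the
#' Z score depends on the two group sizes.
#'
#' @param n_case,n_ctrl positive counts.
#' @return numeric scalar.
#' @export
effective_n <- function(n_case, n_ctrl) {
  if (any(c(n_case, n_ctrl) <= 0)) stop("counts must be positive", call. = FALSE)
  1 / (1 / n_case + 1 / n_ctrl)
}

#' Z score from effect size, sample SD and sample size
#'
#' `Z = beta / (sigma / sqrt(n))`: at fixed effect and dispersion the Z
#' score scales with the square root of the (effective) sample size, which
#' is why subgroup and whole-group statistics cannot be compared without
#' matching power.
#'
#' @param beta effect estimate.
#' @param sigma positive sample standard deviation.
#' @param n positive (effective) sample size.
#' @return numeric scalar.
#' @export
z_score <- function(beta, sigma, n) {
  if (sigma <= 0 || n <= 0) stop("sigma and n must be positive", call. = FALSE)
  beta / (sigma / sqrt(n))
}

#' Stratified allocation by largest-remainder rounding
#'
#' Allocates `target_total` draws across strata proportionally to their
#' sizes: integer floors first, then the remaining units to the largest
#' fractional remainders, ties broken toward the lowest stratum index.
#'
#' @param strata_sizes positive integer sizes.
#' @param target_total total draws, at most `sum(strata_sizes)`.
#' @return integer allocation summing exactly to `target_total`.
#' @export
proportional_allocation <- function(strata_sizes, target_total) {
  if (target_total > sum(strata_sizes)) {
    stop("target_total exceeds the population", call. = FALSE)
  }
  quota <- target_total * strata_sizes / sum(strata_sizes)
  alloc <- floor(quota)
  rem <- target_total - sum(alloc)
  if (rem > 0) {
    frac <- quota - alloc
    give <- order(-frac, seq_along(frac))[seq_len(rem)]
    alloc[give] <- alloc[give] + 1
  }
  if (any(alloc > strata_sizes)) {
    stop("allocation exceeds a stratum size", call. = FALSE)
  }
  as.integer(alloc)
}

#' Stratified subsample of ids, proportional within strata
#'
#' @param ids_by_stratum list of id vectors, one per stratum.
#' @param target_total number of ids to draw in total.
#' @return list with `counts` (per-stratum draws) and `ids` (sampled ids).
#' @export
stratified_subsample <- function(ids_by_stratum, target_total) {
  sizes <- lengths(ids_by_stratum)
  counts <- proportional_allocation(sizes, target_total)
  ids <- unlist(mapply(function(v, k) {
    if (k == 0L) character(0) else v[sample.int(length(v), k)]
  }, ids_by_stratum, counts, SIMPLIFY = FALSE), use.names = FALSE)
  list(counts = counts, ids = ids)
}

#' Empirical sample of projected whole-group Z scores
#'
#' Repeats `R` times: draw cases and controls from the whole group, shrunk
#' to the subgroup's sizes with the stratum composition proportionally
#' unchanged, refit the association, record the Z.  Failed fits are
#' recorded as missing; more than `max_missing_frac` missing draws is an
#' error.
#'
#' @param assoc_fn function(case_ids, ctrl_ids) returning a Z score (or NA).
#' @param cases_by_stratum,ctrls_by_stratum lists of id vectors per stratum.
#' @param n_case_s,n_ctrl_s subgroup case/control sizes to match.
#' @param R number of subsampling replicates.
#' @param seed seed for the replicate stream.
#' @param max_missing_frac tolerated fraction of failed draws (default 0.05).
#' @return numeric vector of length <= R (missing draws removed), with
#'   attribute `n_missing`.
#' @export
project_z <- function(assoc_fn, cases_by_stratum, ctrls_by_stratum,
                      n_case_s, n_ctrl_s, R = 2000L, seed = 1L,
                      max_missing_frac = 0.05) {
  stopifnot(R >= 1L)
  set.seed(child_seed(seed, 9100L))
  zs <- vapply(seq_len(R), function(r) {
    cs <- stratified_subsample(cases_by_stratum, n_case_s)
    ct <- stratified_subsample(ctrls_by_stratum, n_ctrl_s)
    z <- tryCatch(assoc_fn(cs$ids, ct$ids), error = function(e) NA_real_)
    if (is.null(z) || !is.finite(z)) NA_real_ else z
  }, numeric(1))
  n_miss <- sum(is.na(zs))
  if (n_miss > max_missing_frac * R) {
    stop(sprintf("%d of %d projection draws failed", n_miss, R), call. = FALSE)
  }
  out <- zs[!is.na(zs)]
  attr(out, "n_missing") <- n_miss
  out
}

#' Empirical two-tailed p value against a projected sample
#'
#' Doubles the smaller one-sided add-one count:
#' `p = min(1, 2 (min(#\{z >= z_s\}, #\{z <= z_s\}) + 1) / (R + 1))`,
#' so p is never below `2/(R+1)` and never zero.
#'
#' @param z_s observed subgroup Z score.
#' @param projected_z projected sample.
#' @return empirical p value.
#' @export
empirical_two_tailed_p <- function(z_s, projected_z) {
  if (!length(projected_z)) stop("empty projected sample", call. = FALSE)
  r <- length(projected_z)
  upper <- sum(projected_z >= z_s)
  lower <- sum(projected_z <= z_s)
  min(1, 2 * (min(upper, lower) + 1) / (r + 1))
}

#' Flag subgroup associations significantly stronger than the whole group
#'
#' For every candidate (a subgroup association below the suggestive
#' threshold), builds the projected whole-group Z distribution at the
#' subgroup's matched sample sizes, computes the empirical two-tailed p,
#' adjusts across candidates with Benjamini-Hochberg, and flags FDR <
#' `alpha_fdr`.
#'
#' @param candidates data.frame with columns snp, z_s, n_case_s, n_ctrl_s.
#' @param assoc_fn_factory function(snp) returning the `assoc_fn` for
#'   [project_z()] on that SNP.
#' @param cases_by_stratum,ctrls_by_stratum whole-group ids per stratum.
#' @param R replicates per candidate (default 2000).
#' @param seed master seed.
#' @param alpha_fdr flag threshold (default 0.05).
#' @return data.frame: candidates plus empirical_p, fdr, stronger.
#' @export
stronger_locus_test <- function(candidates, assoc_fn_factory,
                                cases_by_stratum, ctrls_by_stratum,
                                R = 2000L, seed = 1L, alpha_fdr = 0.05) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$empirical_p <- numeric(0)
    out$fdr <- numeric(0)
    out$stronger <- logical(0)
    return(out)
  }
  ps <- vapply(seq_len(nrow(candidates)), function(i) {
    proj <- project_z(assoc_fn_factory(candidates$snp[i]),
                      cases_by_stratum, ctrls_by_stratum,
                      candidates$n_case_s[i], candidates$n_ctrl_s[i],
                      R = R, seed = child_seed(seed, 9200L + i))
    empirical_two_tailed_p(candidates$z_s[i], proj)
  }, numeric(1))
  out <- candidates
  out$empirical_p <- ps
  out$fdr <- stats::p.adjust(ps, method = "BH")
  out$stronger <- out$fdr < alpha_fdr
  out
}
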