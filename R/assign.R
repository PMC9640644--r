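# Assignment of individuals to subgroups by nonnegative least-squares
# decomposition of their diagnosis count distribution over the subgroup
# representative profiles.

#' Project one diagnosis count vector onto the subgroup representatives
#'
#' The count vector is normalized to a frequency vector and decomposed as a
#' nonnegative linear combination of the K subgroup representatives
#' (`theta = argmin ||w_norm - t(Phi) theta||` with `theta >= 0`); the
#' individual is labeled with the subgroup of largest coefficient, ties
#' broken toward the lowest index.
#'
#' @param w nonnegative count vector of length V (at least one nonzero).
#' @param Phi K x V matrix of subgroup representatives (simplex rows).
#' @param nonneg constrain coefficients to be nonnegative (default TRUE;
#'   FALSE gives the unconstrained least-squares fit for comparison).
#' @return list of class `assignment_result`: `theta`, `subgroup_label`,
#'   `residual` (L2 reconstruction error), `tie` (logical).
#' @export
project_record <- function(w, Phi, nonneg = TRUE) {
  Phi <- as.matrix(Phi)
  if (length(w) != ncol(Phi)) stop("w and Phi dimensions differ", call. = FALSE)
  if (any(w < 0)) stop("negative counts", call. = FALSE)
  s <- sum(w)
  if (s == 0) stop("no comorbid diagnoses: all-zero count vector", call. = FALSE)
  wn <- w / s
  A <- t(Phi)
  theta <- if (nonneg) {
    pracma::lsqnonneg(A, wn)$x
  } else {
    stats::lsfit(A, wn, intercept = FALSE)$coefficients
  }
  resid <- sqrt(sum((wn - A %*% theta)^2))
  mx <- max(theta)
  winners <- which(theta >= mx - 1e-12)
  structure(list(theta = as.numeric(theta),
                 subgroup_label = winners[1L],
                 residual = resid,
                 tie = length(winners) > 1L),
            class = "assignment_result")
}

#' Assign every eligible patient in a cohort to a subgroup
#'
#' Cases and controls alike are assigned: the subgroups were learnt from
#' cases, but controls sharing a comorbidity pattern are classified with the
#' same representatives so each subgroup has its own control stratum.
#' Patients with no comorbid diagnosis are excluded (counted).
#'
#' @param W patient-by-disease count matrix (rownames = patient ids).
#' @param subgroups list of `subgroup_profile` (or a K x V matrix).
#' @param nonneg see [project_record()].
#' @return data.frame (patient_id, subgroup_id, residual, tie, theta matrix
#'   column); attributes `n_excluded` and `n_ties`.
#' @export
assign_cohort <- function(W, subgroups, nonneg = TRUE) {
  Phi <- if (is.list(subgroups) && inherits(subgroups[[1]], "subgroup_profile")) {
    do.call(rbind, lapply(subgroups, function(p) p$representative))
  } else {
    as.matrix(subgroups)
  }
  W <- as.matrix(W)
  eligible <- rowSums(W) > 0
  res <- lapply(which(eligible), function(i) project_record(W[i, ], Phi, nonneg))
  out <- data.frame(
    patient_id = rownames(W)[eligible],
    subgroup_id = vapply(res, `[[`, integer(1), "subgroup_label"),
    residual = vapply(res, `[[`, numeric(1), "residual"),
    tie = vapply(res, `[[`, logical(1), "tie"),
    stringsAsFactors = FALSE
  )
  out$theta <- do.call(rbind, lapply(res, `[[`, "theta"))
  attr(out, "n_excluded") <- sum(!eligible)
  attr(out, "n_ties") <- sum(out$tie)
  out
}

#' Subgroup/code co-occurrence fractions
#'
#' Two diagnostics of assignment coherence: (i) the fraction of patients in
#' `subgroup` who carry at least one deduplicated event of disease group
#' `top_code`, and (ii) the fraction of carriers of `top_code` who are
#' assigned to `subgroup`.
#'
#' @param labels assignment data.frame from [assign_cohort()].
#' @param W count matrix used for the assignment.
#' @param subgroup subgroup id.
#' @param top_code disease-group column (index or name).
#' @return named numeric vector `c(frac_i, frac_ii)`; NA with a warning for
#'   an empty subgroup or an uncarried code.
#' @export
assignment_fractions <- function(labels, W, subgroup, top_code) {
  W <- as.matrix(W)
  in_sub <- labels$patient_id[labels$subgroup_id == subgroup]
  carriers <- rownames(W)[W[, top_code] > 0]
  carriers <- intersect(carriers, labels$patient_id)
  if (length(in_sub) == 0L) {
    warning("empty subgroup: fractions undefined")
    return(c(frac_i = NA_real_, frac_ii = NA_real_))
  }
  frac_i <- mean(in_sub %in% carriers)
  frac_ii <- if (length(carriers)) mean(carriers %in% in_sub) else NA_real_
  c(frac_i = frac_i, frac_ii = frac_ii)
}

#' Write assignment labels as TSV
#' @param labels data.frame from [assign_cohort()].
#' @param path TSV path.
#' @export
write_labels <- function(labels, path) {
  theta <- labels$theta
  colnames(theta) <- sprintf("theta_%d", seq_len(ncol(theta)))
  flat <- cbind(labels[c("patient_id", "subgroup_id", "residual")], theta)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
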