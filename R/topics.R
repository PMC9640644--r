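# Ensemble HDP topic modeling of the patient-by-disease count matrix.

#' HDP sampler and ensemble configuration
#'
#' @param doc_concentration alpha, concentration of the per-record topic
#'   mixture around the global topic weights.
#' @param top_concentration gamma, concentration of the top-level stick;
#'   larger values make new topics easier to create.
#' @param topic_prior beta, symmetric Dirichlet smoothing of topic rows over
#'   the vocabulary.
#' @param max_iter Gibbs sweeps (default 500, enough to converge on corpora
#'   of this scale).
#' @param burn_in sweeps before the retained state; kept for interface
#'   completeness (topics are extracted from the final state, so it only
#'   needs `max_iter >= burn_in`).
#' @param k_init number of topics at initialization; the sampler grows and
#'   shrinks the count regardless.
#' @param min_topic_share drop topics holding less than this fraction of all
#'   tokens (ephemeral singleton topics).
#' @param ensemble_runs number of independent subsampled runs R.
#' @param subsample_size patients drawn (without replacement) per run.
#' @param seed master seed for the ensemble.
#' @return object of class `hdp_config`.
#' @export
hdp_config <- function(doc_concentration = 1.0,
                       top_concentration = 1.0,
                       topic_prior = 0.05,
                       max_iter = 500L,
                       burn_in = 0L,
                       k_init = 3L,
                       min_topic_share = 0.002,
                       ensemble_runs = 10L,
                       subsample_size = 1000L,
                       seed = 1L) {
  stopifnot(doc_concentration > 0, top_concentration > 0, topic_prior > 0,
            max_iter >= burn_in, burn_in >= 0,
            min_topic_share >= 0, min_topic_share < 0.5)
  structure(list(
    doc_concentration = doc_concentration,
    top_concentration = top_concentration,
    topic_prior = topic_prior,
    max_iter = as.integer(max_iter), burn_in = as.integer(burn_in),
    k_init = as.integer(k_init),
    min_topic_share = min_topic_share,
    ensemble_runs = as.integer(ensemble_runs),
    subsample_size = as.integer(subsample_size),
    seed = as.integer(seed)
  ), class = "hdp_config")
}

#' Fit the HDP topic model to a count matrix by collapsed Gibbs sampling
#'
#' Direct-assignment sampler: token-level topic indicators are resampled
#' against the global topic weights, table counts are regenerated each sweep
#' to resample the weights, and empty topics are pruned, so the number of
#' topics is inferred rather than fixed.  Topic rows are extracted from the
#' final state as `(counts + beta) / (total + V beta)`; topics holding less
#' than `min_topic_share` of the tokens are dropped.
#'
#' @param W patient-by-disease count matrix (nonnegative integers).
#' @param cfg an [hdp_config()].
#' @param run_id identifier attached to the returned topic points.
#' @return data.frame of topic points: `run_id`, `topic_id`, `topic_mass`,
#'   and a `phi` matrix column (`V` columns named after `colnames(W)`);
#'   attributes `log_joint_init` / `log_joint_final`.
#' @export
hdp_gibbs_run <- function(W, cfg = hdp_config(), run_id = 1L) {
  stopifnot(inherits(cfg, "hdp_config"))
  W <- as.matrix(W)
  if (nrow(W) == 0L || sum(W) == 0) {
    stop("count matrix has no tokens to model", call. = FALSE)
  }
  storage.mode(W) <- "integer"
  set.seed(child_seed(cfg$seed, 7000L + run_id))
  res <- .hdp_gibbs_cpp(W, cfg$doc_concentration, cfg$top_concentration,
                        cfg$topic_prior, cfg$max_iter, cfg$k_init)
  phi <- res$phi
  mass <- as.numeric(res$topic_mass)
  keep <- mass >= cfg$min_topic_share
  phi <- phi[keep, , drop = FALSE]
  mass <- mass[keep]
  ord <- order(mass, decreasing = TRUE)
  phi <- phi[ord, , drop = FALSE]
  mass <- mass[ord]
  colnames(phi) <- colnames(W)
  out <- data.frame(run_id = rep(run_id, length(mass)),
                    topic_id = seq_along(mass),
                    topic_mass = mass)
  out$phi <- phi
  attr(out, "log_joint_init") <- res$log_joint_init
  attr(out, "log_joint_final") <- res$log_joint_final
  class(out) <- c("topic_points", class(out))
  out
}

#' Run the subsampled HDP ensemble
#'
#' Draws `ensemble_runs` subsamples of `subsample_size` patients without
#' replacement (within a run), fits the HDP to each with a run-specific
#' child seed, and pools the resulting topic points.
#'
#' @param W full patient-by-disease count matrix.
#' @param cfg an [hdp_config()].
#' @return pooled `topic_points` data.frame.
#' @export
run_ensemble <- function(W, cfg = hdp_config()) {
  stopifnot(inherits(cfg, "hdp_config"))
  W <- as.matrix(W)
  n <- nrow(W)
  if (cfg$subsample_size > n) {
    stop("subsample_size exceeds the number of patients", call. = FALSE)
  }
  runs <- lapply(seq_len(cfg$ensemble_runs), function(r) {
    set.seed(child_seed(cfg$seed, 8000L + r))
    idx <- sample.int(n, cfg$subsample_size)
    Wr <- W[idx, , drop = FALSE]
    Wr <- Wr[rowSums(Wr) > 0, , drop = FALSE]
    hdp_gibbs_run(Wr, cfg, run_id = r)
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  class(out) <- c("topic_points", class(out))
  out
}

#' Write / read pooled topic points as TSV
#'
#' Columns: run_id, topic_id, topic_mass, then one probability column per
#' disease group.
#'
#' @param points a `topic_points` data.frame.
#' @param path TSV path.
#' @export
write_topic_points <- function(points, path) {
  flat <- cbind(points[c("run_id", "topic_id", "topic_mass")],
                as.data.frame(points$phi))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topic_points
#' @export
read_topic_points <- function(path) {
  flat <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  out <- flat[c("run_id", "topic_id", "topic_mass")]
  out$phi <- as.matrix(flat[setdiff(names(flat),
                                    c("run_id", "topic_id", "topic_mass"))])
  class(out) <- c("topic_points", class(out))
  out
}
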