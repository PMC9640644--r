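# Consensus clustering of pooled topic points: Jensen-Shannon divergence,
# HDBSCAN on the precomputed divergence matrix, stability-based threshold
# selection, subgroup profile summaries, and cross-cohort matching.

#' Jensen-Shannon divergence between two probability vectors
#'
#' Base-2 JSD, `0.5 KL(p||m) + 0.5 KL(q||m)` with `m = (p+q)/2`, so the
#' value lies in `[0, 1]`: 0 iff `p == q`, 1 for disjoint supports.
#'
#' @param p,q simplex vectors of equal length.
#' @return numeric scalar in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("negative probability entries", call. = FALSE)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  max(0, 0.5 * kl(p, m) + 0.5 * kl(q, m))
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' @param points either a numeric matrix with one simplex row per point or a
#'   `topic_points` data.frame (its `phi` rows are used).
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_divergence <- function(points) {
  P <- if (is.data.frame(points)) as.matrix(points$phi) else as.matrix(points)
  n <- nrow(P)
  if (n == 0L) stop("no points given", call. = FALSE)
  if (any(P < 0)) stop("negative probability entries", call. = FALSE)
  # vectorized base-2 JSD via entropies: JSD = H(m) - (H(p)+H(q))/2
  xlog <- function(M) {
    out <- M * log2(M)
    out[M == 0] <- 0
    out
  }
  h <- -rowSums(xlog(P))                 # per-point entropy
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i == n) break
    M <- (P[rep(i, n - i), , drop = FALSE] + P[(i + 1):n, , drop = FALSE]) / 2
    hm <- -rowSums(xlog(M))
    v <- pmax(0, hm - (h[i] + h[(i + 1):n]) / 2)
    D[i, (i + 1):n] <- v
    D[(i + 1):n, i] <- v
  }
  D
}

# ---------------------------------------------------------------------------
# HDBSCAN on a precomputed distance matrix.
#
# Core distances -> mutual reachability -> minimum spanning tree ->
# single-linkage hierarchy -> condensed tree at min_cluster_size ->
# excess-of-mass cluster selection.  Stability of a cluster is the usual
# condensed-tree persistence, sum over its points of (lambda_leave -
# lambda_birth) with lambda = 1 / mutual-reachability distance.
# ---------------------------------------------------------------------------

#' HDBSCAN clustering of a precomputed distance matrix
#'
#' @param dist symmetric distance matrix with zero diagonal.
#' @param min_cluster_size smallest cluster retained; smaller components are
#'   dissolved into noise.
#' @param min_samples neighborhood size for core distances; defaults to
#'   `min_cluster_size` (single-knob convention).
#' @return list with `labels` (integer, 0 = noise), `stability` (named by
#'   cluster label), and `n_clusters`.
#' @export
hdbscan_precomputed <- function(dist, min_cluster_size,
                                min_samples = NULL) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2", call. = FALSE)
  if (is.null(min_samples)) min_samples <- min_cluster_size
  if (n < min_cluster_size || n < 2L) {
    return(list(labels = rep(0L, n), stability = numeric(0), n_clusters = 0L))
  }
  min_samples <- min(min_samples, n)

  core <- vapply(seq_len(n), function(i) {
    sort(dist[i, ], partial = min_samples)[min_samples]
  }, numeric(1))
  mreach <- pmax(dist, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mreach) <- 0

  # Prim's minimum spanning tree on the dense mutual-reachability graph.
  in_tree <- logical(n)
  best_w <- rep(Inf, n)
  best_from <- integer(n)
  in_tree[1] <- TRUE
  best_w <- mreach[1, ]
  best_from[] <- 1L
  edges <- matrix(0, nrow = n - 1L, ncol = 3L)  # a, b, w
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & mreach[j, ] < best_w
    best_w[upd] <- mreach[j, upd]
    best_from[upd] <- j
  }
  edges <- edges[order(edges[, 3]), , drop = FALSE]

  # Single-linkage hierarchy via union-find; leaves 1..n, internal nodes
  # n+1 .. 2n-1 created in merge order, root = 2n-1.
  parent_uf <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  comp_node <- seq_len(n)           # component root -> current dendrogram node
  node_left <- integer(2L * n - 1L)
  node_right <- integer(2L * n - 1L)
  node_height <- numeric(2L * n - 1L)
  node_size <- c(rep(1L, n), integer(n - 1L))
  node_leaves <- vector("list", 2L * n - 1L)
  node_leaves[seq_len(n)] <- as.list(seq_len(n))
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    na <- comp_node[ra]; nb <- comp_node[rb]
    nxt <- nxt + 1L
    node_left[nxt] <- na; node_right[nxt] <- nb
    node_height[nxt] <- edges[e, 3]
    node_size[nxt] <- node_size[na] + node_size[nb]
    node_leaves[[nxt]] <- c(node_leaves[[na]], node_leaves[[nb]])
    parent_uf[ra] <- rb
    comp_node[rb] <- nxt
  }
  root <- 2L * n - 1L
  lam <- function(h) 1 / max(h, 1e-12)

  # Condensed tree.
  cl_parent <- 0L               # per-cluster parent cluster id
  cl_birth <- 0                 # lambda at which the cluster appears
  cl_stab <- 0
  n_cl <- 1L
  point_cluster <- integer(n)   # condensed-tree cluster each point falls from
  point_lambda <- numeric(n)
  stack <- list(list(node = root, cl = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cur <- top$node; cl <- top$cl
    repeat {
      if (cur <= n) { # single point left in the cluster's chain
        point_cluster[cur] <- cl
        point_lambda[cur] <- Inf
        break
      }
      l <- lam(node_height[cur])
      kids <- c(node_left[cur], node_right[cur])
      big <- node_size[kids] >= min_cluster_size
      if (all(big)) {
        for (ch in kids) {
          n_cl <- n_cl + 1L
          cl_parent[n_cl] <- cl
          cl_birth[n_cl] <- l
          cl_stab[n_cl] <- 0
          stack[[length(stack) + 1L]] <- list(node = ch, cl = n_cl)
        }
        cl_stab[cl] <- cl_stab[cl] +
          (l - cl_birth[cl]) * sum(node_size[kids])
        break
      }
      small <- kids[!big]
      for (ch in small) {
        pts <- node_leaves[[ch]]
        point_cluster[pts] <- cl
        point_lambda[pts] <- l
        cl_stab[cl] <- cl_stab[cl] + (l - cl_birth[cl]) * length(pts)
      }
      if (!any(big)) break
      cur <- kids[big][1]
    }
  }

  # Excess-of-mass selection; the root cluster is never selected.
  children <- split(seq_len(n_cl), factor(cl_parent, levels = seq_len(n_cl)))
  selected <- logical(n_cl)
  score <- numeric(n_cl)
  for (id in rev(seq_len(n_cl))) {
    kids <- children[[id]]
    if (length(kids) == 0L) {
      selected[id] <- id != 1L
      score[id] <- cl_stab[id]
    } else {
      sub <- sum(score[kids])
      if (id != 1L && cl_stab[id] >= sub) {
        selected[id] <- TRUE
        score[id] <- cl_stab[id]
        # deselect all descendants
        desc <- kids
        while (length(desc)) {
          selected[desc] <- FALSE
          desc <- unlist(children[desc], use.names = FALSE)
        }
      } else {
        score[id] <- sub
      }
    }
  }

  # Assign each point to the nearest selected ancestor of the cluster it
  # fell from, if any; otherwise noise.
  sel_ids <- which(selected)
  labels <- integer(n)
  if (length(sel_ids)) {
    lab_of <- integer(n_cl)
    lab_of[sel_ids] <- seq_along(sel_ids)
    for (p in seq_len(n)) {
      c0 <- point_cluster[p]
      while (c0 != 0L && !selected[c0]) c0 <- cl_parent[c0]
      labels[p] <- if (c0 != 0L) lab_of[c0] else 0L
    }
    # Dissolve clusters that end up with fewer members than the threshold.
    sizes <- tabulate(labels, nbins = length(sel_ids))
    drop <- which(sizes < min_cluster_size)
    if (length(drop)) {
      labels[labels %in% drop] <- 0L
      keep <- setdiff(seq_along(sel_ids), drop)
      relab <- integer(length(sel_ids))
      relab[keep] <- seq_along(keep)
      labels[labels > 0L] <- relab[labels[labels > 0L]]
      sel_ids <- sel_ids[keep]
    }
  }
  stability <- cl_stab[sel_ids]
  names(stability) <- as.character(seq_along(sel_ids))
  list(labels = labels, stability = stability,
       n_clusters = length(sel_ids))
}

#' Consensus subgroups from pooled topic points
#'
#' Clusters the pooled ensemble of topic points on their pairwise
#' Jensen-Shannon divergences with HDBSCAN; a candidate subgroup is kept
#' only if it encloses at least `min_points` topic points (the stability
#' rule).
#'
#' @param points a `topic_points` data.frame (or simplex matrix).
#' @param min_points stability threshold on enclosed cluster points.
#' @param min_samples core-distance neighborhood; defaults to `min_points`.
#' @param div optional precomputed divergence matrix.
#' @return object of class `consensus_result`: `labels` (0 = noise),
#'   `subgroups` (list of subgroup profiles, see [summarize_profiles()]),
#'   `stability_scores`, `noise_count`, `chosen_min_points`.
#' @export
hdbscan_consensus <- function(points, min_points, min_samples = NULL,
                              div = NULL) {
  P <- if (is.data.frame(points)) as.matrix(points$phi) else as.matrix(points)
  if (is.null(div)) div <- pairwise_divergence(P)
  cl <- hdbscan_precomputed(div, min_cluster_size = max(2L, min_points),
                            min_samples = min_samples)
  res <- structure(list(
    labels = cl$labels,
    stability_scores = cl$stability,
    noise_count = sum(cl$labels == 0L),
    chosen_min_points = min_points,
    phi = P
  ), class = "consensus_result")
  res$subgroups <- summarize_profiles(res)
  res
}

#' Five-number subgroup profiles
#'
#' For each subgroup, the per-disease minimum, first quartile, median, third
#' quartile and maximum of the occurring frequencies over the enclosed topic
#' points; the representative vector is the median profile renormalized to
#' the simplex, and the subgroup is named after its highest-median disease.
#'
#' @param result a `consensus_result`.
#' @return list of `subgroup_profile` objects with fields `subgroup_id`,
#'   `n_points`, `summary` (5 x V matrix), `representative`, `label`.
#' @export
summarize_profiles <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  P <- result$phi
  vnames <- colnames(P)
  if (is.null(vnames)) vnames <- sprintf("group_%03d", seq_len(ncol(P)))
  ids <- sort(unique(result$labels[result$labels > 0L]))
  lapply(ids, function(id) {
    sub <- P[result$labels == id, , drop = FALSE]
    qs <- apply(sub, 2L, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    rownames(qs) <- c("min", "q1", "median", "q3", "max")
    colnames(qs) <- vnames
    med <- qs["median", ]
    structure(list(
      subgroup_id = id,
      n_points = nrow(sub),
      summary = qs,
      representative = med / sum(med),
      label = vnames[which.max(med)]
    ), class = "subgroup_profile")
  })
}

#' Choose the stability threshold by the elbow rule
#'
#' Reruns the consensus clustering at each candidate threshold, records the
#' mean HDBSCAN stability score of the resulting subgroups, and picks the
#' threshold where the curve's increase switches from fast to slow, i.e. the
#' interior point maximizing the drop in slope
#' `(y_i - y_{i-1}) - (y_{i+1} - y_i)`.  A flat curve falls back to the
#' smallest threshold with a warning.
#'
#' @param points pooled `topic_points` (or simplex matrix).
#' @param candidate_thresholds at least three `min_points` candidates.
#' @param div optional precomputed divergence matrix.
#' @return list with `chosen` and `elbow_curve` (threshold, mean_stability,
#'   n_subgroups).
#' @export
stability_elbow <- function(points, candidate_thresholds, div = NULL) {
  if (length(candidate_thresholds) < 3L) {
    stop("need at least three candidate thresholds", call. = FALSE)
  }
  thr <- sort(candidate_thresholds)
  P <- if (is.data.frame(points)) as.matrix(points$phi) else as.matrix(points)
  if (is.null(div)) div <- pairwise_divergence(P)
  curve <- vapply(thr, function(tt) {
    cl <- hdbscan_precomputed(div, min_cluster_size = max(2L, tt))
    c(mean_stability = if (length(cl$stability)) mean(cl$stability) else 0,
      n_subgroups = cl$n_clusters)
  }, numeric(2))
  list(chosen = elbow_threshold(thr, curve["mean_stability", ]),
       elbow_curve = data.frame(threshold = thr,
                                mean_stability = curve["mean_stability", ],
                                n_subgroups = curve["n_subgroups", ]))
}

#' Elbow location of a threshold/score curve
#'
#' @param thresholds increasing thresholds.
#' @param scores mean stability at each threshold.
#' @return the chosen threshold.
#' @export
elbow_threshold <- function(thresholds, scores) {
  stopifnot(length(thresholds) == length(scores), length(thresholds) >= 3L)
  if (diff(range(scores)) == 0) {
    warning("stability curve is flat; falling back to the smallest threshold")
    return(thresholds[1L])
  }
  i <- 2:(length(scores) - 1L)
  drop_in_slope <- (scores[i] - scores[i - 1L]) - (scores[i + 1L] - scores[i])
  thresholds[i[which.max(drop_in_slope)]]
}

#' Match subgroup profiles across cohorts and flag replications
#'
#' Pearson correlations between all pairs of median profiles, greedy
#' one-to-one matching by descending correlation, and a replication flag for
#' a matched pair iff its correlation test survives Benjamini-Hochberg
#' adjustment over all candidate pairs at `alpha`.
#'
#' @param profiles_a,profiles_b lists of `subgroup_profile` (same vocabulary).
#' @param alpha FDR level for the replication flag (default 0.05).
#' @return data.frame with columns id_a, id_b, r, p, fdr, replicated.
#' @export
match_profiles_across_cohorts <- function(profiles_a, profiles_b,
                                          alpha = 0.05) {
  med <- function(p) p$summary["median", ]
  A <- do.call(rbind, lapply(profiles_a, med))
  B <- do.call(rbind, lapply(profiles_b, med))
  if (ncol(A) != ncol(B)) stop("profile vocabularies differ", call. = FALSE)
  pairs <- expand.grid(a = seq_len(nrow(A)), b = seq_len(nrow(B)))
  ct <- lapply(seq_len(nrow(pairs)), function(i) {
    stats::cor.test(A[pairs$a[i], ], B[pairs$b[i], ])
  })
  pairs$r <- vapply(ct, function(x) unname(x$estimate), numeric(1))
  pairs$p <- vapply(ct, function(x) x$p.value, numeric(1))
  pairs$fdr <- stats::p.adjust(pairs$p, method = "BH")
  ord <- order(-pairs$r)
  used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
  take <- logical(nrow(pairs))
  for (i in ord) {
    if (!used_a[pairs$a[i]] && !used_b[pairs$b[i]]) {
      take[i] <- TRUE
      used_a[pairs$a[i]] <- TRUE
      used_b[pairs$b[i]] <- TRUE
    }
  }
  out <- pairs[take, , drop = FALSE]
  out$replicated <- out$fdr < alpha & out$r > 0
  out <- out[order(out$a), ]
  names(out)[1:2] <- c("id_a", "id_b")
  rownames(out) <- NULL
  out
}

#' Write subgroup profiles as a long TSV
#'
#' Columns: subgroup_id, n_points, disease_group, min, q1, median, q3, max.
#' @param profiles list of `subgroup_profile`.
#' @param path TSV path.
#' @export
write_subgroups <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(subgroup_id = p$subgroup_id, n_points = p$n_points,
               disease_group = colnames(p$summary),
               min = p$summary["min", ], q1 = p$summary["q1", ],
               median = p$summary["median", ], q3 = p$summary["q3", ],
               max = p$summary["max", ], stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_subgroups
#' @export
read_subgroups <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lapply(split(tab, tab$subgroup_id), function(s) {
    qs <- t(as.matrix(s[c("min", "q1", "median", "q3", "max")]))
    colnames(qs) <- s$disease_group
    med <- qs["median", ]
    structure(list(
      subgroup_id = s$subgroup_id[1], n_points = s$n_points[1],
      summary = qs, representative = med / sum(med),
      label = s$disease_group[which.max(med)]
    ), class = "subgroup_profile")
  })
}
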