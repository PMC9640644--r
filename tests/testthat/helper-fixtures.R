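# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Well-separated five-topic cohort (the recovery fixture).
fixture_cohort <- function(seed = 42L, n = 2000L, doc_conc = 0.1) {
  cached(sprintf("cohort_%d_%d_%g", seed, n, doc_conc), function() {
    cfg <- synth_config(seed = seed, n_patients = n, vocab_size = 60L,
                        n_topics = 5L, dirichlet_doc_conc = doc_conc)
    topics <- generate_topics(cfg)
    sim <- generate_diagnosis_records(cfg, topics)
    mapping <- demo_code_mapping(cfg$vocab_size)
    class(mapping) <- c("code_mapping", class(mapping))
    corpus <- apply_cohort_filters(sim$corpus)
    W <- build_count_matrix(corpus, mapping)
    list(cfg = cfg, topics = topics, sim = sim, corpus = corpus,
         mapping = mapping, W = W)
  })
}

# Pooled ensemble topic points on the recovery fixture.
fixture_ensemble <- function(seed = 42L, runs = 10L, subsample = 500L,
                             iters = 200L) {
  key <- sprintf("ensemble_%d_%d_%d_%d", seed, runs, subsample, iters)
  cached(key, function() {
    fx <- fixture_cohort(seed)
    cfg <- hdp_config(ensemble_runs = runs, subsample_size = subsample,
                      max_iter = iters, seed = seed)
    run_ensemble(fx$W, cfg)
  })
}

# Brute-force best matching of estimated to true topics over all
# permutations (independent oracle for Hungarian-style assignment at K <= 6).
match_topics_bruteforce <- function(truth, est) {
  K <- nrow(truth)
  stopifnot(nrow(est) == K)
  d <- outer(seq_len(K), seq_len(K),
             Vectorize(function(i, j) js_divergence(truth[i, ], est[j, ])))
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
  costs <- apply(perms, 1, function(p) sum(d[cbind(seq_len(K), p)]))
  best <- perms[which.min(costs), ]
  list(perm = best, per_topic = d[cbind(seq_len(K), best)])
}

# Tight simplex clusters plus uniform noise, for clustering tests.
planted_simplex_points <- function(seed, n_groups = 3L, per_group = 60L,
                                   n_noise = 20L, dim = 12L) {
  set.seed(seed)
  centers <- t(vapply(seq_len(n_groups), function(k) {
    x <- stats::rgamma(dim, 0.2)
    x / sum(x)
  }, numeric(dim)))
  pts <- do.call(rbind, lapply(seq_len(n_groups), function(k) {
    t(vapply(seq_len(per_group), function(i) {
      x <- centers[k, ] * 400 + 0.5
      y <- stats::rgamma(dim, x)
      y / sum(y)
    }, numeric(dim)))
  }))
  noise <- t(vapply(seq_len(n_noise), function(i) {
    x <- stats::rgamma(dim, 1)
    x / sum(x)
  }, numeric(dim)))
  list(points = rbind(pts, noise),
       labels = c(rep(seq_len(n_groups), each = per_group),
                  rep(0L, n_noise)))
}
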