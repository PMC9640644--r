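// Direct-assignment collapsed Gibbs sampler for the hierarchical Dirichlet
// process topic model.  Token-level topic indicators are resampled against
// global topic weights (the top-level stick); table counts are drawn from
// the Chinese-restaurant distribution each sweep to resample the stick, so
// the number of topics grows and shrinks during sampling.
//
// Uses R's RNG throughout, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Number of occupied tables for n customers at dish weight a, by the
// Chinese-restaurant construction (sum of Bernoulli(a/(a+j))).
static int crt_sample(int n, double a) {
  int m = 0;
  for (int j = 0; j < n; ++j) {
    if (unif_rand() < a / (a + j)) ++m;
  }
  return m;
}

struct HdpState {
  int D, V, K;
  std::vector<int> doc, word, z;          // token-level
  std::vector<std::vector<int>> n_dk;     // per-doc topic counts
  std::vector<std::vector<int>> n_kw;     // per-topic word counts
  std::vector<int> n_k;                   // per-topic totals
  std::vector<double> pi;                 // global topic weights
  double pi_new;                          // weight of the unborn topic
  double alpha, gamma, beta;
};

static double log_joint(const HdpState& s) {
  double ll = 0.0;
  for (int k = 0; k < s.K; ++k) {
    ll += R::lgammafn(s.V * s.beta) - s.V * R::lgammafn(s.beta)
        - R::lgammafn(s.n_k[k] + s.V * s.beta);
    for (int w = 0; w < s.V; ++w) {
      ll += R::lgammafn(s.n_kw[k][w] + s.beta);
    }
  }
  for (int d = 0; d < s.D; ++d) {
    int nd = 0;
    for (int k = 0; k < s.K; ++k) {
      int c = s.n_dk[d][k];
      nd += c;
      if (c > 0) {
        double a = s.alpha * s.pi[k];
        ll += R::lgammafn(c + a) - R::lgammafn(a);
      }
    }
    ll += R::lgammafn(s.alpha) - R::lgammafn(s.alpha + nd);
  }
  return ll;
}

static void add_topic(HdpState& s) {
  s.K += 1;
  for (int d = 0; d < s.D; ++d) s.n_dk[d].push_back(0);
  s.n_kw.push_back(std::vector<int>(s.V, 0));
  s.n_k.push_back(0);
  // split the unborn-topic weight with a Beta(1, gamma) stick break
  double b = R::rbeta(1.0, s.gamma);
  s.pi.push_back(b * s.pi_new);
  s.pi_new *= (1.0 - b);
}

// Drop globally empty topics, remapping indices.
static void prune_topics(HdpState& s) {
  std::vector<int> remap(s.K, -1);
  int knew = 0;
  double freed = 0.0;
  for (int k = 0; k < s.K; ++k) {
    if (s.n_k[k] > 0) {
      remap[k] = knew++;
    } else {
      freed += s.pi[k];
    }
  }
  if (knew == s.K) return;
  for (size_t t = 0; t < s.z.size(); ++t) s.z[t] = remap[s.z[t]];
  for (int d = 0; d < s.D; ++d) {
    std::vector<int> nd(knew, 0);
    for (int k = 0; k < s.K; ++k) {
      if (remap[k] >= 0) nd[remap[k]] = s.n_dk[d][k];
    }
    s.n_dk[d] = nd;
  }
  std::vector<std::vector<int>> nkw(knew);
  std::vector<int> nk(knew, 0);
  std::vector<double> pi(knew, 0.0);
  for (int k = 0; k < s.K; ++k) {
    if (remap[k] >= 0) {
      nkw[remap[k]] = s.n_kw[k];
      nk[remap[k]] = s.n_k[k];
      pi[remap[k]] = s.pi[k];
    }
  }
  s.n_kw = nkw; s.n_k = nk; s.pi = pi;
  s.pi_new += freed;
  s.K = knew;
}

// Resample the global stick from the table counts (Chinese-restaurant
// franchise bookkeeping): m_dk ~ CRT(n_dk, alpha*pi_k), then
// (pi_1..pi_K, pi_new) ~ Dirichlet(m_.1, .., m_.K, gamma).
static void resample_pi(HdpState& s) {
  std::vector<double> m(s.K + 1, 0.0);
  for (int d = 0; d < s.D; ++d) {
    for (int k = 0; k < s.K; ++k) {
      int c = s.n_dk[d][k];
      if (c > 0) m[k] += crt_sample(c, s.alpha * s.pi[k]);
    }
  }
  m[s.K] = s.gamma;
  double tot = 0.0;
  std::vector<double> g(s.K + 1);
  for (int k = 0; k <= s.K; ++k) {
    double shape = std::max(m[k], 1e-3);
    g[k] = R::rgamma(shape, 1.0);
    tot += g[k];
  }
  for (int k = 0; k < s.K; ++k) s.pi[k] = g[k] / tot;
  s.pi_new = g[s.K] / tot;
}

// [[Rcpp::export(name = ".hdp_gibbs_cpp")]]
List hdp_gibbs_cpp(IntegerMatrix W, double alpha, double gamma, double beta,
                   int max_iter, int k_init) {
  int D = W.nrow(), V = W.ncol();
  HdpState s;
  s.D = D; s.V = V; s.alpha = alpha; s.gamma = gamma; s.beta = beta;

  // expand count matrix to token stream
  for (int d = 0; d < D; ++d) {
    for (int w = 0; w < V; ++w) {
      for (int c = 0; c < W(d, w); ++c) {
        s.doc.push_back(d);
        s.word.push_back(w);
      }
    }
  }
  int T = (int)s.doc.size();
  if (T == 0) stop("count matrix has zero tokens");

  s.K = std::max(1, k_init);
  s.n_dk.assign(D, std::vector<int>(s.K, 0));
  s.n_kw.assign(s.K, std::vector<int>(V, 0));
  s.n_k.assign(s.K, 0);
  s.z.resize(T);
  for (int t = 0; t < T; ++t) {
    int k = (int)(unif_rand() * s.K);
    if (k >= s.K) k = s.K - 1;
    s.z[t] = k;
    s.n_dk[s.doc[t]][k]++;
    s.n_kw[k][s.word[t]]++;
    s.n_k[k]++;
  }
  s.pi.assign(s.K, 1.0 / (s.K + 1.0));
  s.pi_new = 1.0 / (s.K + 1.0);

  double ll_init = log_joint(s);
  std::vector<double> prob;

  for (int it = 0; it < max_iter; ++it) {
    for (int t = 0; t < T; ++t) {
      int d = s.doc[t], w = s.word[t], k = s.z[t];
      s.n_dk[d][k]--; s.n_kw[k][w]--; s.n_k[k]--;

      prob.resize(s.K + 1);
      double tot = 0.0;
      for (int j = 0; j < s.K; ++j) {
        double p = (s.n_dk[d][j] + alpha * s.pi[j]) *
                   (s.n_kw[j][w] + beta) / (s.n_k[j] + V * beta);
        prob[j] = p;
        tot += p;
      }
      prob[s.K] = alpha * s.pi_new / V;
      tot += prob[s.K];

      double u = unif_rand() * tot, acc = 0.0;
      int knew = s.K;
      for (int j = 0; j <= s.K; ++j) {
        acc += prob[j];
        if (u <= acc) { knew = j; break; }
      }
      if (knew == s.K) add_topic(s);
      s.z[t] = knew;
      s.n_dk[d][knew]++; s.n_kw[knew][w]++; s.n_k[knew]++;
    }
    resample_pi(s);
    prune_topics(s);
    if (it % 16 == 15) Rcpp::checkUserInterrupt();
  }

  double ll_final = log_joint(s);

  NumericMatrix phi(s.K, V);
  NumericVector mass(s.K);
  for (int k = 0; k < s.K; ++k) {
    for (int w = 0; w < V; ++w) {
      phi(k, w) = (s.n_kw[k][w] + beta) / (s.n_k[k] + V * beta);
    }
    mass[k] = (double)s.n_k[k] / T;
  }
  return List::create(_["phi"] = phi, _["topic_mass"] = mass,
                      _["n_topics"] = s.K, _["n_tokens"] = T,
                      _["log_joint_init"] = ll_init,
                      _["log_joint_final"] = ll_final);
}
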