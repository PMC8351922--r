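// Collapsed Gibbs sampler for a Twitter-style LDA: one latent topic z per
// tweet drawn from the author's topic distribution, and a per-word Bernoulli
// switch y between a corpus-wide background word distribution (y = 0) and
// the tweet's topic word distribution (y = 1).
//
// Uses R's RNG throughout so set.seed() in R makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

namespace {

struct Corpus {
  std::vector<std::vector<int> > docs; // word ids, 0-based
  std::vector<int> user;               // author of each doc, 0-based
  int U, V, K;
};

struct State {
  std::vector<int> z;                            // doc topic
  std::vector<std::vector<unsigned char> > y;    // word switch (1 = topic)
  std::vector<std::vector<int> > n_ut;           // U x K docs per user/topic
  std::vector<int> n_u;                          // docs per user
  std::vector<std::vector<int> > n_tw;           // K x V topic-word counts
  std::vector<int> n_t;                          // topic totals
  std::vector<int> n_bw;                         // background word counts
  int n_b;
  long n_y[2];
};

void build_counts(const Corpus& c, State& s) {
  s.n_ut.assign(c.U, std::vector<int>(c.K, 0));
  s.n_u.assign(c.U, 0);
  s.n_tw.assign(c.K, std::vector<int>(c.V, 0));
  s.n_t.assign(c.K, 0);
  s.n_bw.assign(c.V, 0);
  s.n_b = 0;
  s.n_y[0] = s.n_y[1] = 0;
  for (size_t d = 0; d < c.docs.size(); ++d) {
    int u = c.user[d], t = s.z[d];
    s.n_ut[u][t]++;
    s.n_u[u]++;
    for (size_t i = 0; i < c.docs[d].size(); ++i) {
      int w = c.docs[d][i];
      if (s.y[d][i]) {
        s.n_tw[t][w]++; s.n_t[t]++; s.n_y[1]++;
      } else {
        s.n_bw[w]++; s.n_b++; s.n_y[0]++;
      }
    }
  }
}

// Log full conditional of z_d (doc d already removed from the counts).
// Within-document repeated words advance the smoothed counts incrementally,
// which makes this the exact collapsed conditional.
std::vector<double> z_log_conditional(const Corpus& c, const State& s, int d,
                                      double alpha, double beta) {
  int u = c.user[d];
  std::vector<double> lp(c.K);
  for (int t = 0; t < c.K; ++t) {
    double l = std::log(s.n_ut[u][t] + alpha);
    std::unordered_map<int, int> seen;
    int tot = 0;
    for (size_t i = 0; i < c.docs[d].size(); ++i) {
      if (!s.y[d][i]) continue;
      int w = c.docs[d][i];
      double num = s.n_tw[t][w] + beta + seen[w];
      double den = s.n_t[t] + c.V * beta + tot;
      l += std::log(num / den);
      seen[w]++; tot++;
    }
    lp[t] = l;
  }
  return lp;
}

int sample_discrete_log(const std::vector<double>& lp) {
  double mx = lp[0];
  for (size_t i = 1; i < lp.size(); ++i) if (lp[i] > mx) mx = lp[i];
  std::vector<double> p(lp.size());
  double sum = 0.0;
  for (size_t i = 0; i < lp.size(); ++i) { p[i] = std::exp(lp[i] - mx); sum += p[i]; }
  double u = unif_rand() * sum, acc = 0.0;
  for (size_t i = 0; i < p.size(); ++i) { acc += p[i]; if (u <= acc) return (int)i; }
  return (int)p.size() - 1;
}

// Collapsed joint log density log p(w, z, y) up to constant data terms;
// monitored for convergence.
double joint_log_lik(const Corpus& c, const State& s, double alpha,
                     double beta, double gamma_, double lambda) {
  double ll = 0.0;
  for (int u = 0; u < c.U; ++u) {
    ll += std::lgamma(c.K * alpha) - c.K * std::lgamma(alpha)
        - std::lgamma(s.n_u[u] + c.K * alpha);
    for (int t = 0; t < c.K; ++t) ll += std::lgamma(s.n_ut[u][t] + alpha);
  }
  for (int t = 0; t < c.K; ++t) {
    ll += std::lgamma(c.V * beta) - std::lgamma(s.n_t[t] + c.V * beta);
    for (int w = 0; w < c.V; ++w)
      if (s.n_tw[t][w] > 0)
        ll += std::lgamma(s.n_tw[t][w] + beta) - std::lgamma(beta);
  }
  ll += std::lgamma(c.V * lambda) - std::lgamma(s.n_b + c.V * lambda);
  for (int w = 0; w < c.V; ++w)
    if (s.n_bw[w] > 0)
      ll += std::lgamma(s.n_bw[w] + lambda) - std::lgamma(lambda);
  ll += std::lgamma(2 * gamma_) - 2 * std::lgamma(gamma_)
      + std::lgamma(s.n_y[0] + gamma_) + std::lgamma(s.n_y[1] + gamma_)
      - std::lgamma(s.n_y[0] + s.n_y[1] + 2 * gamma_);
  return ll;
}

Corpus corpus_from_r(List docs_, IntegerVector doc_user, int U, int V, int K) {
  Corpus c;
  c.U = U; c.V = V; c.K = K;
  int D = docs_.size();
  c.docs.resize(D);
  c.user.resize(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector v = docs_[d];
    c.docs[d].assign(v.begin(), v.end());
    c.user[d] = doc_user[d];
  }
  return c;
}

} // namespace

// [[Rcpp::export(name = ".tlda_gibbs")]]
List tlda_gibbs(List docs_, IntegerVector doc_user, int U, int V, int K,
                double alpha, double beta, double gamma_, double lambda,
                int iters, int burn_in) {
  if (iters <= burn_in) stop("iters must exceed burn_in");
  Corpus c = corpus_from_r(docs_, doc_user, U, V, K);
  int D = c.docs.size();

  State s;
  s.z.resize(D);
  s.y.resize(D);
  for (int d = 0; d < D; ++d) {
    s.z[d] = (int)(unif_rand() * K);
    if (s.z[d] == K) s.z[d] = K - 1;
    s.y[d].resize(c.docs[d].size());
    for (size_t i = 0; i < c.docs[d].size(); ++i)
      s.y[d][i] = unif_rand() < 0.5 ? 1 : 0;
  }
  build_counts(c, s);

  IntegerMatrix z_counts(D, K);
  NumericMatrix phi_sum(U, K), theta_sum(K, V);
  NumericVector thetaB_sum(V), loglik(iters);
  double pi_sum = 0.0;
  int n_samples = 0;

  for (int iter = 0; iter < iters; ++iter) {
    // --- resample each document's topic ---
    for (int d = 0; d < D; ++d) {
      int u = c.user[d], t_old = s.z[d];
      s.n_ut[u][t_old]--;
      for (size_t i = 0; i < c.docs[d].size(); ++i) {
        if (!s.y[d][i]) continue;
        int w = c.docs[d][i];
        s.n_tw[t_old][w]--; s.n_t[t_old]--;
      }
      std::vector<double> lp = z_log_conditional(c, s, d, alpha, beta);
      int t_new = sample_discrete_log(lp);
      s.z[d] = t_new;
      s.n_ut[u][t_new]++;
      for (size_t i = 0; i < c.docs[d].size(); ++i) {
        if (!s.y[d][i]) continue;
        int w = c.docs[d][i];
        s.n_tw[t_new][w]++; s.n_t[t_new]++;
      }
    }
    // --- resample each word's background/topic switch ---
    for (int d = 0; d < D; ++d) {
      int t = s.z[d];
      for (size_t i = 0; i < c.docs[d].size(); ++i) {
        int w = c.docs[d][i];
        if (s.y[d][i]) { s.n_tw[t][w]--; s.n_t[t]--; s.n_y[1]--; }
        else           { s.n_bw[w]--; s.n_b--; s.n_y[0]--; }
        double p0 = (s.n_y[0] + gamma_) *
                    (s.n_bw[w] + lambda) / (s.n_b + c.V * lambda);
        double p1 = (s.n_y[1] + gamma_) *
                    (s.n_tw[t][w] + beta) / (s.n_t[t] + c.V * beta);
        unsigned char y_new = unif_rand() * (p0 + p1) < p1 ? 1 : 0;
        s.y[d][i] = y_new;
        if (y_new) { s.n_tw[t][w]++; s.n_t[t]++; s.n_y[1]++; }
        else       { s.n_bw[w]++; s.n_b++; s.n_y[0]++; }
      }
    }
    loglik[iter] = joint_log_lik(c, s, alpha, beta, gamma_, lambda);
    if (iter >= burn_in) {
      n_samples++;
      for (int d = 0; d < D; ++d) z_counts(d, s.z[d])++;
      for (int u = 0; u < U; ++u)
        for (int t = 0; t < K; ++t)
          phi_sum(u, t) += (s.n_ut[u][t] + alpha) / (s.n_u[u] + K * alpha);
      for (int t = 0; t < K; ++t)
        for (int w = 0; w < V; ++w)
          theta_sum(t, w) += (s.n_tw[t][w] + beta) / (s.n_t[t] + V * beta);
      for (int w = 0; w < V; ++w)
        thetaB_sum[w] += (s.n_bw[w] + lambda) / (s.n_b + V * lambda);
      pi_sum += (s.n_y[1] + gamma_) / (s.n_y[0] + s.n_y[1] + 2 * gamma_);
    }
  }

  for (int u = 0; u < U; ++u)
    for (int t = 0; t < K; ++t) phi_sum(u, t) /= n_samples;
  for (int t = 0; t < K; ++t)
    for (int w = 0; w < V; ++w) theta_sum(t, w) /= n_samples;
  for (int w = 0; w < V; ++w) thetaB_sum[w] /= n_samples;

  return List::create(
    _["z_counts"] = z_counts,
    _["phi"] = phi_sum,
    _["theta"] = theta_sum,
    _["theta_b"] = thetaB_sum,
    _["pi"] = pi_sum / n_samples,
    _["loglik"] = loglik,
    _["n_samples"] = n_samples
  );
}

// Exact full conditional of one document's topic given the rest of the
// state, computed by the same routine the sampler uses. Exposed so tests
// can compare it against brute-force enumeration of the collapsed
// posterior. `d` is 1-based; z is 1-based topic ids; y_ is a list of 0/1
// vectors.
// [[Rcpp::export(name = ".tlda_z_conditional")]]
NumericVector tlda_z_conditional(List docs_, IntegerVector doc_user,
                                 IntegerVector z, List y_, int U, int V,
                                 int K, double alpha, double beta, int d) {
  Corpus c = corpus_from_r(docs_, doc_user, U, V, K);
  int D = c.docs.size();
  if (d < 1 || d > D) stop("document index out of range");
  State s;
  s.z.resize(D);
  s.y.resize(D);
  for (int i = 0; i < D; ++i) {
    s.z[i] = z[i] - 1;
    IntegerVector yv = y_[i];
    s.y[i].assign(yv.begin(), yv.end());
  }
  build_counts(c, s);
  int di = d - 1, u = c.user[di], t_old = s.z[di];
  s.n_ut[u][t_old]--;
  for (size_t i = 0; i < c.docs[di].size(); ++i) {
    if (!s.y[di][i]) continue;
    int w = c.docs[di][i];
    s.n_tw[t_old][w]--; s.n_t[t_old]--;
  }
  std::vector<double> lp = z_log_conditional(c, s, di, alpha, beta);
  double mx = lp[0];
  for (int t = 1; t < K; ++t) if (lp[t] > mx) mx = lp[t];
  NumericVector p(K);
  double sum = 0.0;
  for (int t = 0; t < K; ++t) { p[t] = std::exp(lp[t] - mx); sum += p[t]; }
  for (int t = 0; t < K; ++t) p[t] /= sum;
  return p;
}
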