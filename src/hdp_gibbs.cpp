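// Collapsed direct-assignment Gibbs sampler for a two-level hierarchical
// Dirichlet process mixture over count matrices (samples x categories).
// Each count unit ("item") carries a category; items are assigned to global
// dishes (signatures) shared across samples.  Per-sample DPs have
// concentration alpha over the global weights beta; the top-level DP has
// concentration gamma0 with a symmetric Dirichlet(eta) base over categories.
// Table counts for the beta update are drawn by simulating the Chinese
// restaurant (Antoniak) counts.  All randomness flows through R's RNG so
// results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List hdp_gibbs_chain(IntegerMatrix counts, int burnin, int n_collect,
                     int thin, double alpha, double gamma0, double eta) {
  const int S = counts.nrow(), K = counts.ncol();

  std::vector<int> item_s, item_c;
  for (int j = 0; j < S; ++j)
    for (int c = 0; c < K; ++c)
      for (int r = 0; r < counts(j, c); ++r) {
        item_s.push_back(j);
        item_c.push_back(c);
      }
  const int M = (int)item_s.size();
  if (M == 0) stop("count matrix has no events");

  int T = 1; // current number of dishes
  std::vector<int> z(M, 0);
  std::vector<std::vector<int>> Nkc(1, std::vector<int>(K, 0));
  std::vector<int> Nk(1, 0);
  std::vector<std::vector<int>> njk(S, std::vector<int>(1, 0));
  for (int i = 0; i < M; ++i) {
    Nkc[0][item_c[i]]++;
    Nk[0]++;
    njk[item_s[i]][0]++;
  }
  std::vector<double> beta(1, 0.5);
  double beta_new = 0.5;

  List phi_samples, theta_samples, weight_samples;
  std::vector<double> prob;

  const int total_iter = burnin + n_collect * thin;
  int collected = 0;

  for (int iter = 1; iter <= total_iter; ++iter) {
    // --- sweep over items -------------------------------------------------
    for (int i = 0; i < M; ++i) {
      const int j = item_s[i], c = item_c[i], kold = z[i];
      // remove item
      Nkc[kold][c]--;
      Nk[kold]--;
      njk[j][kold]--;
      if (Nk[kold] == 0) {
        // delete empty dish: fold its weight back, swap with last dish
        beta_new += beta[kold];
        const int klast = T - 1;
        if (kold != klast) {
          Nkc[kold] = Nkc[klast];
          Nk[kold] = Nk[klast];
          beta[kold] = beta[klast];
          for (int jj = 0; jj < S; ++jj) njk[jj][kold] = njk[jj][klast];
          for (int ii = 0; ii < M; ++ii)
            if (z[ii] == klast) z[ii] = kold;
        }
        Nkc.pop_back();
        Nk.pop_back();
        beta.pop_back();
        for (int jj = 0; jj < S; ++jj) njk[jj].pop_back();
        --T;
      }
      // sampling distribution over T existing dishes + a new one
      prob.resize(T + 1);
      double tot = 0.0;
      for (int k = 0; k < T; ++k) {
        const double like = (Nkc[k][c] + eta) / (Nk[k] + K * eta);
        prob[k] = (njk[j][k] + alpha * beta[k]) * like;
        tot += prob[k];
      }
      prob[T] = alpha * beta_new / (double)K;
      tot += prob[T];
      double u = unif_rand() * tot;
      int knew = 0;
      while (knew < T && u > prob[knew]) {
        u -= prob[knew];
        ++knew;
      }
      if (knew == T) {
        Nkc.push_back(std::vector<int>(K, 0));
        Nk.push_back(0);
        for (int jj = 0; jj < S; ++jj) njk[jj].push_back(0);
        const double b = R::rbeta(1.0, gamma0);
        beta.push_back(b * beta_new);
        beta_new *= (1.0 - b);
        ++T;
      }
      z[i] = knew;
      Nkc[knew][c]++;
      Nk[knew]++;
      njk[j][knew]++;
    }

    // --- table counts and global weights ---------------------------------
    std::vector<double> mk(T, 0.0);
    for (int j = 0; j < S; ++j)
      for (int k = 0; k < T; ++k) {
        const int n = njk[j][k];
        if (n == 0) continue;
        const double ab = alpha * beta[k];
        int m = 0;
        for (int i = 0; i < n; ++i)
          if (unif_rand() < ab / (ab + i)) ++m;
        mk[k] += m;
      }
    double tot = 0.0;
    std::vector<double> g(T + 1);
    for (int k = 0; k < T; ++k) {
      g[k] = R::rgamma(std::max(mk[k], 1e-3), 1.0);
      tot += g[k];
    }
    g[T] = R::rgamma(gamma0, 1.0);
    tot += g[T];
    for (int k = 0; k < T; ++k) beta[k] = g[k] / tot;
    beta_new = g[T] / tot;

    // --- collect ----------------------------------------------------------
    if (iter > burnin && (iter - burnin) % thin == 0 && collected < n_collect) {
      NumericMatrix phi(T, K), theta(S, T);
      NumericVector w(T);
      for (int k = 0; k < T; ++k) {
        for (int c = 0; c < K; ++c)
          phi(k, c) = (Nkc[k][c] + eta) / (Nk[k] + K * eta);
        w[k] = Nk[k] / (double)M;
      }
      for (int j = 0; j < S; ++j) {
        double rj = 0.0;
        for (int k = 0; k < T; ++k) rj += njk[j][k];
        for (int k = 0; k < T; ++k)
          theta(j, k) = rj > 0 ? njk[j][k] / rj : 0.0;
      }
      phi_samples.push_back(phi);
      theta_samples.push_back(theta);
      weight_samples.push_back(w);
      ++collected;
    }
  }

  return List::create(
    _["phi"] = phi_samples,
    _["theta"] = theta_samples,
    _["weights"] = weight_samples
  );
}
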