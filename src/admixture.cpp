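#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent allele
// frequencies (the STRUCTURE "no-admixture-prior-update" variant):
//   z_{ilc} | Q,P  ~ Cat( q_{ik} p_{kl,a_{ilc}} )
//   P_{kl.} | z    ~ Dirichlet( lambda + counts )
//   q_{i.}  | z    ~ Dirichlet( alpha + origin counts )
// G is an N x 2L integer matrix of 0-based allele indices (-1 = missing),
// columns (2l, 2l+1) holding the two copies at locus l. J[l] gives the
// allele count of locus l. Uses R's RNG so results follow set.seed().

static int sample_cat(const std::vector<double> &w, double tot) {
  double u = unif_rand() * tot;
  double acc = 0.0;
  int K = (int)w.size();
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix G, IntegerVector J, int K,
                         int sweeps, int burn, double alpha, double lambda) {
  const int N = G.nrow();
  const int L = J.size();
  int Jmax = 0, Jtot = 0;
  for (int l = 0; l < L; ++l) { Jmax = std::max(Jmax, (int)J[l]); Jtot += J[l]; }

  // allele frequencies P[k][l][j], ancestry Q[i][k]
  std::vector<double> P((size_t)K * L * Jmax, 0.0);
  std::vector<double> Q((size_t)N * K, 1.0 / K);
  std::vector<int> z((size_t)N * 2 * L, 0);

  // init P from pooled frequencies with Dirichlet noise
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) {
      double tot = 0.0;
      for (int j = 0; j < J[l]; ++j) {
        double g = R::rgamma(1.0, 1.0);
        P[((size_t)k * L + l) * Jmax + j] = g;
        tot += g;
      }
      for (int j = 0; j < J[l]; ++j)
        P[((size_t)k * L + l) * Jmax + j] /= tot;
    }

  NumericVector trace(sweeps);
  std::vector<double> Qsum((size_t)N * K, 0.0);
  std::vector<double> Psum((size_t)K * L * Jmax, 0.0);
  std::vector<double> cnt((size_t)K * L * Jmax);
  std::vector<double> ocnt((size_t)N * K);
  std::vector<double> w(K);
  int kept = 0;

  for (int s = 0; s < sweeps; ++s) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(ocnt.begin(), ocnt.end(), 0.0);

    // (i) sample cluster origins of every allele copy
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < 2 * L; ++c) {
        int a = G(i, c);
        if (a < 0) continue;
        int l = c / 2;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double v = Q[(size_t)i * K + k] * P[((size_t)k * L + l) * Jmax + a];
          w[k] = v;
          tot += v;
        }
        int zk = (tot > 0.0) ? sample_cat(w, tot)
                             : (int)(unif_rand() * K) % K;
        z[((size_t)i * 2 * L) + c] = zk;
        cnt[((size_t)zk * L + l) * Jmax + a] += 1.0;
        ocnt[(size_t)i * K + zk] += 1.0;
      }
    }

    // (ii) update cluster allele frequencies
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double tot = 0.0;
        for (int j = 0; j < J[l]; ++j) {
          double g = R::rgamma(lambda + cnt[((size_t)k * L + l) * Jmax + j], 1.0);
          P[((size_t)k * L + l) * Jmax + j] = g;
          tot += g;
        }
        for (int j = 0; j < J[l]; ++j)
          P[((size_t)k * L + l) * Jmax + j] /= tot;
      }

    // (iii) update individual ancestry proportions
    for (int i = 0; i < N; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + ocnt[(size_t)i * K + k], 1.0);
        Q[(size_t)i * K + k] = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) Q[(size_t)i * K + k] /= tot;
    }

    // observed-data log-likelihood given current P, Q
    double ll = 0.0;
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 2 * L; ++c) {
        int a = G(i, c);
        if (a < 0) continue;
        int l = c / 2;
        double mix = 0.0;
        for (int k = 0; k < K; ++k)
          mix += Q[(size_t)i * K + k] * P[((size_t)k * L + l) * Jmax + a];
        ll += std::log(std::max(mix, 1e-300));
      }
    trace[s] = ll;

    if (s >= burn) {
      ++kept;
      for (size_t t = 0; t < Qsum.size(); ++t) Qsum[t] += Q[t];
      for (size_t t = 0; t < Psum.size(); ++t) Psum[t] += P[t];
    }
  }

  NumericMatrix Qout(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k)
      Qout(i, k) = Qsum[(size_t)i * K + k] / std::max(kept, 1);

  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, J[l]);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J[l]; ++j)
        pm(k, j) = Psum[((size_t)k * L + l) * Jmax + j] / std::max(kept, 1);
    Pout[l] = pm;
  }

  return List::create(_["Q"] = Qout, _["P"] = Pout, _["trace"] = trace);
}
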