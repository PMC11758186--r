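#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// docs0: list of integer vectors of 0-based word indices.
// Sampling uses R's RNG stream (unif_rand), so results are fully
// reproducible under set.seed() on the R side.
//
// phi/theta are posterior-mean estimates averaged over every post-burn-in
// sweep:
//   phi[k,w]   = (n_kw + beta)  / (n_k + V*beta)
//   theta[d,k] = (n_dk + alpha) / (N_d + K*alpha)
//
// When check_counts is true the sampler verifies, after every sweep, that
// sum_k n_dk == N_d for all d and sum_w n_kw == n_k for all k.
// [[Rcpp::export]]
List gibbs_lda_cpp(List docs0, int V, int K, double alpha, double beta,
                   int iterations, int burn_in, bool check_counts) {
  int M = docs0.size();
  std::vector< std::vector<int> > w(M), z(M);
  IntegerMatrix ndk(M, K);
  IntegerMatrix nkw(K, V);
  std::vector<long> nk(K, 0);
  IntegerVector Nd(M);

  for (int d = 0; d < M; ++d) {
    IntegerVector wd = docs0[d];
    int n = wd.size();
    Nd[d] = n;
    w[d].resize(n);
    z[d].resize(n);
    for (int i = 0; i < n; ++i) {
      int wi = wd[i];
      if (wi < 0 || wi >= V) stop("word index out of range");
      int k = (int)(unif_rand() * K);
      if (k >= K) k = K - 1;
      w[d][i] = wi;
      z[d][i] = k;
      ndk(d, k)++;
      nkw(k, wi)++;
      nk[k]++;
    }
  }

  NumericMatrix phi_acc(K, V), theta_acc(M, K);
  int n_samples = 0;
  std::vector<double> cum(K);
  LogicalVector conserved(iterations, true);
  double Vb = V * beta;

  for (int it = 0; it < iterations; ++it) {
    for (int d = 0; d < M; ++d) {
      int n = Nd[d];
      for (int i = 0; i < n; ++i) {
        int wi = w[d][i];
        int k = z[d][i];
        ndk(d, k)--; nkw(k, wi)--; nk[k]--;
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          tot += (ndk(d, kk) + alpha) * (nkw(kk, wi) + beta) / (nk[kk] + Vb);
          cum[kk] = tot;
        }
        double u = unif_rand() * tot;
        int knew = 0;
        while (knew < K - 1 && cum[knew] < u) ++knew;
        z[d][i] = knew;
        ndk(d, knew)++; nkw(knew, wi)++; nk[knew]++;
      }
    }

    if (check_counts) {
      bool ok = true;
      for (int d = 0; d < M && ok; ++d) {
        long s = 0;
        for (int k = 0; k < K; ++k) s += ndk(d, k);
        if (s != Nd[d]) ok = false;
      }
      for (int k = 0; k < K && ok; ++k) {
        long s = 0;
        for (int v = 0; v < V; ++v) s += nkw(k, v);
        if (s != nk[k]) ok = false;
      }
      conserved[it] = ok;
    }

    if (it >= burn_in) {
      ++n_samples;
      for (int k = 0; k < K; ++k) {
        double denom = nk[k] + Vb;
        for (int v = 0; v < V; ++v)
          phi_acc(k, v) += (nkw(k, v) + beta) / denom;
      }
      for (int d = 0; d < M; ++d) {
        double denom = Nd[d] + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_acc(d, k) += (ndk(d, k) + alpha) / denom;
      }
    }
  }

  if (n_samples > 0) {
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v) phi_acc(k, v) /= n_samples;
    for (int d = 0; d < M; ++d)
      for (int k = 0; k < K; ++k) theta_acc(d, k) /= n_samples;
  }

  List zout(M);
  for (int d = 0; d < M; ++d) {
    IntegerVector zd(Nd[d]);
    for (int i = 0; i < Nd[d]; ++i) zd[i] = z[d][i] + 1; // 1-based
    zout[d] = zd;
  }
  IntegerVector nk_out(K);
  for (int k = 0; k < K; ++k) nk_out[k] = (int)nk[k];

  return List::create(
    _["phi"] = phi_acc,
    _["theta"] = theta_acc,
    _["z"] = zout,
    _["n_dk"] = ndk,
    _["n_kw"] = nkw,
    _["n_k"] = nk_out,
    _["n_samples"] = n_samples,
    _["counts_conserved"] = conserved);
}
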