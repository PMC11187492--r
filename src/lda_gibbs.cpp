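#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// docs: list of 0-based integer token-id vectors; uses R's RNG so results are
// reproducible under set.seed().

// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int K, int V, double alpha, double beta,
                   int n_iter) {
  int D = docs.size();
  IntegerMatrix ndk(D, K);
  IntegerMatrix nkw(K, V);
  IntegerVector nk(K);
  std::vector<std::vector<int>> z(D);
  std::vector<std::vector<int>> w(D);

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    int N = doc.size();
    z[d].resize(N);
    w[d].resize(N);
    for (int i = 0; i < N; ++i) {
      int wi = doc[i];
      int k = (int)std::floor(unif_rand() * K);
      if (k == K) k = K - 1;
      w[d][i] = wi;
      z[d][i] = k;
      ndk(d, k)++;
      nkw(k, wi)++;
      nk[k]++;
    }
  }

  std::vector<double> p(K);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      int N = (int)w[d].size();
      for (int i = 0; i < N; ++i) {
        int wi = w[d][i];
        int k = z[d][i];
        ndk(d, k)--; nkw(k, wi)--; nk[k]--;
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          p[kk] = (ndk(d, kk) + alpha) *
                  (nkw(kk, wi) + beta) / (nk[kk] + V * beta);
          tot += p[kk];
        }
        double u = unif_rand() * tot;
        int knew = 0;
        double cum = 0.0;
        for (; knew < K; ++knew) {
          cum += p[knew];
          if (u <= cum) break;
        }
        if (knew == K) knew = K - 1;
        z[d][i] = knew;
        ndk(d, knew)++; nkw(knew, wi)++; nk[knew]++;
      }
    }
  }
  return List::create(_["ndk"] = ndk, _["nkw"] = nkw, _["nk"] = nk);
}

// Fold-in inference for held-out documents: topic-word distributions fixed,
// per-document topic assignments resampled.

// [[Rcpp::export]]
NumericMatrix lda_foldin_cpp(List docs, NumericMatrix phi, double alpha,
                             int n_iter) {
  int D = docs.size();
  int K = phi.nrow();
  NumericMatrix theta(D, K);
  std::vector<double> p(K);

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    int N = doc.size();
    std::vector<int> z(N);
    std::vector<int> ndk(K, 0);
    for (int i = 0; i < N; ++i) {
      int wi = doc[i];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk[k] + alpha) * phi(k, wi);
        tot += p[k];
      }
      double u = unif_rand() * tot;
      int k = 0; double cum = 0.0;
      for (; k < K; ++k) { cum += p[k]; if (u <= cum) break; }
      if (k == K) k = K - 1;
      z[i] = k; ndk[k]++;
    }
    for (int iter = 0; iter < n_iter; ++iter) {
      for (int i = 0; i < N; ++i) {
        int wi = doc[i];
        ndk[z[i]]--;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (ndk[k] + alpha) * phi(k, wi);
          tot += p[k];
        }
        double u = unif_rand() * tot;
        int k = 0; double cum = 0.0;
        for (; k < K; ++k) { cum += p[k]; if (u <= cum) break; }
        if (k == K) k = K - 1;
        z[i] = k; ndk[k]++;
      }
    }
    double denom = N + K * alpha;
    for (int k = 0; k < K; ++k) theta(d, k) = (ndk[k] + alpha) / denom;
  }
  return theta;
}
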