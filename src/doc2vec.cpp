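#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Paragraph-vector training (DBOW and DM) with negative sampling.
// Uses R's RNG; single-threaded, so results are reproducible under set.seed().

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0 - 1e-8;
  if (x < -8.0) return 1e-8;
  return 1.0 / (1.0 + std::exp(-x));
}

static inline int sample_unigram(const NumericVector& cum) {
  double u = unif_rand();
  int lo = 0, hi = cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// algorithm: 0 = DBOW (doc vector predicts each word),
//            1 = DM   (mean of doc vector + window context predicts word).

// [[Rcpp::export]]
NumericMatrix doc2vec_cpp(List docs, int V, int dim, int algorithm, int window,
                          double lr0, double lr_min, int epochs, int negative,
                          NumericVector unigram_cum) {
  int D = docs.size();
  NumericMatrix docvec(D, dim);
  NumericMatrix wordvec(V, dim);   // input word vectors (DM only)
  NumericMatrix outvec(V, dim);    // output (context) vectors, zero-init
  for (int d = 0; d < D; ++d)
    for (int j = 0; j < dim; ++j)
      docvec(d, j) = (unif_rand() - 0.5) / dim;
  for (int v = 0; v < V; ++v)
    for (int j = 0; j < dim; ++j)
      wordvec(v, j) = (unif_rand() - 0.5) / dim;

  long long total_tokens = 0;
  for (int d = 0; d < D; ++d) total_tokens += ((IntegerVector)docs[d]).size();
  long long budget = total_tokens * (long long)epochs;
  long long processed = 0;

  std::vector<double> h(dim), dh(dim);
  std::vector<int> ctx;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < D; ++d) {
      IntegerVector doc = docs[d];
      int N = doc.size();
      for (int i = 0; i < N; ++i) {
        double frac = budget > 0 ? (double)processed / (double)budget : 0.0;
        double lr = lr0 - (lr0 - lr_min) * frac;
        if (lr < lr_min) lr = lr_min;
        processed++;
        int target = doc[i];

        int nctx = 0;
        if (algorithm == 0) {
          // DBOW: hidden layer is the document vector alone
          for (int j = 0; j < dim; ++j) h[j] = docvec(d, j);
        } else {
          ctx.clear();
          int lo = i - window, hi = i + window;
          if (lo < 0) lo = 0;
          if (hi > N - 1) hi = N - 1;
          for (int c = lo; c <= hi; ++c)
            if (c != i) ctx.push_back(doc[c]);
          nctx = (int)ctx.size();
          double denom = 1.0 + nctx;
          for (int j = 0; j < dim; ++j) h[j] = docvec(d, j);
          for (int c = 0; c < nctx; ++c)
            for (int j = 0; j < dim; ++j) h[j] += wordvec(ctx[c], j);
          for (int j = 0; j < dim; ++j) h[j] /= denom;
        }

        std::fill(dh.begin(), dh.end(), 0.0);
        for (int s = 0; s <= negative; ++s) {
          int tok; double label;
          if (s == 0) { tok = target; label = 1.0; }
          else {
            tok = sample_unigram(unigram_cum);
            if (tok == target) continue;
            label = 0.0;
          }
          double f = 0.0;
          for (int j = 0; j < dim; ++j) f += h[j] * outvec(tok, j);
          double g = (label - sigmoid_clip(f)) * lr;
          for (int j = 0; j < dim; ++j) {
            dh[j] += g * outvec(tok, j);
            outvec(tok, j) += g * h[j];
          }
        }

        if (algorithm == 0) {
          for (int j = 0; j < dim; ++j) docvec(d, j) += dh[j];
        } else {
          double denom = 1.0 + nctx;
          for (int j = 0; j < dim; ++j) {
            double u = dh[j] / denom;
            docvec(d, j) += u;
            for (size_t c = 0; c < ctx.size(); ++c) wordvec(ctx[c], j) += u;
          }
        }
      }
    }
  }
  return docvec;
}
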