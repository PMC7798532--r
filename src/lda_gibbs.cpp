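#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// docs: list of integer vectors, 0-based word ids.
// Uses R's RNG so determinism is controlled by set.seed() on the R side.
// Returns final-sweep count matrices and assignments; phi/theta are formed
// in R with alpha/eta smoothing.
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double eta,
                   int iters) {
  int D = docs.size();
  IntegerMatrix nkw(K, V);   // topic x word counts
  IntegerVector nk(K);       // tokens per topic
  IntegerMatrix ndk(D, K);   // doc x topic counts
  std::vector<std::vector<int>> w(D), z(D);

  RNGScope scope;
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    int n = doc.size();
    w[d].resize(n);
    z[d].resize(n);
    for (int i = 0; i < n; ++i) {
      int wi = doc[i];
      if (wi < 0 || wi >= V) stop("word id out of range");
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      w[d][i] = wi;
      z[d][i] = k;
      ++nkw(k, wi);
      ++nk[k];
      ++ndk(d, k);
    }
  }

  std::vector<double> p(K);
  double Veta = V * eta;
  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < D; ++d) {
      int n = w[d].size();
      for (int i = 0; i < n; ++i) {
        int wi = w[d][i], k = z[d][i];
        --nkw(k, wi); --nk[k]; --ndk(d, k);
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          tot += (ndk(d, kk) + alpha) * (nkw(kk, wi) + eta) / (nk[kk] + Veta);
          p[kk] = tot;
        }
        double u = unif_rand() * tot;
        int knew = 0;
        while (knew < K - 1 && p[knew] < u) ++knew;
        z[d][i] = knew;
        ++nkw(knew, wi); ++nk[knew]; ++ndk(d, knew);
      }
    }
  }

  List zout(D);
  for (int d = 0; d < D; ++d) zout[d] = IntegerVector(z[d].begin(), z[d].end());
  return List::create(_["nkw"] = nkw, _["nk"] = nk, _["ndk"] = ndk,
                      _["z"] = zout);
}
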