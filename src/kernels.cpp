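#include <Rcpp.h>
using namespace Rcpp;

// Manhattan (L1) distance from one query vector to every row of a matrix.
// [[Rcpp::export]]
NumericVector row_l1(NumericMatrix m, NumericVector v) {
  const int n = m.nrow(), p = m.ncol();
  if (v.size() != p) stop("vector length does not match matrix columns");
  NumericVector d(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += std::abs(m(i, j) - v[j]);
    d[i] = s;
  }
  return d;
}

// Sample a DNA sequence from an order-3 Markov chain. `w` holds one row of
// next-base weights per 3-base context (contexts indexed base-4, A=0..T=3).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
std::string markov_sample(int len, NumericMatrix w) {
  if (w.nrow() != 64 || w.ncol() != 4) stop("weight matrix must be 64 x 4");
  const char bases[5] = "ACGT";
  std::string out(len, 'A');
  int ctx = 0;
  for (int i = 0; i < 3 && i < len; ++i) {
    int b = (int)(unif_rand() * 4.0); if (b > 3) b = 3;
    out[i] = bases[b];
    ctx = (ctx * 4 + b) % 64;
  }
  for (int i = 3; i < len; ++i) {
    double tot = 0.0;
    for (int j = 0; j < 4; ++j) tot += w(ctx, j);
    double u = unif_rand() * tot, acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) { acc += w(ctx, j); if (u < acc) { b = j; break; } }
    out[i] = bases[b];
    ctx = (ctx % 16) * 4 + b;
  }
  return out;
}
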