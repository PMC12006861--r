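#include <Rcpp.h>
using namespace Rcpp;

// Sample a nucleotide chain of length n from a fitted order-k Markov model.
// trans_cum: (4^k x 4) row-wise cumulative transition probabilities; a row
// whose last entry is not finite marks a context with zero observed
// transitions. init_cum: cumulative initial distribution over contexts.
// Dead contexts trigger a restart: a fresh context is drawn from the
// initial distribution and its bases are emitted. Uses R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".sample_chain_cpp")]]
List sample_chain_cpp(int n, int k, NumericMatrix trans_cum,
                      NumericVector init_cum) {
  IntegerVector out(n);
  int n_ctx = trans_cum.nrow();
  int restarts = 0;

  // draw a context index from the cumulative initial distribution
  auto draw_ctx = [&]() {
    double u = R::runif(0.0, 1.0);
    int lo = 0;
    while (lo < n_ctx - 1 && init_cum[lo] < u) ++lo;
    return lo;
  };
  // emit the k bases of a context code (most significant digit first)
  auto emit_ctx = [&](int ctx, int pos) {
    for (int j = k - 1; j >= 0; --j) {
      int p = pos + (k - 1 - j);
      if (p < n) out[p] = (ctx / (int)std::pow(4.0, j)) % 4;
    }
  };

  int ctx = draw_ctx();
  emit_ctx(ctx, 0);
  int pos = std::min(k, n);
  int mod = 1;
  for (int j = 0; j < k; ++j) mod *= 4;

  while (pos < n) {
    double last = trans_cum(ctx, 3);
    if (!R_finite(last) || last <= 0.0) {   // dead context: restart
      ++restarts;
      ctx = draw_ctx();
      emit_ctx(ctx, pos);
      pos = std::min(pos + k, n);
      continue;
    }
    double u = R::runif(0.0, 1.0) * last;
    int b = 0;
    while (b < 3 && trans_cum(ctx, b) < u) ++b;
    out[pos] = b;
    ++pos;
    ctx = (ctx * 4 + b) % mod;
  }
  return List::create(_["codes"] = out, _["restarts"] = restarts);
}
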