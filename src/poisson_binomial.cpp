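#include <Rcpp.h>
#include <vector>

// Exact Poisson-Binomial upper tail P(S >= k) by dynamic-programming
// convolution of the per-trial Bernoulli distributions. Accumulation is in
// long double (80-bit extended precision on x86) so that the full pmf is
// built without meaningful rounding and small tails are summed directly,
// avoiding 1-minus cancellation.

// [[Rcpp::export(name = ".pb_tail_cpp")]]
double pb_tail_cpp(int k, Rcpp::NumericVector p) {
  const int n = p.size();
  if (k <= 0) return 1.0;
  std::vector<long double> f(n + 1, 0.0L);
  f[0] = 1.0L;
  for (int i = 0; i < n; ++i) {
    const long double pi = p[i];
    for (int j = i + 1; j >= 1; --j)
      f[j] = f[j] * (1.0L - pi) + f[j - 1] * pi;
    f[0] *= (1.0L - pi);
  }
  long double tail = 0.0L;
  for (int j = n; j >= k; --j) tail += f[j];
  if (tail < 0.0L) tail = 0.0L;
  if (tail > 1.0L) tail = 1.0L;
  return (double)tail;
}
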