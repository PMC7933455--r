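#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv 1976 component counter (Kaspar-Schuster scan).
// Counts the components of the exhaustive production history of a
// binary sequence; the final, possibly non-novel, component is counted.
// Self-overlapping copies are allowed, so a constant string parses into
// exactly two components.
// [[Rcpp::export]]
int lz76_count_cpp(const IntegerVector& bits) {
  const int n = bits.size();
  if (n < 1) stop("empty sequence");
  for (int j = 0; j < n; ++j) {
    if (bits[j] != 0 && bits[j] != 1) stop("non-binary symbol at position %d", j + 1);
  }
  if (n == 1) return 1;

  // 1-indexed pointers as in the classic formulation:
  //   l   start of the current component
  //   i   candidate copy-source offset (0 .. l-1)
  //   k   current match length
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  for (;;) {
    if (bits[i + k - 1] == bits[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }  // ran off the end mid-component
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {          // no copy source reproduces a longer word
        ++c;
        l += kmax;
        if (l + 1 > n) break;  // last component ended exactly at n
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
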