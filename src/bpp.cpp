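#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Equilibrium base-pair probabilities over the Boltzmann ensemble of
// pseudoknot-free secondary structures, by the inside-outside algorithm.
//
// Inside recurrences (Q = all structures on [i,j], Qb = structures with the
// pair (i,j); w(i,j) is the Boltzmann weight of that pair, wstack the weight
// of an immediate helix stack between (i,j) and (i+1,j-1)):
//   Qb(i,j) = w(i,j) * [ Q(i+1,j-1) + (wstack - 1) * Qb(i+1,j-1) ]
//   Q(i,j)  = Q(i,j-1) + sum_k Q(i,k-1) * Qb(k,j)
// The outside pass accumulates the adjoint of each Qb cell by reverse
// propagation through the same recurrences; the total partition function is
// linear in each Qb cell, so P(i,j) = adj(i,j) * Qb(i,j) / Z.
//
// All cells carry a per-base scale factor 1/sigma to keep magnitudes inside
// long-double range for windows of up to a few thousand nt.

// [[Rcpp::export]]
NumericMatrix bpp_partition_cpp(IntegerVector codes, NumericMatrix wpair,
                                double wstack, int min_loop) {
  const int n = codes.size();
  NumericMatrix P(n, n);
  if (n < min_loop + 2) return P;

  const int m = n + 2;
  std::vector<long double> Q((size_t)m * m, 0.0L), Qb((size_t)m * m, 0.0L);
  std::vector<long double> Qbar((size_t)m * m, 0.0L), Qbbar((size_t)m * m, 0.0L);
  auto at = [m](int i, int j) { return (size_t)i * m + j; };

  // pair weight lookup, 0 for disallowed pairs
  auto w = [&](int i, int j) -> long double {
    double v = wpair(codes[i - 1], codes[j - 1]);
    return (long double)v;
  };

  long double wmax = 0.0L;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      if (wpair(a, b) > wmax) wmax = wpair(a, b);
  long double wst = (long double)wstack;
  long double sigma = sqrtl(wmax * (wst > 1.0L ? wst : 1.0L));
  if (sigma < 1.0L) sigma = 1.0L;
  const long double invsig = 1.0L / sigma, invsig2 = invsig * invsig;

  for (int i = 1; i <= n + 1; ++i) Q[at(i, i - 1)] = 1.0L;

  // inside pass, increasing span
  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      const int j = i + len - 1;
      if (j - i - 1 >= min_loop) {
        long double wij = w(i, j);
        if (wij > 0.0L)
          Qb[at(i, j)] = wij * invsig2 *
            (Q[at(i + 1, j - 1)] + (wst - 1.0L) * Qb[at(i + 1, j - 1)]);
      }
      long double q = Q[at(i, j - 1)] * invsig;
      for (int k = i; k <= j - min_loop - 1; ++k)
        q += Q[at(i, k - 1)] * Qb[at(k, j)];
      Q[at(i, j)] = q;
    }
  }

  const long double Z = Q[at(1, n)];
  if (Z <= 0.0L) stop("partition function vanished");

  // outside pass, decreasing span; within one cell the Q-recurrence must be
  // propagated before the Qb-recurrence (Q(i,j) feeds Qb(i,j) via k = i)
  Qbar[at(1, n)] = 1.0L;
  for (int len = n; len >= 1; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      const int j = i + len - 1;
      long double qbar = Qbar[at(i, j)];
      if (qbar != 0.0L) {
        if (j - 1 >= i) Qbar[at(i, j - 1)] += qbar * invsig;
        for (int k = i; k <= j - min_loop - 1; ++k) {
          if (k - 1 >= i) Qbar[at(i, k - 1)] += qbar * Qb[at(k, j)];
          Qbbar[at(k, j)] += qbar * Q[at(i, k - 1)];
        }
      }
      long double qbbar = Qbbar[at(i, j)];
      if (qbbar != 0.0L && j - i - 1 >= min_loop) {
        long double wij = w(i, j);
        if (wij > 0.0L) {
          long double c = qbbar * wij * invsig2;
          Qbar[at(i + 1, j - 1)] += c;
          Qbbar[at(i + 1, j - 1)] += c * (wst - 1.0L);
        }
      }
    }
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = i + min_loop + 1; j <= n; ++j) {
      long double p = Qbbar[at(i, j)] * Qb[at(i, j)] / Z;
      double pd = (double)p;
      if (pd < 0) pd = 0;
      if (pd > 1) pd = 1;
      P(i - 1, j - 1) = pd;
      P(j - 1, i - 1) = pd;
    }
  }
  return P;
}
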