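#include <Rcpp.h>
using namespace Rcpp;

// Maximal-scoring contiguous segment of a match(1)/mismatch(0) indicator
// vector under Sawyer-type scoring: each match scores +1, the j-th mismatch
// inside the segment scores -g*j (quadratic ramp).  Because the mismatch
// penalty depends on the segment's own mismatch count, a plain Kadane reset
// is not optimal; this is an exact incremental scan over all start
// positions.  Ties broken leftmost start, then longest segment.
// Returns 0-based half-open [start, end); start = end = -1 for "no segment".
// [[Rcpp::export(name = ".best_fragment_cpp")]]
List best_fragment_cpp(IntegerVector match01, double g) {
  const int n = match01.size();
  double best = 0.0;
  int bs = -1, be = -1;
  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    double sc = 0.0;
    int k = 0;
    for (int j = i; j < n; ++j) {
      if (match01[j] == 1) {
        sc += 1.0;
      } else {
        ++k;
        sc -= g * k;
      }
      if (sc > best + eps) {
        best = sc; bs = i; be = j + 1;
      } else if (sc > best - eps && bs == i && j + 1 > be) {
        // same score, same (leftmost) start: prefer longer
        be = j + 1;
      }
    }
  }
  return List::create(_["score"] = best, _["start"] = bs, _["end"] = be);
}

// Permutation null for the fragment statistic: shuffles the match/mismatch
// vector (equivalent to shuffling polymorphic-column order identically for
// both rows) and counts permutations whose best score reaches `observed`.
// Uses R's RNG (honours set.seed).  If max_exceed > 0, stops once the
// exceedance count passes it (the p-value is then a conservative lower
// summary whose significance decision at the corresponding threshold is
// exact).  Returns c(n_done, n_exceed).
// [[Rcpp::export(name = ".perm_null_cpp")]]
IntegerVector perm_null_cpp(IntegerVector match01, double g, int n_perm,
                            double observed, int max_exceed) {
  const int n = match01.size();
  std::vector<int> mv(match01.begin(), match01.end());
  int done = 0, exceed = 0;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(mv[i], mv[j]);
    }
    // exact max segment score in O(n * Kmax): for a segment ending at j
    // with k internal mismatches the best choice extends back to just
    // after the (k+1)-th previous mismatch; scores fall once
    // g*k*(k+1)/2 >= n, bounding k.
    double best = 0.0;
    {
      int kmax = n;
      if (g > 0) {
        kmax = (int)std::floor((std::sqrt(1.0 + 8.0 * n / g) - 1.0) / 2.0) + 1;
        if (kmax > n) kmax = n;
      }
      std::vector<int> mmpos; mmpos.reserve(n + 1);
      mmpos.push_back(-1);                       // sentinel before start
      for (int j = 0; j < n; ++j) {
        if (mv[j] == 0) mmpos.push_back(j);
        int nmm = (int)mmpos.size() - 1;         // mismatches in [0..j]
        int kup = nmm < kmax ? nmm : kmax;
        for (int k = 0; k <= kup; ++k) {
          int start = mmpos[nmm - k] + 1;        // after (k+1)-th prev mismatch
          int len = j - start + 1;
          // k == 0 handled separately: g may be +Inf (mismatch-free mode)
          double pen = (k == 0) ? 0.0 : g * k * (k + 1) / 2.0;
          double sc = (len - k) - pen;
          if (sc > best) best = sc;
        }
        if (best >= observed - 1e-9) break;
      }
    }
    ++done;
    if (best >= observed - 1e-9) {
      ++exceed;
      if (max_exceed > 0 && exceed >= max_exceed) break;
    }
  }
  return IntegerVector::create(done, exceed);
}

// Nussinov-style nested-structure minimum free energy.
// codes: A=0, C=1, G=2, T/U=3, anything else = -1 (unpairable).
// Pair energies: Watson-Crick (A:T, G:C) = -1, wobble G:T = -0.5.
// A pair stacked directly on an inner pair gains an extra `stack` (-1).
// Minimum hairpin loop of `minloop` (3) unpaired bases.
// Returns the minimum energy (<= 0) over all nested structures.
// [[Rcpp::export(name = ".fold_mfe_cpp")]]
double fold_mfe_cpp(IntegerVector codes, double stack, int minloop) {
  const int n = codes.size();
  if (n < 2) return 0.0;
  // pair energy lookup
  auto pairE = [&](int a, int b) -> double {
    if (a < 0 || b < 0) return 1.0;        // sentinel: no pair
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -1.0;
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -1.0;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -0.5;
    return 1.0;
  };
  const double INF = 1e9;
  std::vector<double> M(n * n, 0.0), E(n * n, INF);
  // M(i,j): best energy of subsequence [i..j]; E(i,j): best with (i,j) paired
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double e = pairE(codes[i], codes[j]);
      if (e < 0 && j - i - 1 >= minloop) {
        double inner = M[(i + 1) * n + (j - 1)];
        double innerStacked = E[(i + 1) * n + (j - 1)];
        if (innerStacked < INF / 2) {
          double with_stack = innerStacked + stack;
          if (with_stack < inner) inner = with_stack;
        }
        E[i * n + j] = e + inner;
      }
      double best = M[(i + 1) * n + j];                 // i unpaired
      double mj = M[i * n + (j - 1)];                   // j unpaired
      if (mj < best) best = mj;
      if (E[i * n + j] < best) best = E[i * n + j];
      for (int k = i; k < j; ++k) {                     // bifurcation
        double b = M[i * n + k] + M[(k + 1) * n + j];
        if (b < best) best = b;
      }
      if (best > 0) best = 0;
      M[i * n + j] = best;
    }
  }
  return M[0 * n + (n - 1)];
}
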