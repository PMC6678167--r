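#include <Rcpp.h>
using namespace Rcpp;

// Nussinov-style secondary structure DP.
// Primary objective: maximum number of base pairs (AU/GC/GU wobble, minimum
// hairpin loop length minLoop). Secondary objective (tie-break): maximum
// total stacking bonus, i.e. the most helix-like structure among the
// maximum-pairing ones. stackBonus is a 6x6 matrix of positive integer
// bonuses (centi-kcal/mol magnitudes of the nearest-neighbor stacking free
// energies), indexed by pair type of the outer and inner pair.
//
// Pair type codes: 0 AT/AU, 1 TA/UA, 2 GC, 3 CG, 4 GT/GU, 5 TG/UG, -1 none.
// Base codes: 0 A, 1 C, 2 G, 3 T. Positions with other characters (e.g. N)
// get code -1 and never pair.

static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// score packing: value = pairs * PAIRW + stackBonusTotal.
// max total stack bonus < n * 400 (deepest stack ~ -4 kcal/mol); PAIRW
// dominates for any n <= 2000.
static const int PAIRW = 1 << 20;

// [[Rcpp::export(name = ".nussinov_fold")]]
IntegerVector nussinov_fold(IntegerVector bases, IntegerMatrix stackBonus,
                            int minLoop = 3) {
  const int n = bases.size();
  IntegerVector pt(n, 0);
  if (n < minLoop + 2) return pt;

  std::vector<int> N((size_t)n * n, 0), P((size_t)n * n, -1);
  std::vector<int> ptype((size_t)n * n, -1);
  #define IDX(i, j) ((size_t)(i) * n + (j))

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      ptype[IDX(i, j)] = pair_type(bases[i], bases[j]);

  for (int len = minLoop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // P[i][j]: best structure with (i,j) paired
      if (ptype[IDX(i, j)] >= 0) {
        int best = -1;
        int innerN = (j - 1 >= i + 1) ? N[IDX(i + 1, j - 1)] : 0;
        best = innerN + PAIRW;
        if (j - 1 >= i + 1 && P[IDX(i + 1, j - 1)] >= 0) {
          int withStack = P[IDX(i + 1, j - 1)] + PAIRW +
            stackBonus(ptype[IDX(i, j)], ptype[IDX(i + 1, j - 1)]);
          if (withStack > best) best = withStack;
        }
        P[IDX(i, j)] = best;
      }
      // N[i][j]: j unpaired, or j paired with some k
      int best = N[IDX(i, j - 1)];
      for (int k = i; k <= j - minLoop - 1; ++k) {
        if (P[IDX(k, j)] < 0) continue;
        int v = P[IDX(k, j)] + (k > i ? N[IDX(i, k - 1)] : 0);
        if (v > best) best = v;
      }
      N[IDX(i, j)] = best;
    }
  }

  // traceback (deterministic: smallest k first, stacked extension preferred)
  std::vector<std::pair<int, std::pair<int, bool> > > stack;
  // entry: (i, (j, viaP)) — viaP means (i,j) is known paired
  stack.push_back(std::make_pair(0, std::make_pair(n - 1, false)));
  while (!stack.empty()) {
    int i = stack.back().first;
    int j = stack.back().second.first;
    bool viaP = stack.back().second.second;
    stack.pop_back();
    if (j <= i) continue;
    if (viaP) {
      pt[i] = j + 1;  // 1-based partner
      pt[j] = i + 1;
      if (j - 1 < i + 1) continue;
      int innerN = N[IDX(i + 1, j - 1)];
      int target = P[IDX(i, j)] - PAIRW;
      if (P[IDX(i + 1, j - 1)] >= 0 &&
          P[IDX(i + 1, j - 1)] +
            stackBonus(ptype[IDX(i, j)], ptype[IDX(i + 1, j - 1)]) == target) {
        stack.push_back(std::make_pair(i + 1,
                        std::make_pair(j - 1, true)));
      } else if (innerN == target) {
        stack.push_back(std::make_pair(i + 1,
                        std::make_pair(j - 1, false)));
      }
      continue;
    }
    if (j - i + 1 < minLoop + 2) continue;
    int val = N[IDX(i, j)];
    bool done = false;
    for (int k = i; k <= j - minLoop - 1 && !done; ++k) {
      if (P[IDX(k, j)] < 0) continue;
      int v = P[IDX(k, j)] + (k > i ? N[IDX(i, k - 1)] : 0);
      if (v == val) {
        if (k > i)
          stack.push_back(std::make_pair(i, std::make_pair(k - 1, false)));
        stack.push_back(std::make_pair(k, std::make_pair(j, true)));
        done = true;
      }
    }
    if (!done)  // j unpaired
      stack.push_back(std::make_pair(i, std::make_pair(j - 1, false)));
  }
  return pt;
}
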