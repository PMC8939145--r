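#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). A gap of length L costs
// gap_open + L * gap_extend. States: 0 = M (diagonal), 1 = Ix (gap in b,
// consumes a residue of a, "up"), 2 = Iy (gap in a, "left"). Ties are
// broken M > Ix > Iy everywhere so the traceback is deterministic
// (diagonal > up > left).

static const double NEG = -1e30;

// pointer codes: 0,1,2 = predecessor state; 3 = local-alignment start
struct DPTables {
  int n, m;
  std::vector<double> M, Ix, Iy;
  std::vector<signed char> pM, pIx, pIy;
  DPTables(int n_, int m_) : n(n_), m(m_),
    M((n_ + 1) * (m_ + 1), NEG), Ix((n_ + 1) * (m_ + 1), NEG),
    Iy((n_ + 1) * (m_ + 1), NEG),
    pM((n_ + 1) * (m_ + 1), -1), pIx((n_ + 1) * (m_ + 1), -1),
    pIy((n_ + 1) * (m_ + 1), -1) {}
  inline int at(int i, int j) const { return i * (m + 1) + j; }
};

// pick the best of (m, ix, iy) with preference M > Ix > Iy
static inline int best3(double m, double ix, double iy, double &val) {
  val = m; int s = 0;
  if (ix > val) { val = ix; s = 1; }
  if (iy > val) { val = iy; s = 2; }
  return s;
}

// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  DPTables T(n, m);
  const double go = gap_open + gap_extend, ge = gap_extend;

  T.M[T.at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (!local) {
      T.Ix[T.at(i, 0)] = -(gap_open + gap_extend * i);
      T.pIx[T.at(i, 0)] = (i == 1) ? 0 : 1;
    } else {
      T.M[T.at(i, 0)] = 0.0; T.pM[T.at(i, 0)] = 3;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (!local) {
      T.Iy[T.at(0, j)] = -(gap_open + gap_extend * j);
      T.pIy[T.at(0, j)] = (j == 1) ? 0 : 2;
    } else {
      T.M[T.at(0, j)] = 0.0; T.pM[T.at(0, j)] = 3;
    }
  }
  if (local) { T.pM[T.at(0, 0)] = 3; }

  double best = 0.0; int bi = 0, bj = 0;   // local optimum tracker
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = T.at(i, j), up = T.at(i - 1, j), lf = T.at(i, j - 1),
                dg = T.at(i - 1, j - 1);
      // Ix: gap in b (prefer opening from M on ties)
      double vIx_open = (T.M[up] <= NEG / 2) ? NEG : T.M[up] - go;
      double vIx_ext  = (T.Ix[up] <= NEG / 2) ? NEG : T.Ix[up] - ge;
      if (vIx_open >= vIx_ext) { T.Ix[c] = vIx_open; T.pIx[c] = 0; }
      else                     { T.Ix[c] = vIx_ext;  T.pIx[c] = 1; }
      // Iy: gap in a
      double vIy_open = (T.M[lf] <= NEG / 2) ? NEG : T.M[lf] - go;
      double vIy_ext  = (T.Iy[lf] <= NEG / 2) ? NEG : T.Iy[lf] - ge;
      if (vIy_open >= vIy_ext) { T.Iy[c] = vIy_open; T.pIy[c] = 0; }
      else                     { T.Iy[c] = vIy_ext;  T.pIy[c] = 2; }
      // M
      double vprev;
      int st = best3(T.M[dg], T.Ix[dg], T.Iy[dg], vprev);
      double sc = S(a[i - 1] - 1, b[j - 1] - 1);
      if (vprev <= NEG / 2) { T.M[c] = NEG; }
      else {
        T.M[c] = vprev + sc; T.pM[c] = (signed char) st;
      }
      if (local) {
        if (T.M[c] < sc) { T.M[c] = sc; T.pM[c] = 3; } // restart
        if (T.M[c] <= 0) { T.M[c] = NEG; T.pM[c] = -1; }
        if (T.pM[c] >= 0 && T.M[c] > best) { best = T.M[c]; bi = i; bj = j; }
      }
    }
  }

  std::vector<int> ares, bres;  // 0 denotes a gap
  double score;
  int i, j, state;
  if (local) {
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["a_aln"] = IntegerVector(0),
                          _["b_aln"] = IntegerVector(0),
                          _["a_start"] = 0, _["b_start"] = 0);
    }
    score = best; i = bi; j = bj; state = 0;
    while (i > 0 && j > 0) {
      if (state == 0) {
        signed char p = T.pM[T.at(i, j)];
        ares.push_back(a[i - 1]); bres.push_back(b[j - 1]);
        --i; --j;
        if (p == 3) break;
        state = p;
      } else if (state == 1) {
        signed char p = T.pIx[T.at(i, j)];
        ares.push_back(a[i - 1]); bres.push_back(0);
        --i; state = p;
      } else {
        signed char p = T.pIy[T.at(i, j)];
        ares.push_back(0); bres.push_back(b[j - 1]);
        --j; state = p;
      }
    }
    std::reverse(ares.begin(), ares.end());
    std::reverse(bres.begin(), bres.end());
    return List::create(_["score"] = score,
                        _["a_aln"] = wrap(ares), _["b_aln"] = wrap(bres),
                        _["a_start"] = i + 1, _["b_start"] = j + 1);
  }

  // global: pick final state with M > Ix > Iy preference
  const int fin = T.at(n, m);
  state = best3(T.M[fin], T.Ix[fin], T.Iy[fin], score);
  i = n; j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char p = T.pM[T.at(i, j)];
      ares.push_back(a[i - 1]); bres.push_back(b[j - 1]);
      --i; --j; state = p;
    } else if (state == 1) {
      signed char p = T.pIx[T.at(i, j)];
      ares.push_back(a[i - 1]); bres.push_back(0);
      --i; state = p;
    } else {
      signed char p = T.pIy[T.at(i, j)];
      ares.push_back(0); bres.push_back(b[j - 1]);
      --j; state = p;
    }
  }
  std::reverse(ares.begin(), ares.end());
  std::reverse(bres.begin(), bres.end());
  return List::create(_["score"] = score,
                      _["a_aln"] = wrap(ares), _["b_aln"] = wrap(bres),
                      _["a_start"] = 1, _["b_start"] = 1);
}

// Best local profile-to-sequence alignment score under affine gaps.
// prof is L x K: prof(i, c) is the gain for placing residue c (1-based
// column index passed from R) against profile position i + 1.
// [[Rcpp::export(name = ".cpp_profile_score")]]
double cpp_profile_score(NumericMatrix prof, IntegerVector s,
                         double gap_open, double gap_extend) {
  const int n = prof.nrow(), m = s.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> M((n + 1) * (m + 1), NEG), Ix((n + 1) * (m + 1), NEG),
      Iy((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) M[at(0, j)] = 0.0;
  for (int i = 0; i <= n; ++i) M[at(i, 0)] = 0.0;
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = at(i, j), up = at(i - 1, j), lf = at(i, j - 1),
                dg = at(i - 1, j - 1);
      double vIx = std::max(M[up] <= NEG / 2 ? NEG : M[up] - go,
                            Ix[up] <= NEG / 2 ? NEG : Ix[up] - ge);
      double vIy = std::max(M[lf] <= NEG / 2 ? NEG : M[lf] - go,
                            Iy[lf] <= NEG / 2 ? NEG : Iy[lf] - ge);
      Ix[c] = vIx; Iy[c] = vIy;
      double vprev = std::max(M[dg], std::max(Ix[dg], Iy[dg]));
      double sc = prof(i - 1, s[j - 1] - 1);
      double v = (vprev <= NEG / 2 ? NEG : vprev + sc);
      if (v < sc) v = sc;       // restart
      if (v <= 0) v = NEG;      // local clamp
      M[c] = v;
      if (v > best) best = v;
    }
  }
  return best;
}

// ---------------------------------------------------------------------
// Fast integer identity DP and a UCLUST-like greedy clustering loop.
// Scores are integers; traceback over signed-char state matrices yields
// the number of identical aligned positions of the optimal (tie-broken)
// global alignment.

static const int INEG = -1000000000;

struct IdentityResult { int score; int matches; int cols; };

static IdentityResult identity_dp(const int *a, int n, const int *b, int m,
                                  const int *S, int K,
                                  int go_total, int ge) {
  std::vector<int> M((n + 1) * (m + 1), INEG), Ix((n + 1) * (m + 1), INEG),
      Iy((n + 1) * (m + 1), INEG);
  std::vector<signed char> pM((n + 1) * (m + 1), -1),
      pIx((n + 1) * (m + 1), -1), pIy((n + 1) * (m + 1), -1);
  const int W = m + 1;
  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    Ix[i * W] = -(go_total + ge * (i - 1));
    pIx[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = -(go_total + ge * (j - 1));
    pIy[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    const int *srow = S + (size_t)(a[i - 1]) * K;
    int *Mi = &M[i * W], *Ixi = &Ix[i * W], *Iyi = &Iy[i * W];
    const int *Mu = &M[(i - 1) * W], *Ixu = &Ix[(i - 1) * W],
              *Iyu = &Iy[(i - 1) * W];
    signed char *pMi = &pM[i * W], *pIxi = &pIx[i * W], *pIyi = &pIy[i * W];
    for (int j = 1; j <= m; ++j) {
      int vo = (Mu[j] <= INEG / 2) ? INEG : Mu[j] - go_total;
      int ve = (Ixu[j] <= INEG / 2) ? INEG : Ixu[j] - ge;
      if (vo >= ve) { Ixi[j] = vo; pIxi[j] = 0; }
      else          { Ixi[j] = ve; pIxi[j] = 1; }
      vo = (Mi[j - 1] <= INEG / 2) ? INEG : Mi[j - 1] - go_total;
      ve = (Iyi[j - 1] <= INEG / 2) ? INEG : Iyi[j - 1] - ge;
      if (vo >= ve) { Iyi[j] = vo; pIyi[j] = 0; }
      else          { Iyi[j] = ve; pIyi[j] = 2; }
      int best = Mu[j - 1]; signed char st = 0;
      if (Ixu[j - 1] > best) { best = Ixu[j - 1]; st = 1; }
      if (Iyu[j - 1] > best) { best = Iyu[j - 1]; st = 2; }
      if (best <= INEG / 2) { Mi[j] = INEG; }
      else { Mi[j] = best + srow[b[j - 1]]; pMi[j] = st; }
    }
  }
  const int fin = n * W + m;
  int score = M[fin]; int state = 0;
  if (Ix[fin] > score) { score = Ix[fin]; state = 1; }
  if (Iy[fin] > score) { score = Iy[fin]; state = 2; }
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    ++cols;
    if (state == 0) {
      signed char p = pM[i * W + j];
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j; state = p;
    } else if (state == 1) {
      signed char p = pIx[i * W + j];
      --i; state = p;
    } else {
      signed char p = pIy[i * W + j];
      --j; state = p;
    }
  }
  IdentityResult r; r.score = score; r.matches = matches; r.cols = cols;
  return r;
}

// multiplicity-aware shared count of two sorted integer vectors
static int shared_sorted(const std::vector<int> &x, const std::vector<int> &y) {
  size_t i = 0, j = 0; int c = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (x[i] > y[j]) ++j;
    else { ++c; ++i; ++j; }
  }
  return c;
}

// [[Rcpp::export(name = ".cpp_identity_global")]]
List cpp_identity_global(IntegerVector a, IntegerVector b, NumericMatrix S,
                         double gap_open, double gap_extend) {
  int K = S.nrow();
  std::vector<int> Si((size_t)K * K);
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < K; ++c) Si[(size_t)r * K + c] = (int) S(r, c);
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  for (auto &v : av) --v;
  for (auto &v : bv) --v;
  IdentityResult r = identity_dp(av.data(), av.size(), bv.data(), bv.size(),
                                 Si.data(), K,
                                 (int)(gap_open + gap_extend),
                                 (int) gap_extend);
  return List::create(_["score"] = r.score, _["matches"] = r.matches,
                      _["columns"] = r.cols);
}

// Greedy centroid clustering over pre-ordered sequences. seqs are
// 1-based residue index vectors, already in processing order. The
// 4-mer prescreen and the near-identity Hamming shortcut are
// deterministic accelerations (UCLUST-like); accel = false forces the
// full DP for every candidate pair.
// [[Rcpp::export(name = ".cpp_greedy_cluster")]]
IntegerVector cpp_greedy_cluster(List seqs, double threshold,
                                 NumericMatrix S, double gap_open,
                                 double gap_extend, bool accel) {
  const int N = seqs.size();
  const int K = S.nrow();
  std::vector<int> Si((size_t)K * K);
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < K; ++c) Si[(size_t)r * K + c] = (int) S(r, c);
  std::vector<std::vector<int> > sq(N), km(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v = seqs[i];
    sq[i].assign(v.begin(), v.end());
    for (auto &x : sq[i]) --x;
    if (accel) {
      const std::vector<int> &s = sq[i];
      if ((int) s.size() >= 4) {
        std::vector<int> codes;
        codes.reserve(s.size() - 3);
        for (size_t p = 0; p + 3 < s.size(); ++p) {
          if (s[p] >= 20 || s[p+1] >= 20 || s[p+2] >= 20 || s[p+3] >= 20)
            continue;  // skip 4-mers containing X
          codes.push_back(((s[p] * 20 + s[p+1]) * 20 + s[p+2]) * 20 + s[p+3]);
        }
        std::sort(codes.begin(), codes.end());
        km[i] = codes;
      }
    }
  }
  const int go_total = (int)(gap_open + gap_extend), ge = (int) gap_extend;
  const double t4 = threshold * threshold * threshold * threshold;
  std::vector<int> centroid;           // indices of centroids
  IntegerVector membership(N);
  for (int i = 0; i < N; ++i) {
    int assigned = 0;
    const int li = sq[i].size();
    for (size_t k = 0; k < centroid.size() && !assigned; ++k) {
      const int c = centroid[k];
      const int lc = sq[c].size();
      const int lmin = std::min(li, lc);
      if (lmin == 0) continue;
      if (accel) {
        // near-identical equal-length pair: diagonal comparison
        if (li == lc) {
          // Hamming identity is the gap-free alignment's identity; at
          // near-identity the optimal alignment is the diagonal
          int ham = 0;
          for (int p = 0; p < li; ++p) if (sq[i][p] == sq[c][p]) ++ham;
          double hid = (double) ham / lmin;
          if (hid >= threshold && hid >= 0.95) { assigned = k + 1; break; }
        }
        if (lmin >= 20) {
          int kmin = (int)(0.25 * (lmin - 3) * t4);
          if (kmin > 0 && shared_sorted(km[i], km[c]) < kmin) continue;
        }
      }
      IdentityResult r = identity_dp(sq[c].data(), lc, sq[i].data(), li,
                                     Si.data(), K, go_total, ge);
      // identity over all alignment columns, terminal gaps included
      if ((double) r.matches / r.cols >= threshold) assigned = k + 1;
    }
    if (!assigned) {
      centroid.push_back(i);
      assigned = centroid.size();
    }
    membership[i] = assigned;
  }
  return membership;
}
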