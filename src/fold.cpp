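// Wavefront (anti-diagonal) free-energy minimization engine.
//
// All energies are integers in units of 0.01 kcal/mol; ENERGY_INF is the
// forbidden sentinel, saturating under addition. The recursion mirrors the
// R loop evaluators exactly (same rounding, same end-contribution
// conventions); the R re-scorer certifies agreement at test time.
//
// Tables (1-based logical indices):
//   V(i,j)   minimum energy over structures on s_i..s_j with (i,j) paired
//   WM1(i,j) multiloop fragment on s_i..s_j whose 5' end starts a branch
//            at i, trailing unpaired bases allowed (each costs c)
//   WM(i,j)  multiloop fragment with >= 1 branch, leading/trailing
//            unpaired allowed
//   W(j)     minimum energy over all structures on s_1..s_j, W(0) = 0
//
// Cells are processed diagonal by diagonal (subsequence length k = 1..n);
// cells within a diagonal depend only on strictly shorter subsequences,
// so any visiting order - here a round-robin permutation indexed by the
// `workers` argument - yields bit-identical tables.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int E_INF = 100000000;

static inline int sadd(int a, int b) {
  return (a >= E_INF || b >= E_INF) ? E_INF : a + b;
}

struct Engine {
  int n;
  std::vector<int> code;      // 1-based, values 1..4
  std::vector<char> cand;     // candidate pair flags, (i-1)*n + (j-1)
  std::vector<int> mps;       // prefix counts of must-pair positions
  std::vector<char> must;     // 1-based must-pair flags
  std::vector<int> shp;       // 1-based SHAPE pseudo-energies (centi)
  IntegerMatrix stack_, d5_, d3_;
  IntegerVector hinit_, binit_, iinit_, tmh_, tmi_;
  IntegerMatrix adm_, all_;
  int au, mla, mlb, mlc, h, lmax, extrap, asymC, asymMax;
  int mode, maxSpan;

  Engine(IntegerVector codes, LogicalMatrix cmat, LogicalVector mustPair,
         IntegerVector shape, List par, IntegerMatrix adm, IntegerMatrix all,
         int mode_, int maxSpan_)
      : stack_(as<IntegerMatrix>(par["stack"])),
        d5_(as<IntegerMatrix>(par["dangle5"])),
        d3_(as<IntegerMatrix>(par["dangle3"])),
        hinit_(as<IntegerVector>(par["hairpin_init"])),
        binit_(as<IntegerVector>(par["bulge_init"])),
        iinit_(as<IntegerVector>(par["internal_init"])),
        tmh_(as<IntegerVector>(par["tmismatch_h"])),
        tmi_(as<IntegerVector>(par["tmismatch_i"])),
        adm_(adm), all_(all), mode(mode_), maxSpan(maxSpan_) {
    n = codes.size();
    code.assign(n + 1, 0);
    for (int i = 1; i <= n; i++) code[i] = codes[i - 1];
    cand.assign((size_t)n * n, 0);
    for (int i = 1; i <= n; i++)
      for (int j = 1; j <= n; j++)
        cand[(size_t)(i - 1) * n + (j - 1)] = cmat(i - 1, j - 1) ? 1 : 0;
    must.assign(n + 1, 0);
    mps.assign(n + 1, 0);
    for (int i = 1; i <= n; i++) {
      must[i] = mustPair[i - 1] ? 1 : 0;
      mps[i] = mps[i - 1] + (must[i] ? 1 : 0);
    }
    shp.assign(n + 1, 0);
    for (int i = 1; i <= n; i++) shp[i] = shape[i - 1];
    au = as<int>(par["terminal_au"]);
    mla = as<int>(par["ml_a"]); mlb = as<int>(par["ml_b"]); mlc = as<int>(par["ml_c"]);
    h = as<int>(par["h"]); lmax = as<int>(par["l_max"]);
    extrap = as<int>(par["extrapolation"]);
    asymC = as<int>(par["asym_coeff"]); asymMax = as<int>(par["asym_max"]);
  }

  inline bool isCand(int i, int j) const { return cand[(size_t)(i - 1) * n + (j - 1)] != 0; }
  inline bool noMust(int a, int b) const { return a > b || mps[b] - mps[a - 1] == 0; }
  inline int ptAdm(int i, int j) const { return adm_(code[i] - 1, code[j] - 1); }
  inline int ptAll(int i, int j) const { return all_(code[i] - 1, code[j] - 1); }
  inline int tmH(int p, int b1, int b2) const { return tmh_[(p - 1) + 6 * (b1 - 1) + 24 * (b2 - 1)]; }
  inline int tmI(int p, int b1, int b2) const { return tmi_[(p - 1) + 6 * (b1 - 1) + 24 * (b2 - 1)]; }
  inline int auPen(int pt) const { return (pt == 3 || pt == 4) ? 0 : au; }

  inline int initL(const IntegerVector &tab, int len) const {
    if (len <= lmax) return tab[len - 1];
    return tab[lmax - 1] +
           (int)std::floor(extrap * std::log((double)len / lmax) + 0.5);
  }

  int hairpinE(int i, int j) const {
    int pt = ptAdm(i, j);
    int len = j - i - 1;
    if (pt == 0 || len < h) return E_INF;
    int e = initL(hinit_, len);
    if (len >= 2) e += tmH(pt, code[i + 1], code[j - 1]);
    return e + auPen(pt);
  }

  int stackE(int i, int j) const {
    if (j - i < 3) return E_INF;
    int p1 = ptAdm(i, j), p2 = ptAdm(i + 1, j - 1);
    if (p1 == 0 || p2 == 0) return E_INF;
    return stack_(p1 - 1, p2 - 1);
  }

  int internalE(int i, int j, int ip, int jp) const {
    int p1 = ptAdm(i, j), p2 = ptAdm(ip, jp);
    if (p1 == 0 || p2 == 0) return E_INF;
    int l1 = ip - i - 1, l2 = j - jp - 1, lt = l1 + l2;
    if (l1 == 0 || l2 == 0) {
      int e = initL(binit_, lt);
      if (lt == 1) e += stack_(p1 - 1, p2 - 1);
      else e += auPen(p1) + auPen(p2);
      return e;
    }
    int e = initL(iinit_, lt);
    int asym = asymC * std::abs(l1 - l2);
    e += (asym < asymMax) ? asym : asymMax;
    e += tmI(p1, code[i + 1], code[j - 1]);
    int pr = ptAll(jp, ip);
    e += tmI(pr, code[jp + 1], code[ip - 1]);
    return e;
  }

  // end contribution of a branch (i,j) facing its enclosing loop
  int endBranch(int i, int j) const {
    if (mode == 0) return 0;
    int rev = all_(code[j] - 1, code[i] - 1);
    if (rev == 0) return 0;
    if (mode == 1) {
      int best = 0;
      bool has5 = i > 1, has3 = j < n;
      int d5 = has5 ? d5_(rev - 1, code[i - 1] - 1) : 0;
      int d3 = has3 ? d3_(rev - 1, code[j + 1] - 1) : 0;
      if (has5 && d5 < best) best = d5;
      if (has3 && d3 < best) best = d3;
      if (has5 && has3 && d5 + d3 < best) best = d5 + d3;
      return best;
    }
    if (i > 1 && j < n) return tmI(rev, code[j + 1], code[i - 1]);
    return 0;
  }

  // end contribution of a multiloop closing pair (i,j), seen from inside
  int endClose(int i, int j) const {
    if (mode == 0) return 0;
    int pt = ptAll(i, j);
    if (pt == 0) return 0;
    if (mode == 1) {
      int d5 = d5_(pt - 1, code[j - 1] - 1);
      int d3 = d3_(pt - 1, code[i + 1] - 1);
      int best = 0;
      if (d5 < best) best = d5;
      if (d3 < best) best = d3;
      if (d5 + d3 < best) best = d5 + d3;
      return best;
    }
    return tmI(pt, code[i + 1], code[j - 1]);
  }
};

struct Tables {
  int n;
  IntegerMatrix V, WM, WM1;
  IntegerVector W; // length n + 1, W[0] = 0
  Tables(int n_) : n(n_), V(n_, n_), WM(n_, n_), WM1(n_, n_), W(n_ + 1) {
    std::fill(V.begin(), V.end(), E_INF);
    std::fill(WM.begin(), WM.end(), E_INF);
    std::fill(WM1.begin(), WM1.end(), E_INF);
  }
  Tables(IntegerMatrix V_, IntegerMatrix WM_, IntegerMatrix WM1_, IntegerVector W_)
      : n(V_.nrow()), V(V_), WM(WM_), WM1(WM1_), W(W_) {}
  inline int v(int i, int j) const { return V(i - 1, j - 1); }
  inline int wm(int i, int j) const { return WM(i - 1, j - 1); }
  inline int wm1(int i, int j) const { return WM1(i - 1, j - 1); }
};

static inline int branchE(const Engine &E, const Tables &T, int i, int j) {
  int v = T.v(i, j);
  if (v >= E_INF) return E_INF;
  int pt = E.ptAdm(i, j);
  return sadd(v, E.mlb + E.auPen(pt) + E.endBranch(i, j));
}

static inline int extE(const Engine &E, const Tables &T, int i, int j) {
  int v = T.v(i, j);
  if (v >= E_INF) return E_INF;
  int pt = E.ptAdm(i, j);
  return sadd(v, E.auPen(pt) + E.endBranch(i, j));
}

static void computeCell(const Engine &E, Tables &T, int i, int j) {
  int n = E.n;
  // ---- V(i, j)
  if (E.isCand(i, j)) {
    int best = E_INF;
    if (E.noMust(i + 1, j - 1)) best = E.hairpinE(i, j);
    if (j - i >= 3) {
      int e = E.stackE(i, j);
      if (e < E_INF && T.v(i + 1, j - 1) < E_INF)
        best = std::min(best, sadd(e, T.v(i + 1, j - 1)));
    }
    // internal loops / bulges within the span bound
    for (int ip = i + 1; ip <= j - 2; ip++) {
      int l1 = ip - i - 1;
      if (l1 > E.maxSpan) break;
      if (l1 > 0 && !E.noMust(i + 1, ip - 1)) break; // 5' gap only grows
      for (int jp = j - 1; jp > ip; jp--) {
        int l2 = j - jp - 1;
        if (l1 + l2 > E.maxSpan) break;
        if (l2 > 0 && !E.noMust(jp + 1, j - 1)) break; // 3' gap only grows
        if (l1 == 0 && l2 == 0) continue;              // that is the stack case
        int v = T.v(ip, jp);
        if (v >= E_INF) continue;
        best = std::min(best, sadd(E.internalE(i, j, ip, jp), v));
      }
    }
    // multiloop closing
    if (j - i >= 4) {
      int pt = E.ptAdm(i, j);
      int mlBase = E.mla + E.mlb + E.auPen(pt) + E.endClose(i, j);
      for (int k = i + 2; k <= j - 1; k++) {
        int wmL = T.wm(i + 1, k - 1);
        if (wmL >= E_INF) continue;
        int w1 = T.wm1(k, j - 1);
        if (w1 >= E_INF) continue;
        best = std::min(best, sadd(mlBase, sadd(wmL, w1)));
      }
    }
    T.V(i - 1, j - 1) = sadd(best, E.shp[i] + E.shp[j]);
  }
  // ---- WM1(i, j): branch starts at i, trailing unpaired allowed
  {
    int v = E_INF;
    if (j > i && !E.must[j]) v = sadd(T.wm1(i, j - 1), E.mlc);
    v = std::min(v, branchE(E, T, i, j));
    T.WM1(i - 1, j - 1) = v;
  }
  // ---- WM(i, j): >= 1 branch, leading unpaired allowed, splits
  {
    int v = T.wm1(i, j);
    if (j > i && !E.must[i]) v = std::min(v, sadd(T.wm(i + 1, j), E.mlc));
    for (int k = i + 1; k <= j; k++) {
      int L = T.wm(i, k - 1);
      if (L >= E_INF) continue;
      int R = T.wm1(k, j);
      if (R >= E_INF) continue;
      v = std::min(v, sadd(L, R));
    }
    T.WM(i - 1, j - 1) = v;
  }
  (void)n;
}

// [[Rcpp::export]]
List cpp_fill(IntegerVector codes, LogicalMatrix cand, LogicalVector mustPair,
              IntegerVector shape, List par, IntegerMatrix adm, IntegerMatrix all,
              int mode, int maxSpan, int workers) {
  Engine E(codes, cand, mustPair, shape, par, adm, all, mode, maxSpan);
  int n = E.n;
  Tables T(n);
  if (workers < 1) workers = 1;
  for (int k = 1; k <= n; k++) {
    int cells = n - k + 1;
    // round-robin permutation over `workers` chunks: cells of one diagonal
    // are mutually independent, so every order gives identical tables
    for (int r = 0; r < workers; r++) {
      for (int c = r; c < cells; c += workers) {
        int i = c + 1, j = i + k - 1;
        computeCell(E, T, i, j);
      }
    }
  }
  T.W[0] = 0;
  for (int j = 1; j <= n; j++) {
    int v = E_INF;
    if (!E.must[j]) v = T.W[j - 1];
    for (int i = 1; i <= j; i++) {
      int e = extE(E, T, i, j);
      if (e >= E_INF) continue;
      v = std::min(v, sadd(T.W[i - 1], e));
    }
    T.W[j] = v;
  }
  return List::create(_["V"] = T.V, _["WM"] = T.WM, _["WM1"] = T.WM1, _["W"] = T.W);
}

// ---------------------------------------------------------------------------
// Traceback: re-derives the minimizing case of each cell in a fixed
// documented order (hairpin, stack, internal/bulge lexicographic in
// (ip, jp), multiloop with smallest split; unpaired-before-paired in W,
// WM, WM1; smallest 5' partner in W). Fully deterministic.

struct Task { int what; int i; int j; }; // 0 = V, 1 = WM, 2 = WM1

// [[Rcpp::export]]
IntegerMatrix cpp_traceback(IntegerMatrix V, IntegerMatrix WM, IntegerMatrix WM1,
                            IntegerVector W, IntegerVector codes, LogicalMatrix cand,
                            LogicalVector mustPair, IntegerVector shape, List par,
                            IntegerMatrix adm, IntegerMatrix all, int mode, int maxSpan) {
  Engine E(codes, cand, mustPair, shape, par, adm, all, mode, maxSpan);
  Tables T(V, WM, WM1, W);
  int n = E.n;
  std::vector<int> pi, pj;
  std::vector<Task> todo;

  // exterior loop: walk W from the 3' end
  {
    int j = n;
    while (j >= 1) {
      if (!E.must[j] && T.W[j] == T.W[j - 1]) { j--; continue; }
      bool found = false;
      for (int i = 1; i <= j; i++) {
        int e = extE(E, T, i, j);
        if (e < E_INF && sadd(T.W[i - 1], e) == T.W[j]) {
          todo.push_back({0, i, j});
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) stop("traceback failed in W at j = %d (corrupt tables?)", j);
    }
  }

  while (!todo.empty()) {
    Task t = todo.back();
    todo.pop_back();
    int i = t.i, j = t.j;
    if (t.what == 0) { // V
      pi.push_back(i); pj.push_back(j);
      int target = T.v(i, j) - E.shp[i] - E.shp[j];
      if (E.noMust(i + 1, j - 1) && E.hairpinE(i, j) == target) continue;
      bool found = false;
      if (j - i >= 3) {
        int e = E.stackE(i, j);
        if (e < E_INF && T.v(i + 1, j - 1) < E_INF &&
            sadd(e, T.v(i + 1, j - 1)) == target) {
          todo.push_back({0, i + 1, j - 1});
          found = true;
        }
      }
      if (!found) {
        for (int ip = i + 1; ip <= j - 2 && !found; ip++) {
          int l1 = ip - i - 1;
          if (l1 > E.maxSpan) break;
          if (l1 > 0 && !E.noMust(i + 1, ip - 1)) break;
          for (int jp = ip + 1; jp <= j - 1; jp++) {
            int l2 = j - jp - 1;
            if (l1 + l2 > E.maxSpan || (l1 == 0 && l2 == 0)) continue;
            if (l2 > 0 && !E.noMust(jp + 1, j - 1)) continue;
            int v = T.v(ip, jp);
            if (v < E_INF && sadd(E.internalE(i, j, ip, jp), v) == target) {
              todo.push_back({0, ip, jp});
              found = true;
              break;
            }
          }
        }
      }
      if (!found && j - i >= 4) {
        int pt = E.ptAdm(i, j);
        int mlBase = E.mla + E.mlb + E.auPen(pt) + E.endClose(i, j);
        for (int k = i + 2; k <= j - 1; k++) {
          int wmL = T.wm(i + 1, k - 1), w1 = T.wm1(k, j - 1);
          if (wmL < E_INF && w1 < E_INF && sadd(mlBase, sadd(wmL, w1)) == target) {
            todo.push_back({1, i + 1, k - 1});
            todo.push_back({2, k, j - 1});
            found = true;
            break;
          }
        }
      }
      if (!found) stop("traceback failed in V at (%d, %d)", i, j);
    } else if (t.what == 1) { // WM
      int v = T.wm(i, j);
      if (j > i && !E.must[i] && sadd(T.wm(i + 1, j), E.mlc) == v) {
        todo.push_back({1, i + 1, j});
        continue;
      }
      if (T.wm1(i, j) == v) { todo.push_back({2, i, j}); continue; }
      bool found = false;
      for (int k = i + 1; k <= j; k++) {
        int L = T.wm(i, k - 1), R = T.wm1(k, j);
        if (L < E_INF && R < E_INF && sadd(L, R) == v) {
          todo.push_back({1, i, k - 1});
          todo.push_back({2, k, j});
          found = true;
          break;
        }
      }
      if (!found) stop("traceback failed in WM at (%d, %d)", i, j);
    } else { // WM1
      int v = T.wm1(i, j);
      if (j > i && !E.must[j] && sadd(T.wm1(i, j - 1), E.mlc) == v) {
        todo.push_back({2, i, j - 1});
        continue;
      }
      if (branchE(E, T, i, j) == v) { todo.push_back({0, i, j}); continue; }
      stop("traceback failed in WM1 at (%d, %d)", i, j);
    }
  }

  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); k++) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}
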