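// Compiled core for exact quorum planted (l,d)-motif search.
//
// Sequences arrive as integer code vectors (0..sigma-1; negative = character
// outside the alphabet, which makes every window covering it ineligible).
// All offsets are 0-based half-open throughout.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <chrono>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

typedef std::vector<int> Codes;
typedef std::vector<Codes> CodeSet;

static const int INF = 1 << 28;

static CodeSet as_codeset(const List& seqs) {
  CodeSet out;
  out.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    out.emplace_back(v.begin(), v.end());
  }
  return out;
}

// offsets of windows free of out-of-alphabet codes
static std::vector<int> valid_offsets(const Codes& s, int l) {
  std::vector<int> out;
  int m = (int)s.size();
  if (m < l) return out;
  // bad[i] true if s[i] < 0; window o valid iff no bad in [o, o+l)
  int run = 0;  // length of current clean run ending at i
  for (int i = 0; i < m; ++i) {
    run = (s[i] >= 0) ? run + 1 : 0;
    if (i >= l - 1 && run >= l) out.push_back(i - l + 1);
  }
  return out;
}

static inline int hamming_codes(const int* a, const int* b, int l) {
  int h = 0;
  for (int j = 0; j < l; ++j) h += (a[j] != b[j]);
  return h;
}

static inline int hamming_codes_capped(const int* a, const int* b, int l, int cap) {
  int h = 0;
  for (int j = 0; j < l; ++j) {
    h += (a[j] != b[j]);
    if (h > cap) return h;
  }
  return h;
}

// [[Rcpp::export]]
List cpp_min_hamming(IntegerVector seq, IntegerVector t) {
  int l = (int)t.size();
  Codes s(seq.begin(), seq.end());
  Codes tt(t.begin(), t.end());
  std::vector<int> offs = valid_offsets(s, l);
  int best = INF;
  std::vector<int> where;
  for (int o : offs) {
    int h = hamming_codes(&s[o], &tt[0], l);
    if (h < best) { best = h; where.clear(); }
    if (h == best) where.push_back(o);
  }
  return List::create(_["dist"] = (best == INF ? NA_INTEGER : best),
                      _["offsets"] = IntegerVector(where.begin(), where.end()));
}

// [[Rcpp::export]]
int cpp_quorum_count(List seqs, IntegerVector t, int d, IntegerVector exclude0) {
  CodeSet S = as_codeset(seqs);
  int l = (int)t.size();
  Codes tt(t.begin(), t.end());
  std::vector<bool> excl(S.size(), false);
  for (int e : exclude0) if (e >= 0 && e < (int)S.size()) excl[e] = true;
  int cnt = 0;
  for (size_t i = 0; i < S.size(); ++i) {
    if (excl[i]) continue;
    for (int o : valid_offsets(S[i], l)) {
      if (hamming_codes_capped(&S[i][o], &tt[0], l, d) <= d) { ++cnt; break; }
    }
  }
  return cnt;
}

// per-motif, per-sequence best distance and attaining offsets
// [[Rcpp::export]]
List cpp_evidence(List seqs, IntegerMatrix motifs) {
  CodeSet S = as_codeset(seqs);
  int k = motifs.nrow(), l = motifs.ncol(), n = (int)S.size();
  IntegerMatrix dist(k, n);
  List offs_out(k);
  std::vector<std::vector<int>> voffs(n);
  for (int j = 0; j < n; ++j) voffs[j] = valid_offsets(S[j], l);
  Codes t(l);
  for (int a = 0; a < k; ++a) {
    for (int j = 0; j < l; ++j) t[j] = motifs(a, j);
    List per_seq(n);
    for (int j = 0; j < n; ++j) {
      int best = INF;
      std::vector<int> where;
      for (int o : voffs[j]) {
        int h = hamming_codes(&S[j][o], &t[0], l);
        if (h < best) { best = h; where.clear(); }
        if (h == best) where.push_back(o);
      }
      dist(a, j) = (best == INF ? NA_INTEGER : best);
      per_seq[j] = IntegerVector(where.begin(), where.end());
    }
    offs_out[a] = per_seq;
  }
  return List::create(_["dist"] = dist, _["offsets"] = offs_out);
}

// ---------------------------------------------------------------------------
// d-neighborhood enumeration via the mutation tree T_d(x):
// node (t, p) with t agreeing with x at all positions > p; children mutate a
// single position p' > p (1-based) to each character != x[p'], depth < d.
// DFS preorder; children in increasing p', then code order.
// ---------------------------------------------------------------------------

struct BallCollector {
  std::vector<int> flat;  // members, row-major
  std::vector<int> pvec, depthvec;
  int l;
  void add(const Codes& t, int p, int depth) {
    flat.insert(flat.end(), t.begin(), t.end());
    pvec.push_back(p);
    depthvec.push_back(depth);
  }
};

static void ball_dfs(Codes& t, const Codes& x, int p, int depth, int d, int sigma,
                     BallCollector& col) {
  col.add(t, p, depth);
  if (depth >= d) return;
  int l = (int)x.size();
  for (int pp = p + 1; pp <= l; ++pp) {
    int j = pp - 1;
    for (int c = 0; c < sigma; ++c) {
      if (c == x[j]) continue;
      t[j] = c;
      ball_dfs(t, x, pp, depth + 1, d, sigma, col);
      t[j] = x[j];
    }
  }
}

// [[Rcpp::export]]
List cpp_ball_nodes(IntegerVector x, int d, int sigma) {
  Codes xx(x.begin(), x.end());
  int l = (int)xx.size();
  BallCollector col;
  col.l = l;
  Codes t = xx;
  ball_dfs(t, xx, 0, 0, d, sigma, col);
  int nn = (int)col.pvec.size();
  IntegerMatrix mem(nn, l);
  for (int i = 0; i < nn; ++i)
    for (int j = 0; j < l; ++j) mem(i, j) = col.flat[(size_t)i * l + j];
  return List::create(_["members"] = mem,
                      _["p"] = IntegerVector(col.pvec.begin(), col.pvec.end()),
                      _["depth"] = IntegerVector(col.depthvec.begin(), col.depthvec.end()));
}

static double ball_size_d(int l, int d, int sigma) {
  double tot = 0;
  for (int i = 0; i <= d; ++i)
    tot += ::Rf_choose((double)l, (double)i) * std::pow((double)(sigma - 1), (double)i);
  return tot;
}

// exhaustive self-check of ball enumeration over every center of length l:
// count matches the closed form, no duplicates, every member within d,
// node depth equals Hamming distance to the center.
// [[Rcpp::export]]
List cpp_ball_exhaustive_check(int l, int sigma) {
  double space_d = std::pow((double)sigma, (double)l);
  if (space_d > 2e7) stop("alphabet^l too large for exhaustive check");
  int space = (int)space_d;
  std::vector<int> stamp(space, -1);
  double nodes_total = 0;
  int centers = 0;
  Codes x(l, 0);
  int check_id = 0;
  bool ok = true;
  std::string msg = "";
  while (true) {
    for (int d = 0; d <= l && ok; ++d) {
      BallCollector col;
      col.l = l;
      Codes t = x;
      ball_dfs(t, x, 0, 0, d, sigma, col);
      int nn = (int)col.pvec.size();
      nodes_total += nn;
      if ((double)nn != ball_size_d(l, d, sigma)) { ok = false; msg = "count mismatch"; break; }
      ++check_id;
      for (int i = 0; i < nn && ok; ++i) {
        const int* ti = &col.flat[(size_t)i * l];
        int key = 0;
        for (int j = 0; j < l; ++j) key = key * sigma + ti[j];
        if (stamp[key] == check_id) { ok = false; msg = "duplicate member"; break; }
        stamp[key] = check_id;
        int h = hamming_codes(ti, &x[0], l);
        if (h > d) { ok = false; msg = "member outside ball"; break; }
        if (h != col.depthvec[i]) { ok = false; msg = "depth != distance"; break; }
      }
    }
    ++centers;
    if (!ok) break;
    // next center (odometer)
    int j = l - 1;
    while (j >= 0 && x[j] == sigma - 1) { x[j] = 0; --j; }
    if (j < 0) break;
    ++x[j];
  }
  return List::create(_["ok"] = ok, _["centers"] = centers,
                      _["nodes"] = nodes_total, _["message"] = msg);
}

// ---------------------------------------------------------------------------
// Three-ball intersection feasibility, exact DP.
// Is there z with h(z,c1)<=r1, h(z,c2)<=r2, h(z,c3)<=r3?
// State after each position: (e1, e2) = mismatches to c1, c2 so far; value =
// minimum mismatches to c3. Per-column choices: copy c1 / c2 / c3 / any
// character distinct from all present ones (only when sigma permits).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
bool cpp_three_ball_nonempty(IntegerVector c1, IntegerVector c2, IntegerVector c3,
                             int r1, int r2, int r3, int sigma) {
  int L = (int)c1.size();
  if ((int)c2.size() != L || (int)c3.size() != L) stop("centers must have equal length");
  if (r1 < 0 || r2 < 0 || r3 < 0) return false;
  if (r1 > L) r1 = L;
  if (r2 > L) r2 = L;
  if (r3 > L) r3 = L;
  int W = r2 + 1;
  std::vector<int> dp((size_t)(r1 + 1) * W, INF), nx;
  dp[0] = 0;
  nx.assign(dp.size(), INF);
  for (int i = 0; i < L; ++i) {
    int a = c1[i], b = c2[i], c = c3[i];
    // candidate characters: the distinct column characters, plus one "other"
    int cand[4];
    int ncand = 0;
    cand[ncand++] = a;
    if (b != a) cand[ncand++] = b;
    if (c != a && c != b) cand[ncand++] = c;
    int distinct = ncand;
    if (sigma > distinct) cand[ncand++] = -1;  // "other": mismatches all three
    std::fill(nx.begin(), nx.end(), INF);
    for (int e1 = 0; e1 <= r1; ++e1) {
      for (int e2 = 0; e2 <= r2; ++e2) {
        int v = dp[(size_t)e1 * W + e2];
        if (v >= INF) continue;
        for (int k = 0; k < ncand; ++k) {
          int z = cand[k];
          int m1 = (z != a), m2 = (z != b), m3 = (z != c);
          if (z < 0) { m1 = m2 = m3 = 1; }
          int f1 = e1 + m1, f2 = e2 + m2;
          if (f1 > r1 || f2 > r2) continue;
          int f3 = v + m3;
          size_t idx = (size_t)f1 * W + f2;
          if (f3 < nx[idx]) nx[idx] = f3;
        }
      }
    }
    dp.swap(nx);
  }
  for (size_t i = 0; i < dp.size(); ++i)
    if (dp[i] <= r3) return true;
  return false;
}

// ---------------------------------------------------------------------------
// Brute-force oracle: all l-mers m with quorum_count(m) >= q, by full
// enumeration of sigma^l (lexicographic) or by union of d-balls around the
// windows of s_1..s_{n-q+1} (exact by the pivot observation).
// ---------------------------------------------------------------------------

struct QuorumTester {
  const CodeSet* S;
  const std::vector<std::vector<int>>* offs;
  int l, d, q, n;
  bool test(const int* t) const {
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (cnt + (n - j) < q) return false;  // cannot reach quorum
      for (int o : (*offs)[j]) {
        if (hamming_codes_capped(&(*S)[j][o], t, l, d) <= d) { ++cnt; break; }
      }
      if (cnt >= q) return true;
    }
    return cnt >= q;
  }
};

static void apply_keep(std::vector<std::vector<int>>& offs, const Nullable<List>& keep) {
  if (keep.isNull()) return;
  List kl(keep);
  for (size_t j = 0; j < offs.size(); ++j) {
    IntegerVector kj = kl[j];
    std::set<int> ks(kj.begin(), kj.end());
    std::vector<int> filt;
    for (int o : offs[j]) if (ks.count(o)) filt.push_back(o);
    offs[j] = filt;
  }
}

// [[Rcpp::export]]
List cpp_brute_force(List seqs, int l, int d, int q, double cap, std::string mode,
                     int sigma, Nullable<List> keep) {
  CodeSet S = as_codeset(seqs);
  int n = (int)S.size();
  std::vector<std::vector<int>> offs(n);
  for (int j = 0; j < n; ++j) offs[j] = valid_offsets(S[j], l);
  apply_keep(offs, keep);
  QuorumTester qt{&S, &offs, l, d, q, n};

  double full_size = std::pow((double)sigma, (double)l);
  bool full = (mode == "full") || (mode == "auto" && full_size <= cap);
  if (mode == "full" && full_size > cap)
    stop("full enumeration of %g candidates exceeds cap %g", full_size, cap);

  std::set<Codes> found;
  double candidates = 0;
  if (full) {
    Codes t(l, 0);
    while (true) {
      ++candidates;
      if (qt.test(&t[0])) found.insert(t);
      int j = l - 1;
      while (j >= 0 && t[j] == sigma - 1) { t[j] = 0; --j; }
      if (j < 0) break;
      ++t[j];
    }
  } else {
    // union of balls around windows of the first n-q+1 sequences
    if ((double)l * std::log2((double)sigma) > 62)
      stop("l too large for union-of-balls candidate hashing");
    std::set<uint64_t> seen;
    int last_pivot = n - q;  // 0-based inclusive
    for (int i = 0; i <= last_pivot; ++i) {
      for (int o : offs[i]) {
        Codes x(S[i].begin() + o, S[i].begin() + o + l);
        BallCollector col;
        col.l = l;
        Codes t = x;
        ball_dfs(t, x, 0, 0, d, sigma, col);
        int nn = (int)col.pvec.size();
        for (int a = 0; a < nn; ++a) {
          const int* ta = &col.flat[(size_t)a * l];
          uint64_t key = 0;
          for (int j = 0; j < l; ++j) key = key * (uint64_t)sigma + (uint64_t)ta[j];
          if (!seen.insert(key).second) continue;
          ++candidates;
          if (qt.test(ta)) found.insert(Codes(ta, ta + l));
        }
      }
    }
  }
  IntegerMatrix out((int)found.size(), l);
  int r = 0;
  for (const Codes& t : found) {
    for (int j = 0; j < l; ++j) out(r, j) = t[j];
    ++r;
  }
  return List::create(_["motifs"] = out, _["candidates"] = candidates,
                      _["mode"] = full ? "full" : "union");
}

// ---------------------------------------------------------------------------
// 2d preprocessing filter: keep window u of s_i iff at least q-1 other
// sequences have a window v with h(u,v) <= 2d.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_preprocess_filter(List seqs, int l, int d, int q) {
  CodeSet S = as_codeset(seqs);
  int n = (int)S.size();
  int thr = 2 * d;
  std::vector<std::vector<int>> offs(n);
  for (int j = 0; j < n; ++j) offs[j] = valid_offsets(S[j], l);
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> kept;
    for (int u : offs[i]) {
      const int* pu = &S[i][u];
      int cnt = 0;
      for (int j = 0; j < n && cnt < q - 1; ++j) {
        if (j == i) continue;
        for (int v : offs[j]) {
          if (hamming_codes_capped(&S[j][v], pu, l, thr) <= thr) { ++cnt; break; }
        }
      }
      if (cnt >= q - 1) kept.push_back(u);
    }
    out[i] = IntegerVector(kept.begin(), kept.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// qPMSPrune / qPMSPruneI
//
// For each pivot string s_i (i = 1..n-q+1) and window x of s_i, DFS T_d(x),
// maintaining for each other string the minimum window distance to the
// current node t (incrementally: one code comparison per window per
// mutation).  Emit t when >= q-1 other strings are within d; prune when
// fewer than q-1 are within 2d - depth (triangle inequality).  Surviving
// lists drop window y once its best achievable distance over all descendants,
// a + max(0, b - (d - depth)), exceeds d; a dropped list makes the string
// unreachable.
// ---------------------------------------------------------------------------

struct PruneSolver {
  const CodeSet* S;
  int n, l, d, q, sigma;
  bool use_lists;
  double budget;  // seconds, <= 0 means none
  std::chrono::steady_clock::time_point t0;
  bool timed_out = false;

  std::vector<std::vector<int>> offs;   // usable offsets per sequence
  // per-pivot state
  int pivot;
  Codes x, t;
  std::vector<std::vector<int>> dist;   // dist[j][k] ~ offs[j][k]
  std::vector<std::vector<int>> cum;    // cum[j][k*(l+1)+pos] mismatches of x vs window over 1..pos
  std::vector<std::vector<int>> surv;   // indices k into offs[j]
  std::vector<std::pair<int,int>> undo_rm;   // (j, k) removals, with
  std::vector<int> undo_rm_idx;              // position in surv[j] at removal

  std::set<Codes> found;
  double nodes = 0, pruned = 0, updates = 0;

  long tick = 0;
  bool over_budget() {
    if (budget <= 0) return false;
    if (timed_out) return true;
    if ((++tick & 4095) != 0) return false;
    double el = std::chrono::duration<double>(std::chrono::steady_clock::now() - t0).count();
    if (el > budget) timed_out = true;
    return timed_out;
  }

  // drop surviving windows of j failing the ignore bound at (p, depth)
  void drop_pass(int j, int p, int depth) {
    auto& sv = surv[j];
    int slack = d - depth;
    for (size_t idx = 0; idx < sv.size();) {
      int k = sv[idx];
      int b = cum[j][(size_t)k * (l + 1) + l] - cum[j][(size_t)k * (l + 1) + p];
      int a = dist[j][k] - b;
      int over = b - slack;
      if (a + (over > 0 ? over : 0) > d) {
        undo_rm.emplace_back(j, k);
        undo_rm_idx.push_back((int)idx);
        sv[idx] = sv.back();
        sv.pop_back();
      } else {
        ++idx;
      }
    }
  }

  void restore_to(size_t mark) {
    while (undo_rm.size() > mark) {
      int j = undo_rm.back().first, k = undo_rm.back().second;
      int idx = undo_rm_idx.back();
      auto& sv = surv[j];
      sv.push_back(0);
      if (idx < (int)sv.size() - 1) sv.back() = sv[idx];
      sv[idx] = k;
      undo_rm.pop_back();
      undo_rm_idx.pop_back();
    }
  }

  // node body: emission + prune decision; returns true if children explored
  void visit(int p, int depth) {
    ++nodes;
    if (over_budget()) return;
    int cnt_emit = 0, cnt_keep = 0;
    int bound = 2 * d - depth;
    for (int j = 0; j < n; ++j) {
      if (j == pivot) continue;
      int best = INF;
      for (int k : surv[j]) { int v = dist[j][k]; if (v < best) best = v; }
      if (best <= d) ++cnt_emit;
      if (best <= bound) ++cnt_keep;
    }
    if (cnt_emit >= q - 1) found.insert(t);
    if (cnt_keep < q - 1) { ++pruned; return; }
    if (depth >= d) return;
    for (int pp = p + 1; pp <= l; ++pp) {
      int jx = pp - 1;
      for (int c = 0; c < sigma; ++c) {
        if (c == x[jx]) continue;
        if (timed_out) return;
        // apply mutation jx: x[jx] -> c, update surviving distances
        t[jx] = c;
        for (int j = 0; j < n; ++j) {
          if (j == pivot) continue;
          const Codes& sj = (*S)[j];
          for (int k : surv[j]) {
            int ch = sj[offs[j][k] + jx];
            dist[j][k] += (ch != c) - (ch != x[jx]);
            ++updates;
          }
        }
        size_t mark = undo_rm.size();
        if (use_lists) {
          for (int j = 0; j < n; ++j) {
            if (j == pivot) continue;
            drop_pass(j, pp, depth + 1);
          }
        }
        visit(pp, depth + 1);
        restore_to(mark);
        for (int j = 0; j < n; ++j) {
          if (j == pivot) continue;
          const Codes& sj = (*S)[j];
          for (int k : surv[j]) {
            int ch = sj[offs[j][k] + jx];
            dist[j][k] -= (ch != c) - (ch != x[jx]);
          }
        }
        t[jx] = x[jx];
      }
    }
  }

  void run_pivot(int i, const std::vector<int>& pivot_offs) {
    pivot = i;
    for (int o : pivot_offs) {
      if (timed_out) return;
      Rcpp::checkUserInterrupt();
      x.assign((*S)[i].begin() + o, (*S)[i].begin() + o + l);
      t = x;
      for (int j = 0; j < n; ++j) {
        if (j == pivot) continue;
        int nk = (int)offs[j].size();
        dist[j].assign(nk, 0);
        surv[j].clear();
        for (int k = 0; k < nk; ++k) {
          const int* w = &(*S)[j][offs[j][k]];
          dist[j][k] = hamming_codes(w, &x[0], l);
          ++updates;
          if (use_lists) {
            int* ck = &cum[j][(size_t)k * (l + 1)];
            ck[0] = 0;
            for (int jj = 0; jj < l; ++jj) ck[jj + 1] = ck[jj] + (w[jj] != x[jj]);
          }
        }
        for (int k = 0; k < nk; ++k) {
          // root drop: a = 0, b = dist; ignore iff dist > 2d
          if (use_lists && dist[j][k] > 2 * d) continue;
          surv[j].push_back(k);
        }
      }
      undo_rm.clear();
      undo_rm_idx.clear();
      visit(0, 0);
    }
  }
};

// [[Rcpp::export]]
List cpp_qpmsprune(List seqs, int l, int d, int q, bool use_lists,
                   Nullable<List> keep, double time_budget, int sigma) {
  PruneSolver sol;
  CodeSet S = as_codeset(seqs);
  sol.S = &S;
  sol.n = (int)S.size();
  sol.l = l; sol.d = d; sol.q = q; sol.sigma = sigma;
  sol.use_lists = use_lists;
  sol.budget = time_budget;
  sol.t0 = std::chrono::steady_clock::now();
  sol.offs.resize(sol.n);
  for (int j = 0; j < sol.n; ++j) sol.offs[j] = valid_offsets(S[j], l);
  apply_keep(sol.offs, keep);
  sol.dist.resize(sol.n);
  sol.cum.resize(sol.n);
  sol.surv.resize(sol.n);
  for (int j = 0; j < sol.n; ++j)
    sol.cum[j].assign((size_t)sol.offs[j].size() * (l + 1), 0);
  int last_pivot = sol.n - q;  // 0-based: pivots 0..n-q
  for (int i = 0; i <= last_pivot && !sol.timed_out; ++i)
    sol.run_pivot(i, sol.offs[i]);
  IntegerMatrix out((int)sol.found.size(), l);
  int r = 0;
  for (const Codes& t : sol.found) {
    for (int j = 0; j < l; ++j) out(r, j) = t[j];
    ++r;
  }
  return List::create(_["motifs"] = out, _["nodes_visited"] = sol.nodes,
                      _["nodes_pruned"] = sol.pruned,
                      _["distance_updates"] = sol.updates,
                      _["timed_out"] = sol.timed_out);
}

// ---------------------------------------------------------------------------
// qPMS7: two pivot windows x (from s_r1) and y (from s_r2), h(x,y) <= 2d.
// DFS over T_d(x) restricted to nodes whose subtree can still reach B_d(y);
// per non-pivot window w the survival test is the exact three-ball emptiness
// check over the suffix positions p+1..l with radii (d-depth, d-a_w, d-a_y).
// Emit t with h(t,x) <= d, h(t,y) <= d and >= q-2 other strings holding a
// surviving window within d; backtrack when fewer than q-2 surviving lists
// are non-empty.
// ---------------------------------------------------------------------------

struct SevenSolver {
  const CodeSet* S;
  int n, l, d, q, sigma;
  double budget;
  std::chrono::steady_clock::time_point t0;
  bool timed_out = false;

  std::vector<std::vector<int>> offs;

  int r1, r2;
  Codes x, y, t;
  // per (x): cumulative mismatch arrays of x vs each window of each j != r1
  std::vector<std::vector<int>> cum;    // cum[j][k*(l+1)+pos]
  std::vector<std::vector<int>> xcompat; // per j: windows with h(x,w) <= 2d
  std::vector<int> cumy;                 // x vs y window, length l+1
  // per (x,y) DFS state
  std::vector<std::vector<int>> aw;     // prefix mismatches of window vs t
  std::vector<std::vector<int>> surv;
  std::vector<std::pair<int,int>> undo_rm;
  std::vector<int> undo_rm_idx;

  std::set<Codes> found;
  double nodes = 0, pruned = 0, updates = 0, pairs = 0;

  long tick = 0;
  bool over_budget() {
    if (budget <= 0) return false;
    if (timed_out) return true;
    if ((++tick & 4095) != 0) return false;
    double el = std::chrono::duration<double>(std::chrono::steady_clock::now() - t0).count();
    if (el > budget) timed_out = true;
    return timed_out;
  }

  inline int bw_of(int j, int k, int p) const {
    const int* ck = &cum[j][(size_t)k * (l + 1)];
    return ck[l] - ck[p];
  }

  // exact survival test for window (j,k) at node (p, depth) given a_y
  bool survives(int j, int k, int p, int depth, int ay) {
    int a = aw[j][k];
    int rw = d - a;
    if (rw < 0) return false;
    int rt = d - depth;
    int bw = bw_of(j, k, p);
    if (bw > rw + rt) return false;  // two-ball t/w on the suffix
    int ry = d - ay;
    // suffix three-ball DP: centers t-suffix (= x-suffix), w-suffix, y-suffix
    int L = l - p;
    if (L == 0) return true;
    const int* xs = &x[p];
    const int* ws = &(*S)[j][offs[j][k] + p];
    const int* ys = &y[p];
    if (rt > L) rt = L;
    if (ry > L) ry = L;
    int W = ry + 1;
    static thread_local std::vector<int> dp, nx;
    dp.assign((size_t)(rt + 1) * W, INF);
    nx.assign(dp.size(), INF);
    dp[0] = 0;
    for (int i = 0; i < L; ++i) {
      int a1 = xs[i], a2 = ys[i], a3 = ws[i];
      int cand[4];
      int ncand = 0;
      cand[ncand++] = a1;
      if (a2 != a1) cand[ncand++] = a2;
      if (a3 != a1 && a3 != a2) cand[ncand++] = a3;
      if (sigma > ncand) cand[ncand++] = -1;
      std::fill(nx.begin(), nx.end(), INF);
      for (int e1 = 0; e1 <= rt; ++e1)
        for (int e2 = 0; e2 <= ry; ++e2) {
          int v = dp[(size_t)e1 * W + e2];
          if (v >= INF) continue;
          for (int kk = 0; kk < ncand; ++kk) {
            int z = cand[kk];
            int m1, m2, m3;
            if (z < 0) { m1 = m2 = m3 = 1; }
            else { m1 = (z != a1); m2 = (z != a2); m3 = (z != a3); }
            int f1 = e1 + m1, f2 = e2 + m2;
            if (f1 > rt || f2 > ry) continue;
            int f3 = v + m3;
            size_t idx = (size_t)f1 * W + f2;
            if (f3 < nx[idx]) nx[idx] = f3;
          }
        }
      dp.swap(nx);
    }
    for (size_t i = 0; i < dp.size(); ++i)
      if (dp[i] <= rw) return true;
    return false;
  }

  void restore_to(size_t mark) {
    while (undo_rm.size() > mark) {
      int j = undo_rm.back().first, k = undo_rm.back().second;
      int idx = undo_rm_idx.back();
      auto& sv = surv[j];
      sv.push_back(0);
      if (idx < (int)sv.size() - 1) sv.back() = sv[idx];
      sv[idx] = k;
      undo_rm.pop_back();
      undo_rm_idx.pop_back();
    }
  }

  void visit(int p, int depth, int ay) {
    ++nodes;
    if (over_budget()) return;
    int by = cumy[l] - cumy[p];
    int cnt_emit = 0, cnt_keep = 0;
    for (int j = 0; j < n; ++j) {
      if (j == r1 || j == r2) continue;
      if (!surv[j].empty()) ++cnt_keep;
      for (int k : surv[j]) {
        if (aw[j][k] + bw_of(j, k, p) <= d) { ++cnt_emit; break; }
      }
    }
    if (ay + by <= d && cnt_emit >= q - 2) found.insert(t);
    if (cnt_keep < q - 2) { ++pruned; return; }
    if (depth >= d) return;
    for (int pp = p + 1; pp <= l; ++pp) {
      int jx = pp - 1;
      for (int c = 0; c < sigma; ++c) {
        if (c == x[jx]) continue;
        if (timed_out) return;
        // child prefix mismatch of y vs t': positions p+1..pp-1 carry x, pp carries c
        int ay2 = ay + (cumy[pp - 1] - cumy[p]) + (y[jx] != c);
        int by2 = cumy[l] - cumy[pp];
        int slack = d - (depth + 1);
        int over = by2 - slack;
        if (ay2 + (over > 0 ? over : 0) > d) continue;  // subtree cannot reach B_d(y)
        t[jx] = c;
        for (int j = 0; j < n; ++j) {
          if (j == r1 || j == r2) continue;
          const Codes& sj = (*S)[j];
          for (int k : surv[j]) {
            const int* ck = &cum[j][(size_t)k * (l + 1)];
            aw[j][k] += (ck[pp - 1] - ck[p]) + (sj[offs[j][k] + jx] != c);
            ++updates;
          }
        }
        size_t mark = undo_rm.size();
        for (int j = 0; j < n; ++j) {
          if (j == r1 || j == r2) continue;
          auto& sv = surv[j];
          for (size_t idx = 0; idx < sv.size();) {
            int k = sv[idx];
            if (!survives(j, k, pp, depth + 1, ay2)) {
              undo_rm.emplace_back(j, k);
              undo_rm_idx.push_back((int)idx);
              sv[idx] = sv.back();
              sv.pop_back();
            } else {
              ++idx;
            }
          }
        }
        visit(pp, depth + 1, ay2);
        restore_to(mark);
        for (int j = 0; j < n; ++j) {
          if (j == r1 || j == r2) continue;
          const Codes& sj = (*S)[j];
          for (int k : surv[j]) {
            const int* ck = &cum[j][(size_t)k * (l + 1)];
            aw[j][k] -= (ck[pp - 1] - ck[p]) + (sj[offs[j][k] + jx] != c);
          }
        }
        t[jx] = x[jx];
      }
    }
  }

  void run() {
    int lim = n - q + 1;  // 0-based: r1 < r2 <= n-q+1
    for (int j = 0; j < n; ++j) aw[j].assign(offs[j].size(), 0);
    for (r1 = 0; r1 <= lim - 1; ++r1) {
      for (r2 = r1 + 1; r2 <= lim; ++r2) {
        for (int xo : offs[r1]) {
          if (timed_out) return;
          Rcpp::checkUserInterrupt();
          x.assign((*S)[r1].begin() + xo, (*S)[r1].begin() + xo + l);
          // cumulative arrays of x vs all windows of all j != r1, and the
          // windows within 2d of x (the only possible root survivors)
          int compat_seqs = 0;
          for (int j = 0; j < n; ++j) {
            if (j == r1) continue;
            int nk = (int)offs[j].size();
            cum[j].assign((size_t)nk * (l + 1), 0);
            xcompat[j].clear();
            for (int k = 0; k < nk; ++k) {
              const int* w = &(*S)[j][offs[j][k]];
              int* ck = &cum[j][(size_t)k * (l + 1)];
              for (int jj = 0; jj < l; ++jj) ck[jj + 1] = ck[jj] + (w[jj] != x[jj]);
              if (ck[l] <= 2 * d) xcompat[j].push_back(k);
            }
            if (j != r2 && !xcompat[j].empty()) ++compat_seqs;
          }
          // with fewer than q-2 compatible sequences no y can succeed
          if (compat_seqs < q - 2) continue;
          for (int ky : xcompat[r2]) {
            if (timed_out) return;
            int yo = offs[r2][ky];
            ++pairs;
            y.assign((*S)[r2].begin() + yo, (*S)[r2].begin() + yo + l);
            cumy.assign(cum[r2].begin() + (size_t)ky * (l + 1),
                        cum[r2].begin() + (size_t)ky * (l + 1) + l + 1);
            t = x;
            // root surviving lists: full-length three-ball with radii (d,d,d);
            // aw is all zeros here (every DFS update is undone on leave)
            for (int j = 0; j < n; ++j) {
              if (j == r1 || j == r2) continue;
              surv[j].clear();
              for (int k : xcompat[j]) {
                const int* w = &(*S)[j][offs[j][k]];
                if (hamming_codes_capped(w, &y[0], l, 2 * d) > 2 * d) continue;
                if (!survives(j, k, 0, 0, 0)) continue;
                surv[j].push_back(k);
              }
            }
            undo_rm.clear();
            undo_rm_idx.clear();
            visit(0, 0, 0);
          }
        }
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_qpms7(List seqs, int l, int d, int q, Nullable<List> keep,
               double time_budget, int sigma) {
  SevenSolver sol;
  CodeSet S = as_codeset(seqs);
  sol.S = &S;
  sol.n = (int)S.size();
  sol.l = l; sol.d = d; sol.q = q; sol.sigma = sigma;
  sol.budget = time_budget;
  sol.t0 = std::chrono::steady_clock::now();
  sol.offs.resize(sol.n);
  for (int j = 0; j < sol.n; ++j) sol.offs[j] = valid_offsets(S[j], l);
  apply_keep(sol.offs, keep);
  sol.cum.resize(sol.n);
  sol.xcompat.resize(sol.n);
  sol.aw.resize(sol.n);
  sol.surv.resize(sol.n);
  sol.run();
  IntegerMatrix out((int)sol.found.size(), l);
  int r = 0;
  for (const Codes& t : sol.found) {
    for (int j = 0; j < l; ++j) out(r, j) = t[j];
    ++r;
  }
  return List::create(_["motifs"] = out, _["nodes_visited"] = sol.nodes,
                      _["nodes_pruned"] = sol.pruned,
                      _["distance_updates"] = sol.updates,
                      _["pivot_pairs"] = sol.pairs,
                      _["timed_out"] = sol.timed_out);
}
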