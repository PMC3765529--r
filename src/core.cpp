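// Core engines: the sequence-structure alignment DP over the matrix family,
// the two online scanning algorithms, the two enhanced-suffix-array
// algorithms, and suffix-array construction.
//
// Conventions (validated against the brute-force oracle in R):
//   * Text characters are coded A=0 C=1 G=2 U=3, anything else 4 (mismatches
//     every class, complementary to nothing).
//   * For a window/suffix text T of length len there are len+1 matrices, one
//     per suffix T_k (k = 1..len) plus one for the empty suffix. Column j of
//     matrix k covers T[k..k+j-1]; the left partner of an arc consumes T[k],
//     the right partner consumes T[k+j-1].
//   * Each cell carries (cost, indels) where indels is the minimum number of
//     indels among minimum-cost alignments (lexicographic minimisation);
//     match reporting requires cost <= K and indels <= d.
//   * Row storage: one row per unpaired position (prefix value within its
//     structural segment), one per arc-closing position (the arc substructure
//     value), plus a separate merged row where material precedes the arc in
//     its segment (the concatenation over split columns).

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e15;
static const double EPS = 1e-9;

struct RowPlan {
  int type;       // 0 unpaired, 1 arc (pure), 2 merged
  int pos;        // pattern position (1-based)
  int slot;
  int prevslot;   // unpaired: prefix row for pos-1 (-1 = base row)
  int left;       // arc/merged: left partner position
  int innerslot;  // arc: prefix row for the enclosed segment (-1 = base)
  int beforeslot; // merged: prefix row for left-1 (-1 = base)
  int arcslot;    // merged: the pure arc row
};

struct Pat {
  int m;
  std::vector<int> mask, partner, kind, segstart; // 1-based
  int nslots;
  std::vector<int> slot_main, slot_merged;        // 1-based, -1 if absent
  std::vector<RowPlan> rows;                      // in position order
  std::vector<int> plan_main, plan_merged;        // pos -> index into rows
  int finalslot;
};

// prefix row holding dist(Q[s..j], .): base row if j < s, else the main row
// of an unpaired position, else (arc-closing j) the pure row when the arc
// starts the segment, else the merged row.
static int refrow(const Pat& P, int j, int s) {
  if (j < s) return -1;
  if (P.kind[j] == 0) return P.slot_main[j];
  int a = P.partner[j];
  if (a == s) return P.slot_main[j];
  return P.slot_merged[j];
}

static Pat buildPat(const IntegerVector& mask, const IntegerVector& partner) {
  Pat P;
  P.m = mask.size();
  P.mask.assign(P.m + 1, 0);
  P.partner.assign(P.m + 1, 0);
  P.kind.assign(P.m + 1, 0);
  P.segstart.assign(P.m + 1, 1);
  for (int i = 1; i <= P.m; i++) {
    P.mask[i] = mask[i - 1];
    P.partner[i] = partner[i - 1];
    if (P.partner[i] > i) P.kind[i] = 1;        // left end of an arc
    else if (P.partner[i] > 0) P.kind[i] = 2;   // right end
  }
  std::vector<int> st;
  for (int i = 1; i <= P.m; i++) {
    if (P.kind[i] == 2) st.pop_back();
    P.segstart[i] = st.empty() ? 1 : st.back() + 1;
    if (P.kind[i] == 1) st.push_back(i);
  }
  P.slot_main.assign(P.m + 1, -1);
  P.slot_merged.assign(P.m + 1, -1);
  P.plan_main.assign(P.m + 1, -1);
  P.plan_merged.assign(P.m + 1, -1);
  int ns = 0;
  for (int i = 1; i <= P.m; i++) {
    if (P.kind[i] != 1) P.slot_main[i] = ns++;
    if (P.kind[i] == 2 && P.segstart[i] < P.partner[i]) P.slot_merged[i] = ns++;
  }
  P.nslots = ns;
  for (int i = 1; i <= P.m; i++) {
    if (P.kind[i] == 0) {
      RowPlan r; r.type = 0; r.pos = i; r.slot = P.slot_main[i];
      r.prevslot = refrow(P, i - 1, P.segstart[i]);
      r.left = r.innerslot = r.beforeslot = r.arcslot = -1;
      P.plan_main[i] = P.rows.size();
      P.rows.push_back(r);
    } else if (P.kind[i] == 2) {
      int a = P.partner[i];
      RowPlan r; r.type = 1; r.pos = i; r.slot = P.slot_main[i];
      r.left = a; r.innerslot = refrow(P, i - 1, a + 1);
      r.prevslot = r.beforeslot = r.arcslot = -1;
      P.plan_main[i] = P.rows.size();
      P.rows.push_back(r);
      if (P.slot_merged[i] >= 0) {
        RowPlan rm; rm.type = 2; rm.pos = i; rm.slot = P.slot_merged[i];
        rm.left = a; rm.beforeslot = refrow(P, a - 1, P.segstart[i]);
        rm.arcslot = P.slot_main[i]; rm.prevslot = rm.innerslot = -1;
        P.plan_merged[i] = P.rows.size();
        P.rows.push_back(rm);
      }
    }
  }
  P.finalslot = refrow(P, P.m, 1);
  return P;
}

struct DpMat {
  int L;
  std::vector<double> c, e;
};

struct Ctx {
  Pat P;
  double wm, wd, wb, wa, wr;
  int comp[5][5];
  int stride;
  std::deque<DpMat> mats;
  std::vector<int> tw;  // 1-based text codes of the current window
  int len;
  long long cells;                    // computed row cells (running total)
  long long slots_done, slots_reused; // column-slot accounting (last op)
};

static void initCtx(Ctx& C, const IntegerVector& mask, const IntegerVector& partner,
                    const NumericVector& costs, const IntegerMatrix& compm,
                    int stride) {
  C.P = buildPat(mask, partner);
  C.wm = costs[0]; C.wd = costs[1]; C.wb = costs[2];
  C.wa = costs[3]; C.wr = costs[4];
  for (int i = 0; i < 5; i++)
    for (int j = 0; j < 5; j++) C.comp[i][j] = compm(i, j);
  C.stride = stride;
  C.len = 0;
  C.cells = 0; C.slots_done = 0; C.slots_reused = 0;
}

static DpMat freshMat(const Ctx& C) {
  DpMat M; M.L = 0;
  M.c.assign((size_t)C.P.nslots * C.stride, INF);
  M.e.assign((size_t)C.P.nslots * C.stride, 0.0);
  return M;
}

static void allocMats(Ctx& C, int count) {
  while ((int)C.mats.size() < count) C.mats.push_back(freshMat(C));
  while ((int)C.mats.size() > count) C.mats.pop_back();
}

static void setLens(Ctx& C) {
  for (int k = 1; k <= (int)C.mats.size(); k++) C.mats[k - 1].L = C.len - k + 1;
}

static inline void getref(const Ctx& C, const DpMat& M, int slot, int j,
                          double& c, double& e) {
  if (slot < 0) { c = j * C.wd; e = j; }
  else {
    c = M.c[(size_t)slot * C.stride + j];
    e = M.e[(size_t)slot * C.stride + j];
  }
}

static inline int chi(const Ctx& C, int pos, int code) {
  return (code < 4 && ((C.P.mask[pos] >> code) & 1)) ? 0 : 1;
}

static inline void take(double cc, double ee, double& bc, double& be) {
  if (cc < bc - EPS || (cc < bc + EPS && ee < be)) { bc = cc; be = ee; }
}

// compute cells of one row in matrix k (1-based), columns jfrom..jto
static void computeRow(Ctx& C, const RowPlan& rp, int k, int jfrom, int jto) {
  DpMat& M = C.mats[k - 1];
  if (jto > M.L) jto = M.L;
  if (jfrom < 0) jfrom = 0;
  const DpMat* M1 = (k < (int)C.mats.size()) ? &C.mats[k] : NULL;
  size_t off = (size_t)rp.slot * C.stride;
  for (int j = jfrom; j <= jto; j++) {
    double bc = INF, be = 0, pc, pe;
    if (rp.type == 0) {
      if (j == 0) {
        getref(C, M, rp.prevslot, 0, pc, pe);
        bc = pc + C.wd; be = pe + 1;
      } else {
        int tc = C.tw[k + j - 1];
        getref(C, M, rp.prevslot, j, pc, pe);
        bc = pc + C.wd; be = pe + 1;                       // delete Q[i]
        take(M.c[off + j - 1] + C.wd, M.e[off + j - 1] + 1, bc, be); // insert
        getref(C, M, rp.prevslot, j - 1, pc, pe);
        take(pc + chi(C, rp.pos, tc) * C.wm, pe, bc, be);  // (mis)match
      }
    } else if (rp.type == 1) {
      // a deleted arc partner costs its base deletion omega_d plus the arc
      // penalty share (altering/removing) on top
      if (j == 0) {
        getref(C, M, rp.innerslot, 0, pc, pe);
        bc = pc + C.wr + 2 * C.wd; be = pe + 2;            // arc removing
      } else {
        int tlast = C.tw[k + j - 1];
        getref(C, M, rp.innerslot, j, pc, pe);
        bc = pc + C.wr + 2 * C.wd; be = pe + 2;            // arc removing
        getref(C, M, rp.innerslot, j - 1, pc, pe);         // right matched
        take(pc + chi(C, rp.pos, tlast) * C.wm + C.wa + C.wd, pe + 1, bc, be);
        take(M.c[off + j - 1] + C.wd, M.e[off + j - 1] + 1, bc, be); // ins right
        if (M1) {
          int tfirst = C.tw[k];
          getref(C, *M1, rp.innerslot, j - 1, pc, pe);     // left matched
          take(pc + chi(C, rp.left, tfirst) * C.wm + C.wa + C.wd, pe + 1, bc, be);
          take(M1->c[off + j - 1] + C.wd, M1->e[off + j - 1] + 1, bc, be); // ins left
          if (j >= 2) {                                    // both matched
            getref(C, *M1, rp.innerslot, j - 2, pc, pe);
            double cc = pc + (chi(C, rp.left, tfirst) + chi(C, rp.pos, tlast)) * C.wm
                        + (C.comp[tfirst][tlast] ? C.wb : 0.0);
            take(cc, pe, bc, be);
          }
        }
      }
    } else {
      // merged: split columns between the prefix before the arc and the arc
      for (int jp = 0; jp <= j; jp++) {
        getref(C, M, rp.beforeslot, jp, pc, pe);
        const DpMat& MA = C.mats[k - 1 + jp];
        double ac = MA.c[(size_t)rp.arcslot * C.stride + (j - jp)];
        double ae = MA.e[(size_t)rp.arcslot * C.stride + (j - jp)];
        take(pc + ac, pe + ae, bc, be);
      }
    }
    M.c[off + j] = bc;
    M.e[off + j] = be;
    C.cells++;
  }
}

// ---- regions -------------------------------------------------------------

struct Region { int x, y, cond; };

static std::vector<Region> decodeRegions(const IntegerMatrix& regs) {
  std::vector<Region> out;
  for (int r = 0; r < regs.nrow(); r++) {
    Region rg; rg.x = regs(r, 0); rg.y = regs(r, 1); rg.cond = regs(r, 2);
    out.push_back(rg);
  }
  return out;
}

// row plans of a region, in computation order
static void regionRows(const Pat& P, const Region& rg, std::vector<int>& plans) {
  plans.clear();
  if (rg.cond == 1) {
    for (int i = rg.x; i <= rg.y; i++) plans.push_back(P.plan_main[i]);
  } else if (rg.cond == 2) {
    int yp = rg.y;
    while (yp >= rg.x && P.kind[yp] == 0) yp--;
    for (int i = yp + 1; i <= rg.y; i++) plans.push_back(P.plan_main[i]);
  } else if (rg.cond == 3) {
    plans.push_back(P.plan_main[rg.y]);
  } else {
    plans.push_back(P.plan_merged[rg.y]);
  }
}

// Band test for sub-region [x..y] whose value lives in `slot`: true iff every
// probed cell on the allowed diagonals exceeds K (cells outside the matrices
// count as exceeding).
static bool bandExceeded(const Ctx& C, int x, int y, int slot, double K, int d) {
  int l = y - x + 1;
  int hi = std::min(d, x);
  for (int dp = -d; dp <= hi; dp++) {
    int k = x + dp;
    if (k < 1 || k > (int)C.mats.size()) continue;
    // shifts whose placement spills past a short window are handled by the
    // column bound below: clipped probes cover the shorter prefixes that
    // remain feasible there
    for (int z = std::abs(dp) - d; z <= d - std::abs(dp); z++) {
      int col = l + z;
      if (col < 0 || col > C.mats[k - 1].L) continue;
      if (C.mats[k - 1].c[(size_t)slot * C.stride + col] <= K + EPS) return false;
    }
  }
  return true;
}

// Compute one region; reuse columns <= vplcp-k+1 per matrix (vplcp < 0: none).
// With bandtest, stop as soon as one computed row's band exceeds K; returns
// false then, reporting the failing sub-region [x..stop_y].
static bool computeRegion(Ctx& C, const Region& rg, int vplcp, double K, int d,
                          bool bandtest, int& stop_y) {
  std::vector<int> plans;
  regionRows(C.P, rg, plans);
  int nmat = C.mats.size();
  for (size_t t = 0; t < plans.size(); t++) {
    const RowPlan& rp = C.P.rows[plans[t]];
    for (int k = nmat; k >= 1; k--) {
      int vc = (vplcp >= 0) ? (vplcp - k + 1) : -1;
      int jfrom = (vc >= 1) ? vc + 1 : 0;
      computeRow(C, rp, k, jfrom, C.mats[k - 1].L);
    }
    if (bandtest && bandExceeded(C, rg.x, rp.pos, rp.slot, K, d)) {
      stop_y = rp.pos;
      return false;
    }
  }
  return true;
}

// ---- match emission ------------------------------------------------------

struct MatchAcc {
  std::vector<int> start, len;
  std::vector<double> cost, ind;
};

static bool emitMatches(const Ctx& C, double K, int d, int start, MatchAcc& acc) {
  int lo = std::max(1, C.P.m - d);
  const DpMat& M = C.mats[0];
  bool any = false;
  int hi = std::min(M.L, C.P.m + d);
  for (int pp = lo; pp <= hi; pp++) {
    double c, e;
    getref(C, M, C.P.finalslot, pp, c, e);
    if (c <= K + EPS && e <= d + EPS) {
      acc.start.push_back(start);
      acc.len.push_back(pp);
      acc.cost.push_back(c);
      acc.ind.push_back(e);
      any = true;
    }
  }
  return any;
}

static List matchResult(const MatchAcc& acc, long long cells, long long nstop) {
  return List::create(_["start"] = wrap(acc.start), _["len"] = wrap(acc.len),
                      _["cost"] = wrap(acc.cost), _["indels"] = wrap(acc.ind),
                      _["cells"] = (double)cells, _["stops"] = (double)nstop);
}

// ---- online engines ------------------------------------------------------

// [[Rcpp::export]]
List cpp_scan(IntegerVector mask, IntegerVector partner, NumericVector costs,
              IntegerMatrix compm, IntegerVector text, double K, int d,
              bool lscan, IntegerMatrix regs) {
  Ctx C;
  int m = mask.size();
  int mprime = m + d;
  initCtx(C, mask, partner, costs, compm, mprime + 2);
  int n = text.size();
  int lo = std::max(1, m - d);
  MatchAcc acc;
  long long nstop = 0;
  if (n < lo) return matchResult(acc, 0, 0);
  std::vector<Region> regions = decodeRegions(regs);
  int z = regions.size();
  std::vector<long long> Z(z, -1);  // window start of last full computation
  int lastp = n - lo + 1;
  for (int p = 1; p <= lastp; p++) {
    int newlen = std::min(mprime, n - p + 1);
    bool grew = false;
    if (p == 1) {
      C.len = newlen;
      allocMats(C, newlen + 1);
    } else {
      grew = (newlen == C.len);
      C.mats.pop_front();
      if (grew) C.mats.push_back(freshMat(C));
      C.len = newlen;
    }
    C.tw.assign(C.len + 1, 0);
    for (int t = 1; t <= C.len; t++) C.tw[t] = text[p + t - 2];
    setLens(C);
    if (!lscan) {
      int vplcp = (p == 1) ? -1 : (grew ? C.len - 1 : C.len);
      for (size_t t = 0; t < C.P.rows.size(); t++) {
        for (int k = (int)C.mats.size(); k >= 1; k--) {
          int vc = (vplcp >= 0) ? (vplcp - k + 1) : -1;
          int jfrom = (vc >= 1) ? vc + 1 : 0;
          computeRow(C, C.P.rows[t], k, jfrom, C.mats[k - 1].L);
        }
      }
      emitMatches(C, K, d, p, acc);
    } else {
      bool stopped = false;
      int stop_y = 0;
      for (int r = 0; r < z; r++) {
        int vplcp = -1;
        if (Z[r] >= 1) {
          long long diff = p - Z[r];
          long long len0 = std::min<long long>(mprime, n - Z[r] + 1);
          long long v = len0 - diff;
          vplcp = (v >= 0) ? (int)v : -1;
        }
        if (!computeRegion(C, regions[r], vplcp, K, d, true, stop_y)) {
          stopped = true;
          nstop++;
          break;
        }
        Z[r] = p;
      }
      if (!stopped) emitMatches(C, K, d, p, acc);
    }
  }
  return matchResult(acc, C.cells, nstop);
}

// ---- index-based engines -------------------------------------------------

// [[Rcpp::export]]
List cpp_esa_search(IntegerVector mask, IntegerVector partner, NumericVector costs,
                    IntegerMatrix compm, IntegerVector text,
                    IntegerVector suf, IntegerVector lcp, IntegerVector isuf,
                    double K, int d, bool uselinks, IntegerMatrix regs,
                    bool collect_events) {
  Ctx C;
  int m = mask.size();
  int mprime = m + d;
  initCtx(C, mask, partner, costs, compm, mprime + 2);
  int n = text.size();
  int nn = suf.size();  // n + 1
  int lo = std::max(1, m - d);
  MatchAcc acc;
  long long nstop = 0;
  std::vector<Region> regions = decodeRegions(regs);
  int z = regions.size();
  std::vector<char> vtab(nn + 1, 0);
  std::vector<int> etype, evalue;  // 1 main, 2 chain, 3 mark, 4 stop(y)
  MatchAcc dummy;
  if (n < lo || m > n + d) {
    List res = matchResult(acc, 0, 0);
    res["events"] = DataFrame::create(_["type"] = wrap(etype), _["rank"] = wrap(evalue));
    return res;
  }

  bool haveLast = false, lastMatched = false;
  int rstore = z + 1;    // 1-based index of first non-computed region
  int p_last = 0;
  long long shared = 0;
  std::vector<double> lastC, lastE;  // final-row values of last full suffix

  // process one suffix (text already loaded): returns first stopped region
  // (1-based) or z+1 when complete; stop_x/stop_y give the failing sub-region
  struct StopInfo { int x, y; };
  StopInfo si;

  // mark all ranks around rank j sharing a prefix of length >= depth
  // (lgslink only)
  #define MARK(rr) do { if (!vtab[(rr)]) { vtab[(rr)] = 1; \
      if (collect_events) { etype.push_back(3); evalue.push_back(rr); } } } while (0)

  // substring-based skipping after a stop at [sx..sy] for suffix at sufpos
  auto substrMark = [&](int sufpos, int sx, int sy) {
    int xs = sx - d - 1;
    if (xs < 1) return;
    int depth = (sy - sx + 1) + 2 * d;
    int abspos = sufpos + xs;
    if (abspos > n) return;
    int jl = isuf[abspos - 1];
    int js = jl, je = jl;
    while (js > 1 && lcp[js - 1] >= depth) js--;
    while (je < nn && lcp[je] >= depth) je++;
    for (int q = js; q <= je; q++) {
      int sq = suf[q - 1];
      if (sq > xs && sq - xs <= n) MARK(isuf[sq - xs - 1]);
    }
  };

  auto markPrefixAround = [&](int j, int depth) {
    for (int q = j - 1; q >= 1 && lcp[q] >= depth; q--) MARK(q);
    for (int q = j + 1; q <= nn && lcp[q - 1] >= depth; q++) MARK(q);
  };

  auto processLoaded = [&](int plcp, int rst) -> int {
    for (int r = 0; r < z; r++) {
      int vplcp = (r + 1 < rst) ? plcp : -1;
      int sy = 0;
      if (!computeRegion(C, regions[r], vplcp, K, d, true, sy)) {
        si.x = regions[r].x; si.y = sy;
        nstop++;
        if (collect_events) { etype.push_back(4); evalue.push_back(sy); }
        return r + 1;
      }
    }
    return z + 1;
  };

  auto loadText = [&](int sufpos, int p_i) {
    C.len = p_i;
    C.tw.assign(p_i + 1, 0);
    for (int t = 1; t <= p_i; t++) C.tw[t] = text[sufpos + t - 2];
    allocMats(C, p_i + 1);
    setLens(C);
  };

  auto storeFinal = [&](int p_i) {
    lastC.assign(p_i + 1, INF);
    lastE.assign(p_i + 1, 0);
    const DpMat& M = C.mats[0];
    for (int pp = lo; pp <= M.L; pp++)
      getref(C, M, C.P.finalslot, pp, lastC[pp], lastE[pp]);
  };

  int i = 1;
  while (i <= nn) {
    int sp = suf[i - 1];
    int p_i = std::min(mprime, n - sp + 1);
    bool skip = (sp > n) || (p_i < lo) || (uselinks && vtab[i]);
    if (!skip && haveLast && (long long)p_i <= shared) {
      // situation 1/2: the whole reading depth is shared with the last
      // computed suffix
      if (uselinks) vtab[i] = 1;
      if (lastMatched) {
        for (int pp = lo; pp <= p_i; pp++)
          if (lastC[pp] <= K + EPS && lastE[pp] <= d + EPS) {
            acc.start.push_back(sp); acc.len.push_back(pp);
            acc.cost.push_back(lastC[pp]); acc.ind.push_back(lastE[pp]);
          }
      }
      while (i + 1 <= nn && lcp[i] >= p_i) {  // lcp[i] is lcp(rank i, rank i+1)
        i++;
        shared = std::min<long long>(shared, lcp[i - 1]);
        int sp2 = suf[i - 1];
        if (uselinks && vtab[i]) continue;
        if (uselinks) vtab[i] = 1;
        int p2 = std::min(std::min(mprime, n - sp2 + 1), p_i);
        if (sp2 <= n && p2 >= lo && lastMatched) {
          for (int pp = lo; pp <= p2; pp++)
            if (lastC[pp] <= K + EPS && lastE[pp] <= d + EPS) {
              acc.start.push_back(sp2); acc.len.push_back(pp);
              acc.cost.push_back(lastC[pp]); acc.ind.push_back(lastE[pp]);
            }
        }
      }
      i++;
      if (i <= nn) shared = std::min<long long>(shared, lcp[i - 1]);
      continue;
    }
    if (skip) {
      i++;
      if (i <= nn) shared = std::min<long long>(shared, lcp[i - 1]);
      continue;
    }

    // full or partial alignment of this suffix
    int plcp = haveLast ? (int)std::min<long long>(shared, p_i) : -1;
    if (plcp > p_last) plcp = p_last;
    loadText(sp, p_i);
    if (collect_events) { etype.push_back(1); evalue.push_back(i); }
    if (uselinks) vtab[i] = 1;
    int newr = processLoaded(plcp, rstore);
    haveLast = true; p_last = p_i; rstore = newr; shared = p_i;
    bool chainSeed = true;
    if (newr == z + 1) {
      storeFinal(p_i);
      lastMatched = emitMatches(C, K, d, sp, acc);
    } else {
      lastMatched = false;
      int yd = si.y + d;
      if (uselinks && si.x - d > 1 && yd <= p_i) substrMark(sp, si.x, si.y);
      if (yd <= p_i) {
        if (uselinks) {
          markPrefixAround(i, yd);  // vtab handles the forward skip
        } else {
          while (i + 1 <= nn && lcp[i] >= yd) {
            i++;
            shared = std::min<long long>(shared, lcp[i - 1]);
          }
        }
      }
    }

    // suffix-link chain: process the suffixes obtained by chopping the first
    // character, reusing all matrices but their last column
    if (uselinks && chainSeed) {
      int cursuf = sp, curp = p_i, currst = newr;
      bool any = false;
      while (true) {
        int nsuf = cursuf + 1;
        if (nsuf > n) break;
        int j = isuf[nsuf - 1];
        int pj = std::min(mprime, n - nsuf + 1);
        if (pj < lo) break;
        if (vtab[j]) break;
        C.mats.pop_front();
        int plcp2 = curp - 1;
        loadText(nsuf, pj);
        if (collect_events) { etype.push_back(2); evalue.push_back(j); }
        vtab[j] = 1;
        int nr = processLoaded(plcp2, currst);
        any = true;
        if (nr == z + 1) {
          emitMatches(C, K, d, nsuf, acc);
        } else {
          int yd = si.y + d;
          if (si.x - d > 1 && yd <= pj) substrMark(nsuf, si.x, si.y);
          if (yd <= pj) markPrefixAround(j, yd);
        }
        cursuf = nsuf; curp = pj; currst = nr;
      }
      if (any) {
        // matrices now belong to the chain tail; disable reuse bookkeeping
        haveLast = false; lastMatched = false;
        rstore = 1; p_last = 0;
      }
    }
    i++;
    if (i <= nn) shared = std::min<long long>(shared, lcp[i - 1]);
  }
  #undef MARK
  List res = matchResult(acc, C.cells, nstop);
  res["events"] = DataFrame::create(_["type"] = wrap(etype), _["rank"] = wrap(evalue));
  return res;
}

// ---- DP session (exposed state for inspection, traceback, accounting) ----

struct DpSession {
  Ctx C;
};

static long long totalSlots(const Ctx& C) {
  long long t = 0;
  for (size_t k = 0; k < C.mats.size(); k++) t += C.mats[k].L;
  return t;
}

static void sessionComputeAll(Ctx& C, int vplcp) {
  for (size_t t = 0; t < C.P.rows.size(); t++) {
    for (int k = (int)C.mats.size(); k >= 1; k--) {
      int vc = (vplcp >= 0) ? (vplcp - k + 1) : -1;
      int jfrom = (vc >= 1) ? vc + 1 : 0;
      computeRow(C, C.P.rows[t], k, jfrom, C.mats[k - 1].L);
    }
  }
  long long done = 0;
  for (int k = 1; k <= (int)C.mats.size(); k++) {
    int vc = (vplcp >= 0) ? std::max(0, std::min(vplcp - k + 1, C.mats[k - 1].L)) : 0;
    done += C.mats[k - 1].L - vc;
  }
  C.slots_done = done;
  C.slots_reused = totalSlots(C) - done;
}

// [[Rcpp::export]]
SEXP cpp_dp_new(IntegerVector mask, IntegerVector partner, NumericVector costs,
                IntegerMatrix compm, IntegerVector text, int reserve) {
  DpSession* S = new DpSession();
  int len = text.size();
  initCtx(S->C, mask, partner, costs, compm, std::max(len, reserve) + 2);
  S->C.len = len;
  S->C.tw.assign(len + 1, 0);
  for (int t = 1; t <= len; t++) S->C.tw[t] = text[t - 1];
  allocMats(S->C, len + 1);
  setLens(S->C);
  sessionComputeAll(S->C, -1);
  XPtr<DpSession> p(S, true);
  return p;
}

// [[Rcpp::export]]
void cpp_dp_shift(SEXP ptr, int newcode) {
  XPtr<DpSession> S(ptr);
  Ctx& C = S->C;
  C.mats.pop_front();
  C.mats.push_back(freshMat(C));
  for (int t = 1; t < C.len; t++) C.tw[t] = C.tw[t + 1];
  C.tw[C.len] = newcode;
  setLens(C);
  sessionComputeAll(C, C.len - 1);
}

// [[Rcpp::export]]
void cpp_dp_reuse(SEXP ptr, IntegerVector text, int sharedlen) {
  XPtr<DpSession> S(ptr);
  Ctx& C = S->C;
  int len = text.size();
  if (len + 2 > C.stride) stop("replacement text longer than the session allows");
  if (sharedlen > std::min(len, C.len)) stop("shared prefix longer than the texts");
  C.len = len;
  C.tw.assign(len + 1, 0);
  for (int t = 1; t <= len; t++) C.tw[t] = text[t - 1];
  allocMats(C, len + 1);
  setLens(C);
  sessionComputeAll(C, sharedlen);
}

// [[Rcpp::export]]
NumericVector cpp_dp_counts(SEXP ptr) {
  XPtr<DpSession> S(ptr);
  return NumericVector::create(
      _["computed_slots"] = (double)S->C.slots_done,
      _["reused_slots"] = (double)S->C.slots_reused,
      _["total_slots"] = (double)totalSlots(S->C),
      _["cells"] = (double)S->C.cells);
}

// [[Rcpp::export]]
NumericMatrix cpp_dp_final(SEXP ptr) {
  XPtr<DpSession> S(ptr);
  const Ctx& C = S->C;
  int L = C.mats[0].L;
  NumericMatrix out(2, L + 1);
  for (int j = 0; j <= L; j++) {
    double c, e;
    getref(C, C.mats[0], C.P.finalslot, j, c, e);
    out(0, j) = c; out(1, j) = e;
  }
  rownames(out) = CharacterVector::create("cost", "indels");
  return out;
}

// [[Rcpp::export]]
List cpp_dp_matrices(SEXP ptr) {
  XPtr<DpSession> S(ptr);
  const Ctx& C = S->C;
  List out(C.mats.size());
  for (size_t k = 0; k < C.mats.size(); k++) {
    const DpMat& M = C.mats[k];
    NumericMatrix mc(C.P.nslots, M.L + 1), me(C.P.nslots, M.L + 1);
    for (int s = 0; s < C.P.nslots; s++)
      for (int j = 0; j <= M.L; j++) {
        mc(s, j) = M.c[(size_t)s * C.stride + j];
        me(s, j) = M.e[(size_t)s * C.stride + j];
      }
    out[k] = List::create(_["cost"] = mc, _["indels"] = me);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dp_layout(IntegerVector mask, IntegerVector partner) {
  Pat P = buildPat(mask, partner);
  return List::create(
      _["nslots"] = P.nslots,
      _["slot_main"] = wrap(std::vector<int>(P.slot_main.begin() + 1, P.slot_main.end())),
      _["slot_merged"] = wrap(std::vector<int>(P.slot_merged.begin() + 1, P.slot_merged.end())),
      _["finalslot"] = P.finalslot,
      _["segstart"] = wrap(std::vector<int>(P.segstart.begin() + 1, P.segstart.end())),
      _["kind"] = wrap(std::vector<int>(P.kind.begin() + 1, P.kind.end())));
}

// [[Rcpp::export]]
bool cpp_dp_band(SEXP ptr, int x, int y, int slot, double K, int d) {
  XPtr<DpSession> S(ptr);
  return bandExceeded(S->C, x, y, slot, K, d);
}

// one-shot distance computation: final row (cost; indels) for all lengths
// [[Rcpp::export]]
NumericMatrix cpp_dist(IntegerVector mask, IntegerVector partner, NumericVector costs,
                       IntegerMatrix compm, IntegerVector text) {
  Ctx C;
  int len = text.size();
  initCtx(C, mask, partner, costs, compm, len + 2);
  C.len = len;
  C.tw.assign(len + 1, 0);
  for (int t = 1; t <= len; t++) C.tw[t] = text[t - 1];
  allocMats(C, len + 1);
  setLens(C);
  sessionComputeAll(C, -1);
  int L = C.mats[0].L;
  NumericMatrix out(2, L + 1);
  for (int j = 0; j <= L; j++) {
    double c, e;
    getref(C, C.mats[0], C.P.finalslot, j, c, e);
    out(0, j) = c; out(1, j) = e;
  }
  rownames(out) = CharacterVector::create("cost", "indels");
  return out;
}

// ---- suffix array --------------------------------------------------------

// prefix-doubling construction over S$ with $ greater than every character
// [[Rcpp::export]]
List cpp_build_sa(IntegerVector text) {
  int n = text.size();
  int N = n + 1;  // virtual terminator at position n+1
  std::vector<int> sa(N), rank_(N), tmp(N);
  for (int i = 0; i < N; i++) {
    sa[i] = i;
    rank_[i] = (i < n) ? text[i] : 5;  // terminator sorts last
  }
  for (int h = 1;; h <<= 1) {
    struct Cmp {
      const std::vector<int>* r; int h, N;
      bool operator()(int a, int b) const {
        if ((*r)[a] != (*r)[b]) return (*r)[a] < (*r)[b];
        int ra = a + h < N ? (*r)[a + h] : -1;
        int rb = b + h < N ? (*r)[b + h] : -1;
        return ra < rb;
      }
    } cmp;
    cmp.r = &rank_; cmp.h = h; cmp.N = N;
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < N; i++)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[N - 1]] == N - 1) break;
  }
  // Kasai lcp
  std::vector<int> lcp(N, 0), inv(N);
  for (int i = 0; i < N; i++) inv[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < N; i++) {
    if (inv[i] > 0) {
      int j = sa[inv[i] - 1];
      while (i + h < N && j + h < N) {
        int ci = (i + h < n) ? text[i + h] : 5;
        int cj = (j + h < n) ? text[j + h] : 5;
        if (ci != cj) break;
        h++;
      }
      lcp[inv[i]] = h;
      if (h > 0) h--;
    } else {
      h = 0;
    }
  }
  IntegerVector suf(N), lcpv(N), isuf(N);
  for (int i = 0; i < N; i++) {
    suf[i] = sa[i] + 1;
    lcpv[i] = lcp[i];
    isuf[sa[i]] = i + 1;
  }
  return List::create(_["suf"] = suf, _["lcp"] = lcpv, _["isuf"] = isuf);
}
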