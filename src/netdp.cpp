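// Generalised Waterman-Byers dynamic programme: align a network of
// alignments against another network of alignments.
//
// Vertices of each network are alignment columns stored in a linear
// extension; index 0 is the Start sentinel and index V+1 the End sentinel,
// both behaving as virtual all-residue columns so that terminal gaps are
// charged through the ordinary transitions. Cells are indexed by vertex
// pairs and a state: M (both sides advance), I (only the second network
// advances; the first index is the anchor, i.e. the last non-all-gap column
// of the first side), D (mirror image).
//
// Gap costs use the left-attributed variant of the indel pattern matrix
// (G4): per pair of rows, the pattern each row forms over two adjoining
// columns is scored so that totals along complete paths equal the Table-1
// internal score while prefix cells match the classical affine convention.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

struct Net {
  int V, k;
  // gap[r + k*v] for v in 0..V+1 (0 and V+1 are all-residue sentinels)
  std::vector<bool> gap;
  // res[r + k*v]: 0-based residue index, -1 for gap/sentinel
  std::vector<int> res;
  std::vector<std::vector<int>> preds; // index 1..V+1 (preds of End at V+1)
  std::vector<std::vector<int>> succs; // index 0..V (may contain V+1)
  std::vector<bool> end_adj;           // 0..V: is End a successor?
};

static Net build_net(const IntegerMatrix& cols, const List& preds) {
  Net net;
  net.k = cols.nrow();
  net.V = cols.ncol();
  net.gap.assign(net.k * (net.V + 2), false);
  net.res.assign(net.k * (net.V + 2), -1);
  for (int v = 1; v <= net.V; ++v)
    for (int r = 0; r < net.k; ++r) {
      int code = cols(r, v - 1);
      net.gap[r + net.k * v] = (code == 0);
      net.res[r + net.k * v] = code - 1;
    }
  net.preds.resize(net.V + 2);
  for (int v = 1; v <= net.V + 1; ++v) {
    IntegerVector p = preds[v - 1];
    net.preds[v] = std::vector<int>(p.begin(), p.end());
  }
  net.succs.resize(net.V + 1);
  net.end_adj.assign(net.V + 1, false);
  for (int v = 1; v <= net.V + 1; ++v)
    for (int p : net.preds[v]) {
      net.succs[p].push_back(v);
      if (v == net.V + 1) net.end_adj[p] = true;
    }
  return net;
}

class NetDP {
public:
  Net A, B;
  NumericMatrix S;        // residue similarity
  NumericVector wA, wB;
  NumericMatrix G4;       // 4x4, pattern code = 2*gapLeft + gapRight
  int mode;               // 0 pairwise, 1 clustalw
  double OP, EX;

  std::vector<double> simM, simI, simD; // precomputed column similarities
  std::vector<double> withinA, withinB;

  NetDP(const IntegerMatrix& colsA, const List& predsA,
        const IntegerMatrix& colsB, const List& predsB,
        NumericMatrix S_, NumericVector wA_, NumericVector wB_,
        NumericMatrix G4_, int mode_, double OP_, double EX_)
    : S(S_), wA(wA_), wB(wB_), G4(G4_), mode(mode_), OP(OP_), EX(EX_) {
    A = build_net(colsA, predsA);
    B = build_net(colsB, predsB);
    precompute_sim();
  }

  double within_sim(const Net& net, const NumericVector& w, int v) {
    double s = 0;
    for (int r = 0; r < net.k; ++r) {
      int a = net.res[r + net.k * v];
      if (a < 0) continue;
      for (int t = r + 1; t < net.k; ++t) {
        int b = net.res[t + net.k * v];
        if (b < 0) continue;
        s += w[r] * w[t] * S(a, b);
      }
    }
    return s;
  }

  void precompute_sim() {
    withinA.assign(A.V + 1, 0.0);
    withinB.assign(B.V + 1, 0.0);
    for (int i = 1; i <= A.V; ++i) withinA[i] = within_sim(A, wA, i);
    for (int j = 1; j <= B.V; ++j) withinB[j] = within_sim(B, wB, j);
    simM.assign((A.V + 1) * (B.V + 1), 0.0);
    for (int i = 1; i <= A.V; ++i)
      for (int j = 1; j <= B.V; ++j) {
        double cross = 0;
        for (int r = 0; r < A.k; ++r) {
          int a = A.res[r + A.k * i];
          if (a < 0) continue;
          for (int t = 0; t < B.k; ++t) {
            int b = B.res[t + B.k * j];
            if (b < 0) continue;
            cross += wA[r] * wB[t] * S(a, b);
          }
        }
        simM[i + (A.V + 1) * j] = cross +
          (mode == 0 ? withinA[i] + withinB[j] : 0.0);
      }
    simI.assign(B.V + 1, 0.0);
    simD.assign(A.V + 1, 0.0);
    if (mode == 0) {
      for (int j = 1; j <= B.V; ++j) simI[j] = withinB[j];
      for (int i = 1; i <= A.V; ++i) simD[i] = withinA[i];
    }
  }

  // Pairwise-mode gap score between two adjoining combined columns.
  // Column halves are given as (vertex index, all-gap flag): when the flag
  // is set the half is an all-gap stack, otherwise the vertex's own gap
  // mask applies (vertex 0 / V+1 are all-residue sentinels).
  double gcol(int aL, bool aLgap, int aR, bool aRgap,
              int bL, bool bLgap, int bR, bool bRgap) {
    double s[4] = {0, 0, 0, 0}, sq[4] = {0, 0, 0, 0};
    for (int r = 0; r < A.k; ++r) {
      bool gl = aLgap || A.gap[r + A.k * aL];
      bool gr = aRgap || A.gap[r + A.k * aR];
      int p = (gl ? 2 : 0) + (gr ? 1 : 0);
      s[p] += wA[r]; sq[p] += wA[r] * wA[r];
    }
    for (int r = 0; r < B.k; ++r) {
      bool gl = bLgap || B.gap[r + B.k * bL];
      bool gr = bRgap || B.gap[r + B.k * bR];
      int p = (gl ? 2 : 0) + (gr ? 1 : 0);
      s[p] += wB[r]; sq[p] += wB[r] * wB[r];
    }
    double tot = 0, self = 0;
    for (int p = 0; p < 4; ++p) {
      if (s[p] == 0) continue;
      for (int q = 0; q < 4; ++q)
        if (s[q] != 0) tot += s[p] * s[q] * G4(p, q);
      self += sq[p] * G4(p, p);
    }
    return (tot - self) / 2.0;
  }

  // ClustalW-imitation gap score: one OP/EX per full-column event, decided
  // by the preceding column's state. States: 0 M (also Start/End), 1 I, 2 D.
  double gcw(int prevState, int curState) {
    if (curState == 0) return 0.0;
    return (prevState == curState) ? EX : OP;
  }

  // Transition score into a column with state `st` at (i, j) from a column
  // with state `ps` at (pi, pj). Sentinel flags handled by index 0 / V+1.
  double trans(int ps, int pi, int pj, int st, int i, int j) {
    if (mode == 1) return gcw(ps, st);
    bool pAgap = (ps == 1), pBgap = (ps == 2);
    bool cAgap = (st == 1), cBgap = (st == 2);
    return gcol(pi, pAgap, i, cAgap, pj, pBgap, j, cBgap);
  }

  double end_trans(int st, int i, int j) {
    if (mode == 1) return 0.0;
    return gcol(i, st == 1, A.V + 1, false, j, st == 2, B.V + 1, false);
  }

  NumericMatrix Mf, If, Df, Mb, Ib, Db;

  void forward() {
    int VA = A.V, VB = B.V;
    Mf = NumericMatrix(VA + 2, VB + 2);
    If = NumericMatrix(VA + 2, VB + 2);
    Df = NumericMatrix(VA + 2, VB + 2);
    std::fill(Mf.begin(), Mf.end(), NEG);
    std::fill(If.begin(), If.end(), NEG);
    std::fill(Df.begin(), Df.end(), NEG);
    Mf(0, 0) = 0.0;
    for (int i = 0; i <= VA; ++i) {
      for (int j = 0; j <= VB; ++j) {
        if (i >= 1 && j >= 1) { // match column a_i/b_j
          double best = NEG;
          for (int ip : A.preds[i]) {
            for (int jp : B.preds[j]) {
              double v;
              v = Mf(ip, jp);
              if (v > NEG) best = std::max(best, v + trans(0, ip, jp, 0, i, j));
              v = If(ip, jp);
              if (v > NEG) best = std::max(best, v + trans(1, ip, jp, 0, i, j));
              v = Df(ip, jp);
              if (v > NEG) best = std::max(best, v + trans(2, ip, jp, 0, i, j));
            }
          }
          if (best > NEG) Mf(i, j) = best + simM[i + (VA + 1) * j];
        }
        if (j >= 1) { // insertion column -_i/b_j (anchor i may be Start)
          double best = NEG;
          for (int jp : B.preds[j]) {
            double v;
            v = Mf(i, jp);
            if (v > NEG) best = std::max(best, v + trans(0, i, jp, 1, i, j));
            v = If(i, jp);
            if (v > NEG) best = std::max(best, v + trans(1, i, jp, 1, i, j));
            v = Df(i, jp);
            if (v > NEG) best = std::max(best, v + trans(2, i, jp, 1, i, j));
          }
          if (best > NEG) If(i, j) = best + simI[j];
        }
        if (i >= 1) { // deletion column a_i/-_j (anchor j may be Start)
          double best = NEG;
          for (int ip : A.preds[i]) {
            double v;
            v = Mf(ip, j);
            if (v > NEG) best = std::max(best, v + trans(0, ip, j, 2, i, j));
            v = If(ip, j);
            if (v > NEG) best = std::max(best, v + trans(1, ip, j, 2, i, j));
            v = Df(ip, j);
            if (v > NEG) best = std::max(best, v + trans(2, ip, j, 2, i, j));
          }
          if (best > NEG) Df(i, j) = best + simD[i];
        }
      }
    }
  }

  void backward() {
    int VA = A.V, VB = B.V;
    Mb = NumericMatrix(VA + 2, VB + 2);
    Ib = NumericMatrix(VA + 2, VB + 2);
    Db = NumericMatrix(VA + 2, VB + 2);
    std::fill(Mb.begin(), Mb.end(), NEG);
    std::fill(Ib.begin(), Ib.end(), NEG);
    std::fill(Db.begin(), Db.end(), NEG);
    for (int i = VA; i >= 0; --i) {
      for (int j = VB; j >= 0; --j) {
        for (int st = 0; st < 3; ++st) {
          if (st == 0 && (i < 1 || j < 1)) continue;
          if (st == 1 && j < 1) continue;
          if (st == 2 && i < 1) continue;
          double best = NEG;
          if (A.end_adj[i] && B.end_adj[j])
            best = end_trans(st, i, j);
          // successor match columns
          for (int is : A.succs[i]) {
            if (is > VA) continue;
            for (int js : B.succs[j]) {
              if (js > VB) continue;
              double v = Mb(is, js);
              if (v > NEG)
                best = std::max(best, trans(st, i, j, 0, is, js) +
                                        simM[is + (VA + 1) * js] + v);
            }
          }
          // successor insertion columns share the anchor i
          for (int js : B.succs[j]) {
            if (js > VB) continue;
            double v = Ib(i, js);
            if (v > NEG)
              best = std::max(best, trans(st, i, j, 1, i, js) + simI[js] + v);
          }
          // successor deletion columns share the anchor j
          for (int is : A.succs[i]) {
            if (is > VA) continue;
            double v = Db(is, j);
            if (v > NEG)
              best = std::max(best, trans(st, i, j, 2, is, j) + simD[is] + v);
          }
          if (best > NEG) {
            if (st == 0) Mb(i, j) = best;
            else if (st == 1) Ib(i, j) = best;
            else Db(i, j) = best;
          }
        }
      }
    }
  }

  double opt() {
    double best = NEG;
    for (int i = 0; i <= A.V; ++i) {
      if (!A.end_adj[i]) continue;
      for (int j = 0; j <= B.V; ++j) {
        if (!B.end_adj[j]) continue;
        if (i >= 1 && j >= 1 && Mf(i, j) > NEG)
          best = std::max(best, Mf(i, j) + end_trans(0, i, j));
        if (j >= 1 && If(i, j) > NEG)
          best = std::max(best, If(i, j) + end_trans(1, i, j));
        if (i >= 1 && Df(i, j) > NEG)
          best = std::max(best, Df(i, j) + end_trans(2, i, j));
      }
    }
    return best;
  }

  // Deterministic best-path traceback: ties prefer state M, then D, then I,
  // then the smaller (i, j) pair.
  IntegerMatrix traceback() {
    const double tol = 1e-9;
    double target = opt();
    int ci = -1, cj = -1, cst = -1;
    int order[3] = {0, 2, 1}; // M, D, I
    for (int s = 0; s < 3 && ci < 0; ++s) {
      int st = order[s];
      for (int i = 0; i <= A.V && ci < 0; ++i) {
        if (!A.end_adj[i]) continue;
        for (int j = 0; j <= B.V; ++j) {
          if (!B.end_adj[j]) continue;
          double v = cell(st, i, j, true);
          if (v > NEG && v + end_trans(st, i, j) >= target - tol) {
            ci = i; cj = j; cst = st;
            break;
          }
        }
      }
    }
    std::vector<int> pi, pj, ps;
    while (ci >= 0) {
      pi.push_back(ci); pj.push_back(cj); ps.push_back(cst);
      double need = cell(cst, ci, cj, true) - simcell(cst, ci, cj);
      int ni = -1, nj = -1, nst = -1;
      // enumerate predecessor candidates in tie-break order
      bool done = false;
      for (int s = 0; s < 3 && !done; ++s) {
        int st = order[s];
        if (cst == 0) { // preds of M(i,j) at (i', j')
          for (int ip : A.preds[ci]) {
            for (int jp : B.preds[cj]) {
              double v = cell(st, ip, jp, true);
              if (v > NEG && v + trans(st, ip, jp, 0, ci, cj) >= need - tol) {
                ni = ip; nj = jp; nst = st; done = true; break;
              }
            }
            if (done) break;
          }
        } else if (cst == 1) { // preds of I(i,j) at (i, j')
          for (int jp : B.preds[cj]) {
            double v = cell(st, ci, jp, true);
            if (v > NEG && v + trans(st, ci, jp, 1, ci, cj) >= need - tol) {
              ni = ci; nj = jp; nst = st; done = true; break;
            }
          }
        } else { // preds of D(i,j) at (i', j)
          for (int ip : A.preds[ci]) {
            double v = cell(st, ip, cj, true);
            if (v > NEG && v + trans(st, ip, cj, 2, ci, cj) >= need - tol) {
              ni = ip; nj = cj; nst = st; done = true; break;
            }
          }
        }
      }
      if (!done) break; // reached Start: Mf(0,0) is its own fixed point
      if (nst == 0 && ni == 0 && nj == 0) { ci = -1; }
      else { ci = ni; cj = nj; cst = nst; }
    }
    int n = pi.size();
    IntegerMatrix path(n, 3);
    for (int t = 0; t < n; ++t) { // reverse into Start->End order
      path(n - 1 - t, 0) = pi[t];
      path(n - 1 - t, 1) = pj[t];
      path(n - 1 - t, 2) = ps[t] + 1;
    }
    return path;
  }

  double cell(int st, int i, int j, bool fwd) {
    if (st == 0) {
      if (i < 1 || j < 1) return (fwd && i == 0 && j == 0) ? Mf(0, 0) : NEG;
      return fwd ? Mf(i, j) : Mb(i, j);
    }
    if (st == 1) {
      if (j < 1) return NEG;
      return fwd ? If(i, j) : Ib(i, j);
    }
    if (i < 1) return NEG;
    return fwd ? Df(i, j) : Db(i, j);
  }

  double simcell(int st, int i, int j) {
    if (st == 0) return simM[i + (A.V + 1) * j];
    if (st == 1) return simI[j];
    return simD[i];
  }
};

// [[Rcpp::export(name = ".net_dp_tables")]]
List net_dp_tables(IntegerMatrix colsA, List predsA,
                   IntegerMatrix colsB, List predsB,
                   NumericMatrix S, NumericVector wA, NumericVector wB,
                   NumericMatrix G4, int mode, double OP, double EX,
                   bool backward = true, bool path = true) {
  NetDP dp(colsA, predsA, colsB, predsB, S, wA, wB, G4, mode, OP, EX);
  dp.forward();
  List out = List::create(
    _["Mf"] = dp.Mf, _["If"] = dp.If, _["Df"] = dp.Df,
    _["opt"] = dp.opt());
  if (backward) {
    dp.backward();
    out["Mb"] = dp.Mb; out["Ib"] = dp.Ib; out["Db"] = dp.Db;
  }
  if (path) out["path"] = dp.traceback();
  return out;
}
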