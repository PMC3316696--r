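#include <Rcpp.h>
#include <cstdio>
#include <string>
#include <vector>
using namespace Rcpp;

// Pairwise site counts under pairwise deletion.
// seqs: n x L integer matrix coded 0=A, 1=C, 2=G, 3=T, -1=gap/ambiguity.
// Transitions are A<->G and C<->T; with this coding the two purines are
// even and the two pyrimidines odd, so a mismatch is a transition iff the
// two codes share parity.
// [[Rcpp::export]]
List pair_counts_cpp(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  IntegerMatrix comp(n, n), ts(n, n), tv(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int c = 0, t = 0, v = 0;
      for (int k = 0; k < L; ++k) {
        const int a = seqs(i, k), b = seqs(j, k);
        if (a < 0 || b < 0) continue;
        ++c;
        if (a != b) {
          if ((a & 1) == (b & 1)) ++t; else ++v;
        }
      }
      comp(i, j) = comp(j, i) = c;
      ts(i, j) = ts(j, i) = t;
      tv(i, j) = tv(j, i) = v;
    }
  }
  return List::create(_["comparable"] = comp,
                      _["transitions"] = ts,
                      _["transversions"] = tv);
}

static std::string fmt_len(double x) {
  char buf[40];
  std::snprintf(buf, sizeof(buf), "%.12g", x);
  return std::string(buf);
}

// Saitou-Nei neighbor joining with the Studier-Keppler Q criterion.
// Ties in Q are broken by the smallest (i, j) position pair in the current
// label order; the joined node takes the position of i. Negative branch
// lengths are clamped to zero at output; reduced distances are left as
// computed. Returns the unrooted tree as a newick string with a
// trifurcating base.
// [[Rcpp::export]]
std::string nj_newick_cpp(NumericMatrix d0, CharacterVector labels) {
  const int n = d0.nrow();
  if (n < 3) stop("neighbor joining needs at least 3 taxa");
  std::vector<std::vector<double> > d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = d0(i, j);
  std::vector<std::string> sub(n);
  for (int i = 0; i < n; ++i) sub[i] = as<std::string>(labels[i]);
  std::vector<int> act(n);  // active slots in current label order
  for (int i = 0; i < n; ++i) act[i] = i;
  int r = n;

  while (r > 3) {
    // net divergences
    std::vector<double> R(r, 0.0);
    for (int p = 0; p < r; ++p) {
      double s = 0.0;
      for (int q = 0; q < r; ++q)
        if (q != p) s += d[act[p]][act[q]];
      R[p] = s;
    }
    int bi = -1, bj = -1;
    double bestQ = R_PosInf;
    for (int p = 0; p < r; ++p) {
      for (int q = p + 1; q < r; ++q) {
        const double Q = (r - 2) * d[act[p]][act[q]] - R[p] - R[q];
        if (Q < bestQ) { bestQ = Q; bi = p; bj = q; }
      }
    }
    const int si = act[bi], sj = act[bj];
    const double dij = d[si][sj];
    double li = 0.5 * dij + (R[bi] - R[bj]) / (2.0 * (r - 2));
    double lj = dij - li;
    if (li < 0) li = 0;
    if (lj < 0) lj = 0;
    sub[si] = "(" + sub[si] + ":" + fmt_len(li) + "," +
              sub[sj] + ":" + fmt_len(lj) + ")";
    for (int p = 0; p < r; ++p) {
      const int k = act[p];
      if (k == si || k == sj) continue;
      const double nd = 0.5 * (d[si][k] + d[sj][k] - dij);
      d[si][k] = d[k][si] = nd;
    }
    act.erase(act.begin() + bj);
    --r;
  }

  const int a = act[0], b = act[1], c = act[2];
  double la = 0.5 * (d[a][b] + d[a][c] - d[b][c]);
  double lb = 0.5 * (d[a][b] + d[b][c] - d[a][c]);
  double lc = 0.5 * (d[a][c] + d[b][c] - d[a][b]);
  if (la < 0) la = 0;
  if (lb < 0) lb = 0;
  if (lc < 0) lc = 0;
  return "(" + sub[a] + ":" + fmt_len(la) + "," +
         sub[b] + ":" + fmt_len(lb) + "," +
         sub[c] + ":" + fmt_len(lc) + ");";
}
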