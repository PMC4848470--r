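#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <string>
#include <vector>
using namespace Rcpp;

// Pairwise raw difference and comparable-site counts over the rows of an
// integer-coded alignment. Codes <= 0 are missing (N, gap, X); a column
// contributes to a pair only when both codes are positive.
// [[Rcpp::export]]
List cpp_pair_counts(IntegerMatrix x) {
  const int n = x.nrow(), L = x.ncol();
  IntegerMatrix diffs(n, n), comp(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = 0, c = 0;
      for (int k = 0; k < L; ++k) {
        const int a = x(i, k), b = x(j, k);
        if (a > 0 && b > 0) {
          ++c;
          if (a != b) ++d;
        }
      }
      diffs(i, j) = diffs(j, i) = d;
      comp(i, j) = comp(j, i) = c;
    }
  }
  return List::create(_["diffs"] = diffs, _["comparable"] = comp);
}

// --- shared NJ machinery -------------------------------------------------
//
// Saitou-Nei neighbor joining on a working copy of the distance matrix.
// Ties in the Q-matrix minimisation are broken by the lexicographically
// smallest label pair; each cluster carries the rank (in sorted label
// order) of its smallest member so the comparison is an integer one.

struct NJPick {
  int i, j;
};

static NJPick nj_pick(const std::vector<std::vector<double> > &d,
                      const std::vector<int> &act,
                      const std::vector<int> &rep,
                      const std::vector<double> &r) {
  const int m = (int)act.size();
  double qmin = R_PosInf;
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      const double q = (m - 2) * d[act[a]][act[b]] - r[a] - r[b];
      if (q < qmin) qmin = q;
    }
  const double tol = 1e-10 * (1.0 + std::fabs(qmin));
  NJPick best;
  best.i = -1;
  best.j = -1;
  int bi = -1, bj = -1;
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      const double q = (m - 2) * d[act[a]][act[b]] - r[a] - r[b];
      if (q <= qmin + tol) {
        int lo = rep[act[a]], hi = rep[act[b]];
        if (lo > hi) std::swap(lo, hi);
        if (best.i < 0 || lo < bi || (lo == bi && hi < bj)) {
          best.i = a;
          best.j = b;
          bi = lo;
          bj = hi;
        }
      }
    }
  return best;
}

static std::string fmt_bl(double x) {
  if (x < 0) x = 0;
  char buf[40];
  std::snprintf(buf, sizeof(buf), "%.10g", x);
  return std::string(buf);
}

// Neighbor joining returning a Newick string (unrooted; trifurcation at the
// last join). Negative branch lengths are clamped to zero.
// [[Rcpp::export]]
std::string cpp_nj_newick(NumericMatrix dm, CharacterVector labels,
                          IntegerVector label_rank) {
  const int n = dm.nrow();
  if (n < 2) stop("neighbor joining needs at least 2 labels");
  std::vector<std::vector<double> > d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = dm(i, j);
  std::vector<std::string> nwk(n);
  std::vector<int> rep(n);
  for (int i = 0; i < n; ++i) {
    nwk[i] = as<std::string>(labels[i]);
    rep[i] = label_rank[i];
  }
  if (n == 2) {
    const std::string h = fmt_bl(d[0][1] / 2.0);
    return "(" + nwk[0] + ":" + h + "," + nwk[1] + ":" + h + ");";
  }
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  while ((int)act.size() > 3) {
    const int m = (int)act.size();
    std::vector<double> r(m, 0.0);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        if (b != a) r[a] += d[act[a]][act[b]];
    NJPick p = nj_pick(d, act, rep, r);
    const int ci = act[p.i], cj = act[p.j];
    const double dij = d[ci][cj];
    double bi = dij / 2.0 + (r[p.i] - r[p.j]) / (2.0 * (m - 2));
    double bj = dij - bi;
    if (bi < 0) bi = 0;
    if (bj < 0) bj = 0;
    // reuse slot ci for the merged cluster
    for (int b = 0; b < m; ++b) {
      const int ck = act[b];
      if (ck == ci || ck == cj) continue;
      double nd = (d[ci][ck] + d[cj][ck] - dij) / 2.0;
      if (nd < 0) nd = 0;
      d[ci][ck] = d[ck][ci] = nd;
    }
    nwk[ci] =
        "(" + nwk[ci] + ":" + fmt_bl(bi) + "," + nwk[cj] + ":" + fmt_bl(bj) + ")";
    if (rep[cj] < rep[ci]) rep[ci] = rep[cj];
    act.erase(act.begin() + p.j);
  }
  const int a = act[0], b = act[1], c = act[2];
  const double la = (d[a][b] + d[a][c] - d[b][c]) / 2.0;
  const double lb = (d[a][b] + d[b][c] - d[a][c]) / 2.0;
  const double lc = (d[a][c] + d[b][c] - d[a][b]) / 2.0;
  return "(" + nwk[a] + ":" + fmt_bl(la) + "," + nwk[b] + ":" + fmt_bl(lb) +
         "," + nwk[c] + ":" + fmt_bl(lc) + ");";
}

// Does the NJ tree of distance matrix d contain an edge whose removal
// bipartitions the leaves exactly into species 1 vs species 2?  Bitset
// version of the same NJ (same tie-break); every bipartition of the final
// unrooted tree corresponds either to a single leaf or to a cluster created
// during agglomeration, so the check runs alongside the merges.
static bool nj_separates(std::vector<std::vector<double> > &d,
                         const std::vector<int> &rank0,
                         const uint64_t maskA, const uint64_t maskB) {
  const int n = (int)d.size();
  // single-leaf species: the pendant edge is the separating edge
  if (__builtin_popcountll(maskA) == 1 || __builtin_popcountll(maskB) == 1)
    return true;
  if (n < 4) return false;
  std::vector<uint64_t> bits(n);
  std::vector<int> rep(rank0);
  for (int i = 0; i < n; ++i) bits[i] = (uint64_t)1 << i;
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  while ((int)act.size() > 3) {
    const int m = (int)act.size();
    std::vector<double> r(m, 0.0);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        if (b != a) r[a] += d[act[a]][act[b]];
    NJPick p = nj_pick(d, act, rep, r);
    const int ci = act[p.i], cj = act[p.j];
    const double dij = d[ci][cj];
    for (int b = 0; b < m; ++b) {
      const int ck = act[b];
      if (ck == ci || ck == cj) continue;
      double nd = (d[ci][ck] + d[cj][ck] - dij) / 2.0;
      if (nd < 0) nd = 0;
      d[ci][ck] = d[ck][ci] = nd;
    }
    bits[ci] |= bits[cj];
    if (rep[cj] < rep[ci]) rep[ci] = rep[cj];
    if (bits[ci] == maskA || bits[ci] == maskB) return true;
    act.erase(act.begin() + p.j);
  }
  return false;
}

// Column-bootstrap support (count of separating replicates) for the species
// bipartition.  x: integer-coded alignment (rows = haplotype leaves), codes
// <= 0 missing; species: 1/2 per row; label_rank: rank of each row's label
// in sorted order (tie-break); reps: number of replicates.  Uses R's RNG.
// A replicate with any fully incomparable pair counts as non-separating.
// [[Rcpp::export]]
List cpp_boot_support(IntegerMatrix x, IntegerVector species,
                      IntegerVector label_rank, int reps) {
  const int n = x.nrow(), L = x.ncol();
  if (n > 64) stop("bootstrap supports at most 64 leaves");
  if (L < 1) stop("alignment has no columns");
  uint64_t maskA = 0, maskB = 0;
  for (int i = 0; i < n; ++i) {
    if (species[i] == 1)
      maskA |= (uint64_t)1 << i;
    else
      maskB |= (uint64_t)1 << i;
  }
  std::vector<int> rank0(n);
  for (int i = 0; i < n; ++i) rank0[i] = label_rank[i];
  // per-pair indicator rows (contiguous) so each replicate reduces to a
  // weighted sum over column multiplicities
  const int P = n * (n - 1) / 2;
  std::vector<unsigned char> diffbit((size_t)P * L), compbit((size_t)P * L);
  std::vector<bool> full(P, true);
  {
    int p = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++p) {
        unsigned char *db = &diffbit[(size_t)p * L];
        unsigned char *cb = &compbit[(size_t)p * L];
        for (int c = 0; c < L; ++c) {
          const int a = x(i, c), b = x(j, c);
          const bool cmp = a > 0 && b > 0;
          cb[c] = cmp;
          db[c] = cmp && a != b;
          if (!cmp) full[p] = false;
        }
      }
  }
  int nsep = 0, nincomp = 0;
  std::vector<int> w(L);
  std::vector<std::vector<double> > d(n, std::vector<double>(n, 0.0));
  for (int rep = 0; rep < reps; ++rep) {
    std::fill(w.begin(), w.end(), 0);
    for (int k = 0; k < L; ++k) {
      int c = (int)(unif_rand() * L);
      if (c >= L) c = L - 1;
      ++w[c];
    }
    bool ok = true;
    int p = 0;
    for (int i = 0; i < n && ok; ++i)
      for (int j = i + 1; j < n; ++j, ++p) {
        const unsigned char *db = &diffbit[(size_t)p * L];
        int df = 0, cp = L;
        for (int c = 0; c < L; ++c) df += w[c] * db[c];
        if (!full[p]) {
          const unsigned char *cb = &compbit[(size_t)p * L];
          cp = 0;
          for (int c = 0; c < L; ++c) cp += w[c] * cb[c];
          if (cp == 0) {
            ok = false;
            ++nincomp;
            break;
          }
        }
        d[i][j] = d[j][i] = 100.0 * df / cp;
      }
    if (ok && nj_separates(d, rank0, maskA, maskB)) ++nsep;
  }
  return List::create(_["separating"] = nsep, _["incomparable"] = nincomp);
}

// Separation test for a single precomputed distance matrix (NJ + bipartition
// check with the same tie-break as cpp_nj_newick).
// [[Rcpp::export]]
bool cpp_dist_separates(NumericMatrix dm, IntegerVector species,
                        IntegerVector label_rank) {
  const int n = dm.nrow();
  if (n > 64) stop("at most 64 leaves supported");
  uint64_t maskA = 0, maskB = 0;
  for (int i = 0; i < n; ++i) {
    if (species[i] == 1)
      maskA |= (uint64_t)1 << i;
    else
      maskB |= (uint64_t)1 << i;
  }
  std::vector<std::vector<double> > d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = dm(i, j);
  std::vector<int> rank0(n);
  for (int i = 0; i < n; ++i) rank0[i] = label_rank[i];
  return nj_separates(d, rank0, maskA, maskB);
}
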