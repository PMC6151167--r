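// Structured coalescent with recombination (Hudson ancestral recombination
// graph), piecewise-constant deme sizes, symmetric or arbitrary backwards
// migration, a single common merge time, and infinite-sites mutation.
//
// Lineages carry sorted lists of ancestral segments; each segment remembers
// the tree node currently rooting it and the number of sample leaves below.
// Segments whose leaf count reaches the full sample size have found their
// marginal MRCA and are dropped, so recombination and mutation opportunity
// shrink as the ARG resolves. Time is in generations throughout.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;   // half-open [l, r) in bp
  int node;      // tree node rooting this segment
  int nleaf;     // sample leaves below `node` over this interval
};

struct Lin {
  std::vector<Seg> segs;
  int deme;
  double span() const {
    return segs.empty() ? 0.0 : (segs.back().r - segs.front().l);
  }
};

struct EdgeRec {
  double l, r;
  int parent, child;
};

// append a segment, squashing with the previous one when contiguous
inline void push_seg(std::vector<Seg> &out, const Seg &s) {
  if (!out.empty()) {
    Seg &b = out.back();
    if (b.node == s.node && b.nleaf == s.nleaf && b.r == s.l) {
      b.r = s.r;
      return;
    }
  }
  out.push_back(s);
}

}  // namespace

// [[Rcpp::export]]
List arg_simulate_cpp(IntegerVector n_per_deme,
                      NumericVector epoch_start,
                      NumericMatrix epoch_sizes,
                      double merge_time,
                      NumericMatrix mig,
                      double rec_rate,
                      double locus_length,
                      int seed,
                      double max_events = 5e6,
                      int max_lineages = 100000) {
  const int n_deme = n_per_deme.size();
  const int n_epoch = epoch_start.size();
  if (epoch_sizes.nrow() != n_epoch || epoch_sizes.ncol() != n_deme)
    stop("epoch_sizes must be n_epoch x n_deme");

  int ntot = 0;
  for (int d = 0; d < n_deme; ++d) ntot += n_per_deme[d];
  if (ntot < 2) stop("need at least two sampled haplotypes");

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761u + 1u);
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  auto runif = [&](double a, double b) { return a + (b - a) * U01(rng); };

  // migration row sums (per-lineage total out-rate per deme)
  std::vector<double> mig_out(n_deme, 0.0);
  for (int d = 0; d < n_deme; ++d)
    for (int j = 0; j < n_deme; ++j)
      if (j != d) mig_out[d] += mig(d, j);

  std::vector<Lin> lins;
  lins.reserve(2 * ntot);
  {
    int id = 0;
    for (int d = 0; d < n_deme; ++d)
      for (int i = 0; i < n_per_deme[d]; ++i, ++id) {
        Lin L;
        L.deme = d;
        L.segs.push_back(Seg{0.0, locus_length, id, 1});
        lins.push_back(L);
      }
  }

  std::vector<double> node_time(ntot, 0.0);
  std::vector<EdgeRec> edges;
  edges.reserve(4 * ntot);

  double tau = 0.0;
  int epoch = 0;
  bool merged = (n_deme == 1) || !R_finite(merge_time);
  if (n_deme == 1) merge_time = R_PosInf;
  double n_events = 0.0;

  // coalesce lineages ia and ib at time `tau`; result replaces ia
  auto coalesce = [&](int ia, int ib) {
    std::vector<Seg> A; A.swap(lins[ia].segs);
    std::vector<Seg> B; B.swap(lins[ib].segs);
    std::vector<Seg> out;
    out.reserve(A.size() + B.size());
    int newnode = -1;
    size_t i = 0, j = 0;
    while (i < A.size() && j < B.size()) {
      Seg &a = A[i];
      Seg &b = B[j];
      if (a.r <= b.l) { push_seg(out, a); ++i; continue; }
      if (b.r <= a.l) { push_seg(out, b); ++j; continue; }
      const double lo = std::max(a.l, b.l);
      const double hi = std::min(a.r, b.r);
      if (a.l < lo) push_seg(out, Seg{a.l, lo, a.node, a.nleaf});
      if (b.l < lo) push_seg(out, Seg{b.l, lo, b.node, b.nleaf});
      if (newnode < 0) {
        newnode = static_cast<int>(node_time.size());
        node_time.push_back(tau);
      }
      edges.push_back(EdgeRec{lo, hi, newnode, a.node});
      edges.push_back(EdgeRec{lo, hi, newnode, b.node});
      const int nl = a.nleaf + b.nleaf;
      if (nl < ntot) push_seg(out, Seg{lo, hi, newnode, nl});
      // keep remainders for the next sweep step
      if (a.r > hi) a.l = hi; else ++i;
      if (b.r > hi) b.l = hi; else ++j;
    }
    for (; i < A.size(); ++i) push_seg(out, A[i]);
    for (; j < B.size(); ++j) push_seg(out, B[j]);
    lins[ia].segs.swap(out);
    lins.erase(lins.begin() + ib);
    if (lins[ia].segs.empty()) lins.erase(lins.begin() + ia);
  };

  while (lins.size() > 1) {
    if (++n_events > max_events)
      stop("ARG simulation exceeded the event cap; model may be nonconvergent");
    if (static_cast<int>(lins.size()) > max_lineages)
      stop("runaway lineage count in ARG simulation");

    // per-deme lineage counts and per-lineage spans
    std::vector<int> k(n_deme, 0);
    for (const Lin &L : lins) k[L.deme]++;

    double crate_tot = 0.0;
    std::vector<double> crate(n_deme, 0.0);
    for (int d = 0; d < n_deme; ++d) {
      const double N = epoch_sizes(epoch, d);
      crate[d] = k[d] * (k[d] - 1) / 2.0 / (2.0 * N);
      crate_tot += crate[d];
    }
    double mrate_tot = 0.0;
    if (!merged)
      for (const Lin &L : lins) mrate_tot += mig_out[L.deme];
    double rrate_tot = 0.0;
    for (const Lin &L : lins) rrate_tot += rec_rate * L.span();

    const double R = crate_tot + mrate_tot + rrate_tot;

    double boundary = R_PosInf;
    if (epoch + 1 < n_epoch) boundary = epoch_start[epoch + 1];
    if (!merged && merge_time < boundary) boundary = merge_time;

    double wait = (R > 0.0) ? -std::log(1.0 - U01(rng)) / R : R_PosInf;
    if (tau + wait >= boundary) {
      if (!R_finite(boundary))
        stop("no coalescence possible: zero total rate and no further epochs");
      tau = boundary;
      if (!merged && boundary == merge_time) {
        merged = true;
        for (Lin &L : lins) L.deme = 0;
      }
      while (epoch + 1 < n_epoch && epoch_start[epoch + 1] <= tau) ++epoch;
      continue;
    }
    tau += wait;

    double u = runif(0.0, R);
    if (u < crate_tot) {
      // coalescence: choose deme, then a uniform pair within it
      int d = 0;
      while (u >= crate[d]) { u -= crate[d]; ++d; }
      std::vector<int> idx;
      for (int ii = 0; ii < static_cast<int>(lins.size()); ++ii)
        if (lins[ii].deme == d) idx.push_back(ii);
      const int na = static_cast<int>(idx.size());
      int a = static_cast<int>(runif(0.0, na));
      if (a >= na) a = na - 1;
      int b = static_cast<int>(runif(0.0, na - 1));
      if (b >= na - 1) b = na - 2;
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      if (ia > ib) std::swap(ia, ib);
      coalesce(ia, ib);
    } else if (u < crate_tot + mrate_tot) {
      u -= crate_tot;
      int ii = 0;
      while (ii < static_cast<int>(lins.size()) - 1 && u >= mig_out[lins[ii].deme]) {
        u -= mig_out[lins[ii].deme];
        ++ii;
      }
      const int d = lins[ii].deme;
      double v = runif(0.0, mig_out[d]);
      int dest = -1;
      for (int j = 0; j < n_deme; ++j) {
        if (j == d) continue;
        if (v < mig(d, j)) { dest = j; break; }
        v -= mig(d, j);
      }
      if (dest < 0) dest = (d + 1) % n_deme;
      lins[ii].deme = dest;
    } else {
      // recombination: lineage proportional to span, breakpoint uniform in it
      u -= crate_tot + mrate_tot;
      int ii = 0;
      while (ii < static_cast<int>(lins.size()) - 1 &&
             u >= rec_rate * lins[ii].span()) {
        u -= rec_rate * lins[ii].span();
        ++ii;
      }
      Lin &L = lins[ii];
      const double lmin = L.segs.front().l, rmax = L.segs.back().r;
      const double bp = runif(lmin, rmax);
      if (bp <= lmin || bp >= rmax) continue;  // numerically degenerate
      Lin Rn;
      Rn.deme = L.deme;
      std::vector<Seg> left;
      for (Seg &s : L.segs) {
        if (s.r <= bp) left.push_back(s);
        else if (s.l >= bp) Rn.segs.push_back(s);
        else {
          left.push_back(Seg{s.l, bp, s.node, s.nleaf});
          Rn.segs.push_back(Seg{bp, s.r, s.node, s.nleaf});
        }
      }
      if (left.empty() || Rn.segs.empty()) continue;
      L.segs.swap(left);
      lins.push_back(Rn);
    }
  }

  // squash contiguous edge records with identical parent/child
  std::sort(edges.begin(), edges.end(), [](const EdgeRec &a, const EdgeRec &b) {
    if (a.parent != b.parent) return a.parent < b.parent;
    if (a.child != b.child) return a.child < b.child;
    return a.l < b.l;
  });
  std::vector<EdgeRec> sq;
  sq.reserve(edges.size());
  for (const EdgeRec &e : edges) {
    if (!sq.empty()) {
      EdgeRec &b = sq.back();
      if (b.parent == e.parent && b.child == e.child && b.r == e.l) {
        b.r = e.r;
        continue;
      }
    }
    sq.push_back(e);
  }

  const int ne = static_cast<int>(sq.size());
  NumericVector el(ne), er(ne);
  IntegerVector ep(ne), ec(ne);
  for (int i = 0; i < ne; ++i) {
    el[i] = sq[i].l;
    er[i] = sq[i].r;
    ep[i] = sq[i].parent;
    ec[i] = sq[i].child;
  }
  return List::create(_["left"] = el, _["right"] = er, _["parent"] = ep,
                      _["child"] = ec,
                      _["node_time"] = NumericVector(node_time.begin(), node_time.end()),
                      _["n_samples"] = ntot);
}

// Poisson infinite-sites mutation on an edge table: each mutation falls at a
// real-valued position within its edge's interval and is carried by all
// sample leaves below the edge's child node at that position.
// [[Rcpp::export]]
List drop_mutations_cpp(NumericVector e_left, NumericVector e_right,
                        IntegerVector e_parent, IntegerVector e_child,
                        NumericVector node_time, int n_samples,
                        double mu, int seed) {
  const int ne = e_left.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 1442695040888963407ull + 3u);
  std::uniform_real_distribution<double> U01(0.0, 1.0);

  const int n_nodes = node_time.size();
  std::vector<std::vector<int>> by_parent(n_nodes);
  for (int i = 0; i < ne; ++i) by_parent[e_parent[i]].push_back(i);

  std::vector<double> pos;
  std::vector<std::vector<int>> carriers;

  std::vector<int> stack;
  for (int i = 0; i < ne; ++i) {
    const double blen = node_time[e_parent[i]] - node_time[e_child[i]];
    const double lam = mu * (e_right[i] - e_left[i]) * blen;
    if (lam <= 0.0) continue;
    std::poisson_distribution<int> P(lam);
    const int nm = P(rng);
    for (int m = 0; m < nm; ++m) {
      const double x = e_left[i] + (e_right[i] - e_left[i]) * U01(rng);
      std::vector<int> leaves;
      stack.clear();
      stack.push_back(e_child[i]);
      while (!stack.empty()) {
        const int v = stack.back();
        stack.pop_back();
        if (v < n_samples) {
          leaves.push_back(v);
          continue;
        }
        for (int j : by_parent[v])
          if (e_left[j] <= x && x < e_right[j]) stack.push_back(e_child[j]);
      }
      if (leaves.empty() || static_cast<int>(leaves.size()) >= n_samples)
        continue;  // not segregating (should not happen pre-MRCA)
      pos.push_back(x);
      carriers.push_back(std::move(leaves));
    }
  }

  const int S = static_cast<int>(pos.size());
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos[a] < pos[b]; });

  NumericVector positions(S);
  IntegerMatrix mat(n_samples, S);
  for (int s = 0; s < S; ++s) {
    positions[s] = pos[ord[s]];
    for (int v : carriers[ord[s]]) mat(v, s) = 1;
  }
  return List::create(_["positions"] = positions, _["alleles"] = mat);
}
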