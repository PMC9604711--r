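#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Flood-fill connected-component labeling and the local-sensitive traversal.
// Coordinates are 0-based (row, col); adjacency is supplied from R as an
// ordered offset matrix (canonical clockwise order starting at North), so
// the metric lives in one place on the R side.

namespace {

struct Labeling {
  IntegerMatrix labels;       // 0 = background, 1..L component ids
  std::vector<int> sizes;     // sizes[l] = pixel count of component l (1-based)
  // per-component pixel lists in BFS discovery order, plus the offset index
  // that reached each pixel (-1 for the seed): the walker's momentum
  std::vector< std::vector<int> > pix_r, pix_c, mom;
};

// Deterministic BFS flood fill: seeds in storage (column-major) order,
// neighbors expanded in the canonical offset order.
Labeling label_components(const LogicalMatrix& mask, const IntegerMatrix& off) {
  const int nr = mask.nrow(), nc = mask.ncol(), k = off.nrow();
  Labeling L;
  L.labels = IntegerMatrix(nr, nc);
  L.sizes.push_back(0); // dummy for 1-based ids
  L.pix_r.emplace_back(); L.pix_c.emplace_back(); L.mom.emplace_back();
  int lab = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || L.labels(r, c) != 0) continue;
      ++lab;
      std::vector<int> qr, qc, qm;
      qr.push_back(r); qc.push_back(c); qm.push_back(-1);
      L.labels(r, c) = lab;
      for (size_t head = 0; head < qr.size(); ++head) {
        const int ur = qr[head], uc = qc[head];
        for (int j = 0; j < k; ++j) {
          const int vr = ur + off(j, 0), vc = uc + off(j, 1);
          if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
          if (!mask(vr, vc) || L.labels(vr, vc) != 0) continue;
          L.labels(vr, vc) = lab;
          qr.push_back(vr); qc.push_back(vc); qm.push_back(j);
        }
      }
      L.sizes.push_back((int)qr.size());
      L.pix_r.push_back(qr); L.pix_c.push_back(qc); L.mom.push_back(qm);
    }
  }
  return L;
}

struct DSU {
  std::vector<int> par;
  explicit DSU(int n) : par(n + 1) { for (int i = 0; i <= n; ++i) par[i] = i; }
  int find(int x) { while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; } return x; }
  void unite(int a, int b) { par[find(a)] = find(b); }
};

} // namespace

// [[Rcpp::export]]
List cpp_label_components(LogicalMatrix mask, IntegerMatrix offsets) {
  Labeling L = label_components(mask, offsets);
  return List::create(_["labels"] = L.labels,
                      _["sizes"] = IntegerVector(L.sizes.begin() + 1, L.sizes.end()));
}

// Local-sensitive connectivity traversal.
//
// On-vessel movement is the flood fill above. Each (merged) component then
// grows an off-vessel excursion wave: every member pixel simultaneously
// seeds a breadth-first walk over background, neighbors enqueued
// momentum-first (continuing the direction of the previous move before
// turning clockwise). A walker's tolerance is its excursion path depth —
// the number of consecutive background pixels visited since it left the
// vessel — and may not exceed maxScore; every step must stay within
// Chebyshev distance maxDist of the vessel pixel the walker departed from.
// The wave's first contact with a vessel pixel of a different (union-find)
// group is a globally shortest admissible bridge: its realized path is
// painted as vessel, the groups merge, and the merged group's wave is
// regrown until no contact remains. Exhausted walkers leave no trace.
//
// [[Rcpp::export]]
List cpp_ls_connectivity(LogicalMatrix mask, IntegerMatrix offsets,
                         int maxScore, double maxDist) {
  const int nr = mask.nrow(), nc = mask.ncol(), k = offsets.nrow();
  Labeling L = label_components(mask, offsets);
  const int nlab = (int)L.sizes.size() - 1;
  DSU dsu(nlab);

  LogicalMatrix bridged(nr, nc);
  std::vector<int> bridge_r, bridge_c, bridge_lab;
  IntegerMatrix stamp(nr, nc); // last wave id that visited a bg pixel
  int wave = 0;

  // wave node pools
  std::vector<int> qr, qc, qm, qpar, qdep, qar, qac;

  std::vector<char> processed(nlab + 1, 0);
  for (int root_lab = 1; root_lab <= nlab; ++root_lab) {
    if (processed[dsu.find(root_lab)]) continue;
    bool contact = true;
    while (contact) {
      contact = false;
      ++wave;
      qr.clear(); qc.clear(); qm.clear(); qpar.clear(); qdep.clear();
      qar.clear(); qac.clear();
      const int g = dsu.find(root_lab);
      // seed: all member pixels, labels ascending, discovery order within
      for (int l = 1; l <= nlab; ++l) {
        if (dsu.find(l) != g) continue;
        const std::vector<int>& pr = L.pix_r[l];
        const std::vector<int>& pc = L.pix_c[l];
        const std::vector<int>& pm = L.mom[l];
        for (size_t i = 0; i < pr.size(); ++i) {
          if (maxScore < 1 || maxDist < 1) break;
          const int ar = pr[i], ac = pc[i], am = pm[i];
          for (int jj = 0; jj < k; ++jj) {
            const int j = (am < 0) ? jj : (am + jj) % k;
            const int vr = ar + offsets(j, 0), vc = ac + offsets(j, 1);
            if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
            if (mask(vr, vc)) continue; // vessel neighbors are same group
            if (std::max(std::abs(vr - ar), std::abs(vc - ac)) > maxDist) continue;
            if (stamp(vr, vc) == wave) continue;
            stamp(vr, vc) = wave;
            qr.push_back(vr); qc.push_back(vc); qm.push_back(j);
            qpar.push_back(-1); qdep.push_back(1);
            qar.push_back(ar); qac.push_back(ac);
          }
        }
      }
      // breadth-first expansion; FIFO keeps depth (tolerance) order
      for (size_t head = 0; head < qr.size() && !contact; ++head) {
        const int ur = qr[head], uc = qc[head], um = qm[head];
        const int dep = qdep[head], ar = qar[head], ac = qac[head];
        for (int jj = 0; jj < k; ++jj) {
          const int j = (um + jj) % k;
          const int vr = ur + offsets(j, 0), vc = uc + offsets(j, 1);
          if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
          if (mask(vr, vc)) {
            const int vlab = L.labels(vr, vc);
            if (dsu.find(vlab) != g) {
              // bridge found: paint the realized path, merge the groups
              int node = (int)head;
              while (node >= 0) {
                const int br = qr[node], bc = qc[node];
                if (!bridged(br, bc)) {
                  bridged(br, bc) = true;
                  bridge_r.push_back(br); bridge_c.push_back(bc);
                  bridge_lab.push_back(root_lab);
                }
                node = qpar[node];
              }
              processed[dsu.find(vlab)] = 0;
              dsu.unite(vlab, root_lab);
              contact = true;
              break;
            }
          } else {
            if (dep + 1 > maxScore) continue;
            if (std::max(std::abs(vr - ar), std::abs(vc - ac)) > maxDist) continue;
            if (stamp(vr, vc) == wave) continue;
            stamp(vr, vc) = wave;
            qr.push_back(vr); qc.push_back(vc); qm.push_back(j);
            qpar.push_back((int)head); qdep.push_back(dep + 1);
            qar.push_back(ar); qac.push_back(ac);
          }
        }
      }
    }
    processed[dsu.find(root_lab)] = 1;
  }

  // merged-group cardinalities, bridge pixels included
  std::vector<long long> total(nlab + 1, 0);
  for (int l = 1; l <= nlab; ++l) total[dsu.find(l)] += L.sizes[l];
  for (size_t b = 0; b < bridge_lab.size(); ++b) total[dsu.find(bridge_lab[b])] += 1;

  IntegerMatrix scores(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (L.labels(r, c) > 0)
        scores(r, c) = (int)total[dsu.find(L.labels(r, c))];
  for (size_t b = 0; b < bridge_lab.size(); ++b)
    scores(bridge_r[b], bridge_c[b]) = (int)total[dsu.find(bridge_lab[b])];

  return List::create(_["scores"] = scores, _["bridged"] = bridged,
                      _["labels"] = L.labels);
}
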