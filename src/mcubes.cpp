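#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra: each grid cell is split
// into six tetrahedra around the (0,0,0)-(1,1,1) diagonal so that face
// diagonals agree between neighbouring cells, giving a watertight surface.
// Interpolated vertices are shared through an edge-keyed hash map.

namespace {

struct VKey {
  std::uint64_t k;
  bool operator==(const VKey& o) const { return k == o.k; }
};
struct VKeyHash {
  std::size_t operator()(const VKey& v) const {
    return std::hash<std::uint64_t>()(v.k);
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_march_tetra")]]
List march_tetra(NumericVector vol, IntegerVector dims, double level,
                 NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::uint64_t ntot = (std::uint64_t)nx * ny * nz;
  auto lin = [&](int x, int y, int z) -> std::uint64_t {
    return (std::uint64_t)x + (std::uint64_t)nx * (y + (std::uint64_t)ny * z);
  };

  // cube corner offsets, numbering consistent across cells
  const int cx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // six tetrahedra sharing edge 0-6
  const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                          {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  std::unordered_map<VKey, int, VKeyHash> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto edge_vertex = [&](std::uint64_t ia, std::uint64_t ib, double va,
                         double vb, const int pa[3], const int pb[3]) -> int {
    if (ia > ib) { std::swap(ia, ib); std::swap(va, vb);
      const int* t = pa; pa = pb; pb = t; }
    VKey key{ia * ntot + ib};
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (level - va) / (vb - va);
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    vmap.emplace(key, id);
    return id;
  };

  std::uint64_t gi[8];
  double gv[8];
  int gp[8][3];

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_lo = false, any_hi = false;
        for (int c = 0; c < 8; ++c) {
          int px = x + cx[c], py = y + cy[c], pz = z + cz[c];
          gi[c] = lin(px, py, pz);
          double v = vol[gi[c]];
          if (v == level) v = level + 1e-9 * (std::abs(level) + 1.0);
          gv[c] = v;
          gp[c][0] = px; gp[c][1] = py; gp[c][2] = pz;
          (v > level ? any_hi : any_lo) = true;
        }
        if (!any_lo || !any_hi) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int above[4], below[4], na = 0, nb = 0;
          for (int c = 0; c < 4; ++c)
            (gv[id[c]] > level ? above[na++] : below[nb++]) = id[c];
          if (na == 0 || nb == 0) continue;
          if (na == 1 || nb == 1) {
            int apex = (na == 1) ? above[0] : below[0];
            int* base = (na == 1) ? below : above;
            int e[3];
            for (int c = 0; c < 3; ++c)
              e[c] = edge_vertex(gi[apex], gi[base[c]], gv[apex],
                                 gv[base[c]], gp[apex], gp[base[c]]);
            if (e[0] != e[1] && e[1] != e[2] && e[0] != e[2]) {
              tri.push_back(e[0]); tri.push_back(e[1]); tri.push_back(e[2]);
            }
          } else {
            // two above, two below -> quad split into two triangles
            int a0 = above[0], a1 = above[1], b0 = below[0], b1 = below[1];
            int e00 = edge_vertex(gi[a0], gi[b0], gv[a0], gv[b0], gp[a0], gp[b0]);
            int e01 = edge_vertex(gi[a0], gi[b1], gv[a0], gv[b1], gp[a0], gp[b1]);
            int e10 = edge_vertex(gi[a1], gi[b0], gv[a1], gv[b0], gp[a1], gp[b0]);
            int e11 = edge_vertex(gi[a1], gi[b1], gv[a1], gv[b1], gp[a1], gp[b1]);
            if (e00 != e01 && e01 != e10 && e00 != e10) {
              tri.push_back(e00); tri.push_back(e01); tri.push_back(e10);
            }
            if (e10 != e01 && e01 != e11 && e10 != e11) {
              tri.push_back(e10); tri.push_back(e01); tri.push_back(e11);
            }
          }
        }
      }

  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = origin[0] + vx[i] * spacing[0];
    V(i, 1) = origin[1] + vy[i] * spacing[1];
    V(i, 2) = origin[2] + vz[i] * spacing[2];
  }
  int nt = (int)tri.size() / 3;
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i) {
    F(i, 0) = tri[3 * i] + 1;
    F(i, 1) = tri[3 * i + 1] + 1;
    F(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}
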