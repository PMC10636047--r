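// Voxel-level primitives for anisotropic label volumes.
//
// Conventions shared with the R side:
//  * a volume is an integer vector with dim = c(nr, nc, ns); linear index
//    r + nr * (c + nc * s), all 0-based here (R wrappers convert);
//  * pitch is c(dy, dx, dz) in nm: row, column and slice spacing;
//  * physical coords are x = col*dx, y = row*dy, z = slice*dz.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <array>
#include <algorithm>
#include <climits>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline long long lin(int r, int c, int s, int nr, int nc) {
  return (long long)r + (long long)nr * ((long long)c + (long long)nc * s);
}

// direct membership lookup (label ids are small integers)
struct IdSet {
  std::vector<char> in;
  explicit IdSet(const IntegerVector &ids) {
    int mx = 0;
    for (int v : ids) if (v > mx) mx = v;
    in.assign(mx + 1, 0);
    for (int v : ids) if (v >= 0) in[v] = 1;
  }
  inline bool has(int v) const {
    return v > 0 && v < (int)in.size() && in[v];
  }
};

// ---------------------------------------------------------------- summaries

// Per-label voxel counts, bounding boxes and centroid sums (0-based).
// [[Rcpp::export]]
DataFrame cpp_label_summary(IntegerVector vol, int nr, int nc, int ns) {
  struct Acc {
    long long n = 0;
    int rmin = INT_MAX, rmax = -1, cmin = INT_MAX, cmax = -1,
        smin = INT_MAX, smax = -1;
    double rs = 0, cs = 0, ss = 0;
  };
  std::unordered_map<int, Acc> acc;
  long long i = 0;
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r, ++i) {
        int v = vol[i];
        if (v == 0) continue;
        Acc &a = acc[v];
        a.n++;
        if (r < a.rmin) a.rmin = r;
        if (r > a.rmax) a.rmax = r;
        if (c < a.cmin) a.cmin = c;
        if (c > a.cmax) a.cmax = c;
        if (s < a.smin) a.smin = s;
        if (s > a.smax) a.smax = s;
        a.rs += r; a.cs += c; a.ss += s;
      }
  int k = acc.size();
  IntegerVector lab(k), n(k), rmin(k), rmax(k), cmin(k), cmax(k), smin(k),
      smax(k);
  NumericVector rmean(k), cmean(k), smean(k);
  int j = 0;
  for (auto &kv : acc) {
    lab[j] = kv.first;
    n[j] = (int)kv.second.n;
    rmin[j] = kv.second.rmin; rmax[j] = kv.second.rmax;
    cmin[j] = kv.second.cmin; cmax[j] = kv.second.cmax;
    smin[j] = kv.second.smin; smax[j] = kv.second.smax;
    rmean[j] = kv.second.rs / kv.second.n;
    cmean[j] = kv.second.cs / kv.second.n;
    smean[j] = kv.second.ss / kv.second.n;
    ++j;
  }
  return DataFrame::create(
      _["label"] = lab, _["n_voxels"] = n, _["rmin"] = rmin, _["rmax"] = rmax,
      _["cmin"] = cmin, _["cmax"] = cmax, _["smin"] = smin, _["smax"] = smax,
      _["rmean"] = rmean, _["cmean"] = cmean, _["smean"] = smean);
}

// --------------------------------------------------- per-slice profile stats

static int uf_find(std::vector<int> &par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}
static void uf_union(std::vector<int> &par, int a, int b) {
  a = uf_find(par, a); b = uf_find(par, b);
  if (a != b) par[b] = a;
}

// Crofton 4-direction perimeter coefficients indexed by the 2x2 pixel
// configuration p(i,j) + 4 p(i,j-1) + 2 p(i-1,j) + 8 p(i-1,j-1)
// (cross-checked numerically against scikit-image's estimator).
static const double SQ2 = 1.4142135623730951;
static const double CROFTON[16] = {
    0.0,
    M_PI / 4.0 * (1.0 + 1.0 / SQ2),
    M_PI / (4.0 * SQ2),
    M_PI / (2.0 * SQ2),
    0.0,
    M_PI / 4.0 * (1.0 + 1.0 / SQ2),
    0.0,
    M_PI / (4.0 * SQ2),
    M_PI / 4.0,
    M_PI / 2.0,
    M_PI / (4.0 * SQ2),
    M_PI / (4.0 * SQ2),
    M_PI / 4.0,
    M_PI / 2.0,
    0.0,
    0.0};

// Per-slice 8-connected component statistics for a set of label ids within a
// bounding box.  union_mode treats the ids as one mask; otherwise components
// never cross different ids.  fill_holes (union_mode only) fills 2D enclosed
// background before labeling, so the perimeter is that of the outer contour.
// [[Rcpp::export]]
DataFrame cpp_mask_slice_stats(IntegerVector vol, int nr, int nc, int ns,
                               IntegerVector ids, bool union_mode,
                               bool fill_holes, IntegerVector bbox) {
  IdSet idset(ids);
  int r0 = bbox[0], r1 = bbox[1], c0 = bbox[2], c1 = bbox[3], s0 = bbox[4],
      s1 = bbox[5];
  int W = r1 - r0 + 1, H = c1 - c0 + 1;

  std::vector<int> slice_v, label_v, area_v, er_v, ec_v;
  std::vector<double> crof_v, rsum_v, csum_v;

  std::vector<int> memb(W * H), comp(W * H), par;
  std::vector<char> seen(W * H);

  for (int s = s0; s <= s1; ++s) {
    bool any = false;
    for (int c = 0; c < H; ++c)
      for (int r = 0; r < W; ++r) {
        int v = vol[lin(r + r0, c + c0, s, nr, nc)];
        int m = idset.has(v) ? (union_mode ? 1 : v) : 0;
        memb[r + W * c] = m;
        if (m) any = true;
      }
    if (!any) continue;

    if (fill_holes && union_mode) {
      // flood 4-connected background from the border of the window
      std::fill(seen.begin(), seen.end(), 0);
      std::vector<int> stack;
      for (int c = 0; c < H; ++c)
        for (int r = 0; r < W; ++r)
          if ((r == 0 || r == W - 1 || c == 0 || c == H - 1) &&
              memb[r + W * c] == 0 && !seen[r + W * c]) {
            seen[r + W * c] = 1;
            stack.push_back(r + W * c);
          }
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % W, c = p / W;
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= W || cc < 0 || cc >= H) continue;
          int q = rr + W * cc;
          if (memb[q] == 0 && !seen[q]) { seen[q] = 1; stack.push_back(q); }
        }
      }
      for (int p = 0; p < W * H; ++p)
        if (memb[p] == 0 && !seen[p]) memb[p] = 1;
    }

    // two-pass union-find labeling, 8-connectivity, equal membership value
    par.assign(W * H, 0);
    for (int p = 0; p < W * H; ++p) par[p] = p;
    for (int c = 0; c < H; ++c)
      for (int r = 0; r < W; ++r) {
        int m = memb[r + W * c];
        if (!m) continue;
        // neighbors already visited in scan order (col-major: previous col
        // fully done, current col rows < r)
        if (r > 0 && memb[(r - 1) + W * c] == m)
          uf_union(par, r + W * c, (r - 1) + W * c);
        if (c > 0) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr;
            if (rr < 0 || rr >= W) continue;
            if (memb[rr + W * (c - 1)] == m)
              uf_union(par, r + W * c, rr + W * (c - 1));
          }
        }
      }
    std::unordered_map<int, int> root2comp;
    int ncomp = 0;
    for (int p = 0; p < W * H; ++p) {
      if (!memb[p]) { comp[p] = 0; continue; }
      int rt = uf_find(par, p);
      auto it = root2comp.find(rt);
      if (it == root2comp.end()) {
        root2comp[rt] = ++ncomp;
        comp[p] = ncomp;
      } else comp[p] = it->second;
    }

    std::vector<int> a(ncomp + 1, 0), er(ncomp + 1, 0), ec(ncomp + 1, 0),
        lb(ncomp + 1, 0);
    std::vector<double> rs(ncomp + 1, 0), cs(ncomp + 1, 0),
        crof(ncomp + 1, 0);
    for (int c = 0; c < H; ++c)
      for (int r = 0; r < W; ++r) {
        int k = comp[r + W * c];
        if (!k) continue;
        int m = memb[r + W * c];
        lb[k] = m;
        a[k]++; rs[k] += r + r0; cs[k] += c + c0;
        if (r == 0 || memb[(r - 1) + W * c] != m) er[k]++;
        if (r == W - 1 || memb[(r + 1) + W * c] != m) er[k]++;
        if (c == 0 || memb[r + W * (c - 1)] != m) ec[k]++;
        if (c == H - 1 || memb[r + W * (c + 1)] != m) ec[k]++;
      }
    // Crofton configurations over (W+1) x (H+1) windows
    for (int c = 0; c <= H; ++c)
      for (int r = 0; r <= W; ++r) {
        int k00 = (r < W && c < H) ? comp[r + W * c] : 0;        // bit 1
        int k01 = (r < W && c > 0) ? comp[r + W * (c - 1)] : 0;  // bit 4
        int k10 = (r > 0 && c < H) ? comp[(r - 1) + W * c] : 0;  // bit 2
        int k11 = (r > 0 && c > 0) ? comp[(r - 1) + W * (c - 1)] : 0; // bit 8
        int ks[4] = {k00, k01, k10, k11};
        for (int t = 0; t < 4; ++t) {
          int k = ks[t];
          if (!k) continue;
          bool dup = false;
          for (int u = 0; u < t; ++u) if (ks[u] == k) dup = true;
          if (dup) continue;
          int cfg = (k00 == k ? 1 : 0) + (k01 == k ? 4 : 0) +
                    (k10 == k ? 2 : 0) + (k11 == k ? 8 : 0);
          crof[k] += CROFTON[cfg];
        }
      }
    for (int k = 1; k <= ncomp; ++k) {
      slice_v.push_back(s);
      label_v.push_back(lb[k]);
      area_v.push_back(a[k]);
      er_v.push_back(er[k]);
      ec_v.push_back(ec[k]);
      crof_v.push_back(crof[k]);
      rsum_v.push_back(rs[k] / a[k]);
      csum_v.push_back(cs[k] / a[k]);
    }
  }
  return DataFrame::create(
      _["slice"] = slice_v, _["label"] = label_v, _["area_px"] = area_v,
      _["edges_r"] = er_v, _["edges_c"] = ec_v, _["crofton_px"] = crof_v,
      _["centroid_row"] = rsum_v, _["centroid_col"] = csum_v);
}

// ------------------------------------------------- 3D connected components

// 3D connected components of the union mask of `ids` within a bounding box.
// connectivity is 6 or 26.  Returns component ids over the bbox lattice.
// [[Rcpp::export]]
List cpp_cc3d(IntegerVector vol, int nr, int nc, int ns, IntegerVector ids,
              IntegerVector bbox, int connectivity) {
  IdSet idset(ids);
  int r0 = bbox[0], r1 = bbox[1], c0 = bbox[2], c1 = bbox[3], s0 = bbox[4],
      s1 = bbox[5];
  int W = r1 - r0 + 1, H = c1 - c0 + 1, D = s1 - s0 + 1;
  long long n = (long long)W * H * D;
  IntegerVector comp(n);
  std::vector<char> in(n, 0);
  long long p = 0;
  for (int s = 0; s < D; ++s)
    for (int c = 0; c < H; ++c)
      for (int r = 0; r < W; ++r, ++p) {
        int v = vol[lin(r + r0, c + c0, s + s0, nr, nc)];
        in[p] = idset.has(v) ? 1 : 0;
      }
  int ncomp = 0;
  std::vector<long long> stack;
  for (long long q = 0; q < n; ++q) {
    if (!in[q] || comp[q]) continue;
    ++ncomp;
    comp[q] = ncomp;
    stack.push_back(q);
    while (!stack.empty()) {
      long long cur = stack.back(); stack.pop_back();
      int r = cur % W, c = (cur / W) % H, s = cur / ((long long)W * H);
      for (int ds = -1; ds <= 1; ++ds)
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc && !ds) continue;
            if (connectivity == 6 && std::abs(dr) + std::abs(dc) + std::abs(ds) != 1)
              continue;
            int rr = r + dr, cc = c + dc, ss2 = s + ds;
            if (rr < 0 || rr >= W || cc < 0 || cc >= H || ss2 < 0 || ss2 >= D)
              continue;
            long long nb = rr + (long long)W * (cc + (long long)H * ss2);
            if (in[nb] && !comp[nb]) { comp[nb] = ncomp; stack.push_back(nb); }
          }
    }
  }
  comp.attr("dim") = IntegerVector::create(W, H, D);
  return List::create(_["comp"] = comp, _["n"] = ncomp);
}

// Fill 3D enclosed background (6-connected flood from the box border).
// mask01 is a 0/1 integer array; returns the filled mask.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes3d(IntegerVector mask01, int W, int H, int D) {
  long long n = (long long)W * H * D;
  IntegerVector out(clone(mask01));
  std::vector<char> seen(n, 0);
  std::vector<long long> stack;
  for (int s = 0; s < D; ++s)
    for (int c = 0; c < H; ++c)
      for (int r = 0; r < W; ++r) {
        if (r != 0 && r != W - 1 && c != 0 && c != H - 1 && s != 0 &&
            s != D - 1)
          continue;
        long long p = r + (long long)W * (c + (long long)H * s);
        if (!mask01[p] && !seen[p]) { seen[p] = 1; stack.push_back(p); }
      }
  while (!stack.empty()) {
    long long cur = stack.back(); stack.pop_back();
    int r = cur % W, c = (cur / W) % H, s = cur / ((long long)W * H);
    const int dr[6] = {-1, 1, 0, 0, 0, 0}, dc[6] = {0, 0, -1, 1, 0, 0},
              ds[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      int rr = r + dr[d], cc = c + dc[d], ss2 = s + ds[d];
      if (rr < 0 || rr >= W || cc < 0 || cc >= H || ss2 < 0 || ss2 >= D)
        continue;
      long long nb = rr + (long long)W * (cc + (long long)H * ss2);
      if (!mask01[nb] && !seen[nb]) { seen[nb] = 1; stack.push_back(nb); }
    }
  }
  for (long long p = 0; p < n; ++p)
    if (!mask01[p] && !seen[p]) out[p] = 1;
  out.attr("dim") = IntegerVector::create(W, H, D);
  return out;
}

// ------------------------------------------------------------ adjacency

// Face adjacency between labels of class code A and class code B.
// `code` maps label id -> class code (index = label id, 0 = none).
// Returns one row per (a_label, b_label, slice) with the face count; the
// slice recorded is that of the class-A voxel.
// [[Rcpp::export]]
DataFrame cpp_pair_adjacency(IntegerVector vol, int nr, int nc, int ns,
                             IntegerVector code, int codeA, int codeB) {
  std::unordered_map<uint64_t, int> acc;
  int maxlab = code.size() - 1;
  long long i = 0;
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r, ++i) {
        int v1 = vol[i];
        if (v1 == 0 || v1 > maxlab) continue;
        int k1 = code[v1];
        if (k1 != codeA && k1 != codeB) continue;
        const int dr[3] = {1, 0, 0}, dc[3] = {0, 1, 0}, ds[3] = {0, 0, 1};
        for (int d = 0; d < 3; ++d) {
          int rr = r + dr[d], cc = c + dc[d], ss2 = s + ds[d];
          if (rr >= nr || cc >= nc || ss2 >= ns) continue;
          int v2 = vol[lin(rr, cc, ss2, nr, nc)];
          if (v2 == 0 || v2 > maxlab || v2 == v1) continue;
          int k2 = code[v2];
          int a = 0, b = 0, sa = 0;
          if (k1 == codeA && k2 == codeB) { a = v1; b = v2; sa = s; }
          else if (k1 == codeB && k2 == codeA) { a = v2; b = v1; sa = ss2; }
          else continue;
          uint64_t key = ((uint64_t)a << 40) | ((uint64_t)b << 20) |
                         (uint64_t)sa;
          acc[key]++;
        }
      }
  int k = acc.size();
  IntegerVector al(k), bl(k), sl(k), nf(k);
  int j = 0;
  for (auto &kv : acc) {
    al[j] = (int)(kv.first >> 40);
    bl[j] = (int)((kv.first >> 20) & 0xFFFFF);
    sl[j] = (int)(kv.first & 0xFFFFF);
    nf[j] = kv.second;
    ++j;
  }
  return DataFrame::create(_["a_label"] = al, _["b_label"] = bl,
                           _["slice"] = sl, _["n_faces"] = nf);
}

// ------------------------------------------------------------- distances

// Minimum anisotropic distance between two voxel coordinate sets (0-based
// rows r,c,s).  Slice-bucketed with early termination.
// [[Rcpp::export]]
List cpp_min_dist(IntegerMatrix A, IntegerMatrix B, NumericVector pitch) {
  double py = pitch[0], px = pitch[1], pz = pitch[2];
  int smin = INT_MAX, smax = -1;
  for (int j = 0; j < B.nrow(); ++j) {
    smin = std::min(smin, B(j, 2));
    smax = std::max(smax, B(j, 2));
  }
  int nslice = smax - smin + 1;
  // slice buckets sorted by column for in-bucket window pruning
  std::vector<std::vector<std::array<int, 3>>> bucket(nslice);  // c, r, j
  for (int j = 0; j < B.nrow(); ++j) {
    bucket[B(j, 2) - smin].push_back({B(j, 1), B(j, 0), j});
  }
  for (auto &b : bucket) std::sort(b.begin(), b.end());
  double best = R_PosInf;
  int bi = -1, bj = -1;
  int maxoff = nslice + std::max(std::abs(smax), std::abs(smin)) + 2;
  for (int i = 0; i < A.nrow(); ++i) {
    int ar = A(i, 0), ac = A(i, 1), as = A(i, 2);
    for (int off = 0; off < maxoff; ++off) {
      double dzb = (double)off * pz;
      if (dzb * dzb >= best) break;
      for (int sgn = 0; sgn < 2; ++sgn) {
        if (sgn == 1 && off == 0) continue;
        int s = sgn == 0 ? as + off : as - off;
        if (s < smin || s > smax) continue;
        double dz = (double)(s - as) * pz;
        auto &b = bucket[s - smin];
        if (b.empty()) continue;
        double wd = R_FINITE(best)
          ? std::sqrt(std::max(best - dz * dz, 0.0)) / px
          : 2e9;
        wd = std::min(wd, 2e9);
        int clo = (int)std::max(std::floor(ac - wd), -2e9);
        int chi = (int)std::min(std::ceil(ac + wd), 2e9);
        auto lo = std::lower_bound(b.begin(), b.end(),
                                   std::array<int, 3>{clo, INT_MIN,
                                                      INT_MIN});
        for (auto it = lo; it != b.end() && (*it)[0] <= chi; ++it) {
          double dx = (double)((*it)[0] - ac) * px;
          double dy = (double)((*it)[1] - ar) * py;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) { best = d2; bi = i; bj = (*it)[2]; }
        }
      }
    }
  }
  return List::create(_["dist"] = std::sqrt(best), _["i"] = bi + 1,
                      _["j"] = bj + 1);
}

// Voxels of `id` with at least one 6-neighbor of a different value (or
// outside the lattice), within a bounding box.  Returns 0-based coords.
// [[Rcpp::export]]
IntegerMatrix cpp_surface_coords(IntegerVector vol, int nr, int nc, int ns,
                                 int id, IntegerVector bbox) {
  int r0 = bbox[0], r1 = bbox[1], c0 = bbox[2], c1 = bbox[3], s0 = bbox[4],
      s1 = bbox[5];
  std::vector<int> rs, cs, ss;
  for (int s = s0; s <= s1; ++s)
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        if (vol[lin(r, c, s, nr, nc)] != id) continue;
        bool surf = false;
        const int dr[6] = {-1, 1, 0, 0, 0, 0}, dc[6] = {0, 0, -1, 1, 0, 0},
                  ds[6] = {0, 0, 0, 0, -1, 1};
        for (int d = 0; d < 6 && !surf; ++d) {
          int rr = r + dr[d], cc = c + dc[d], ss2 = s + ds[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || ss2 < 0 ||
              ss2 >= ns)
            surf = true;
          else if (vol[lin(rr, cc, ss2, nr, nc)] != id)
            surf = true;
        }
        if (surf) { rs.push_back(r); cs.push_back(c); ss.push_back(s); }
      }
  IntegerMatrix out(rs.size(), 3);
  for (size_t i = 0; i < rs.size(); ++i) {
    out(i, 0) = rs[i]; out(i, 1) = cs[i]; out(i, 2) = ss[i];
  }
  return out;
}

// Coordinates (0-based) and labels of all voxels whose label is in `ids`.
// [[Rcpp::export]]
IntegerMatrix cpp_coords_of(IntegerVector vol, int nr, int nc, int ns,
                            IntegerVector ids, IntegerVector bbox) {
  IdSet idset(ids);
  int r0 = bbox[0], r1 = bbox[1], c0 = bbox[2], c1 = bbox[3], s0 = bbox[4],
      s1 = bbox[5];
  std::vector<int> rs, cs, ss, ls;
  for (int s = s0; s <= s1; ++s)
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        int v = vol[lin(r, c, s, nr, nc)];
        if (idset.has(v)) {
          rs.push_back(r); cs.push_back(c); ss.push_back(s); ls.push_back(v);
        }
      }
  IntegerMatrix out(rs.size(), 4);
  for (size_t i = 0; i < rs.size(); ++i) {
    out(i, 0) = rs[i]; out(i, 1) = cs[i]; out(i, 2) = ss[i];
    out(i, 3) = ls[i];
  }
  return out;
}

// ------------------------------------------------------------ rasterizers
// These mutate `vol` in place (the generator owns the array).

// Rasterize one circular in-plane disc per listed slice (tube cross
// sections).  Radii are in in-plane voxel units (dx == dy assumed by the
// caller).  Writes `label` only into empty (0) voxels.  Returns the number
// of voxels written per slice; the `overflow` attribute flags discs whose
// bounding box was clipped by the lattice.
// [[Rcpp::export]]
IntegerVector cpp_fill_discs(IntegerVector vol, int nr, int nc, int ns,
                             IntegerVector slice, NumericVector crow,
                             NumericVector ccol, NumericVector rad,
                             int label) {
  int k = slice.size();
  IntegerVector cnt(k);
  LogicalVector ovf(k);
  for (int i = 0; i < k; ++i) {
    int s = slice[i];
    if (s < 0 || s >= ns) { ovf[i] = true; continue; }
    double cr = crow[i], cc = ccol[i], rd = rad[i];
    int rlo = (int)std::floor(cr - rd), rhi = (int)std::ceil(cr + rd);
    int clo = (int)std::floor(cc - rd), chi = (int)std::ceil(cc + rd);
    if (rlo < 0 || clo < 0 || rhi >= nr || chi >= nc) ovf[i] = true;
    rlo = std::max(rlo, 0); clo = std::max(clo, 0);
    rhi = std::min(rhi, nr - 1); chi = std::min(chi, nc - 1);
    double r2 = rd * rd;
    int n = 0;
    for (int c = clo; c <= chi; ++c)
      for (int r = rlo; r <= rhi; ++r) {
        double dr = r - cr, dc = c - cc;
        if (dr * dr + dc * dc > r2) continue;
        long long p = lin(r, c, s, nr, nc);
        if (vol[p] == 0) { vol[p] = label; ++n; }
      }
    cnt[i] = n;
  }
  cnt.attr("overflow") = ovf;
  return cnt;
}

// Axis-aligned ellipsoid written into voxels currently equal to
// `into_label`.  Center and radii in (row, col, slice) voxel units.
// Returns per-slice voxel counts with attribute smin (0-based first slice).
// [[Rcpp::export]]
IntegerVector cpp_fill_ellipsoid(IntegerVector vol, int nr, int nc, int ns,
                                 NumericVector center, NumericVector rad,
                                 int label, int into_label) {
  double cr = center[0], cc = center[1], cs = center[2];
  double ar = rad[0], ac = rad[1], as = rad[2];
  int rlo = std::max(0, (int)std::floor(cr - ar)),
      rhi = std::min(nr - 1, (int)std::ceil(cr + ar));
  int clo = std::max(0, (int)std::floor(cc - ac)),
      chi = std::min(nc - 1, (int)std::ceil(cc + ac));
  int slo = std::max(0, (int)std::floor(cs - as)),
      shi = std::min(ns - 1, (int)std::ceil(cs + as));
  int nsl = std::max(0, shi - slo + 1);
  IntegerVector cnt(nsl);
  for (int s = slo; s <= shi; ++s) {
    int n = 0;
    for (int c = clo; c <= chi; ++c)
      for (int r = rlo; r <= rhi; ++r) {
        double fr = (r - cr) / ar, fc = (c - cc) / ac, fs = (s - cs) / as;
        if (fr * fr + fc * fc + fs * fs > 1.0) continue;
        long long p = lin(r, c, s, nr, nc);
        if (vol[p] == into_label) { vol[p] = label; ++n; }
      }
    cnt[s - slo] = n;
  }
  cnt.attr("smin") = slo;
  return cnt;
}

// Flattened cylinder (presynaptic ribbon): |q.u| <= hu and elliptical in
// (v, w).  center in voxel units, u/v/w orthonormal in physical (x,y,z)
// space, h in nm.  Written into voxels currently equal to `into_label`;
// carve_frac > 0 hollows out a scaled copy (set to 0).
// [[Rcpp::export]]
List cpp_fill_ribbon(IntegerVector vol, int nr, int nc, int ns,
                     NumericVector center, NumericVector pitch,
                     NumericVector u, NumericVector v, NumericVector w,
                     NumericVector h, int label, int into_label,
                     double carve_frac) {
  double py = pitch[0], px = pitch[1], pz = pitch[2];
  double cr = center[0], cc = center[1], cs = center[2];
  double reach = std::sqrt(h[0] * h[0] + h[1] * h[1] + h[2] * h[2]);
  int rlo = std::max(0, (int)std::floor(cr - reach / py)),
      rhi = std::min(nr - 1, (int)std::ceil(cr + reach / py));
  int clo = std::max(0, (int)std::floor(cc - reach / px)),
      chi = std::min(nc - 1, (int)std::ceil(cc + reach / px));
  int slo = std::max(0, (int)std::floor(cs - reach / pz)),
      shi = std::min(ns - 1, (int)std::ceil(cs + reach / pz));
  int placed = 0, carved = 0;
  int nsl = std::max(0, shi - slo + 1);
  IntegerVector per_slice(nsl);
  for (int pass = 0; pass < 2; ++pass) {
    if (pass == 1 && carve_frac <= 0) break;
    double f = pass == 0 ? 1.0 : carve_frac;
    double hu = h[0] * f, hv = h[1] * f, hw = h[2] * f;
    for (int s = slo; s <= shi; ++s)
      for (int c = clo; c <= chi; ++c)
        for (int r = rlo; r <= rhi; ++r) {
          double qx = (c - cc) * px, qy = (r - cr) * py, qz = (s - cs) * pz;
          double du = qx * u[0] + qy * u[1] + qz * u[2];
          double dv = qx * v[0] + qy * v[1] + qz * v[2];
          double dw = qx * w[0] + qy * w[1] + qz * w[2];
          if (std::fabs(du) > hu) continue;
          if ((dv / hv) * (dv / hv) + (dw / hw) * (dw / hw) > 1.0) continue;
          long long p = lin(r, c, s, nr, nc);
          if (pass == 0) {
            if (vol[p] == into_label) {
              vol[p] = label; ++placed; per_slice[s - slo]++;
            }
          } else {
            if (vol[p] == label) {
              vol[p] = 0; ++carved; per_slice[s - slo]--;
            }
          }
        }
  }
  per_slice.attr("smin") = slo;
  return List::create(_["placed"] = placed, _["carved"] = carved,
                      _["per_slice"] = per_slice);
}

// Ball of physical radius (nm) written into empty voxels; used for the IHC
// basal hemisphere (center above the stack top yields the lower cap).
// [[Rcpp::export]]
int cpp_fill_ball(IntegerVector vol, int nr, int nc, int ns,
                  NumericVector center, NumericVector pitch, double radius,
                  int label) {
  double py = pitch[0], px = pitch[1], pz = pitch[2];
  double cr = center[0], cc = center[1], cs = center[2];
  int rlo = std::max(0, (int)std::floor(cr - radius / py)),
      rhi = std::min(nr - 1, (int)std::ceil(cr + radius / py));
  int clo = std::max(0, (int)std::floor(cc - radius / px)),
      chi = std::min(nc - 1, (int)std::ceil(cc + radius / px));
  int slo = std::max(0, (int)std::floor(cs - radius / pz)),
      shi = std::min(ns - 1, (int)std::ceil(cs + radius / pz));
  double r2 = radius * radius;
  int n = 0;
  for (int s = slo; s <= shi; ++s)
    for (int c = clo; c <= chi; ++c)
      for (int r = rlo; r <= rhi; ++r) {
        double dx = (c - cc) * px, dy = (r - cr) * py, dz = (s - cs) * pz;
        if (dx * dx + dy * dy + dz * dz > r2) continue;
        long long p = lin(r, c, s, nr, nc);
        if (vol[p] == 0) { vol[p] = label; ++n; }
      }
  return n;
}
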