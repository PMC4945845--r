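// Low-level voxel operations on 3-D volumes stored as R arrays
// (linear index = x + nx*(y + ny*z), all 0-based on the C++ side).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  Grid(const IntegerVector& dim) : nx(dim[0]), ny(dim[1]), nz(dim[2]) {}
  inline long long n() const { return (long long)nx * ny * nz; }
  inline void coords(long long idx, int& x, int& y, int& z) const {
    x = (int)(idx % nx);
    y = (int)((idx / nx) % ny);
    z = (int)(idx / ((long long)nx * ny));
  }
  inline long long index(int x, int y, int z) const {
    return (long long)x + (long long)nx * ((long long)y + (long long)ny * z);
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// neighbour offsets for 6- or 26-connectivity
std::vector<std::array<int,3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  if (connectivity == 6) {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) off.push_back({{dx,dy,dz}});
  }
  return off;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  Grid g(dim);
  auto off = neighbour_offsets(connectivity);
  IntegerVector labels(mask.size(), 0);
  int next_label = 0;
  std::queue<long long> q;
  for (long long start = 0; start < g.n(); ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    q.push(start);
    while (!q.empty()) {
      long long cur = q.front(); q.pop();
      int x, y, z;
      g.coords(cur, x, y, z);
      for (const auto& o : off) {
        int nx2 = x + o[0], ny2 = y + o[1], nz2 = z + o[2];
        if (!g.inside(nx2, ny2, nz2)) continue;
        long long nb = g.index(nx2, ny2, nz2);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          q.push(nb);
        }
      }
    }
  }
  return labels;
}

//' @noRd
// [[Rcpp::export(name = "cpp_border_touching_labels")]]
IntegerVector cpp_border_touching_labels(IntegerVector labels, IntegerVector dim) {
  Grid g(dim);
  std::vector<bool> seen;
  std::vector<int> out;
  auto note = [&](long long idx) {
    int lab = labels[idx];
    if (lab <= 0) return;
    if ((int)seen.size() < lab + 1) seen.resize(lab + 1, false);
    if (!seen[lab]) { seen[lab] = true; out.push_back(lab); }
  };
  for (int y = 0; y < g.ny; ++y)
    for (int x = 0; x < g.nx; ++x) {
      note(g.index(x, y, 0));
      note(g.index(x, y, g.nz - 1));
    }
  for (int z = 0; z < g.nz; ++z)
    for (int x = 0; x < g.nx; ++x) {
      note(g.index(x, 0, z));
      note(g.index(x, g.ny - 1, z));
    }
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y) {
      note(g.index(0, y, z));
      note(g.index(g.nx - 1, y, z));
    }
  return wrap(out);
}

//' @noRd
// [[Rcpp::export(name = "cpp_dilate")]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  auto off = neighbour_offsets(connectivity);
  LogicalVector out = clone(mask);
  for (long long i = 0; i < g.n(); ++i) {
    if (!mask[i]) continue;
    int x, y, z;
    g.coords(i, x, y, z);
    for (const auto& o : off) {
      int nx2 = x + o[0], ny2 = y + o[1], nz2 = z + o[2];
      if (g.inside(nx2, ny2, nz2)) out[g.index(nx2, ny2, nz2)] = true;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_erode")]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  auto off = neighbour_offsets(connectivity);
  LogicalVector out = clone(mask);
  for (long long i = 0; i < g.n(); ++i) {
    if (!mask[i]) continue;
    int x, y, z;
    g.coords(i, x, y, z);
    bool keep = true;
    for (const auto& o : off) {
      int nx2 = x + o[0], ny2 = y + o[1], nz2 = z + o[2];
      if (!g.inside(nx2, ny2, nz2) || !mask[g.index(nx2, ny2, nz2)]) {
        keep = false; break;
      }
    }
    out[i] = keep;
  }
  return out;
}

// Threshold-relaxation region growing with rollback past a leak step.
// thresholds must be increasing (HU); growth is 6-connected.  Returns the
// final mask, per-step accepted-voxel counts, the index (1-based) of the
// last threshold actually kept, and whether a leak triggered rollback.
//' @noRd
// [[Rcpp::export(name = "cpp_region_grow")]]
List cpp_region_grow(NumericVector vol, IntegerVector dim, int seed0,
                     NumericVector thresholds, double leak_ratio) {
  Grid g(dim);
  auto off = neighbour_offsets(6);
  const int n_steps = thresholds.size();
  // state: 0 = untouched, 1 = accepted, 2 = pending boundary
  std::vector<char> state(g.n(), 0);
  std::vector<long long> pending;       // rejected frontier voxels
  std::vector<long long> added_now;     // voxels accepted this step
  std::queue<long long> q;
  long long count = 0;
  IntegerVector step_counts(n_steps, NA_INTEGER);
  int last_step = 0;
  bool leaked = false;

  if (vol[seed0] >= thresholds[0])
    stop("seed voxel attenuation (%g HU) is not below the initial threshold (%g HU)",
         vol[seed0], thresholds[0]);

  for (int s = 0; s < n_steps; ++s) {
    double thr = thresholds[s];
    added_now.clear();
    if (s == 0) {
      state[seed0] = 1;
      q.push(seed0);
      added_now.push_back(seed0);
    } else {
      std::vector<long long> still_pending;
      for (long long idx : pending) {
        if (vol[idx] < thr) {
          state[idx] = 1;
          q.push(idx);
          added_now.push_back(idx);
        } else {
          still_pending.push_back(idx);
        }
      }
      pending.swap(still_pending);
    }
    while (!q.empty()) {
      long long cur = q.front(); q.pop();
      int x, y, z;
      g.coords(cur, x, y, z);
      for (const auto& o : off) {
        int nx2 = x + o[0], ny2 = y + o[1], nz2 = z + o[2];
        if (!g.inside(nx2, ny2, nz2)) continue;
        long long nb = g.index(nx2, ny2, nz2);
        if (state[nb] == 1) continue;
        if (vol[nb] < thr) {
          state[nb] = 1;
          q.push(nb);
          added_now.push_back(nb);
        } else if (state[nb] == 0) {
          state[nb] = 2;
          pending.push_back(nb);
        }
      }
    }
    long long new_count = count + (long long)added_now.size();
    if (s > 0 && count > 0 && (double)new_count > leak_ratio * (double)count) {
      // leak: roll back this step entirely
      for (long long idx : added_now) state[idx] = 2;
      leaked = true;
      break;
    }
    count = new_count;
    step_counts[s] = (int)count;
    last_step = s + 1;
  }

  LogicalVector out(vol.size(), false);
  for (long long i = 0; i < g.n(); ++i) if (state[i] == 1) out[i] = true;
  return List::create(_["mask"] = out,
                      _["step_counts"] = step_counts,
                      _["last_step"] = last_step,
                      _["leaked"] = leaked,
                      _["n_voxels"] = (double)count);
}

// Wavefront decomposition of a connected lumen mask: 26-connected BFS
// geodesic distance from the root voxel, voxels binned into shells of
// `shell_width` BFS steps, shells split into 26-connected clusters, and
// each cluster linked to its most-contacted cluster in the previous shell.
//' @noRd
// [[Rcpp::export(name = "cpp_wavefront_clusters")]]
List cpp_wavefront_clusters(LogicalVector mask, IntegerVector dim, int root0,
                            int shell_width) {
  Grid g(dim);
  auto off = neighbour_offsets(26);
  if (!mask[root0]) stop("root voxel is not inside the mask");

  std::vector<int> dist(g.n(), -1);
  std::queue<long long> q;
  dist[root0] = 0;
  q.push(root0);
  long long n_mask = 0;
  int max_dist = 0;
  while (!q.empty()) {
    long long cur = q.front(); q.pop();
    ++n_mask;
    int x, y, z;
    g.coords(cur, x, y, z);
    for (const auto& o : off) {
      int nx2 = x + o[0], ny2 = y + o[1], nz2 = z + o[2];
      if (!g.inside(nx2, ny2, nz2)) continue;
      long long nb = g.index(nx2, ny2, nz2);
      if (mask[nb] && dist[nb] < 0) {
        dist[nb] = dist[cur] + 1;
        if (dist[nb] > max_dist) max_dist = dist[nb];
        q.push(nb);
      }
    }
  }

  // cluster labelling within shells: BFS restricted to one shell at a time
  std::vector<int> cluster(g.n(), 0);
  int next_cluster = 0;
  std::vector<int> cl_shell, cl_size;
  std::vector<double> cl_cx, cl_cy, cl_cz;
  for (long long i = 0; i < g.n(); ++i) {
    if (dist[i] < 0 || cluster[i] != 0) continue;
    int shell = dist[i] / shell_width;
    ++next_cluster;
    cluster[i] = next_cluster;
    double sx = 0, sy = 0, sz = 0;
    int sz_count = 0;
    std::queue<long long> cq;
    cq.push(i);
    while (!cq.empty()) {
      long long cur = cq.front(); cq.pop();
      int x, y, z;
      g.coords(cur, x, y, z);
      sx += x; sy += y; sz += z; ++sz_count;
      for (const auto& o : off) {
        int nx2 = x + o[0], ny2 = y + o[1], nz2 = z + o[2];
        if (!g.inside(nx2, ny2, nz2)) continue;
        long long nb = g.index(nx2, ny2, nz2);
        if (dist[nb] >= 0 && cluster[nb] == 0 && dist[nb] / shell_width == shell) {
          cluster[nb] = next_cluster;
          cq.push(nb);
        }
      }
    }
    cl_shell.push_back(shell);
    cl_size.push_back(sz_count);
    cl_cx.push_back(sx / sz_count);
    cl_cy.push_back(sy / sz_count);
    cl_cz.push_back(sz / sz_count);
  }

  // parent linking: for each cluster, count voxel contacts with clusters in
  // the previous shell and keep the most-contacted one
  std::vector<std::unordered_map<int,int>> contact(next_cluster + 1);
  for (long long i = 0; i < g.n(); ++i) {
    if (dist[i] < 0) continue;
    int shell = dist[i] / shell_width;
    int x, y, z;
    g.coords(i, x, y, z);
    for (const auto& o : off) {
      int nx2 = x + o[0], ny2 = y + o[1], nz2 = z + o[2];
      if (!g.inside(nx2, ny2, nz2)) continue;
      long long nb = g.index(nx2, ny2, nz2);
      if (dist[nb] >= 0 && dist[nb] / shell_width == shell - 1)
        ++contact[cluster[i]][cluster[nb]];
    }
  }
  IntegerVector parent(next_cluster, NA_INTEGER);
  for (int c = 1; c <= next_cluster; ++c) {
    int best = -1, best_n = 0;
    for (const auto& kv : contact[c])
      if (kv.second > best_n) { best_n = kv.second; best = kv.first; }
    if (best > 0) parent[c - 1] = best;
  }

  IntegerVector shell_out(next_cluster), size_out(next_cluster);
  NumericVector cx(next_cluster), cy(next_cluster), cz(next_cluster);
  for (int c = 0; c < next_cluster; ++c) {
    shell_out[c] = cl_shell[c];
    size_out[c] = cl_size[c];
    cx[c] = cl_cx[c];
    cy[c] = cl_cy[c];
    cz[c] = cl_cz[c];
  }
  return List::create(
    _["n_clusters"] = next_cluster,
    _["shell"] = shell_out,
    _["size"] = size_out,
    _["cx"] = cx, _["cy"] = cy, _["cz"] = cz,
    _["parent"] = parent,
    _["root_cluster"] = cluster[root0],
    _["n_mask"] = (double)n_mask,
    _["max_dist"] = max_dist);
}

// Half-maximum edge detection along ray profiles.  S is an n_steps x
// n_rays matrix of HU sampled outward from the centreline at distances
// t_i = step * i (i from 1).  For each ray: the lumen level is the minimum
// of the first lumen_k samples; the wall peak is the maximum within
// wall_win samples after the half-rise point; the inner lumen edge is the
// half-maximum crossing between lumen and wall levels walking inward from
// the peak, and the outer wall edge the half-maximum crossing between wall
// and the outer minimum within outer_win samples beyond the peak.
// Returns an n_rays x 2 matrix (r_in, r_out), NA where undetectable.
//' @noRd
// [[Rcpp::export(name = "cpp_ray_edges")]]
NumericMatrix cpp_ray_edges(NumericMatrix S, double step, int lumen_k,
                            int wall_win, int outer_win,
                            double min_contrast_inner,
                            double min_contrast_outer) {
  int m = S.nrow(), nr = S.ncol();
  NumericMatrix out(nr, 2);
  for (int r = 0; r < nr; ++r) {
    out(r, 0) = NA_REAL;
    out(r, 1) = NA_REAL;
    // truncate at first NA (ray left the grid)
    int mm = m;
    for (int i = 0; i < m; ++i) if (NumericVector::is_na(S(i, r))) { mm = i; break; }
    if (mm < lumen_k + 2) continue;
    double lumen = S(0, r);
    for (int i = 1; i < lumen_k && i < mm; ++i) lumen = std::min(lumen, S(i, r));
    double gmax = S(0, r);
    for (int i = 1; i < mm; ++i) gmax = std::max(gmax, S(i, r));
    if (gmax - lumen < min_contrast_inner) continue;
    double seek = lumen + 0.5 * (gmax - lumen);
    int j1 = -1;
    for (int i = 0; i < mm; ++i) if (S(i, r) >= seek) { j1 = i; break; }
    if (j1 < 0) continue;
    int pk = j1;
    double wall = S(j1, r);
    for (int i = j1; i < std::min(mm, j1 + wall_win); ++i)
      if (S(i, r) > wall) { wall = S(i, r); pk = i; }
    // inner edge: walk inward from the peak
    double hi = (lumen + wall) / 2.0;
    int i_in = -1;
    for (int i = pk; i >= 0; --i) if (S(i, r) < hi) { i_in = i; break; }
    if (i_in < 0) continue;
    double frac = (hi - S(i_in, r)) / (S(i_in + 1, r) - S(i_in, r));
    out(r, 0) = step * (i_in + 1 + frac);
    // outer edge: walk outward from the peak
    double outer = wall;
    for (int i = pk + 1; i < std::min(mm, pk + 1 + outer_win); ++i)
      outer = std::min(outer, S(i, r));
    if (wall - outer < min_contrast_outer) continue;
    double ho = (wall + outer) / 2.0;
    int i_out = -1;
    for (int i = pk + 1; i < mm; ++i) if (S(i, r) < ho) { i_out = i; break; }
    if (i_out < 0) continue;
    double frac2 = (S(i_out - 1, r) - ho) / (S(i_out - 1, r) - S(i_out, r));
    out(r, 1) = step * (i_out + frac2);
  }
  return out;
}

// Trilinear interpolation of vol at 0-based voxel coordinates pts (rows =
// points, cols = x,y,z).  Points outside the grid return NA.
//' @noRd
// [[Rcpp::export(name = "cpp_interp_trilinear")]]
NumericVector cpp_interp_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts) {
  Grid g(dim);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (px < 0 || py < 0 || pz < 0 ||
        px > g.nx - 1 || py > g.ny - 1 || pz > g.nz - 1) {
      out[i] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    if (x0 == g.nx - 1) --x0;
    if (y0 == g.ny - 1) --y0;
    if (z0 == g.nz - 1) --z0;
    if (g.nx == 1) x0 = 0;
    if (g.ny == 1) y0 = 0;
    if (g.nz == 1) z0 = 0;
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    int x1 = std::min(x0 + 1, g.nx - 1);
    int y1 = std::min(y0 + 1, g.ny - 1);
    int z1 = std::min(z0 + 1, g.nz - 1);
    double c000 = vol[g.index(x0, y0, z0)], c100 = vol[g.index(x1, y0, z0)];
    double c010 = vol[g.index(x0, y1, z0)], c110 = vol[g.index(x1, y1, z0)];
    double c001 = vol[g.index(x0, y0, z1)], c101 = vol[g.index(x1, y0, z1)];
    double c011 = vol[g.index(x0, y1, z1)], c111 = vol[g.index(x1, y1, z1)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
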