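// Virtual binary pixel sensor chain: Gaussian charge-cloud digitization on a
// 928 x 960 grid (20.7 um pitch), connected-component (8-connectivity)
// cluster finding, chi2-greedy triplet matching to straight tracks, and
// Amanatides-Woo voxel traversal for track back-projection.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline uint64_t mix64b(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
static inline double u01b(uint64_t seed, uint64_t a, uint64_t b) {
  uint64_t h = mix64b(seed + mix64b(a + mix64b(b)));
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
List digitize_cpp(NumericVector x, NumericVector y, IntegerVector frame,
                  int nrow_pix, int ncol_pix, double pitch,
                  double sigma, double threshold, double noise_rate,
                  double seed_d, int sensor_key) {
  const uint64_t seed = (uint64_t)seed_d + 0x5851f42d4c957f2dULL * (uint64_t)sensor_key;
  const double W = ncol_pix * pitch, H = nrow_pix * pitch;
  const int n = x.size();
  std::vector<int> o_frame, o_row, o_col;
  int dropped = 0;
  std::unordered_set<int64_t> seen;  // (frame<<32 | row*ncol+col)

  auto fire = [&](int fr, int r, int c) {
    if (r < 0 || r >= nrow_pix || c < 0 || c >= ncol_pix) return;
    int64_t key = ((int64_t)fr << 32) | (int64_t)(r * ncol_pix + c);
    if (seen.insert(key).second) {
      o_frame.push_back(fr); o_row.push_back(r); o_col.push_back(c);
    }
  };

  const double s2 = sigma * std::sqrt(2.0);
  for (int i = 0; i < n; ++i) {
    double px = x[i] + W / 2.0, py = y[i] + H / 2.0;
    if (px < 0 || px >= W || py < 0 || py >= H) { ++dropped; continue; }
    int c0 = (int)std::floor(px / pitch), r0 = (int)std::floor(py / pitch);
    if (sigma <= 1e-9) { fire(frame[i], r0, c0); continue; }
    int rad = std::max(1, (int)std::ceil(3.0 * sigma / pitch));
    for (int dr = -rad; dr <= rad; ++dr) {
      int r = r0 + dr;
      double y0 = r * pitch, y1 = y0 + pitch;
      double fy = 0.5 * (std::erf((y1 - py) / s2) - std::erf((y0 - py) / s2));
      for (int dc = -rad; dc <= rad; ++dc) {
        int c = c0 + dc;
        double x0 = c * pitch, x1 = x0 + pitch;
        double fx = 0.5 * (std::erf((x1 - px) / s2) - std::erf((x0 - px) / s2));
        if (fx * fy >= threshold) fire(frame[i], r, c);
      }
    }
  }

  // uniform noise pixels, keyed by frame id so runs sharing a seed share noise
  if (noise_rate > 0 && n > 0) {
    std::unordered_set<int> frames(frame.begin(), frame.end());
    std::vector<int> fr_sorted(frames.begin(), frames.end());
    std::sort(fr_sorted.begin(), fr_sorted.end());
    double lambda = noise_rate * (double)nrow_pix * (double)ncol_pix;
    double L = std::exp(-lambda);
    for (int fr : fr_sorted) {
      int k = 0; double p = 1.0;
      do { ++k; p *= u01b(seed, (uint64_t)fr, 1000 + k); } while (p > L);
      --k;
      for (int j = 0; j < k; ++j) {
        int r = (int)(u01b(seed, (uint64_t)fr, 2000 + 2 * j) * nrow_pix);
        int c = (int)(u01b(seed, (uint64_t)fr, 2000 + 2 * j + 1) * ncol_pix);
        fire(fr, std::min(r, nrow_pix - 1), std::min(c, ncol_pix - 1));
      }
    }
  }

  int m = o_frame.size();
  IntegerMatrix out(m, 3);
  for (int j = 0; j < m; ++j) {
    out(j, 0) = o_frame[j]; out(j, 1) = o_row[j]; out(j, 2) = o_col[j];
  }
  colnames(out) = CharacterVector::create("frame", "row", "col");
  return List::create(_["pixels"] = out, _["dropped"] = dropped);
}

struct UF {
  std::vector<int> p;
  void init(int n) { p.resize(n); for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int a) { while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; } return a; }
  void unite(int a, int b) { p[find(a)] = find(b); }
};

// [[Rcpp::export]]
List cluster_cpp(IntegerVector group, IntegerVector row, IntegerVector col,
                 int nrow_pix, int ncol_pix, double pitch) {
  // input must be sorted by group; connected components with 8-connectivity
  const int n = group.size();
  const double W = ncol_pix * pitch, H = nrow_pix * pitch;
  std::vector<int> cg; std::vector<double> cx, cy; std::vector<int> csz;
  int i = 0;
  UF uf;
  while (i < n) {
    int j = i;
    while (j < n && group[j] == group[i]) ++j;
    int m = j - i;
    uf.init(m);
    std::unordered_map<int64_t, int> idx;
    idx.reserve(m * 2);
    for (int k = 0; k < m; ++k)
      idx[(int64_t)row[i + k] * ncol_pix + col[i + k]] = k;
    for (int k = 0; k < m; ++k) {
      for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        auto it = idx.find((int64_t)(row[i + k] + dr) * ncol_pix + (col[i + k] + dc));
        if (it != idx.end()) uf.unite(k, it->second);
      }
    }
    std::unordered_map<int, int> root2out;
    for (int k = 0; k < m; ++k) {
      int r = uf.find(k);
      auto it = root2out.find(r);
      int o;
      if (it == root2out.end()) {
        o = cg.size(); root2out[r] = o;
        cg.push_back(group[i]); cx.push_back(0); cy.push_back(0); csz.push_back(0);
      } else o = it->second;
      cx[o] += (col[i + k] + 0.5) * pitch - W / 2.0;
      cy[o] += (row[i + k] + 0.5) * pitch - H / 2.0;
      csz[o] += 1;
    }
    i = j;
  }
  int nc = cg.size();
  NumericMatrix out(nc, 4);
  for (int k = 0; k < nc; ++k) {
    out(k, 0) = cg[k]; out(k, 1) = cx[k] / csz[k]; out(k, 2) = cy[k] / csz[k];
    out(k, 3) = csz[k];
  }
  colnames(out) = CharacterVector::create("group", "x", "y", "size");
  return List::create(_["clusters"] = out);
}

struct Cand { double chi2; int i, j, k; double x0, y0, tx, ty, rmid; };

// [[Rcpp::export]]
List match_triplets_cpp(IntegerVector f1, NumericVector x1, NumericVector y1,
                        IntegerVector f2, NumericVector x2, NumericVector y2,
                        IntegerVector f3, NumericVector x3, NumericVector y3,
                        double z1, double z2, double z3,
                        double gate, double z_ref) {
  // inputs sorted by frame; straight-line LSQ through three planes
  const double zc[3] = {z1, z2, z3};
  double zbar = (z1 + z2 + z3) / 3.0;
  double szz = 0; for (int q = 0; q < 3; ++q) szz += (zc[q] - zbar) * (zc[q] - zbar);
  const double fproj = (z2 - z1) / (z3 - z1);

  std::vector<double> o_fr, o_x0, o_y0, o_tx, o_ty, o_chi2, o_rmid;
  int unmatched = 0;
  int i1 = 0, i2 = 0, i3 = 0;
  const int n1 = f1.size(), n2 = f2.size(), n3 = f3.size();

  while (i1 < n1 || i2 < n2 || i3 < n3) {
    int fr = INT32_MAX;
    if (i1 < n1) fr = std::min(fr, f1[i1]);
    if (i2 < n2) fr = std::min(fr, f2[i2]);
    if (i3 < n3) fr = std::min(fr, f3[i3]);
    int a1 = i1, a2 = i2, a3 = i3;
    while (i1 < n1 && f1[i1] == fr) ++i1;
    while (i2 < n2 && f2[i2] == fr) ++i2;
    while (i3 < n3 && f3[i3] == fr) ++i3;
    int m1 = i1 - a1, m2 = i2 - a2, m3 = i3 - a3;
    if (m1 == 0 || m2 == 0 || m3 == 0) { unmatched += m1 + m2 + m3; continue; }

    std::vector<Cand> cands;
    for (int a = 0; a < m1; ++a) for (int c = 0; c < m3; ++c) {
      double dx13 = x3[a3 + c] - x1[a1 + a], dy13 = y3[a3 + c] - y1[a1 + a];
      if (std::fabs(dx13) > 8.0 || std::fabs(dy13) > 8.0) continue;
      double xp = x1[a1 + a] + dx13 * fproj, yp = y1[a1 + a] + dy13 * fproj;
      for (int b = 0; b < m2; ++b) {
        double rx = x2[a2 + b] - xp, ry = y2[a2 + b] - yp;
        if (rx * rx + ry * ry > gate * gate) continue;
        // LSQ line x = xb + tx (z - zbar)
        double xv[3] = {x1[a1 + a], x2[a2 + b], x3[a3 + c]};
        double yv[3] = {y1[a1 + a], y2[a2 + b], y3[a3 + c]};
        double xb = (xv[0] + xv[1] + xv[2]) / 3.0, yb = (yv[0] + yv[1] + yv[2]) / 3.0;
        double sxz = 0, syz = 0;
        for (int q = 0; q < 3; ++q) {
          sxz += (zc[q] - zbar) * (xv[q] - xb);
          syz += (zc[q] - zbar) * (yv[q] - yb);
        }
        double tx = sxz / szz, ty = syz / szz, chi2 = 0, rmid = 0;
        for (int q = 0; q < 3; ++q) {
          double rxq = xv[q] - (xb + tx * (zc[q] - zbar));
          double ryq = yv[q] - (yb + ty * (zc[q] - zbar));
          chi2 += rxq * rxq + ryq * ryq;
          if (q == 1) rmid = std::sqrt(rxq * rxq + ryq * ryq);
        }
        Cand cd; cd.chi2 = chi2; cd.i = a; cd.j = b; cd.k = c;
        cd.x0 = xb + tx * (z_ref - zbar); cd.y0 = yb + ty * (z_ref - zbar);
        cd.tx = tx; cd.ty = ty; cd.rmid = rmid;
        cands.push_back(cd);
      }
    }
    std::sort(cands.begin(), cands.end(),
              [](const Cand& a, const Cand& b) { return a.chi2 < b.chi2; });
    std::vector<bool> u1(m1, false), u2(m2, false), u3(m3, false);
    int used = 0;
    for (const Cand& cd : cands) {
      if (u1[cd.i] || u2[cd.j] || u3[cd.k]) continue;
      u1[cd.i] = u2[cd.j] = u3[cd.k] = true; ++used;
      o_fr.push_back(fr); o_x0.push_back(cd.x0); o_y0.push_back(cd.y0);
      o_tx.push_back(cd.tx); o_ty.push_back(cd.ty);
      o_chi2.push_back(cd.chi2); o_rmid.push_back(cd.rmid);
    }
    unmatched += (m1 - used) + (m2 - used) + (m3 - used);
  }

  int nt = o_fr.size();
  NumericMatrix out(nt, 7);
  for (int t = 0; t < nt; ++t) {
    out(t, 0) = o_fr[t]; out(t, 1) = o_x0[t]; out(t, 2) = o_y0[t];
    out(t, 3) = o_tx[t]; out(t, 4) = o_ty[t]; out(t, 5) = o_chi2[t];
    out(t, 6) = o_rmid[t];
  }
  colnames(out) = CharacterVector::create("frame", "x0", "y0", "tx", "ty",
                                          "chi2", "resid_mid");
  return List::create(_["tracks"] = out, _["unmatched"] = unmatched);
}

// [[Rcpp::export]]
IntegerVector backproject_cpp(NumericVector x0, NumericVector y0,
                              NumericVector tx, NumericVector ty,
                              double gx0, double gdx, int gnx,
                              double gy0, double gdy, int gny,
                              double gz0, double gdz, int gnz) {
  // x0/y0 are track positions at z = 0 of the grid frame; every voxel whose
  // volume the infinite line crosses within the grid z-range is counted once
  IntegerVector counts(gnx * gny * gnz);
  const double z_lo = gz0, z_hi = gz0 + gnz * gdz;
  const int n = x0.size();
  for (int i = 0; i < n; ++i) {
    double zc = z_lo;
    while (zc < z_hi - 1e-12) {
      double xc = x0[i] + tx[i] * zc, yc = y0[i] + ty[i] * zc;
      // next boundary crossing in z, x, y
      int iz = (int)std::floor((zc - gz0) / gdz + 1e-9);
      double z_next = gz0 + (iz + 1) * gdz;
      if (z_next <= zc + 1e-12) z_next = zc + gdz;  // float-safety: must advance
      if (tx[i] > 1e-15) {
        int ix = (int)std::floor((xc - gx0) / gdx);
        double zb = zc + ((gx0 + (ix + 1) * gdx) - xc) / tx[i];
        if (zb < z_next && zb > zc + 1e-12) z_next = zb;
      } else if (tx[i] < -1e-15) {
        int ix = (int)std::floor((xc - gx0) / gdx);
        double zb = zc + ((gx0 + ix * gdx) - xc) / tx[i];
        if (zb < z_next && zb > zc + 1e-12) z_next = zb;
      }
      if (ty[i] > 1e-15) {
        int iy = (int)std::floor((yc - gy0) / gdy);
        double zb = zc + ((gy0 + (iy + 1) * gdy) - yc) / ty[i];
        if (zb < z_next && zb > zc + 1e-12) z_next = zb;
      } else if (ty[i] < -1e-15) {
        int iy = (int)std::floor((yc - gy0) / gdy);
        double zb = zc + ((gy0 + iy * gdy) - yc) / ty[i];
        if (zb < z_next && zb > zc + 1e-12) z_next = zb;
      }
      if (z_next > z_hi) z_next = z_hi;
      double zm = 0.5 * (zc + z_next);
      double xm = x0[i] + tx[i] * zm, ym = y0[i] + ty[i] * zm;
      int ix = (int)std::floor((xm - gx0) / gdx);
      int iy = (int)std::floor((ym - gy0) / gdy);
      int izm = (int)std::floor((zm - gz0) / gdz);
      if (ix >= 0 && ix < gnx && iy >= 0 && iy < gny && izm >= 0 && izm < gnz)
        counts[ix + gnx * (iy + (int64_t)gny * izm)] += 1;
      zc = z_next;
    }
  }
  counts.attr("dim") = IntegerVector::create(gnx, gny, gnz);
  return counts;
}
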