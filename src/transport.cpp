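// Condensed-history proton transport through a z-layered geometry with an
// optional fiducial marker. Paraxial (slope) formalism: per step the mean
// Bethe energy loss plus a Gaussian (Bohr) straggling draw is applied, and a
// Highland angular kick in two orthogonal planes with the Fermi-Eyges
// correlated lateral displacement. Randomness is counter-based per
// (seed, particle, step, draw), so with/without-marker runs at the same seed
// share identical histories for every proton that never meets the marker.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double PROTON_M = 938.27208816;
static const double BETHE_K = 0.307075;   // MeV cm^2/mol
static const double BOHR_K = 0.1569;      // MeV^2 cm^2/g
static const double TWO_ME_EV = 2.0 * 0.51099895 * 1e6;

static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t seed, uint64_t pid, uint64_t step, uint64_t draw) {
  uint64_t h = mix64(seed + mix64(pid + mix64(step + mix64(draw))));
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// Acklam's inverse-normal approximation (|error| < 1.2e-8, ample for MC noise)
static double qnorm_fast(double p) {
  static const double a[] = {-3.969683028665376e+01, 2.209460984245205e+02,
    -2.759285104469687e+02, 1.383577518672690e+02, -3.066479806614716e+01,
    2.506628277459239e+00};
  static const double b[] = {-5.447609879822406e+01, 1.615858368580409e+02,
    -1.556989798598866e+02, 6.680131188771972e+01, -1.328068155288572e+01};
  static const double c[] = {-7.784894002430293e-03, -3.223964580411365e-01,
    -2.400758277161838e+00, -2.549732539343734e+00, 4.374664141464968e+00,
    2.938163982698783e+00};
  static const double d[] = {7.784695709041462e-03, 3.224671290700398e-01,
    2.445134137142996e+00, 3.754408661907416e+00};
  const double pl = 0.02425;
  double q, r;
  if (p < pl) {
    q = std::sqrt(-2.0 * std::log(p));
    return (((((c[0]*q+c[1])*q+c[2])*q+c[3])*q+c[4])*q+c[5]) /
           ((((d[0]*q+d[1])*q+d[2])*q+d[3])*q+1.0);
  } else if (p <= 1.0 - pl) {
    q = p - 0.5; r = q * q;
    return (((((a[0]*r+a[1])*r+a[2])*r+a[3])*r+a[4])*r+a[5])*q /
           (((((b[0]*r+b[1])*r+b[2])*r+b[3])*r+b[4])*r+1.0);
  } else {
    q = std::sqrt(-2.0 * std::log(1.0 - p));
    return -(((((c[0]*q+c[1])*q+c[2])*q+c[3])*q+c[4])*q+c[5]) /
            ((((d[0]*q+d[1])*q+d[2])*q+d[3])*q+1.0);
  }
}

static inline double ndraw(uint64_t seed, uint64_t pid, uint64_t step, uint64_t k) {
  return qnorm_fast(u01(seed, pid, step, k));
}

struct Marker {
  bool present;
  int shape;        // 1 tube, 2 cylinder
  double cx, cy, cz, r_out2, r_in2, half_len;
  int mat;
  double fx0, fx1, fy0, fy1, fz0, fz1;  // fine-step bounding box
};

// [[Rcpp::export]]
List transport_cpp(NumericMatrix init, IntegerVector pid,
                   NumericVector bp, IntegerVector region_mat, int ambient_mat,
                   NumericMatrix mats, NumericVector sensor_z,
                   List marker_cfg, List dose_cfg,
                   double step_max, double fine_step, double cutoff,
                   double z_max, double seed_d, bool record_traj) {
  const int n = init.nrow();
  const int nreg = region_mat.size();
  const uint64_t seed = (uint64_t)seed_d;

  Marker mk;
  mk.present = as<bool>(marker_cfg["present"]);
  if (mk.present) {
    mk.shape = as<int>(marker_cfg["shape"]);
    mk.cx = as<double>(marker_cfg["cx"]);
    mk.cy = as<double>(marker_cfg["cy"]);
    mk.cz = as<double>(marker_cfg["cz"]);
    double ro = as<double>(marker_cfg["r_out"]), ri = as<double>(marker_cfg["r_in"]);
    mk.r_out2 = ro * ro; mk.r_in2 = ri * ri;
    mk.half_len = as<double>(marker_cfg["half_len"]);
    mk.mat = as<int>(marker_cfg["mat"]);
    double m = as<double>(marker_cfg["fine_margin"]);
    mk.fx0 = mk.cx - ro - m; mk.fx1 = mk.cx + ro + m;
    mk.fy0 = mk.cy - mk.half_len - m; mk.fy1 = mk.cy + mk.half_len + m;
    mk.fz0 = mk.cz - ro - m; mk.fz1 = mk.cz + ro + m;
  } else {
    mk.shape = 0; mk.cx = mk.cy = mk.cz = 0; mk.r_out2 = mk.r_in2 = 0;
    mk.half_len = 0; mk.mat = -1;
    mk.fx0 = mk.fx1 = mk.fy0 = mk.fy1 = mk.fz0 = mk.fz1 = 0;
  }

  const bool dose_on = as<bool>(dose_cfg["enabled"]);
  double dg_x0 = 0, dg_dx = 1, dg_z0 = 0, dg_dz = 1, dg_yh = 0;
  int dg_nx = 0, dg_nz = 0;
  NumericMatrix dose, dose2;
  if (dose_on) {
    dg_x0 = as<double>(dose_cfg["x0"]); dg_dx = as<double>(dose_cfg["dx"]);
    dg_nx = as<int>(dose_cfg["nx"]);
    dg_z0 = as<double>(dose_cfg["z0"]); dg_dz = as<double>(dose_cfg["dz"]);
    dg_nz = as<int>(dose_cfg["nz"]);
    dg_yh = as<double>(dose_cfg["y_half"]);
    dose = NumericMatrix(dg_nx, dg_nz);
    dose2 = NumericMatrix(dg_nx, dg_nz);
  }

  const int ns = sensor_z.size();
  std::vector<int> h_sensor, h_pid;
  std::vector<double> h_x, h_y, h_e;
  std::vector<double> t_x, t_y, t_z, t_e;
  std::vector<int> t_pid;

  NumericVector stop_z(n, NA_REAL);
  int n_stopped = 0;

  // per-material constants
  const int nm = mats.nrow();
  std::vector<double> m_rho(nm), m_za(nm), m_i(nm), m_x0(nm);
  for (int i = 0; i < nm; ++i) {
    m_rho[i] = mats(i, 0); m_za[i] = mats(i, 1);
    m_i[i] = mats(i, 2); m_x0[i] = mats(i, 3);
  }

  auto deposit = [&](double zq, double xq, double yq, double w) {
    if (!dose_on || w <= 0) return;
    if (std::fabs(yq - mk.cy) > dg_yh && dg_yh > 0) return;
    int ix = (int)std::floor((xq - dg_x0) / dg_dx);
    int iz = (int)std::floor((zq - dg_z0) / dg_dz);
    if (ix >= 0 && ix < dg_nx && iz >= 0 && iz < dg_nz) {
      dose(ix, iz) += w;
      dose2(ix, iz) += w * w;
    }
  };

  for (int i = 0; i < n; ++i) {
    double x = init(i, 0), y = init(i, 1), tx = init(i, 2), ty = init(i, 3);
    double z = init(i, 4), E = init(i, 5);
    const uint64_t id = (uint64_t)pid[i];
    uint64_t step = 0;
    int reg = -1;            // region index: -1 before first bp
    int next_s = 0;
    while (next_s < ns && sensor_z[next_s] <= z + 1e-12) ++next_s;
    double Tcum = 1e-12;     // cumulative radiative thickness (x/X0)
    bool alive = true;

    while (alive) {
      if (record_traj) {
        t_pid.push_back(pid[i]); t_x.push_back(x); t_y.push_back(y);
        t_z.push_back(z); t_e.push_back(E);
      }
      if (z >= z_max || std::fabs(x) > 200.0 || std::fabs(y) > 200.0) break;
      // advance interval pointer: bp has nreg+1 edges bounding nreg intervals;
      // reg = -1 before bp[0], nreg past bp[nreg]
      while (reg < nreg && z >= bp[reg + 1] - 1e-12) ++reg;
      // distance to next breakpoint in z
      double z_next = z_max;
      if (reg < nreg) z_next = bp[reg + 1];
      if (next_s < ns && sensor_z[next_s] < z_next) z_next = sensor_z[next_s];

      bool in_fine = mk.present &&
        x > mk.fx0 && x < mk.fx1 && y > mk.fy0 && y < mk.fy1 &&
        z > mk.fz0 && z < mk.fz1;
      double dz = in_fine ? fine_step : step_max;
      if (z + dz > z_next) dz = z_next - z;
      if (dz < 1e-9) dz = 1e-9;

      // material at segment midpoint
      double xm = x + tx * dz * 0.5, ym = y + ty * dz * 0.5, zm = z + dz * 0.5;
      int mat = (reg >= 0 && reg < nreg) ? region_mat[reg] : ambient_mat;
      if (mk.present && zm > mk.fz0 && zm < mk.fz1 &&
          std::fabs(ym - mk.cy) <= mk.half_len) {
        double ddx = xm - mk.cx, ddz = zm - mk.cz;
        double r2 = ddx * ddx + ddz * ddz;
        if (r2 <= mk.r_out2 && r2 >= mk.r_in2) mat = mk.mat;
      }

      double rho = m_rho[mat];
      double slope2 = tx * tx + ty * ty;
      double path_mm = dz * std::sqrt(1.0 + slope2);
      double dE = 0.0;

      if (rho > 0.0) {
        // Bethe stopping power, with step shrink to keep mean loss < 20%
        double gamma = 1.0 + E / PROTON_M;
        double beta2 = 1.0 - 1.0 / (gamma * gamma);
        double S = BETHE_K * m_za[mat] * rho / beta2 *
          (std::log(TWO_ME_EV * beta2 * gamma * gamma / m_i[mat]) - beta2);
        if (S < 0) S = 1e-6;
        double mean_loss = S * path_mm * 0.1;  // path in cm
        // midpoint re-evaluation (second order in the step size)
        if (mean_loss < 0.5 * E) {
          double Em = E - 0.5 * mean_loss;
          double gm = 1.0 + Em / PROTON_M;
          double b2m = 1.0 - 1.0 / (gm * gm);
          double Sm = BETHE_K * m_za[mat] * rho / b2m *
            (std::log(TWO_ME_EV * b2m * gm * gm / m_i[mat]) - b2m);
          if (Sm > 0) { S = Sm; mean_loss = S * path_mm * 0.1; }
        }
        if (mean_loss > 0.15 * E) {
          double sc = 0.15 * E / mean_loss;
          dz *= sc; path_mm *= sc; mean_loss *= sc;
          if (dz < 1e-5) { // essentially stopped
            deposit(z, x, y, E);
            stop_z[i] = z; ++n_stopped; alive = false; break;
          }
        }
        double sig = std::sqrt(BOHR_K * m_za[mat] * rho * path_mm * 0.1 *
                               (1.0 - beta2 / 2.0) / (1.0 - beta2));
        dE = mean_loss + sig * ndraw(seed, id, step, 0);
        if (dE < 0) dE = 0;
        if (dE > E) dE = E;

        // Highland kick with the cumulative-thickness log correction
        // (Highland-integral treatment for composite targets)
        double t_rl = path_mm * 0.1 * rho / m_x0[mat];
        Tcum += t_rl;
        double f = 1.0 + 0.038 * std::log(Tcum);
        if (f < 0.10) f = 0.10;
        double pc = std::sqrt(E * (E + 2.0 * PROTON_M));
        double th0 = 13.6 / (std::sqrt(beta2) * pc) * std::sqrt(t_rl) * f;

        double z1x = ndraw(seed, id, step, 1), z2x = ndraw(seed, id, step, 2);
        double z1y = ndraw(seed, id, step, 3), z2y = ndraw(seed, id, step, 4);
        double dxs = path_mm * th0 * (z1x * 0.2886751345948129 + z2x * 0.5);
        double dys = path_mm * th0 * (z1y * 0.2886751345948129 + z2y * 0.5);

        // deposit dE along the segment, split over dose z-bins
        if (dose_on && dE > 0) {
          double zA = z, zB = z + dz;
          int izA = (int)std::floor((zA - dg_z0) / dg_dz);
          int izB = (int)std::floor((zB - 1e-12 - dg_z0) / dg_dz);
          if (izA == izB) {
            deposit(zm, xm, ym, dE);
          } else {
            for (int izb = izA; izb <= izB; ++izb) {
              double lo = std::max(zA, dg_z0 + izb * dg_dz);
              double hi = std::min(zB, dg_z0 + (izb + 1) * dg_dz);
              if (hi <= lo) continue;
              double frac = (hi - lo) / dz;
              double zc = 0.5 * (lo + hi);
              deposit(zc, x + tx * (zc - z), y + ty * (zc - z), dE * frac);
            }
          }
        }

        x += tx * dz + dxs; y += ty * dz + dys; z += dz;
        tx += th0 * z2x;  ty += th0 * z2y;
        E -= dE;
        if (E < cutoff) {  // kill, residual deposited locally
          deposit(z, x, y, E);
          stop_z[i] = z; ++n_stopped; alive = false;
        }
      } else {
        x += tx * dz; y += ty * dz; z += dz;
      }
      ++step;

      // sensor-plane crossing (steps end exactly on sensor planes)
      while (next_s < ns && z >= sensor_z[next_s] - 1e-9) {
        if (alive) {
          h_sensor.push_back(next_s + 1); h_pid.push_back(pid[i]);
          h_x.push_back(x); h_y.push_back(y); h_e.push_back(E);
        }
        ++next_s;
      }
      if (step > 2000000) break;  // safety
    }
  }

  NumericMatrix hits(h_x.size(), 5);
  for (size_t j = 0; j < h_x.size(); ++j) {
    hits(j, 0) = h_sensor[j]; hits(j, 1) = h_x[j]; hits(j, 2) = h_y[j];
    hits(j, 3) = h_e[j]; hits(j, 4) = h_pid[j];
  }
  colnames(hits) = CharacterVector::create("sensor", "x", "y", "energy", "pid");

  List out = List::create(
    _["hits"] = hits, _["stop_z"] = stop_z, _["n_stopped"] = n_stopped);
  if (dose_on) { out["dose"] = dose; out["dose2"] = dose2; }
  if (record_traj) {
    NumericMatrix traj(t_x.size(), 5);
    for (size_t j = 0; j < t_x.size(); ++j) {
      traj(j, 0) = t_pid[j]; traj(j, 1) = t_x[j]; traj(j, 2) = t_y[j];
      traj(j, 3) = t_z[j]; traj(j, 4) = t_e[j];
    }
    colnames(traj) = CharacterVector::create("pid", "x", "y", "z", "energy");
    out["traj"] = traj;
  }
  return out;
}
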