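#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Self-contained RNG (xoshiro256++ with splitmix64 seeding) so that phase
// space generation is reproducible from a single integer seed independent of
// platform RNG library details.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
    spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare;
  double spare;
  inline double norm() {  // Box-Muller, cached pair
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Physics: Bragg-Kleeman closed form, shared constants with the R layer.
// ---------------------------------------------------------------------------
static const double BK_ALPHA = 0.022;
static const double BK_P = 1.77;
static const double X0_WATER = 360.8;
static const double M_PROTON = 938.272;

static inline double range_of(double e) { return BK_ALPHA * std::pow(e, BK_P); }
static inline double energy_of_range(double r) {
  return std::pow(r / BK_ALPHA, 1.0 / BK_P);
}
static inline double stop_pow(double e) {
  return std::pow(e, 1.0 - BK_P) / (BK_ALPHA * BK_P);
}
static inline double beta_c_p(double e) {
  return (e * e + 2.0 * e * M_PROTON) / (e + M_PROTON);
}

// Lookup tables over residual range (mm of water) for the per-step hot loop.
// Transport tracks the residual range r: traversing dsw mm of water-equivalent
// material decrements r by exactly dsw, so the WEPL bookkeeping is exact and
// energy is only needed for the scattering power and the straggling
// conversion dR/dE = 1/S.
struct Rlut {
  double r_min, dr;
  std::vector<double> dRdE, inv_bcp;
  Rlut(double r_min_, double r_max, int n) : r_min(r_min_) {
    dr = (r_max - r_min) / (n - 1);
    dRdE.resize(n); inv_bcp.resize(n);
    for (int i = 0; i < n; ++i) {
      double e = energy_of_range(r_min + i * dr);
      dRdE[i] = 1.0 / stop_pow(e);
      inv_bcp[i] = 1.0 / beta_c_p(e);
    }
  }
  inline void at(double r, double &drde, double &ibcp) const {
    double x = (r - r_min) / dr;
    int i = (int)x;
    int imax = (int)dRdE.size() - 2;
    if (i < 0) i = 0;
    if (i > imax) i = imax;
    double f = x - i;
    if (f < 0) f = 0; if (f > 1) f = 1;
    drde = dRdE[i] + f * (dRdE[i + 1] - dRdE[i]);
    ibcp = inv_bcp[i] + f * (inv_bcp[i + 1] - inv_bcp[i]);
  }
};

// ---------------------------------------------------------------------------
// RSP lookup: voxel grid (nearest voxel) or exact cube-phantom geometry.
// ---------------------------------------------------------------------------
struct Geometry {
  int mode; // 0 voxel, 1 cubes
  // voxel
  const double *grid;
  int du_, dt_, dv_;
  double sp[3], org[3];
  // cubes
  double tank_u, tank_half_t, tank_half_v;
  double cube_half, cube_rsp, cth, sth;
  std::vector<double> cu0, ctc, cvc;
  double u_front, u_rear;

  inline double rsp(double u, double t, double v) const {
    if (mode == 0) {
      int iu = (int)std::floor((u - org[0]) / sp[0]);
      int it = (int)std::floor((t - org[1]) / sp[1]);
      int iv = (int)std::floor((v - org[2]) / sp[2]);
      if (iu < 0 || iu >= du_ || it < 0 || it >= dt_ || iv < 0 || iv >= dv_)
        return 0.0;
      return grid[iu + (size_t)du_ * (it + (size_t)dt_ * iv)];
    }
    if (u < 0 || u > tank_u || std::fabs(t) > tank_half_t ||
        std::fabs(v) > tank_half_v)
      return 0.0;
    for (size_t k = 0; k < cu0.size(); ++k) {
      if (u >= cu0[k] && u < cu0[k] + 2.0 * cube_half) {
        double dt = t - ctc[k], dv = v - cvc[k];
        double tp = cth * dt + sth * dv;
        double vp = -sth * dt + cth * dv;
        if (std::fabs(tp) <= cube_half && std::fabs(vp) <= cube_half)
          return cube_rsp;
      }
    }
    return 1.0;
  }
};

static Geometry make_geometry(List phantom) {
  Geometry g;
  std::string mode = as<std::string>(phantom["mode"]);
  if (mode == "voxel") {
    g.mode = 0;
    NumericVector grid = phantom["grid"];
    IntegerVector dims = phantom["dims"];
    NumericVector sp = phantom["spacing"], org = phantom["origin"];
    g.grid = REAL(grid);
    g.du_ = dims[0]; g.dt_ = dims[1]; g.dv_ = dims[2];
    for (int i = 0; i < 3; ++i) { g.sp[i] = sp[i]; g.org[i] = org[i]; }
    g.u_front = org[0];
    g.u_rear = org[0] + dims[0] * sp[0];
  } else {
    g.mode = 1;
    NumericVector size = phantom["size"];
    g.tank_u = size[0]; g.tank_half_t = size[1] / 2; g.tank_half_v = size[2] / 2;
    g.cube_half = as<double>(phantom["cube_edge"]) / 2;
    g.cube_rsp = as<double>(phantom["cube_rsp"]);
    double th = as<double>(phantom["tilt_deg"]) * M_PI / 180.0;
    g.cth = std::cos(th); g.sth = std::sin(th);
    NumericVector u0 = phantom["u0"], tc = phantom["tc"], vc = phantom["vc"];
    g.cu0.assign(u0.begin(), u0.end());
    g.ctc.assign(tc.begin(), tc.end());
    g.cvc.assign(vc.begin(), vc.end());
    g.u_front = 0.0;
    g.u_rear = g.tank_u;
  }
  return g;
}

// [[Rcpp::export]]
List cpp_transport(List phantom, double energy, double spot_sigma,
                   double div_sigma, double spot_spacing, double field_t,
                   double field_v, int n_primaries, double step_length,
                   bool scattering, bool straggling, double outlier_fraction,
                   double outlier_offset, double bohr_rate, double e_cutoff,
                   double seed) {
  Geometry g = make_geometry(phantom);
  Rng rng((uint64_t)seed);
  double r_full = range_of(energy);
  double r_cut = range_of(e_cutoff);
  Rlut lut(0.5 * r_cut, r_full * 1.05, 20000);

  // pencil-beam spot grid, centred on the axis
  int nspot_t = std::max(1, (int)std::floor(field_t / spot_spacing) + 1);
  int nspot_v = std::max(1, (int)std::floor(field_v / spot_spacing) + 1);

  NumericVector t0(n_primaries), v0(n_primaries), st0(n_primaries),
      sv0(n_primaries), t1(n_primaries), v1(n_primaries), st1(n_primaries),
      sv1(n_primaries), e_in_v(n_primaries), e_out_v(n_primaries),
      wepl_v(n_primaries);
  int kept = 0, stopped = 0, outliers = 0;

  double U = g.u_rear - g.u_front;
  int nstep = (int)std::ceil(U / step_length - 1e-9);

  for (int ip = 0; ip < n_primaries; ++ip) {
    // spot selection + Gaussian spot profile + angular divergence
    int is_t = (int)(rng.unif() * nspot_t); if (is_t >= nspot_t) is_t = nspot_t - 1;
    int is_v = (int)(rng.unif() * nspot_v); if (is_v >= nspot_v) is_v = nspot_v - 1;
    double t = (is_t - 0.5 * (nspot_t - 1)) * spot_spacing + spot_sigma * rng.norm();
    double v = (is_v - 0.5 * (nspot_v - 1)) * spot_spacing + spot_sigma * rng.norm();
    double st = div_sigma * rng.norm();
    double sv = div_sigma * rng.norm();
    double r = r_full;  // residual range in water, mm
    double u = g.u_front;
    double et0 = t, ev0 = v, est0 = st, esv0 = sv;
    double xw = 0.0;  // cumulative water-equivalent depth for the Highland log
    bool dead = false;

    for (int is = 0; is < nstep; ++is) {
      double du = std::min(step_length, g.u_rear - u);
      double ds = du * std::sqrt(1.0 + st * st + sv * sv);
      double rsp = g.rsp(u + 0.5 * du, t + 0.5 * du * st, v + 0.5 * du * sv);
      // advance with the pre-kick direction
      t += du * st;
      v += du * sv;
      u += du;
      if (rsp > 0.0) {
        double dsw = rsp * ds;
        double drde, ibcp;
        lut.at(r - 0.5 * dsw, drde, ibcp);
        r -= dsw;
        if (straggling)
          r += std::sqrt(bohr_rate * dsw) * drde * rng.norm();
        if (r <= r_cut) { dead = true; break; }
        if (scattering) {
          xw += dsw;
          double corr = 1.0 + 0.038 * std::log(xw / X0_WATER);
          if (corr < 0.0) corr = 0.0;
          double th0 = 13.6 * ibcp * std::sqrt(dsw / X0_WATER) * corr;
          st += th0 * rng.norm();
          sv += th0 * rng.norm();
        }
      }
    }
    if (dead) { ++stopped; continue; }

    double e_out = energy_of_range(r);
    double wepl = r_full - r;
    if (outlier_fraction > 0.0 && rng.unif() < outlier_fraction) {
      // anomalous energy loss channel (stand-in for nuclear events):
      // shift the residual range so the apparent WEPL grows by the offset
      double r_out = range_of(e_out) - outlier_offset;
      double r_min = range_of(std::max(e_cutoff, 1e-3));
      if (r_out < r_min) r_out = r_min;
      e_out = energy_of_range(r_out);
      wepl = range_of(energy) - r_out;
      ++outliers;
    }

    t0[kept] = et0; v0[kept] = ev0; st0[kept] = est0; sv0[kept] = esv0;
    t1[kept] = t; v1[kept] = v; st1[kept] = st; sv1[kept] = sv;
    e_in_v[kept] = energy; e_out_v[kept] = e_out; wepl_v[kept] = wepl;
    ++kept;
  }

  auto head = [&](NumericVector x) {
    if (kept == n_primaries) return x;
    return NumericVector(x.begin(), x.begin() + kept);
  };
  return List::create(
      _["t0"] = head(t0), _["v0"] = head(v0), _["st0"] = head(st0),
      _["sv0"] = head(sv0), _["t1"] = head(t1), _["v1"] = head(v1),
      _["st1"] = head(st1), _["sv1"] = head(sv1), _["e_in"] = head(e_in_v),
      _["e_out"] = head(e_out_v), _["wepl"] = head(wepl_v),
      _["n_stopped"] = stopped, _["n_outliers"] = outliers,
      _["u_front"] = g.u_front, _["u_rear"] = g.u_rear);
}
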