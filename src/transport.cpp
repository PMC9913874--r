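// Kilovoltage photon Monte Carlo engine: Woodcock (delta) tracking in a voxel
// phantom, Klein-Nishina Compton sampling (Kahn's method), local energy
// deposition (kerma approximation), and analytic ray transmission through a
// divergent multi-slit collimator.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double ELECTRON_REST_KEV = 510.998950;

// ---------------------------------------------------------------------------
// RNG: xoshiro256** seeded via splitmix64. Self-contained so that instance
// streams are bit-reproducible across platforms and independent of R's RNG.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in (0,1); never exactly 0 so -log(u) is finite
  inline double u() {
    double v = (next() >> 11) * 0x1.0p-53;
    return v > 0 ? v : 0x1.0p-53;
  }
};

// ---------------------------------------------------------------------------
// Collimator: slits are divergent prisms. Slit k is tilted by its axis angle
// (tan stored), its centre at depth z (0 = entrance, T = exit) is
//   c_k(z) = exit_offset_k - (T - z) * tan_k
// and its width is linearly interpolated between axial stations
// (entrance/mid/exit for 5-slit geometries, entrance/exit for 3-slit).
// The slit height limits the aperture in y with straight edges.
struct Colli {
  int n_slits;
  std::vector<double> tan_ang;   // per slit
  std::vector<double> offset;    // exit-centre offset, mm
  std::vector<double> wz;        // station positions along thickness, mm
  std::vector<double> ww;        // widths at stations, mm
  double thickness;              // mm
  double half_height;            // mm
  bool ideal;                    // ideal absorber: any brass path -> weight 0

  static Colli from_list(List g) {
    Colli c;
    c.n_slits = as<int>(g["n_slits"]);
    c.tan_ang = as<std::vector<double> >(g["tan_ang"]);
    c.offset = as<std::vector<double> >(g["offset_mm"]);
    c.wz = as<std::vector<double> >(g["station_z"]);
    c.ww = as<std::vector<double> >(g["station_w"]);
    c.thickness = as<double>(g["thickness"]);
    c.half_height = as<double>(g["half_height"]);
    c.ideal = as<bool>(g["ideal"]);
    return c;
  }
};

// clip [lo,hi] to where a + b*z >= 0
static inline void lin_clip(double a, double b, double& lo, double& hi) {
  if (std::fabs(b) < 1e-300) {
    if (a < 0) { lo = 1.0; hi = 0.0; }
    return;
  }
  double z = -a / b;
  if (b > 0) { if (z > lo) lo = z; }
  else       { if (z < hi) hi = z; }
}

// Path length (mm) through brass for a ray crossing the collimator block.
// Ray given at the entrance plane z=0: position (x0,y0), direction (ux,uy,uz)
// normalized with uz > 0. The block is laterally unbounded.
static double brass_path(const Colli& c, double x0, double y0,
                         double ux, double uy, double uz) {
  if (uz < 1e-12)
    stop("ray parallel to collimator entrance plane");
  const double T = c.thickness;
  double gx = ux / uz, gy = uy / uz;   // lateral drift per unit z
  double len_in_z = 0.0;               // z-measure inside slit apertures
  int npieces = (int)c.wz.size() - 1;
  for (int k = 0; k < c.n_slits; ++k) {
    double tk = c.tan_ang[k];
    double cc = c.offset[k] - T * tk;  // centre at z=0
    for (int p = 0; p < npieces; ++p) {
      double za = c.wz[p], zb = c.wz[p + 1];
      double wa = c.ww[p] * 0.5, wb = c.ww[p + 1] * 0.5; // half widths
      // half width as p + q z on the piece
      double q = (wb - wa) / (zb - za);
      double pw = wa - q * za;
      double lo = za, hi = zb;
      // |x(z) - c(z)| <= w(z)/2
      lin_clip(x0 - cc + pw, gx - tk + q, lo, hi);
      lin_clip(cc - x0 + pw, tk - gx + q, lo, hi);
      // |y(z)| <= half_height
      lin_clip(c.half_height - y0, -gy, lo, hi);
      lin_clip(c.half_height + y0, gy, lo, hi);
      if (hi > lo) len_in_z += hi - lo;
    }
  }
  double brass_z = T - len_in_z;
  if (brass_z < 0) brass_z = 0;
  return brass_z / uz;
}

// [[Rcpp::export]]
NumericVector cpp_brass_path(NumericMatrix origin, NumericMatrix direction,
                             List geom) {
  Colli c = Colli::from_list(geom);
  int n = origin.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ux = direction(i, 0), uy = direction(i, 1), uz = direction(i, 2);
    double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= nn; uy /= nn; uz /= nn;
    if (uz < 1e-12)
      stop("ray parallel to collimator entrance plane");
    // advance/retreat the ray to the entrance plane z=0
    double t = (0.0 - origin(i, 2)) / uz;
    double x0 = origin(i, 0) + t * ux;
    double y0 = origin(i, 1) + t * uy;
    out[i] = brass_path(c, x0, y0, ux, uy, uz);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Attenuation tables: uniform grid in log(E), linear interpolation of the
// tabulated values in log(E). Shared convention with the R-side lookup.
struct MuTable {
  double logE0, dlog;
  int nE, nmat;
  const double* pe;   // nE x nmat, linear attenuation per mm
  const double* inc;
  const double* coh;
  std::vector<double> majorant; // per energy node, max over materials
  std::vector<double> brass;    // total linear attenuation of brass per mm

  inline void locate(double E, int& i0, double& f) const {
    double fidx = (std::log(E) - logE0) / dlog;
    if (fidx < 0) fidx = 0;
    if (fidx > nE - 1) fidx = nE - 1;
    i0 = (int)fidx;
    if (i0 > nE - 2) i0 = nE - 2;
    f = fidx - i0;
  }
  inline double at(const double* tab, int m, int i0, double f) const {
    const double* col = tab + (size_t)m * nE;
    return col[i0] * (1 - f) + col[i0 + 1] * f;
  }
  inline double maj(double E) const {
    int i0; double f; locate(E, i0, f);
    // majorant must bound the interpolated value: take the larger node
    double a = majorant[i0], b = majorant[i0 + 1];
    return (a > b ? a : b);
  }
  inline double mu_brass(double E) const {
    int i0; double f; locate(E, i0, f);
    return brass[i0] * (1 - f) + brass[i0 + 1] * f;
  }
};

// ---------------------------------------------------------------------------
// Kahn's rejection method for sampling the Klein-Nishina differential cross
// section. Returns scattered energy and polar cosine; the pair satisfies the
// Compton relation exactly by construction.
static inline void sample_compton_kn(double E, Xoshiro& rng,
                                     double& Eout, double& cost) {
  double x = E / ELECTRON_REST_KEV;
  if (x < 1e-8) { // Thomson limit
    for (;;) {
      double mu = 2.0 * rng.u() - 1.0;
      if (rng.u() <= 0.5 * (1.0 + mu * mu)) { cost = mu; Eout = E; return; }
    }
  }
  for (;;) {
    double r1 = rng.u(), r2 = rng.u(), r3 = rng.u();
    if (r1 <= (2.0 * x + 1.0) / (2.0 * x + 9.0)) {
      double eta = 1.0 + 2.0 * x * r2;
      if (r3 <= 4.0 * (1.0 / eta - 1.0 / (eta * eta))) {
        cost = 1.0 - (eta - 1.0) / x;
        Eout = E / eta;
        return;
      }
    } else {
      double eta = (1.0 + 2.0 * x) / (1.0 + 2.0 * x * r2);
      double cc = 1.0 - (eta - 1.0) / x;
      if (r3 <= 0.5 * (cc * cc + 1.0 / eta)) {
        cost = cc;
        Eout = E / eta;
        return;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double energy, int n, double seed) {
  if (energy <= 0) stop("energy must be positive");
  Xoshiro rng((uint64_t)seed);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double E, c;
    sample_compton_kn(energy, rng, E, c);
    out(i, 0) = E;
    out(i, 1) = c;
  }
  colnames(out) = CharacterVector::create("energy", "cos_theta");
  return out;
}

// Rayleigh: Thomson angular distribution (no form factor).
static inline double sample_thomson(Xoshiro& rng) {
  for (;;) {
    double mu = 2.0 * rng.u() - 1.0;
    if (rng.u() <= 0.5 * (1.0 + mu * mu)) return mu;
  }
}

static inline void rotate_dir(double& ux, double& uy, double& uz,
                              double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  if (std::fabs(uz) > 0.9999999) {
    ux = sint * cphi;
    uy = sint * sphi;
    uz = cost * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = sint * (ux * uz * cphi - uy * sphi) / den + ux * cost;
    double ny = sint * (uy * uz * cphi + ux * sphi) / den + uy * cost;
    double nz = -sint * cphi * den + uz * cost;
    ux = nx; uy = ny; uz = nz;
  }
  double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nn; uy /= nn; uz /= nn;
}

// ---------------------------------------------------------------------------
// One simulation instance.
//
// World frame: collimator entrance plane at z=0, exit at z=thickness; the
// phantom box follows after the air gap (treated as vacuum). All photons are
// started on the entrance plane; brass transmission is applied as a
// statistical weight (or a kill, in ideal-absorber mode).
//
// source$type: 0 pencil, 1 parallel, 2 point, 3 aligned (per-slit fans)
// [[Rcpp::export]]
List cpp_simulate(NumericVector spec_e, NumericVector spec_cdf,
                  List source, Nullable<List> collimator,
                  List phantom, List mu_tables, List cfg) {
  const int src_type = as<int>(source["type"]);
  NumericVector rect = source["rect"]; // xmin xmax ymin ymax on z=0
  const double src_dist = as<double>(source["distance"]); // mm behind entrance

  bool has_colli = collimator.isNotNull();
  Colli colli;
  if (has_colli) colli = Colli::from_list(List(collimator));

  // aligned-mode slit windows
  std::vector<double> al_ce, al_tan;
  double al_w1 = 0;
  if (src_type == 3) {
    if (!has_colli) stop("aligned source mode requires a collimator");
    al_w1 = colli.ww[0];
    for (int k = 0; k < colli.n_slits; ++k) {
      al_tan.push_back(colli.tan_ang[k]);
      al_ce.push_back(colli.offset[k] - colli.thickness * colli.tan_ang[k]);
    }
  }

  IntegerVector mat = phantom["material"];   // 0-based, length nx*ny*nz
  IntegerVector dim = phantom["dim"];
  NumericVector vox = phantom["voxel_size"]; // mm
  NumericVector porig = phantom["origin"];   // world mm, lower corner
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double dx = vox[0], dy = vox[1], dz = vox[2];
  const double ox = porig[0], oy = porig[1], oz = porig[2];
  const double bx1 = ox + nx * dx, by1 = oy + ny * dy, bz1 = oz + nz * dz;

  MuTable mu;
  NumericMatrix pe = mu_tables["pe"], inc = mu_tables["inc"],
                coh = mu_tables["coh"];
  mu.logE0 = as<double>(mu_tables["logE0"]);
  mu.dlog = as<double>(mu_tables["dlog"]);
  mu.nE = pe.nrow();
  mu.nmat = pe.ncol();
  mu.pe = pe.begin(); mu.inc = inc.begin(); mu.coh = coh.begin();
  mu.majorant = as<std::vector<double> >(mu_tables["majorant"]);
  mu.brass = as<std::vector<double> >(mu_tables["brass"]);

  const double n_hist = as<double>(cfg["n_histories"]);
  const double cutoff = as<double>(cfg["cutoff_keV"]);
  const bool primary_only = as<bool>(cfg["primary_only"]);
  const double wmin = as<double>(cfg["weight_min"]);
  Xoshiro rng((uint64_t)as<double>(cfg["seed"]));

  std::vector<double> edep((size_t)nx * ny * nz, 0.0);
  double emitted = 0, in_brass = 0, deposited = 0, escaped = 0;
  const int n_spec = spec_e.size();

  for (double h = 0; h < n_hist; ++h) {
    // --- source energy
    double u = rng.u();
    int lo = 0, hi = n_spec - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    double E = spec_e[lo];
    emitted += E;

    // --- source position/direction on the entrance plane
    double x, y, z = 0.0, ux, uy, uz;
    if (src_type == 0) {            // pencil
      x = 0.5 * (rect[0] + rect[1]); y = 0.5 * (rect[2] + rect[3]);
      ux = 0; uy = 0; uz = 1;
    } else if (src_type == 1) {     // parallel
      x = rect[0] + (rect[1] - rect[0]) * rng.u();
      y = rect[2] + (rect[3] - rect[2]) * rng.u();
      ux = 0; uy = 0; uz = 1;
    } else if (src_type == 2) {     // point source at (0,0,-src_dist)
      x = rect[0] + (rect[1] - rect[0]) * rng.u();
      y = rect[2] + (rect[3] - rect[2]) * rng.u();
      double nn = std::sqrt(x * x + y * y + src_dist * src_dist);
      ux = x / nn; uy = y / nn; uz = src_dist / nn;
    } else {                        // aligned: per-slit axis-parallel fan
      int k = (int)(rng.u() * al_ce.size());
      if (k >= (int)al_ce.size()) k = (int)al_ce.size() - 1;
      x = al_ce[k] + al_w1 * (rng.u() - 0.5);
      y = rect[2] + (rect[3] - rect[2]) * rng.u();
      double tk = al_tan[k];
      double nn = std::sqrt(1.0 + tk * tk);
      ux = tk / nn; uy = 0; uz = 1.0 / nn;
    }

    // --- collimator transmission as statistical weight
    double w = 1.0;
    if (has_colli) {
      double bp = brass_path(colli, x, y, ux, uy, uz);
      if (bp > 0) {
        if (colli.ideal) { in_brass += E; continue; }
        w = std::exp(-mu.mu_brass(E) * bp);
        in_brass += E * (1.0 - w);
        if (w < wmin) { in_brass += E * w; continue; }
      }
      // advance to the exit plane
      double t = (colli.thickness - z) / uz;
      x += t * ux; y += t * uy; z = colli.thickness;
    }

    // --- fly through vacuum to the phantom bounding box
    double tmin = 0.0, tmax = 1e300;
    bool hit = true;
    double pos[3] = {x, y, z}, dir[3] = {ux, uy, uz};
    double blo[3] = {ox, oy, oz}, bhi[3] = {bx1, by1, bz1};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(dir[a]) < 1e-14) {
        if (pos[a] <= blo[a] || pos[a] >= bhi[a]) { hit = false; break; }
      } else {
        double t1 = (blo[a] - pos[a]) / dir[a];
        double t2 = (bhi[a] - pos[a]) / dir[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (!hit || tmax <= tmin) { escaped += w * E; continue; }
    x += (tmin + 1e-9) * ux; y += (tmin + 1e-9) * uy; z += (tmin + 1e-9) * uz;

    // --- Woodcock tracking inside the phantom
    for (;;) {
      double sig = mu.maj(E);
      double s = -std::log(rng.u()) / sig;
      x += s * ux; y += s * uy; z += s * uz;
      if (x <= ox || x >= bx1 || y <= oy || y >= by1 || z <= oz || z >= bz1) {
        escaped += w * E;
        break;
      }
      int ix = (int)((x - ox) / dx); if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
      int iy = (int)((y - oy) / dy); if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
      int iz = (int)((z - oz) / dz); if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
      size_t idx = (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
      int m = mat[idx];
      int i0; double f;
      mu.locate(E, i0, f);
      double mpe = mu.at(mu.pe, m, i0, f);
      double minc = mu.at(mu.inc, m, i0, f);
      double mcoh = mu.at(mu.coh, m, i0, f);
      double mtot = mpe + minc + mcoh;
      if (mtot > sig * (1.0 + 1e-9))
        stop("majorant violation: local attenuation exceeds majorant");
      if (rng.u() * sig > mtot) continue; // virtual interaction

      if (primary_only) { // absorb at first real interaction
        edep[idx] += w * E; deposited += w * E;
        break;
      }
      double r = rng.u() * mtot;
      if (r < mpe) { // photoelectric: full local absorption
        edep[idx] += w * E; deposited += w * E;
        break;
      } else if (r < mpe + minc) { // Compton, kerma approximation
        double Ep, cost;
        sample_compton_kn(E, rng, Ep, cost);
        edep[idx] += w * (E - Ep); deposited += w * (E - Ep);
        E = Ep;
        if (E <= cutoff) {
          edep[idx] += w * E; deposited += w * E;
          break;
        }
        rotate_dir(ux, uy, uz, cost, 2.0 * M_PI * rng.u());
      } else { // Rayleigh: direction change only
        rotate_dir(ux, uy, uz, sample_thomson(rng), 2.0 * M_PI * rng.u());
      }
    }
  }

  return List::create(
    _["edep"] = NumericVector(edep.begin(), edep.end()),
    _["emitted"] = emitted,
    _["absorbed_collimator"] = in_brass,
    _["deposited"] = deposited,
    _["escaped"] = escaped,
    _["n_histories"] = n_hist);
}
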