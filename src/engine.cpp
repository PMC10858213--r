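// Agent-based engine core: 20 s stepping of the alveolar segment
// (secretion -> diffusion -> agent behaviors -> shell projection) plus the
// FTCS reaction-diffusion kernels shared with the R-level grid API.
//
// Cell type codes: 1 AEC1, 2 AEC2, 3 fibroblast, 4 myofibroblast, 5 M1, 6 M2.
// State codes: 0 healthy, 1 damaged, 2 senescent, 3 apoptotic.
// Substance column order (fixed, checked on the R side):
// 0 MCP1, 1 SASP, 2 IL6, 3 TNF, 4 MMP, 5 TIMP, 6 ECM, 7 TGFB, 8 PDGF, 9 IL13.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// splitmix64 stream: bit-reproducible across platforms for a given seed.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double runif() {  // in (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) / 9007199254740992.0;
  }
  double rnorm() {
    double u1 = runif(), u2 = runif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  int rpois(double lambda) {
    if (lambda <= 0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= runif(); } while (p > L);
      return k - 1;
    }
    double v = lambda + std::sqrt(lambda) * rnorm();
    return v < 0 ? 0 : static_cast<int>(v + 0.5);
  }
};

// --------------------------------------------------------- FTCS kernel ----
static void ftcs_step(std::vector<double> &c, std::vector<double> &buf,
                      int nx, int ny, int nz, double h,
                      double D, double decay, double dt) {
  const double a = D * dt / (h * h);
  const int sx = 1, sy = nx, sz = nx * ny;
  buf.assign(c.size(), 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = i + nx * (j + ny * k);
        double lap = 0.0;
        const double cv = c[v];
        // Neumann zero-flux: a missing neighbor mirrors the center value,
        // contributing zero to the flux sum.
        if (i > 0)      lap += c[v - sx] - cv;
        if (i < nx - 1) lap += c[v + sx] - cv;
        if (j > 0)      lap += c[v - sy] - cv;
        if (j < ny - 1) lap += c[v + sy] - cv;
        if (k > 0)      lap += c[v - sz] - cv;
        if (k < nz - 1) lap += c[v + sz] - cv;
        buf[v] = cv + a * lap - decay * dt * cv;
      }
  c.swap(buf);
}

// [[Rcpp::export]]
NumericMatrix cpp_step_ftcs(NumericMatrix conc, int nx, int ny, int nz,
                            double h, NumericVector D, NumericVector decay,
                            double dt) {
  const int nv = nx * ny * nz, ns = conc.ncol();
  if (conc.nrow() != nv) stop("conc rows do not match the voxel count");
  NumericMatrix out(nv, ns);
  std::vector<double> c(nv), buf;
  for (int s = 0; s < ns; ++s) {
    for (int v = 0; v < nv; ++v) c[v] = conc(v, s);
    ftcs_step(c, buf, nx, ny, nz, h, D[s], decay[s], dt);
    for (int v = 0; v < nv; ++v) out(v, s) = c[v];
  }
  return out;
}

// Clamped mass-action depletion. mode 1 (annihilate): both partners lose the
// same amount r = min(k*a*b*dt, a, b) -- the difference a-b is an exact
// invariant. mode 2 (degrade): only b is consumed, implicit-in-sink
// b / (1 + k*a*dt), never negative.
// [[Rcpp::export]]
NumericMatrix cpp_apply_couplings(NumericMatrix conc, IntegerVector ia,
                                  IntegerVector ib, NumericVector k,
                                  IntegerVector mode, double dt) {
  NumericMatrix out = clone(conc);
  const int nv = out.nrow();
  for (int p = 0; p < ia.size(); ++p) {
    const int A = ia[p] - 1, B = ib[p] - 1;
    for (int v = 0; v < nv; ++v) {
      double a = out(v, A), b = out(v, B);
      if (a <= 0.0 || b <= 0.0) continue;
      if (mode[p] == 1) {
        double r = k[p] * a * b * dt;
        if (r > a) r = a;
        if (r > b) r = b;
        out(v, A) = a - r;
        out(v, B) = b - r;
      } else {
        out(v, B) = b / (1.0 + k[p] * a * dt);
      }
    }
  }
  return out;
}

// ------------------------------------------------------------- World ------
enum Sub { MCP1 = 0, SASP, IL6, TNF, MMP, TIMP, ECM, TGFB, PDGF, IL13 };

struct World {
  std::vector<int> id, type, state, alv, byst, phago_left, removal, phag_n;
  std::vector<double> x, y, z, radius;
  std::vector<char> dead;
  // alveoli
  std::vector<double> acx, acy, acz;
  double shell_in, shell_mid, shell_out;
  // grid
  int nx, ny, nz;
  double h, ox, oy, oz, ecm_sat;
  std::vector<std::vector<double>> conc;  // [substance][voxel]
  std::vector<double> D, decay;
  std::vector<int> cia, cib, cmode;
  std::vector<double> ck;
  long births = 0, removals = 0;
  int next_id;

  size_t n() const { return id.size(); }
  int voxel(double px, double py, double pz) const {
    int i = static_cast<int>(std::floor((px - ox) / h));
    int j = static_cast<int>(std::floor((py - oy) / h));
    int k = static_cast<int>(std::floor((pz - oz) / h));
    i = i < 0 ? 0 : (i >= nx ? nx - 1 : i);
    j = j < 0 ? 0 : (j >= ny ? ny - 1 : j);
    k = k < 0 ? 0 : (k >= nz ? nz - 1 : k);
    return i + nx * (j + ny * k);
  }
  double shell_radius(int t) const {
    if (t == 1 || t == 2) return shell_mid;
    if (t == 3 || t == 4) return shell_out;
    return shell_in;
  }
  void project(size_t i) {
    const int a = alv[i] - 1;
    double dx = x[i] - acx[a], dy = y[i] - acy[a], dz = z[i] - acz[a];
    double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (nrm <= 0) return;
    double f = shell_radius(type[i]) / nrm;
    x[i] = acx[a] + dx * f; y[i] = acy[a] + dy * f; z[i] = acz[a] + dz * f;
  }
  void add_agent(int t, int st, int a, double px, double py, double pz,
                 double rad, int pleft) {
    id.push_back(next_id++); type.push_back(t); state.push_back(st);
    alv.push_back(a); x.push_back(px); y.push_back(py); z.push_back(pz);
    radius.push_back(rad); byst.push_back(0); phago_left.push_back(pleft);
    removal.push_back(-1); phag_n.push_back(0); dead.push_back(0);
    ++births;
  }
  void kill(size_t i) { if (!dead[i]) { dead[i] = 1; ++removals; } }
  void compact() {
    size_t w = 0;
    for (size_t i = 0; i < n(); ++i) {
      if (dead[i]) continue;
      if (w != i) {
        id[w] = id[i]; type[w] = type[i]; state[w] = state[i];
        alv[w] = alv[i]; x[w] = x[i]; y[w] = y[i]; z[w] = z[i];
        radius[w] = radius[i]; byst[w] = byst[i];
        phago_left[w] = phago_left[i]; removal[w] = removal[i];
        phag_n[w] = phag_n[i]; dead[w] = 0;
      }
      ++w;
    }
    id.resize(w); type.resize(w); state.resize(w); alv.resize(w);
    x.resize(w); y.resize(w); z.resize(w); radius.resize(w);
    byst.resize(w); phago_left.resize(w); removal.resize(w);
    phag_n.resize(w); dead.resize(w);
  }
};

struct Cfg {
  double dt;
  double speed_mac, speed_mes, speed_epi, speed_impaired, immobility_prob;
  double neighbor_radius, sense_radius, contact_range;
  int bystander_threshold;
  double bystander_k;                    // 1/s per exposure step
  double bystander_fade;                 // counter fade prob when unexposed
  double damaged_to_senescent_rate;      // 1/day
  double apoptotic_removal_mean_steps;
  double aec1_death_rate, aec2_death_rate, aec2_prolif_rate, aec2_diff_rate;
  double repop_gain, repop_K;
  double n_aec1_target, n_aec2_target, n_epi_target;
  double fib_prolif_rate, fib_death_rate, fib_gf_gain, fib_dis_gain;
  double n_fib_target;
  double act_rate, act_gf_w, act_dis_w, gf_K, mcp_K, dis_deadzone;
  double myo_ecm_secretion, ecm_act_gain;
  double mcp1_secretion, gf_secretion, mmp_secretion, timp_secretion,
         sasp_secretion;
  double recruit_rate, mac_cap, mac_lifespan_steps;
  int phagocytic_index;
  double phagocytic_fraction;
  double cell_jitter;
};

static double cfgd(const List &c, const char *nm) {
  if (!c.containsElementNamed(nm))
    stop(std::string("engine config is missing '") + nm + "'");
  return as<double>(c[nm]);
}

static Cfg parse_cfg(const List &c) {
  Cfg f;
  f.dt = cfgd(c, "dt");
  f.speed_mac = cfgd(c, "speed_mac");
  f.speed_mes = cfgd(c, "speed_mes");
  f.speed_epi = cfgd(c, "speed_epi");
  f.speed_impaired = cfgd(c, "speed_impaired");
  f.immobility_prob = cfgd(c, "immobility_prob");
  f.neighbor_radius = cfgd(c, "neighbor_radius");
  f.sense_radius = cfgd(c, "sense_radius");
  f.contact_range = cfgd(c, "contact_range");
  f.bystander_threshold = static_cast<int>(cfgd(c, "bystander_threshold"));
  f.bystander_k = cfgd(c, "bystander_k");
  f.bystander_fade = cfgd(c, "bystander_fade");
  f.damaged_to_senescent_rate = cfgd(c, "damaged_to_senescent_rate");
  f.apoptotic_removal_mean_steps = cfgd(c, "apoptotic_removal_mean_steps");
  f.aec1_death_rate = cfgd(c, "aec1_death_rate");
  f.aec2_death_rate = cfgd(c, "aec2_death_rate");
  f.aec2_prolif_rate = cfgd(c, "aec2_prolif_rate");
  f.aec2_diff_rate = cfgd(c, "aec2_diff_rate");
  f.repop_gain = cfgd(c, "repop_gain");
  f.repop_K = cfgd(c, "repop_K");
  f.n_aec1_target = cfgd(c, "n_aec1_target");
  f.n_aec2_target = cfgd(c, "n_aec2_target");
  f.n_epi_target = f.n_aec1_target + f.n_aec2_target;
  f.fib_prolif_rate = cfgd(c, "fib_prolif_rate");
  f.n_fib_target = cfgd(c, "n_fib_target");
  f.fib_death_rate = cfgd(c, "fib_death_rate");
  f.fib_gf_gain = cfgd(c, "fib_gf_gain");
  f.fib_dis_gain = cfgd(c, "fib_dis_gain");
  f.act_rate = cfgd(c, "act_rate");
  f.act_gf_w = cfgd(c, "act_gf_w");
  f.act_dis_w = cfgd(c, "act_dis_w");
  f.gf_K = cfgd(c, "gf_K");
  f.dis_deadzone = cfgd(c, "dis_deadzone");
  f.mcp_K = cfgd(c, "mcp_K");
  f.myo_ecm_secretion = cfgd(c, "myo_ecm_secretion");
  f.ecm_act_gain = cfgd(c, "ecm_act_gain");
  f.mcp1_secretion = cfgd(c, "mcp1_secretion");
  f.gf_secretion = cfgd(c, "gf_secretion");
  f.mmp_secretion = cfgd(c, "mmp_secretion");
  f.timp_secretion = cfgd(c, "timp_secretion");
  f.sasp_secretion = cfgd(c, "sasp_secretion");
  f.recruit_rate = cfgd(c, "recruit_rate");
  f.mac_lifespan_steps = cfgd(c, "mac_lifespan_steps");
  f.mac_cap = cfgd(c, "mac_cap");
  f.phagocytic_index = static_cast<int>(cfgd(c, "phagocytic_index"));
  f.phagocytic_fraction = cfgd(c, "phagocytic_fraction");
  f.cell_jitter = cfgd(c, "cell_jitter");
  return f;
}

// geodesic step of given arc length from p along tangent direction t (both
// relative to the alveolus center); exact rotation on the sphere.
static void arc_step(double &px, double &py, double &pz,
                     double cx, double cy, double cz,
                     double tx, double ty, double tz, double arc) {
  double dx = px - cx, dy = py - cy, dz = pz - cz;
  double R = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (R <= 0 || arc <= 0) return;
  // remove radial component of t, normalize
  double dot = (tx * dx + ty * dy + tz * dz) / (R * R);
  tx -= dot * dx; ty -= dot * dy; tz -= dot * dz;
  double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
  if (tn <= 1e-12) return;
  tx /= tn; ty /= tn; tz /= tn;
  double th = arc / R, ct = std::cos(th), st = std::sin(th);
  px = cx + ct * dx + st * R * tx;
  py = cy + ct * dy + st * R * ty;
  pz = cz + ct * dz + st * R * tz;
}

static void random_tangent(Rng &rng, double &tx, double &ty, double &tz) {
  // isotropic direction; the radial component is removed in arc_step
  double zc = 2.0 * rng.runif() - 1.0, ph = 6.283185307179586 * rng.runif();
  double sc = std::sqrt(std::max(0.0, 1.0 - zc * zc));
  tx = sc * std::cos(ph); ty = sc * std::sin(ph); tz = zc;
}

// ------------------------------------------------------------ phases ------
struct AlvStats {
  std::vector<int> epi, aec1, aec2_healthy, macs, fib;
};

static AlvStats alv_stats(const World &w) {
  AlvStats s;
  const size_t na = w.acx.size();
  s.epi.assign(na, 0); s.aec1.assign(na, 0);
  s.aec2_healthy.assign(na, 0); s.macs.assign(na, 0);
  s.fib.assign(na, 0);
  for (size_t i = 0; i < w.n(); ++i) {
    if (w.dead[i]) continue;
    const int a = w.alv[i] - 1, t = w.type[i];
    if ((t == 1 || t == 2) && w.state[i] != 3) s.epi[a]++;
    if (t == 1) s.aec1[a]++;
    if (t == 2 && w.state[i] == 0) s.aec2_healthy[a]++;
    if (t == 5 || t == 6) s.macs[a]++;
    if (t == 3) s.fib[a]++;
  }
  return s;
}

// signed saturating response, symmetric near zero (slope gain/K): keeps the
// stochastic equilibrium centered on the homeostatic target instead of
// rectifying count noise into a bias.
static double regulation(double deficit, double gain, double K) {
  double m = 1.0 + gain * deficit / (K + std::fabs(deficit));
  return m > 0 ? m : 0.0;
}

static double sat(double c, double K) { return c > 0 ? c / (K + c) : 0.0; }

static void phase_secrete(World &w, const Cfg &f) {
  const double per_step = f.dt / 86400.0;  // config rates are per day
  for (size_t i = 0; i < w.n(); ++i) {
    if (w.dead[i]) continue;
    const int v = w.voxel(w.x[i], w.y[i], w.z[i]);
    const int t = w.type[i], st = w.state[i];
    if (t == 2 && (st == 1 || st == 2)) {        // damaged/senescent AEC2
      w.conc[MCP1][v] += f.mcp1_secretion * per_step;
      w.conc[SASP][v] += f.sasp_secretion * per_step;
      w.conc[IL6][v] += 0.5 * f.sasp_secretion * per_step;
      w.conc[TNF][v] += 0.5 * f.sasp_secretion * per_step;
    } else if (t == 4) {                         // myofibroblast: ECM
      double act = 1.0 + f.ecm_act_gain * sat(w.conc[TGFB][v], f.gf_K);
      double add = f.myo_ecm_secretion * act * per_step;
      double cur = w.conc[ECM][v];
      w.conc[ECM][v] = std::min(cur + add, std::max(cur, w.ecm_sat));
    } else if (t == 6) {                         // M2, MCP1-activated
      double act = sat(w.conc[MCP1][v], f.mcp_K);
      w.conc[TGFB][v] += f.gf_secretion * act * per_step;
      w.conc[PDGF][v] += 0.5 * f.gf_secretion * act * per_step;
      w.conc[IL13][v] += 0.5 * f.gf_secretion * act * per_step;
    } else if (t == 5) {                         // M1, MCP1-activated
      double act = sat(w.conc[MCP1][v], f.mcp_K);
      w.conc[MMP][v] += f.mmp_secretion * act * per_step;
      w.conc[TNF][v] += 0.5 * f.mmp_secretion * act * per_step;
    } else if (t == 3) {                         // fibroblast: TIMP vs MMP
      double act = sat(w.conc[MMP][v], f.mcp_K);
      w.conc[TIMP][v] += f.timp_secretion * act * per_step;
    }
  }
}

static void phase_diffuse(World &w, const Cfg &f, std::vector<double> &buf) {
  for (size_t s = 0; s < w.conc.size(); ++s)
    if (w.D[s] > 0 || w.decay[s] > 0)
      ftcs_step(w.conc[s], buf, w.nx, w.ny, w.nz, w.h, w.D[s], w.decay[s],
                f.dt);
  for (size_t p = 0; p < w.cia.size(); ++p) {
    const int A = w.cia[p], B = w.cib[p];
    const int nv = w.nx * w.ny * w.nz;
    for (int v = 0; v < nv; ++v) {
      double a = w.conc[A][v], b = w.conc[B][v];
      if (a <= 0 || b <= 0) continue;
      if (w.cmode[p] == 1) {
        double r = w.ck[p] * a * b * f.dt;
        if (r > a) r = a;
        if (r > b) r = b;
        w.conc[A][v] = a - r; w.conc[B][v] = b - r;
      } else {
        w.conc[B][v] = b / (1.0 + w.ck[p] * a * f.dt);
      }
    }
  }
}

// healthy AEC2 exposure accounting + conversion to damaged
static void phase_bystander(World &w, const Cfg &f, Rng &rng,
                            const std::vector<std::vector<int>> &by_alv) {
  const double r2 = f.neighbor_radius * f.neighbor_radius;
  for (const auto &idx : by_alv) {
    std::vector<int> sen;
    for (int i : idx)
      if (!w.dead[i] && w.type[i] == 2 && w.state[i] == 2) sen.push_back(i);
    for (int i : idx) {
      if (w.dead[i] || w.type[i] != 2 || w.state[i] != 0) continue;
      int cnt = 0;
      for (int j : sen) {
        double dx = w.x[i] - w.x[j], dy = w.y[i] - w.y[j],
               dz = w.z[i] - w.z[j];
        if (dx * dx + dy * dy + dz * dz < r2) {
          if (++cnt >= f.bystander_threshold) break;
        }
      }
      if (cnt >= f.bystander_threshold) w.byst[i]++;
      else if (w.byst[i] > 0 && rng.runif() < f.bystander_fade)
        w.byst[i]--;  // exposure memory fades slowly when unexposed
      // the conversion hazard acts while accumulated exposure persists
      if (w.byst[i] > 0) {
        double p = f.bystander_k * w.byst[i] * f.dt;
        if (p > 1) p = 1;
        if (rng.runif() < p) w.state[i] = 1;  // healthy -> damaged
      }
    }
  }
}

static void phase_senesce(World &w, const Cfg &f, Rng &rng) {
  const double p = f.damaged_to_senescent_rate * f.dt / 86400.0;
  for (size_t i = 0; i < w.n(); ++i)
    if (!w.dead[i] && w.type[i] == 2 && w.state[i] == 1 && rng.runif() < p)
      w.state[i] = 2;
}

static void phase_apoptotic(World &w, const Cfg &f, Rng &rng) {
  for (size_t i = 0; i < w.n(); ++i) {
    if (w.dead[i]) continue;
    if (w.state[i] == 3) {
      if (w.removal[i] < 0)  // just entered: draw the Poisson removal delay
        w.removal[i] = rng.rpois(f.apoptotic_removal_mean_steps);
      if (w.removal[i] == 0) w.kill(i);
      else w.removal[i]--;
    } else if ((w.type[i] == 5 || w.type[i] == 6) && w.removal[i] >= 0) {
      // recruited macrophage residence countdown
      if (w.removal[i] == 0) w.kill(i);
      else w.removal[i]--;
    }
  }
}

static void phase_phagocytose(World &w, const Cfg &f,
                              const std::vector<std::vector<int>> &by_alv) {
  const double r2 = f.contact_range * f.contact_range;
  for (const auto &idx : by_alv) {
    std::vector<int> sen;
    for (int i : idx)
      if (!w.dead[i] && w.type[i] == 2 && w.state[i] == 2) sen.push_back(i);
    if (sen.empty()) continue;
    for (int m : idx) {
      if (w.dead[m] || (w.type[m] != 5 && w.type[m] != 6)) continue;
      if (w.phago_left[m] <= 0) continue;  // non-phagocytic or exhausted
      for (int j : sen) {
        if (w.dead[j] || w.phago_left[m] <= 0) continue;
        double dx = w.x[m] - w.x[j], dy = w.y[m] - w.y[j],
               dz = w.z[m] - w.z[j];
        if (dx * dx + dy * dy + dz * dz < r2) {
          w.kill(j);
          w.phago_left[m]--;
          w.phag_n[m]++;
        }
      }
      if (w.phago_left[m] == 0) w.kill(m);  // capacity spent: leaves
    }
  }
}

static void phase_recruit(World &w, const Cfg &f, Rng &rng,
                          const AlvStats &s) {
  const double per_step = f.dt / 86400.0;
  for (size_t a = 0; a < w.acx.size(); ++a) {
    const int v = w.voxel(w.acx[a], w.acy[a], w.acz[a]);
    const double c = w.conc[MCP1][v];
    if (c <= 0) continue;                  // zero influx at baseline MCP-1
    if (s.macs[a] >= f.mac_cap) continue;
    int k = rng.rpois(f.recruit_rate * c * per_step);
    for (int q = 0; q < k && s.macs[a] + q < f.mac_cap; ++q) {
      double tx, ty, tz;
      random_tangent(rng, tx, ty, tz);
      int t = rng.runif() < 0.5 ? 5 : 6;
      int pleft = rng.runif() < f.phagocytic_fraction
                    ? f.phagocytic_index : -1;
      w.add_agent(t, 0, static_cast<int>(a) + 1,
                  w.acx[a] + w.shell_in * tx, w.acy[a] + w.shell_in * ty,
                  w.acz[a] + w.shell_in * tz, 10.5, pleft);
      // monocyte-derived macrophages have a finite residence time;
      // resident macrophages (removal = -1) are permanent
      w.removal.back() = rng.rpois(f.mac_lifespan_steps);
    }
  }
}

static void phase_repopulate(World &w, const Cfg &f, Rng &rng,
                             const AlvStats &s) {
  const double per_step = f.dt / 86400.0;
  const size_t n0 = w.n();  // newborns this step do not act
  for (size_t i = 0; i < n0; ++i) {
    if (w.dead[i]) continue;
    const int a = w.alv[i] - 1, t = w.type[i];
    const double d1 = (f.n_aec1_target - s.aec1[a]) / f.n_aec1_target;
    const double d2 =
      (f.n_aec2_target - s.aec2_healthy[a]) / f.n_aec2_target;
    // births carry the regulation multiplier m; deaths carry its mirror
    // max(0, 2 - m), so restoring is symmetric around the target and count
    // noise is not rectified into a bias
    const double m1 = regulation(d1, f.repop_gain, f.repop_K);
    const double m2 = regulation(d2, f.repop_gain, f.repop_K);
    if (t == 1) {
      double md = std::max(0.0, 2.0 - m1);
      if (rng.runif() < f.aec1_death_rate * md * per_step) w.kill(i);
    } else if (t == 2 && w.state[i] == 0) {
      if (s.aec2_healthy[a] == 0) continue;  // absorbing FSU death guard
      if (rng.runif() < f.aec2_prolif_rate * m2 * per_step) {
        double tx, ty, tz;
        random_tangent(rng, tx, ty, tz);
        double px = w.x[i], py = w.y[i], pz = w.z[i];
        arc_step(px, py, pz, w.acx[a], w.acy[a], w.acz[a], tx, ty, tz,
                 f.cell_jitter);
        w.add_agent(2, 0, a + 1, px, py, pz, w.radius[i], -1);
      }
      if (rng.runif() < f.aec2_diff_rate * m1 * per_step)
        w.type[i] = 1;                        // AEC2 -> AEC1
      else if (rng.runif() <
               f.aec2_death_rate * std::max(0.0, 2.0 - m2) * per_step) {
        w.state[i] = 3;                       // aging: apoptotic, delayed
        w.removal[i] = -1;
      }
    }
  }
}

static void phase_mesenchymal(World &w, const Cfg &f, Rng &rng,
                              const AlvStats &s) {
  const double per_step = f.dt / 86400.0;
  const size_t n0 = w.n();
  for (size_t i = 0; i < n0; ++i) {
    if (w.dead[i] || w.type[i] != 3) continue;
    const int a = w.alv[i] - 1;
    const int v = w.voxel(w.x[i], w.y[i], w.z[i]);
    const double gf = sat(w.conc[TGFB][v], f.gf_K);
    // disruption response has a dead zone: homeostatic count noise does
    // not activate the mesenchymal compartment
    double dis = (f.n_epi_target - s.epi[a]) / f.n_epi_target
                 - f.dis_deadzone;
    if (dis < 0) dis = 0;
    // additive composition: the deficit regulation keeps the homeostatic
    // count centered, while the growth-factor/disruption terms drive the
    // fibrotic expansion even when the count exceeds its baseline target
    const double dfib = (f.n_fib_target - s.fib[a]) / f.n_fib_target;
    const double mfib = regulation(dfib, f.repop_gain, f.repop_K);
    const double mult = mfib + f.fib_gf_gain * gf + f.fib_dis_gain * dis;
    if (rng.runif() < f.fib_prolif_rate * mult * per_step) {
      double tx, ty, tz;
      random_tangent(rng, tx, ty, tz);
      double px = w.x[i], py = w.y[i], pz = w.z[i];
      arc_step(px, py, pz, w.acx[a], w.acy[a], w.acz[a], tx, ty, tz,
               f.cell_jitter);
      w.add_agent(3, 0, a + 1, px, py, pz, w.radius[i], -1);
    }
    const double act = f.act_rate * (f.act_gf_w * gf + f.act_dis_w * dis);
    if (act > 0 && rng.runif() < act * per_step) {
      w.type[i] = 4;                          // fibroblast -> myofibroblast
      w.radius[i] = 8.0;
    } else if (rng.runif() <
               f.fib_death_rate * std::max(0.0, 2.0 - mfib) * per_step) {
      w.kill(i);
    }
  }
}

static void phase_migrate(World &w, const Cfg &f, Rng &rng,
                          const std::vector<std::vector<int>> &by_alv) {
  const double sense2 = f.sense_radius * f.sense_radius;
  for (const auto &idx : by_alv) {
    // epithelial positions for neighborhood-informed migration
    std::vector<int> epi;
    for (int i : idx)
      if (!w.dead[i] && (w.type[i] == 1 || w.type[i] == 2) &&
          w.state[i] != 3)
        epi.push_back(i);
    for (int i : idx) {
      if (w.dead[i] || w.state[i] == 3) continue;  // apoptotic: no movement
      const int t = w.type[i];
      double speed;
      bool informed = false;
      if (t == 5 || t == 6) speed = f.speed_mac;
      else if (t == 3 || t == 4) speed = f.speed_mes;
      else if (w.state[i] == 0) { speed = f.speed_epi; informed = true; }
      else {  // damaged/senescent: slower, sometimes unable to move
        if (rng.runif() < f.immobility_prob) continue;
        speed = f.speed_impaired;
      }
      if (speed <= 0) continue;
      double tx = 0, ty = 0, tz = 0;
      bool have_dir = false;
      if (informed) {
        // repulsion from epithelial neighbors: net step toward depleted zones
        for (int j : epi) {
          if (j == i) continue;
          double dx = w.x[i] - w.x[j], dy = w.y[i] - w.y[j],
                 dz = w.z[i] - w.z[j];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > 1e-12 && d2 < sense2) {
            double inv = 1.0 / std::sqrt(d2);
            tx += dx * inv; ty += dy * inv; tz += dz * inv;
          }
        }
        have_dir = (tx * tx + ty * ty + tz * tz) > 1e-6;
      }
      if (!have_dir) random_tangent(rng, tx, ty, tz);
      const int a = w.alv[i] - 1;
      arc_step(w.x[i], w.y[i], w.z[i], w.acx[a], w.acy[a], w.acz[a],
               tx, ty, tz, speed);
      w.project(i);
    }
  }
}

// --------------------------------------------------------- run driver -----
static World parse_world(const List &agents, const List &alveoli,
                         const NumericVector &shells,
                         const NumericMatrix &conc, const IntegerVector &dims,
                         double h, const NumericVector &origin,
                         const NumericVector &D, const NumericVector &decay,
                         const IntegerVector &ia, const IntegerVector &ib,
                         const NumericVector &ck, const IntegerVector &cmode,
                         double ecm_sat, int next_id) {
  World w;
  w.id = as<std::vector<int>>(agents["id"]);
  w.type = as<std::vector<int>>(agents["type"]);
  w.state = as<std::vector<int>>(agents["state"]);
  w.alv = as<std::vector<int>>(agents["alv"]);
  w.x = as<std::vector<double>>(agents["x"]);
  w.y = as<std::vector<double>>(agents["y"]);
  w.z = as<std::vector<double>>(agents["z"]);
  w.radius = as<std::vector<double>>(agents["radius"]);
  w.byst = as<std::vector<int>>(agents["byst"]);
  w.phago_left = as<std::vector<int>>(agents["phago_left"]);
  w.removal = as<std::vector<int>>(agents["removal"]);
  w.phag_n = as<std::vector<int>>(agents["phag_n"]);
  w.dead.assign(w.n(), 0);
  w.acx = as<std::vector<double>>(alveoli["cx"]);
  w.acy = as<std::vector<double>>(alveoli["cy"]);
  w.acz = as<std::vector<double>>(alveoli["cz"]);
  w.shell_in = shells[0]; w.shell_mid = shells[1]; w.shell_out = shells[2];
  w.nx = dims[0]; w.ny = dims[1]; w.nz = dims[2];
  w.h = h; w.ox = origin[0]; w.oy = origin[1]; w.oz = origin[2];
  w.ecm_sat = ecm_sat;
  const int nv = w.nx * w.ny * w.nz, ns = conc.ncol();
  w.conc.assign(ns, std::vector<double>(nv));
  for (int s = 0; s < ns; ++s)
    for (int v = 0; v < nv; ++v) w.conc[s][v] = conc(v, s);
  w.D = as<std::vector<double>>(D);
  w.decay = as<std::vector<double>>(decay);
  for (int p = 0; p < ia.size(); ++p) {
    w.cia.push_back(ia[p] - 1);
    w.cib.push_back(ib[p] - 1);
    w.ck.push_back(ck[p]);
    w.cmode.push_back(cmode[p]);
  }
  w.next_id = next_id;
  return w;
}

static std::vector<std::vector<int>> group_by_alveolus(const World &w) {
  std::vector<std::vector<int>> g(w.acx.size());
  for (size_t i = 0; i < w.n(); ++i)
    if (!w.dead[i]) g[w.alv[i] - 1].push_back(static_cast<int>(i));
  return g;
}

// one full step; `enabled` bitmask over phases in fixed execution order
enum Phase { P_SECRETE = 1, P_DIFFUSE = 2, P_BYSTANDER = 4, P_SENESCE = 8,
             P_APOPTOTIC = 16, P_PHAGOCYTOSE = 32, P_RECRUIT = 64,
             P_REPOPULATE = 128, P_MESENCHYMAL = 256, P_MIGRATE = 512 };

static void world_step(World &w, const Cfg &f, Rng &rng, int enabled,
                       std::vector<double> &buf) {
  if (enabled & P_SECRETE) phase_secrete(w, f);
  if (enabled & P_DIFFUSE) phase_diffuse(w, f, buf);
  AlvStats s = alv_stats(w);
  auto groups = group_by_alveolus(w);
  if (enabled & P_BYSTANDER) phase_bystander(w, f, rng, groups);
  if (enabled & P_SENESCE) phase_senesce(w, f, rng);
  if (enabled & P_APOPTOTIC) phase_apoptotic(w, f, rng);
  if (enabled & P_PHAGOCYTOSE) phase_phagocytose(w, f, groups);
  if (enabled & P_RECRUIT) phase_recruit(w, f, rng, s);
  if (enabled & P_REPOPULATE) phase_repopulate(w, f, rng, s);
  if (enabled & P_MESENCHYMAL) phase_mesenchymal(w, f, rng, s);
  if (enabled & P_MIGRATE) phase_migrate(w, f, rng, groups);
  w.compact();
}

static int phase_mask(const CharacterVector &phases) {
  int m = 0;
  for (int i = 0; i < phases.size(); ++i) {
    std::string p = as<std::string>(phases[i]);
    if (p == "all") return 1023;
    else if (p == "secrete") m |= P_SECRETE;
    else if (p == "diffuse") m |= P_DIFFUSE;
    else if (p == "bystander") m |= P_BYSTANDER;
    else if (p == "senesce") m |= P_SENESCE;
    else if (p == "apoptotic") m |= P_APOPTOTIC;
    else if (p == "phagocytose") m |= P_PHAGOCYTOSE;
    else if (p == "recruit") m |= P_RECRUIT;
    else if (p == "repopulate") m |= P_REPOPULATE;
    else if (p == "mesenchymal") m |= P_MESENCHYMAL;
    else if (p == "migrate") m |= P_MIGRATE;
    else stop("unknown engine phase: " + p);
  }
  return m;
}

static void record_row(const World &w, std::vector<double> &out, long step) {
  // counts
  double c[12] = {0};  // AEC1, AEC2h, AEC2d, AEC2s, AEC2a, FIB, MYO, M1, M2
  int fsu = 0;
  std::vector<int> healthy_per_alv(w.acx.size(), 0);
  for (size_t i = 0; i < w.n(); ++i) {
    if (w.dead[i]) continue;
    const int t = w.type[i], st = w.state[i];
    if (t == 1) c[0]++;
    else if (t == 2) {
      if (st == 0) { c[1]++; healthy_per_alv[w.alv[i] - 1]++; }
      else if (st == 1) c[2]++;
      else if (st == 2) c[3]++;
      else c[4]++;
    } else if (t == 3) c[5]++;
    else if (t == 4) c[6]++;
    else if (t == 5) c[7]++;
    else c[8]++;
  }
  for (size_t a = 0; a < healthy_per_alv.size(); ++a)
    if (healthy_per_alv[a] > 0) fsu++;
  out.push_back(static_cast<double>(step));
  for (int q = 0; q < 9; ++q) out.push_back(c[q]);
  out.push_back(static_cast<double>(fsu));
  out.push_back(static_cast<double>(w.births));
  out.push_back(static_cast<double>(w.removals));
  const int nv = w.nx * w.ny * w.nz;
  for (size_t s = 0; s < w.conc.size(); ++s) {
    double tot = 0;
    for (int v = 0; v < nv; ++v) tot += w.conc[s][v];
    out.push_back(tot / nv);
  }
}

// [[Rcpp::export]]
List cpp_run_world(List agents, List alveoli, NumericVector shells,
                   NumericMatrix conc, IntegerVector dims, double h,
                   NumericVector origin, NumericVector D,
                   NumericVector decay, IntegerVector cia, IntegerVector cib,
                   NumericVector ck, IntegerVector cmode, double ecm_sat,
                   int next_id, List config, int n_steps, double seed,
                   long clock0, int record_every, CharacterVector phases) {
  World w = parse_world(agents, alveoli, shells, conc, dims, h, origin, D,
                        decay, cia, cib, ck, cmode, ecm_sat, next_id);
  Cfg f = parse_cfg(config);
  Rng rng(static_cast<uint64_t>(seed) * 0x9E3779B97f4A7C15ULL + 12345ULL);
  const int mask = phase_mask(phases);
  std::vector<double> buf, series;
  long step = clock0;
  record_row(w, series, step);
  for (int it = 0; it < n_steps; ++it) {
    world_step(w, f, rng, mask, buf);
    ++step;
    if (record_every > 0 &&
        (step % record_every == 0 || it == n_steps - 1))
      record_row(w, series, step);
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  // serialize back
  const size_t n = w.n();
  List ag = List::create(
    _["id"] = wrap(w.id), _["type"] = wrap(w.type),
    _["state"] = wrap(w.state), _["alv"] = wrap(w.alv),
    _["x"] = wrap(w.x), _["y"] = wrap(w.y), _["z"] = wrap(w.z),
    _["radius"] = wrap(w.radius), _["byst"] = wrap(w.byst),
    _["phago_left"] = wrap(w.phago_left), _["removal"] = wrap(w.removal),
    _["phag_n"] = wrap(w.phag_n));
  (void)n;
  const int nv = w.nx * w.ny * w.nz, ns = static_cast<int>(w.conc.size());
  NumericMatrix cout(nv, ns);
  for (int s = 0; s < ns; ++s)
    for (int v = 0; v < nv; ++v) cout(v, s) = w.conc[s][v];
  const int ncol = 13 + ns;
  const int nrow = static_cast<int>(series.size()) / ncol;
  NumericMatrix sm(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int cidx = 0; cidx < ncol; ++cidx)
      sm(r, cidx) = series[r * ncol + cidx];
  return List::create(_["agents"] = ag, _["conc"] = cout,
                      _["series"] = sm, _["births"] = (double)w.births,
                      _["removals"] = (double)w.removals,
                      _["next_id"] = w.next_id,
                      _["clock"] = (double)step);
}
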