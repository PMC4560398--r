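// Fast trial simulator: 4 differential-drive robots, linear RGB retina,
// quadrant smell sensors, ground sensor, feed-forward controllers.
// All stochastic draws come from a self-contained xorshift128+ stream so a
// trial is bit-identical given (config, params, seed) on any platform.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------- RNG ----

struct XRng {
  uint64_t s0, s1;
  explicit XRng(uint64_t seed) {
    // splitmix64 expansion of the seed into the xorshift128+ state
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      t = t ^ (t >> 31);
      if (i == 0) s0 = t; else s1 = t;
    }
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// ------------------------------------------------------------ helpers ----

static inline double wrap2pi(double a) {
  a -= TWOPI * std::floor(a / TWOPI);
  if (a >= TWOPI) a -= TWOPI;
  if (a < 0) a = 0;
  return a;
}

// wrap to (-pi, pi]
static inline double wrappi(double a) {
  double b = wrap2pi(a + M_PI);
  if (b == 0) b = TWOPI;
  return b - M_PI;
}

struct Config {
  double side, zone_r, robot_r, diam, vmax, coll_disp, reach_radius;
  double zcx[2], zcy[2];
  int steps;
  bool exclude_zones_init;
};

static Config parse_config(const List& cfg) {
  Config c;
  c.side = as<double>(cfg["side_length"]);
  c.zone_r = as<double>(cfg["zone_diameter"]) / 2.0;
  c.diam = as<double>(cfg["robot_diameter"]);
  c.robot_r = c.diam / 2.0;
  c.vmax = as<double>(cfg["wheel_speed_max"]);
  c.coll_disp = as<double>(cfg["collision_displacement"]);
  c.steps = as<int>(cfg["steps_per_trial"]);
  NumericMatrix zc = as<NumericMatrix>(cfg["zone_centers"]);
  for (int k = 0; k < 2; ++k) { c.zcx[k] = zc(k, 0); c.zcy[k] = zc(k, 1); }
  c.exclude_zones_init = as<bool>(cfg["exclude_zones_at_init"]);
  c.reach_radius = 0.0;
  return c;
}

// zone id (0/1) of robot center, -1 if on white floor
static inline int zone_of(double x, double y, const Config& c) {
  for (int k = 0; k < 2; ++k) {
    double dx = x - c.zcx[k], dy = y - c.zcy[k];
    if (dx * dx + dy * dy < c.zone_r * c.zone_r) return k;
  }
  return -1;
}

static inline bool inside_walls(double x, double y, const Config& c) {
  return x >= c.robot_r && x <= c.side - c.robot_r &&
         y >= c.robot_r && y <= c.side - c.robot_r;
}

// closed-form arc integration of the unicycle over one step
static inline void kin_step(double& x, double& y, double& th,
                            double vl, double vr, double diam) {
  double v = 0.5 * (vl + vr);
  double w = (vr - vl) / diam;
  if (std::fabs(w) < 1e-12) {
    x += v * std::cos(th);
    y += v * std::sin(th);
  } else {
    double R = v / w;
    x += R * (std::sin(th + w) - std::sin(th));
    y += -R * (std::cos(th + w) - std::cos(th));
    th = wrap2pi(th + w);
  }
}

// normalized chassis colours: green, blue, light-blue, yellow
static const double COL[4][3] = {
  {0.0, 1.0, 0.0}, {0.0, 0.0, 1.0}, {0.0, 1.0, 1.0}, {1.0, 1.0, 0.0}
};

// retina of observer i: 15 values (R,G,B per photoreceptor 0..4, leftmost
// sector first). Sectors 18 deg wide spanning [-45, 45] deg, half-open on
// the right except the last; a robot's angular extent is +-asin(r/d) around
// its bearing; nearest overlapping robot wins the sector (occlusion).
static void retina(const double* x, const double* y, const double* th,
                   const bool* active, int i, const Config& c, double* out) {
  const double D2R = M_PI / 180.0;
  double sec_lo[5], sec_hi[5];
  for (int k = 0; k < 5; ++k) {
    sec_lo[k] = (-45.0 + 18.0 * k) * D2R;
    sec_hi[k] = sec_lo[k] + 18.0 * D2R;
  }
  double best_d[5];
  int best_j[5];
  for (int k = 0; k < 5; ++k) { best_d[k] = -1.0; best_j[k] = -1; }
  for (int j = 0; j < 4; ++j) {
    if (j == i || !active[j]) continue;
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < 1e-9) continue;
    double s = c.robot_r / d;
    double half = std::asin(s > 1.0 ? 1.0 : s);
    double b = wrappi(std::atan2(dy, dx) - th[i]);
    double lo = b - half, hi = b + half;
    for (int k = 0; k < 5; ++k) {
      // closed extent vs half-open sector ([lo,hi) except last, closed)
      bool overlap = (k == 4) ? (lo <= sec_hi[k] && hi >= sec_lo[k])
                              : (lo < sec_hi[k] && hi >= sec_lo[k]);
      if (overlap && (best_j[k] < 0 || d < best_d[k])) {
        best_d[k] = d;
        best_j[k] = j;
      }
    }
  }
  for (int k = 0; k < 5; ++k) {
    if (best_j[k] >= 0) {
      out[3 * k]     = COL[best_j[k]][0];
      out[3 * k + 1] = COL[best_j[k]][1];
      out[3 * k + 2] = COL[best_j[k]][2];
    } else {
      out[3 * k] = out[3 * k + 1] = out[3 * k + 2] = 0.0;
    }
  }
}

// quadrant smell code toward the nearest zone center:
// bearing in [0,90) -> (0,1); [90,270) -> (1,0); [270,360) -> (1,1)
static inline void smell(double x, double y, double th, const Config& c,
                         double& s0, double& s1) {
  double best = -1.0;
  int kbest = 0;
  for (int k = 0; k < 2; ++k) {
    double dx = c.zcx[k] - x, dy = c.zcy[k] - y;
    double d2 = dx * dx + dy * dy;
    if (best < 0 || d2 < best) { best = d2; kbest = k; }
  }
  double b = wrap2pi(std::atan2(c.zcy[kbest] - y, c.zcx[kbest] - x) - th);
  if (b < M_PI / 2)            { s0 = 0; s1 = 1; }
  else if (b < 3 * M_PI / 2)   { s0 = 1; s1 = 0; }
  else                         { s0 = 1; s1 = 1; }
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// params: 86-vector; 72 input->hidden weights (row-major by input), 4 hidden
// biases, 8 hidden->output weights (row-major by hidden), 2 output biases
static inline void forward(const double* p, const double* in, double vmax,
                           double& vl, double& vr) {
  double h[4];
  for (int j = 0; j < 4; ++j) {
    double z = p[72 + j];
    for (int i = 0; i < 18; ++i) z += p[i * 4 + j] * in[i];
    h[j] = sigmoid(z);
  }
  double o[2];
  for (int j = 0; j < 2; ++j) {
    double z = p[84 + j];
    for (int i = 0; i < 4; ++i) z += p[76 + i * 2 + j] * h[i];
    o[j] = sigmoid(z);
  }
  vl = (2.0 * o[0] - 1.0) * vmax;
  vr = (2.0 * o[1] - 1.0) * vmax;
}

// random non-overlapping placement; pinned robot (if any) is already set
// and is treated as an obstacle
static void place_robots(double* x, double* y, double* th, const bool* active,
                         int pinned, const Config& c, XRng& rng) {
  for (int i = 0; i < 4; ++i) {
    if (!active[i] || i == pinned) continue;
    bool ok = false;
    for (int attempt = 0; attempt < 10000; ++attempt) {
      double px = c.robot_r + rng.unif() * (c.side - 2 * c.robot_r);
      double py = c.robot_r + rng.unif() * (c.side - 2 * c.robot_r);
      if (c.exclude_zones_init && zone_of(px, py, c) >= 0) continue;
      bool clash = false;
      for (int j = 0; j < 4; ++j) {
        if (j == i || !active[j]) continue;
        if (j > i && j != pinned) continue;  // not yet placed
        double dx = px - x[j], dy = py - y[j];
        if (dx * dx + dy * dy < c.diam * c.diam) { clash = true; break; }
      }
      if (clash) continue;
      x[i] = px; y[i] = py; th[i] = rng.unif() * TWOPI;
      ok = true;
      break;
    }
    if (!ok) stop("init_world: could not place robots (arena too small?)");
  }
}

// displace colliding robots to a legal nearby location with random heading
static void resolve(double* x, double* y, double* th, const bool* active,
                    int pinned, const Config& c, XRng& rng, bool* moved) {
  for (int i = 0; i < 4; ++i) {
    if (moved) moved[i] = false;
    if (!active[i] || i == pinned) continue;
    bool bad = !inside_walls(x[i], y[i], c);
    if (!bad) {
      for (int j = 0; j < 4; ++j) {
        if (j == i || !active[j]) continue;
        double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx * dx + dy * dy < c.diam * c.diam) { bad = true; break; }
      }
    }
    if (!bad) continue;
    bool ok = false;
    for (int attempt = 0; attempt < 10000; ++attempt) {
      // the nominal displacement can have an empty legal set when a robot
      // is wedged between a corner and a neighbour; double it periodically
      double disp = c.coll_disp * (double)(1 << (attempt / 1000));
      double a = rng.unif() * TWOPI;
      double px = x[i] + disp * std::cos(a);
      double py = y[i] + disp * std::sin(a);
      if (!inside_walls(px, py, c)) continue;
      bool clash = false;
      for (int j = 0; j < 4; ++j) {
        if (j == i || !active[j]) continue;
        double dx = px - x[j], dy = py - y[j];
        if (dx * dx + dy * dy < c.diam * c.diam) { clash = true; break; }
      }
      if (clash) continue;
      x[i] = px; y[i] = py; th[i] = rng.unif() * TWOPI;
      if (moved) moved[i] = true;
      ok = true;
      break;
    }
    if (!ok) stop("resolve_collisions: no legal reposition found");
  }
}

// ------------------------------------------------------------ exports ----

// [[Rcpp::export(name = ".init_world_cpp")]]
NumericMatrix init_world_cpp(List config, double seed) {
  Config c = parse_config(config);
  XRng rng(static_cast<uint64_t>(seed));
  double x[4], y[4], th[4];
  bool active[4] = {true, true, true, true};
  place_robots(x, y, th, active, -1, c, rng);
  NumericMatrix out(4, 3);
  for (int i = 0; i < 4; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = th[i]; }
  colnames(out) = CharacterVector::create("x", "y", "heading");
  return out;
}

// [[Rcpp::export(name = ".resolve_collisions_cpp")]]
NumericMatrix resolve_collisions_cpp(NumericMatrix poses, List config, double seed) {
  Config c = parse_config(config);
  XRng rng(static_cast<uint64_t>(seed));
  double x[4], y[4], th[4];
  bool active[4] = {true, true, true, true};
  for (int i = 0; i < 4; ++i) { x[i] = poses(i, 0); y[i] = poses(i, 1); th[i] = poses(i, 2); }
  resolve(x, y, th, active, -1, c, rng, nullptr);
  NumericMatrix out(4, 3);
  for (int i = 0; i < 4; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = th[i]; }
  colnames(out) = CharacterVector::create("x", "y", "heading");
  return out;
}

// Run one trial. params: 86 x 4 matrix of decoded controller parameters.
// pinned: 0-based robot index held motionless at the arena center (-1 none).
// removed: logical(4), robots deleted from the world.
// Returns per-robot summary statistics and, optionally, the full log.
// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(NumericMatrix params, List config, double seed,
                   int pinned = -1, LogicalVector removed = LogicalVector(4),
                   std::string fitness_mode = "collective",
                   double reach_radius = 11.0,
                   bool bary_exclude_pinned = false,
                   bool keep_log = false, bool log_sensors = false,
                   Nullable<NumericMatrix> init_poses = R_NilValue) {
  Config c = parse_config(config);
  XRng rng(static_cast<uint64_t>(seed));
  int mode = fitness_mode == "collective" ? 0 :
             fitness_mode == "individual" ? 1 :
             fitness_mode == "mixed" ? 2 : -1;
  if (mode < 0) stop("unknown fitness mode '%s'", fitness_mode.c_str());

  bool active[4];
  int n_active = 0;
  for (int i = 0; i < 4; ++i) {
    active[i] = !removed[i];
    if (active[i]) ++n_active;
  }
  if (n_active < 2) stop("removal of more than 2 robots is unsupported");
  if (pinned >= 0 && !active[pinned]) stop("pinned robot has been removed");

  double x[4] = {0, 0, 0, 0}, y[4] = {0, 0, 0, 0}, th[4] = {0, 0, 0, 0};
  if (pinned >= 0) { x[pinned] = c.side / 2; y[pinned] = c.side / 2; th[pinned] = 0; }
  if (init_poses.isNotNull()) {
    NumericMatrix ip(init_poses);
    for (int i = 0; i < 4; ++i) { x[i] = ip(i, 0); y[i] = ip(i, 1); th[i] = ip(i, 2); }
  } else {
    place_robots(x, y, th, active, pinned, c, rng);
  }

  // accumulators
  double fitness[4] = {0, 0, 0, 0};
  double zone_steps[4] = {0, 0, 0, 0};
  double sum_dbary[4] = {0, 0, 0, 0};
  int vision_steps[4] = {0, 0, 0, 0};
  int first_reach[4] = {-1, -1, -1, -1};
  int ncell = (int)std::ceil(c.side / c.diam);
  std::vector<char> cells(4 * ncell * ncell, 0);
  int cells_n[4] = {0, 0, 0, 0};

  auto mark_cell = [&](int i) {
    int cx = (int)std::floor(x[i] / c.diam); if (cx >= ncell) cx = ncell - 1; if (cx < 0) cx = 0;
    int cy = (int)std::floor(y[i] / c.diam); if (cy >= ncell) cy = ncell - 1; if (cy < 0) cy = 0;
    char& cell = cells[i * ncell * ncell + cy * ncell + cx];
    if (!cell) { cell = 1; ++cells_n[i]; }
  };
  auto check_reach = [&](int step) {
    if (pinned < 0) return;
    for (int i = 0; i < 4; ++i) {
      if (i == pinned || !active[i] || first_reach[i] >= 0) continue;
      double dx = x[i] - x[pinned], dy = y[i] - y[pinned];
      if (std::sqrt(dx * dx + dy * dy) <= reach_radius) first_reach[i] = step;
    }
  };
  for (int i = 0; i < 4; ++i) if (active[i]) mark_cell(i);
  check_reach(0);

  // optional log
  NumericMatrix log_pose, log_ctrl, log_sens;
  IntegerMatrix log_zone, log_coll;
  if (keep_log) {
    log_pose = NumericMatrix(c.steps + 1, 12);  // x,y,heading per robot
    log_ctrl = NumericMatrix(c.steps, 8);       // vl,vr per robot
    log_zone = IntegerMatrix(c.steps, 4);
    log_coll = IntegerMatrix(c.steps, 4);
    if (log_sensors) log_sens = NumericMatrix(c.steps, 72);  // 15+2+1 per robot
    for (int i = 0; i < 4; ++i) {
      log_pose(0, i) = x[i]; log_pose(0, 4 + i) = y[i]; log_pose(0, 8 + i) = th[i];
    }
  }

  double ret[4][15], in[18];
  double vl[4], vr[4];
  bool moved[4];

  for (int t = 0; t < c.steps; ++t) {
    // sense + think on the current state
    for (int i = 0; i < 4; ++i) {
      if (!active[i]) { vl[i] = vr[i] = 0; continue; }
      retina(x, y, th, active, i, c, ret[i]);
      bool any = false;
      for (int k = 0; k < 15; ++k) { in[k] = ret[i][k]; if (ret[i][k] > 0) any = true; }
      if (any) ++vision_steps[i];
      double s0, s1;
      smell(x[i], y[i], th[i], c, s0, s1);
      in[15] = s0; in[16] = s1;
      in[17] = zone_of(x[i], y[i], c) >= 0 ? 1.0 : 0.0;
      forward(&params(0, i), in, c.vmax, vl[i], vr[i]);
      if (keep_log && log_sensors) {
        for (int k = 0; k < 15; ++k) log_sens(t, i * 18 + k) = ret[i][k];
        log_sens(t, i * 18 + 15) = s0; log_sens(t, i * 18 + 16) = s1;
        log_sens(t, i * 18 + 17) = in[17];
      }
    }
    // act
    for (int i = 0; i < 4; ++i) {
      if (!active[i] || i == pinned) continue;
      kin_step(x[i], y[i], th[i], vl[i], vr[i], c.diam);
    }
    resolve(x, y, th, active, pinned, c, rng, moved);

    // score the post-move state
    int zid[4];
    int common = -2;  // -2 unset, -1 broken
    for (int i = 0; i < 4; ++i) {
      if (!active[i]) { zid[i] = -1; continue; }
      zid[i] = zone_of(x[i], y[i], c);
      if (zid[i] >= 0) zone_steps[i] += 1.0;
      if (common == -2) common = zid[i];
      else if (zid[i] != common) common = -1;
      mark_cell(i);
    }
    bool together = (common >= 0);
    for (int i = 0; i < 4; ++i) {
      if (!active[i]) continue;
      double f = 0;
      if (mode == 0) f = together ? 1.0 : 0.0;
      else if (mode == 1) f = zid[i] >= 0 ? 1.0 : 0.0;
      else f = (together ? 1.0 : 0.0) + (zid[i] >= 0 ? 1.0 : 0.0);
      fitness[i] += f;
    }
    double bx = 0, by = 0;
    int nb = 0;
    for (int i = 0; i < 4; ++i) {
      if (!active[i]) continue;
      if (bary_exclude_pinned && i == pinned) continue;
      bx += x[i]; by += y[i]; ++nb;
    }
    bx /= nb; by /= nb;
    for (int i = 0; i < 4; ++i) {
      if (!active[i]) continue;
      double dx = x[i] - bx, dy = y[i] - by;
      sum_dbary[i] += std::sqrt(dx * dx + dy * dy);
    }
    check_reach(t + 1);

    if (keep_log) {
      for (int i = 0; i < 4; ++i) {
        log_pose(t + 1, i) = x[i]; log_pose(t + 1, 4 + i) = y[i]; log_pose(t + 1, 8 + i) = th[i];
        log_ctrl(t, i * 2) = vl[i]; log_ctrl(t, i * 2 + 1) = vr[i];
        log_zone(t, i) = zid[i];
        log_coll(t, i) = moved[i] ? 1 : 0;
      }
    }
  }

  NumericVector out_fit(4), out_zone(4), out_dbary(4);
  IntegerVector out_vis(4), out_cells(4), out_reach(4);
  for (int i = 0; i < 4; ++i) {
    out_fit[i] = active[i] ? fitness[i] : NA_REAL;
    out_zone[i] = active[i] ? zone_steps[i] : NA_REAL;
    out_dbary[i] = active[i] ? sum_dbary[i] / c.steps : NA_REAL;
    out_vis[i] = active[i] ? vision_steps[i] : NA_INTEGER;
    out_cells[i] = active[i] ? cells_n[i] : NA_INTEGER;
    out_reach[i] = !active[i] || i == pinned ? NA_INTEGER :
                   (pinned >= 0 ? (first_reach[i] >= 0 ? first_reach[i] : c.steps) : NA_INTEGER);
  }
  List res = List::create(
    _["fitness"] = out_fit,
    _["steps_in_zone"] = out_zone,
    _["mean_dist_barycenter"] = out_dbary,
    _["vision_steps"] = out_vis,
    _["cells_visited"] = out_cells,
    _["first_reach_step"] = out_reach);
  if (keep_log) {
    res["log"] = List::create(
      _["pose"] = log_pose, _["control"] = log_ctrl,
      _["zone"] = log_zone, _["collided"] = log_coll,
      _["sensors"] = log_sensors ? (SEXP)log_sens : R_NilValue);
  }
  return res;
}

// Retina of one observer on an arbitrary 4-robot state (testing / fixtures).
// [[Rcpp::export(name = ".read_retina_cpp")]]
NumericVector read_retina_cpp(NumericMatrix poses, int observer, List config) {
  Config c = parse_config(config);
  double x[4], y[4], th[4], out[15];
  bool active[4];
  for (int i = 0; i < 4; ++i) {
    x[i] = poses(i, 0); y[i] = poses(i, 1); th[i] = poses(i, 2);
    active[i] = !NumericVector::is_na(poses(i, 0));
  }
  if (observer < 0 || observer > 3) stop("observer index out of range");
  retina(x, y, th, active, observer, c, out);
  return NumericVector(out, out + 15);
}
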