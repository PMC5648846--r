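// Lock-step agent-based axon growth with same-type fasciculation/repulsion.
//
// All axons advance by one elongation step Delta per time unit once their
// scheduled start time has passed.  The turning rule per step is
//   theta_A = theta - G_RC(x,y) sin(theta) + G_DV(x,y) cos(theta) + xi
//   theta_B = theta_p (s > 0)  or  the away-pointing perpendicular (s < 0)
//   theta'  = theta_A + |s| * wrap(theta_B - theta_A)
// where theta_p is the growth angle stored at the nearest same-type axon
// point within radius r (excluding the growing neuron's own axons).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// wrap to (-pi, pi]; op-for-op identical to the R wrap_angle() so the pure-R
// reference grower reproduces engine trajectories exactly
static inline double wrap_angle(double a) {
  double w = a - (2.0 * PI_) * std::floor((a + PI_) / (2.0 * PI_));
  if (w <= -PI_) w = PI_;
  return w;
}

struct HashPoint {
  double x, y, theta;
  int neuron_id, step;
};

// Uniform grid over the arena; cell size >= query radius so a radius-r disc
// is always covered by the 3x3 block around the query cell.
struct SpatialHash {
  double x0, y0, cell;
  int nx, ny;
  std::vector< std::vector<HashPoint> > cells;

  void init(double xmin, double xmax, double ymin, double ymax, double cell_size) {
    x0 = xmin - 2.0 * cell_size;
    y0 = ymin - 2.0 * cell_size;
    cell = cell_size;
    nx = (int)std::ceil((xmax - x0) / cell) + 4;
    ny = (int)std::ceil((ymax - y0) / cell) + 4;
    cells.assign((size_t)nx * ny, std::vector<HashPoint>());
  }
  inline int cix(double x) const {
    int i = (int)std::floor((x - x0) / cell);
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    return i;
  }
  inline int ciy(double y) const {
    int j = (int)std::floor((y - y0) / cell);
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    return j;
  }
  void insert(double x, double y, double theta, int neuron_id, int step) {
    HashPoint p; p.x = x; p.y = y; p.theta = theta;
    p.neuron_id = neuron_id; p.step = step;
    cells[(size_t)cix(x) * ny + ciy(y)].push_back(p);
  }
  // nearest point within r, excluding neuron exclude_id; ties broken by
  // (lower neuron id, lower step index).  Returns found flag.
  bool nearest(double x, double y, double r, int exclude_id,
               HashPoint &best) const {
    double r2 = r * r;
    bool found = false;
    double bd2 = 0.0;
    int i0 = cix(x), j0 = ciy(y);
    for (int di = -1; di <= 1; ++di) {
      int i = i0 + di;
      if (i < 0 || i >= nx) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int j = j0 + dj;
        if (j < 0 || j >= ny) continue;
        const std::vector<HashPoint> &v = cells[(size_t)i * ny + j];
        for (size_t k = 0; k < v.size(); ++k) {
          const HashPoint &p = v[k];
          if (p.neuron_id == exclude_id) continue;
          double dx = p.x - x, dy = p.y - y;
          double d2 = dx * dx + dy * dy;
          if (d2 > r2) continue;
          if (!found || d2 < bd2 ||
              (d2 == bd2 && (p.neuron_id < best.neuron_id ||
                             (p.neuron_id == best.neuron_id && p.step < best.step)))) {
            best = p; bd2 = d2; found = true;
          }
        }
      }
    }
    return found;
  }
};

struct Barrier {
  double y_level, x_start, x_end;
  bool exempt_comm;
  std::vector<double> gap_lo, gap_hi; // open intervals
  bool blocks_at(double x) const {
    if (x < x_start || x > x_end) return false;
    for (size_t g = 0; g < gap_lo.size(); ++g)
      if (x > gap_lo[g] && x < gap_hi[g]) return false;
    return true;
  }
};

enum Phase { PH_NORMAL = 0, PH_PRE = 1, PH_CROSSED = 2 };

struct AxonState {
  int neuron_id, type, side, cls;       // cls 1 primary, 2 secondary
  double x, y, theta;
  int n_steps, step;                    // step = number of steps taken
  double start_time;
  bool commissural;
  double s;                             // interaction sensitivity
  int parent;                           // 0-based index of parent primary (-1 if none)
  int branch_step;
  double theta0;
  int phase;
  bool active, started, dropped;
  int stuck;
  // params: normal set and pre-crossing override (g_rc, k_dv, lambda, k_off, alpha)
  double pn[5], pp[5];
  std::vector<double> xs, ys, th;
  std::vector<int> ph;
  std::vector<int> clip;
};

// sgn_override != 0 anchors the DV cue's sign (commissural pre-crossing
// growth keeps the soma side's ventral drive so the axon is carried across
// the midline instead of being reflected by the mirror-symmetric field)
static inline void eval_gradient(const double *p, double x, double y,
                                 int sgn_override,
                                 double &g_rc, double &g_dv) {
  (void)x;
  double sgn = sgn_override != 0 ? (double)sgn_override
                                 : (double)((y > 0) - (y < 0));
  g_rc = p[0];
  g_dv = p[1] * sgn * std::exp(-std::fabs(y) / p[2]) + p[3];
}

// [[Rcpp::export]]
List grow_axons_cpp(DataFrame ax, List noise, NumericMatrix par_normal,
                    NumericMatrix par_pre, List barriers,
                    double x_min, double x_max, double y_max,
                    double r, double delta, double t_max) {
  IntegerVector neuron_id = ax["neuron_id"], type = ax["type_id"],
    side = ax["side_sign"], cls = ax["class_id"], n_steps = ax["n_steps"],
    parent = ax["parent_row"], branch_step = ax["branch_step"];
  NumericVector x0 = ax["x0"], y0 = ax["y0"], theta0 = ax["theta0"],
    start_time = ax["start_time"], sv = ax["s"];
  LogicalVector comm = ax["commissural"];
  int n = ax.nrows();

  std::vector<Barrier> bars;
  for (int b = 0; b < barriers.size(); ++b) {
    List bl = barriers[b];
    Barrier br;
    br.y_level = as<double>(bl["y_level"]);
    br.x_start = as<double>(bl["x_start"]);
    br.x_end = as<double>(bl["x_end"]);
    br.exempt_comm = as<bool>(bl["exempt_commissural"]);
    NumericMatrix g = as<NumericMatrix>(bl["gaps"]);
    for (int i = 0; i < g.nrow(); ++i) {
      br.gap_lo.push_back(g(i, 0));
      br.gap_hi.push_back(g(i, 1));
    }
    bars.push_back(br);
  }

  std::vector<AxonState> A(n);
  std::vector< std::vector<double> > u(n);
  int n_types = 0;
  for (int i = 0; i < n; ++i) {
    AxonState &a = A[i];
    a.neuron_id = neuron_id[i]; a.type = type[i]; a.side = side[i];
    a.cls = cls[i];
    a.x = x0[i]; a.y = y0[i]; a.theta = theta0[i]; a.theta0 = theta0[i];
    a.n_steps = n_steps[i]; a.step = 0;
    a.start_time = start_time[i];
    a.commissural = comm[i];
    a.s = sv[i];
    a.parent = parent[i] - 1;   // R 1-based; 0 -> -1
    a.branch_step = branch_step[i];
    a.phase = (a.commissural && a.cls == 1) ? PH_PRE
            : (a.commissural ? PH_CROSSED : PH_NORMAL);
    a.active = true; a.started = false; a.dropped = false; a.stuck = 0;
    for (int k = 0; k < 5; ++k) {
      a.pn[k] = par_normal(i, k);
      a.pp[k] = par_pre(i, k);
    }
    u[i] = as< std::vector<double> >(noise[i]);
    if ((int)u[i].size() < a.n_steps)
      stop("noise vector %d shorter than n_steps", i + 1);
    if (a.type > n_types) n_types = a.type;
  }

  double cell = std::max(r, delta);
  std::vector<SpatialHash> hash(n_types + 1);
  for (int t = 1; t <= n_types; ++t)
    hash[t].init(x_min, x_max, -y_max, y_max, cell);

  const double EPS = 1e-6;

  int n_unfinished = n;
  for (double t = 0.0; t < t_max && n_unfinished > 0; t += 1.0) {
    for (int i = 0; i < n; ++i) {
      AxonState &a = A[i];
      if (!a.active || t < a.start_time) continue;
      if (!a.started) {
        // sprout: secondary axons start at their parent's branch point
        if (a.cls == 2 && a.parent >= 0) {
          AxonState &p = A[a.parent];
          int bs = a.branch_step;
          if (bs > (int)p.xs.size() - 1) bs = (int)p.xs.size() - 1;
          if (bs < 0) bs = 0;
          if (a.commissural) { // branch only after midline crossing
            int k = -1;
            for (int q = bs; q < (int)p.ph.size(); ++q)
              if (p.ph[q] == PH_CROSSED) { k = q; break; }
            if (k < 0)
              for (int q = bs; q >= 0; --q)
                if (p.ph[q] == PH_CROSSED) { k = q; break; }
            if (k < 0) { // parent never crossed: no contralateral branch
              a.active = false; a.dropped = true; --n_unfinished; continue;
            }
            bs = k;
          }
          a.x = p.xs[bs]; a.y = p.ys[bs];
        }
        a.started = true;
        a.theta = a.theta0;
        a.xs.push_back(a.x); a.ys.push_back(a.y);
        a.th.push_back(a.theta); a.ph.push_back(a.phase);
        a.clip.push_back(0);
        if (a.phase != PH_PRE)
          hash[a.type].insert(a.x, a.y, a.theta, a.neuron_id, 0);
        if (a.n_steps == 0) { a.active = false; --n_unfinished; continue; }
      }

      const double *par = (a.phase == PH_PRE) ? a.pp : a.pn;
      double g_rc, g_dv;
      eval_gradient(par, a.x, a.y, (a.phase == PH_PRE) ? a.side : 0,
                    g_rc, g_dv);
      double xi = par[4] * u[i][a.step];
      double thA = wrap_angle(a.theta - g_rc * std::sin(a.theta)
                              + g_dv * std::cos(a.theta) + xi);
      double th_new = thA;
      if (a.s != 0.0 && a.phase != PH_PRE) {
        HashPoint np;
        if (hash[a.type].nearest(a.x, a.y, r, a.neuron_id, np)) {
          double thB;
          if (a.s > 0) {
            // align with the neighbour fibre's AXIS: an axon adheres along
            // the shaft in its own direction of travel, so an antiparallel
            // neighbour attracts toward theta_p + pi, not a U-turn
            thB = np.theta;
            if (std::fabs(wrap_angle(thB - thA)) > PI_ / 2.0)
              thB = wrap_angle(thB + PI_);
          } else {
            double c1 = np.theta + PI_ / 2.0;
            double dx = a.x - np.x, dy = a.y - np.y;
            double dot1 = std::cos(c1) * dx + std::sin(c1) * dy;
            thB = (dot1 >= 0) ? c1 : np.theta - PI_ / 2.0;
          }
          th_new = wrap_angle(thA + std::fabs(a.s) * wrap_angle(thB - thA));
        }
      }

      double px = a.x + delta * std::cos(th_new);
      double py = a.y + delta * std::sin(th_new);
      // earliest blocking crossing among barriers and arena bounds
      double best_t = 2.0; int hit_kind = 0; double hit_level = 0.0;
      double dx = px - a.x, dy = py - a.y;
      for (size_t b = 0; b < bars.size(); ++b) {
        const Barrier &br = bars[b];
        if (br.exempt_comm && a.commissural) continue;
        double L = br.y_level;
        double f0 = a.y - L, f1 = py - L;
        if ((f0 > 0 && f1 > 0) || (f0 < 0 && f1 < 0) || f0 == 0) continue;
        double tt = (dy != 0.0) ? f0 / (f0 - f1) : 1.0;
        double xh = a.x + tt * dx;
        if (!br.blocks_at(xh)) continue;
        if (tt < best_t) { best_t = tt; hit_kind = 1; hit_level = L; }
      }
      // arena horizontal bounds
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double L = sgn * y_max;
        double f0 = a.y - L, f1 = py - L;
        if ((f0 > 0 && f1 > 0) || (f0 < 0 && f1 < 0) || f0 == 0) continue;
        double tt = (dy != 0.0) ? f0 / (f0 - f1) : 1.0;
        if (tt < best_t) { best_t = tt; hit_kind = 1; hit_level = L; }
      }
      // arena vertical bounds
      double bx[2] = { x_min, x_max };
      for (int bb = 0; bb < 2; ++bb) {
        double B = bx[bb];
        double f0 = a.x - B, f1 = px - B;
        if ((f0 > 0 && f1 > 0) || (f0 < 0 && f1 < 0) || f0 == 0) continue;
        double tt = (dx != 0.0) ? f0 / (f0 - f1) : 1.0;
        if (tt < best_t) { best_t = tt; hit_kind = 2; hit_level = B; }
      }

      int clipped = 0;
      bool leaves_arena = false;
      double nx_, ny_;
      if (hit_kind == 0) {
        nx_ = px; ny_ = py;
      } else if (hit_kind == 1) { // horizontal line: slide longitudinally
        nx_ = a.x + best_t * dx;
        ny_ = hit_level + ((a.y < hit_level) ? -EPS : EPS);
        th_new = (dx >= 0) ? 0.0 : PI_;
        clipped = 1;
      } else {                    // rostral/caudal end of the modelled
                                  // section: the axon leaves the arena and
                                  // is terminated at the boundary
        nx_ = hit_level + ((a.x < hit_level) ? -EPS : EPS);
        ny_ = a.y + best_t * dy;
        clipped = 1;
        leaves_arena = true;
      }

      double disp = std::hypot(nx_ - a.x, ny_ - a.y);
      if (disp < 1e-9) { a.stuck += 1; } else { a.stuck = 0; }

      a.x = nx_; a.y = ny_; a.theta = th_new;
      a.step += 1;
      // commissural midline-crossing phase transition, checked on the new tip
      if (a.phase == PH_PRE && a.side * a.y <= -25.0) a.phase = PH_CROSSED;
      a.xs.push_back(a.x); a.ys.push_back(a.y);
      a.th.push_back(a.theta); a.ph.push_back(a.phase);
      a.clip.push_back(clipped);
      if (a.phase != PH_PRE)
        hash[a.type].insert(a.x, a.y, a.theta, a.neuron_id, a.step);

      if (a.step >= a.n_steps || a.stuck >= 3 || leaves_arena) {
        a.active = false; --n_unfinished;
      }
    }
  }

  // assemble tidy output
  size_t total = 0;
  for (int i = 0; i < n; ++i) total += A[i].xs.size();
  IntegerVector out_row(total), out_step(total), out_phase(total);
  NumericVector out_x(total), out_y(total), out_theta(total);
  LogicalVector out_clip(total);
  size_t k = 0;
  for (int i = 0; i < n; ++i) {
    AxonState &a = A[i];
    for (size_t j = 0; j < a.xs.size(); ++j, ++k) {
      out_row[k] = i + 1;
      out_step[k] = (int)j;
      out_x[k] = a.xs[j]; out_y[k] = a.ys[j];
      out_theta[k] = a.th[j];
      out_phase[k] = a.ph[j];
      out_clip[k] = a.clip[j] == 1;
    }
  }
  LogicalVector finished(n), dropped(n);
  for (int i = 0; i < n; ++i) {
    finished[i] = !A[i].active;
    dropped[i] = A[i].dropped;
  }
  return List::create(_["axon_row"] = out_row, _["step"] = out_step,
                      _["x"] = out_x, _["y"] = out_y, _["theta"] = out_theta,
                      _["phase"] = out_phase, _["clipped"] = out_clip,
                      _["finished"] = finished, _["dropped"] = dropped);
}

// Spatial-hash nearest-neighbour query exposed for direct use and testing
// against a brute-force scan.
// [[Rcpp::export]]
List nearest_point_cpp(double tip_x, double tip_y, NumericVector px,
                       NumericVector py, NumericVector ptheta,
                       IntegerVector pid, IntegerVector pstep, double r,
                       int exclude_id) {
  int m = px.size();
  double xmin = tip_x, xmax = tip_x, ymin = tip_y, ymax = tip_y;
  for (int i = 0; i < m; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  SpatialHash h;
  h.init(xmin, xmax + 1e-9, ymin, ymax + 1e-9, std::max(r, 1.0));
  for (int i = 0; i < m; ++i) h.insert(px[i], py[i], ptheta[i], pid[i], pstep[i]);
  HashPoint best;
  bool found = h.nearest(tip_x, tip_y, r, exclude_id, best);
  if (!found) return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["x"] = best.x, _["y"] = best.y,
                      _["theta"] = best.theta, _["neuron_id"] = best.neuron_id,
                      _["step"] = best.step);
}

// Exact crossings between axon step segments and vertical dendrite segments.
// Dendrites must be sorted by x ascending.  Endpoint touching counts.
// [[Rcpp::export]]
DataFrame detect_crossings_cpp(NumericVector sx0, NumericVector sy0,
                               NumericVector sx1, NumericVector sy1,
                               NumericVector dx, NumericVector dylo,
                               NumericVector dyhi) {
  int ns = sx0.size(), nd = dx.size();
  std::vector<int> seg_i, den_i;
  std::vector<double> cx, cy;
  for (int i = 0; i < ns; ++i) {
    double xlo = std::min(sx0[i], sx1[i]), xhi = std::max(sx0[i], sx1[i]);
    // first dendrite with x >= xlo
    int lo = (int)(std::lower_bound(dx.begin(), dx.end(), xlo) - dx.begin());
    for (int j = lo; j < nd && dx[j] <= xhi; ++j) {
      double yh;
      if (sx1[i] == sx0[i]) {
        // vertical step exactly on the dendrite line
        double slo = std::min(sy0[i], sy1[i]), shi = std::max(sy0[i], sy1[i]);
        if (shi < dylo[j] || slo > dyhi[j]) continue;
        yh = std::max(slo, dylo[j]);
      } else {
        double tt = (dx[j] - sx0[i]) / (sx1[i] - sx0[i]);
        yh = sy0[i] + tt * (sy1[i] - sy0[i]);
        if (yh < dylo[j] || yh > dyhi[j]) continue;
      }
      seg_i.push_back(i + 1); den_i.push_back(j + 1);
      cx.push_back(dx[j]); cy.push_back(yh);
    }
  }
  return DataFrame::create(_["seg"] = seg_i, _["dendrite"] = den_i,
                           _["x"] = cx, _["y"] = cy);
}
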