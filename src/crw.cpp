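// Correlated-random-walk engine inside a planar lake polygon.
//
// Geometry convention: Cartesian meters, bearings in degrees clockwise from
// +y ("grid north"), so a step of length L along bearing b moves by
// (L sin b, L cos b). Turning angles are signed degrees, positive clockwise.
//
// The per-path random stream is splitmix64 with Box-Muller normals; path i of
// an ensemble seeded with s uses state mix64(s + C*(i+1)) so ensembles are
// bit-reproducible across platforms and independent of R's RNG.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

const double kDeg2Rad = 0.017453292519943295;

inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct TurnStream {
  uint64_t state;
  bool has_spare;
  double spare;
  TurnStream(uint64_t seed, uint64_t stream) : has_spare(false), spare(0.0) {
    state = mix64(seed + 0x632BE59BD9B4E019ULL * (stream + 1ULL));
    state = mix64(state);
  }
  inline uint64_t nextu() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0, 1), never exactly 0 or 1
  inline double unif() {
    return ((double)(nextu() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// even-odd crossing test, boundary not treated specially (measure zero for
// simulated points; the exported R-level test adds a boundary tolerance)
inline bool ring_contains(double x, double y,
                          const double* vx, const double* vy, int n) {
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if ((vy[i] > y) != (vy[j] > y)) {
      double xint = vx[i] + (y - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i]);
      if (x < xint) inside = !inside;
    }
  }
  return inside;
}

inline double pt_seg_d2(double px, double py,
                        double ax, double ay, double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / l2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

inline double cross2(double ox, double oy, double ax, double ay,
                     double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// Does segment a->b cross any edge of the ring?  Crossings at parameter
// t < eps_t along a->b are ignored (a may sit exactly on the shoreline,
// e.g. the river-mouth start point).
inline bool seg_blocked_by_ring(double axp, double ayp, double bxp, double byp,
                                const double* vx, const double* vy, int n,
                                double eps_t) {
  double rx = bxp - axp, ry = byp - ayp;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double cx = vx[j], cy = vy[j], dx_ = vx[i], dy_ = vy[i];
    double sx = dx_ - cx, sy = dy_ - cy;
    double denom = rx * sy - ry * sx;
    if (denom == 0.0) continue;  // parallel/collinear: measure-zero, skip
    double qx = cx - axp, qy = cy - ayp;
    double t = (qx * sy - qy * sx) / denom;  // along a->b
    double u = (qx * ry - qy * rx) / denom;  // along c->d
    if (t >= eps_t && t <= 1.0 && u >= 0.0 && u <= 1.0) return true;
  }
  return false;
}

struct RingSet {
  std::vector<const double*> xs, ys;
  std::vector<int> ns;
  // holds SEXPs alive through the NumericVectors below
  std::vector<NumericVector> keep;
};

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_points_in_ring(NumericVector px, NumericVector py,
                                 NumericVector vx, NumericVector vy,
                                 double tol, bool boundary_value) {
  int np = px.size(), n = vx.size();
  LogicalVector out(np);
  double tol2 = tol * tol;
  for (int p = 0; p < np; ++p) {
    double x = px[p], y = py[p];
    bool on_bd = false;
    if (tol > 0.0) {
      for (int i = 0, j = n - 1; i < n && !on_bd; j = i++) {
        if (pt_seg_d2(x, y, vx[j], vy[j], vx[i], vy[i]) <= tol2) on_bd = true;
      }
    }
    out[p] = on_bd ? boundary_value
                   : ring_contains(x, y, REAL(vx), REAL(vy), n);
  }
  return out;
}

// [[Rcpp::export]]
bool cpp_ring_is_simple(NumericVector vx, NumericVector vy) {
  int n = vx.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    // degenerate (zero-length) edge
    if (vx[i] == vx[i2] && vy[i] == vy[i2]) return false;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2) continue;  // adjacent edges share a vertex
      double ax = vx[i], ay = vy[i], bx = vx[i2], by = vy[i2];
      double cx = vx[j], cy = vy[j], dxx = vx[j2], dyy = vy[j2];
      double d1 = cross2(cx, cy, dxx, dyy, ax, ay);
      double d2 = cross2(cx, cy, dxx, dyy, bx, by);
      double d3 = cross2(ax, ay, bx, by, cx, cy);
      double d4 = cross2(ax, ay, bx, by, dxx, dyy);
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0)
        return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_draw_turns(int n, double mu, double sigma,
                             double seed, double stream) {
  TurnStream rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mu + sigma * rng.norm();
  return out;
}

// Simulate an ensemble of correlated random walks in a lake polygon.
// outcome codes: 0 = success, 1 = failure_cap, 2 = failure_retries
// [[Rcpp::export]]
List cpp_simulate_ensemble(NumericVector outer_x, NumericVector outer_y,
                           List holes,
                           double start_x, double start_y, double bearing0,
                           double cap_x, double cap_y, double cap_r,
                           double step_len, double turn_mu, double turn_sd,
                           int max_steps, double coll_coeff, double coll_exp,
                           int max_retries, int n_paths, double seed,
                           int first_stream, bool keep_points, bool convex,
                           int capture_mode) {
  // capture_mode: 0 = segment (before containment), 1 = point (before
  // containment), 2 = accepted_segment (containment first, then swept
  // segment), 3 = accepted_point (containment first, then endpoint)
  int n_outer = outer_x.size();
  const double* ox = REAL(outer_x);
  const double* oy = REAL(outer_y);

  RingSet hole_rings;
  for (int h = 0; h < holes.size(); ++h) {
    List hr = holes[h];
    NumericVector hx = hr[0], hy = hr[1];
    hole_rings.keep.push_back(hx);
    hole_rings.keep.push_back(hy);
    hole_rings.xs.push_back(REAL(hx));
    hole_rings.ys.push_back(REAL(hy));
    hole_rings.ns.push_back(hx.size());
  }
  int n_holes = (int)hole_rings.ns.size();

  double cap_r2 = cap_r * cap_r;
  double eps_t = 1e-9;  // ignore boundary contact at the moving point itself

  IntegerVector out_outcome(n_paths), out_steps(n_paths);
  NumericVector out_collisions(n_paths);
  List out_points = keep_points ? List(n_paths) : List(0);
  List out_headings = keep_points ? List(n_paths) : List(0);

  for (int p = 0; p < n_paths; ++p) {
    TurnStream rng((uint64_t)seed, (uint64_t)(p + first_stream));
    double heading = bearing0;
    double px = start_x, py = start_y;
    int outcome = 1;  // failure_cap unless success/retry-exhaustion
    int steps_taken = 0;
    double collisions = 0.0;

    std::vector<double> xs, ys, hs;
    if (keep_points) {
      xs.reserve(max_steps + 1); ys.reserve(max_steps + 1);
      hs.reserve(max_steps);
      xs.push_back(px); ys.push_back(py);
    }

    for (int s = 0; s < max_steps; ++s) {
      int k = 0;
      bool accepted = false, success = false;
      double nx = px, ny = py, nh = heading;
      for (int attempt = 0; ; ++attempt) {
        double sd_eff =
            turn_sd * (1.0 + coll_coeff * std::pow((double)k, coll_exp));
        double turn = turn_mu + sd_eff * rng.norm();
        nh = heading + turn;
        nh -= 360.0 * std::floor(nh / 360.0);
        double rad = nh * kDeg2Rad;
        nx = px + step_len * std::sin(rad);
        ny = py + step_len * std::cos(rad);

        bool seg_cap = (capture_mode == 0 || capture_mode == 2);
        double cap_d2 = seg_cap ? pt_seg_d2(cap_x, cap_y, px, py, nx, ny)
                                : (nx - cap_x) * (nx - cap_x) +
                                      (ny - cap_y) * (ny - cap_y);
        bool in_cap = cap_d2 <= cap_r2;

        // modes 0/1: entering the capture region ends the walk even if the
        // step's endpoint would leave the lake (the region straddles the
        // shoreline); modes 2/3: the shoreline bounce is applied first and
        // only accepted (in-lake) steps can register a capture
        if (in_cap && capture_mode <= 1) {
          success = true;
          accepted = true;
          break;
        }

        bool ok = ring_contains(nx, ny, ox, oy, n_outer);
        for (int h = 0; ok && h < n_holes; ++h) {
          if (ring_contains(nx, ny, hole_rings.xs[h], hole_rings.ys[h],
                            hole_rings.ns[h]))
            ok = false;
        }
        if (ok && !convex) {
          if (seg_blocked_by_ring(px, py, nx, ny, ox, oy, n_outer, eps_t))
            ok = false;
          for (int h = 0; ok && h < n_holes; ++h) {
            if (seg_blocked_by_ring(px, py, nx, ny, hole_rings.xs[h],
                                    hole_rings.ys[h], hole_rings.ns[h], eps_t))
              ok = false;
          }
        }
        if (ok) { accepted = true; success = in_cap && capture_mode >= 2; break; }
        ++k;
        collisions += 1.0;
        if (attempt >= max_retries) break;
      }
      if (!accepted) { outcome = 2; break; }
      px = nx; py = ny; heading = nh;
      ++steps_taken;
      if (keep_points) { xs.push_back(px); ys.push_back(py); hs.push_back(heading); }
      if (success) { outcome = 0; break; }
    }

    out_outcome[p] = outcome;
    out_steps[p] = steps_taken;
    out_collisions[p] = collisions;
    if (keep_points) {
      NumericMatrix m(xs.size(), 2);
      for (size_t i = 0; i < xs.size(); ++i) { m(i, 0) = xs[i]; m(i, 1) = ys[i]; }
      out_points[p] = m;
      out_headings[p] = NumericVector(hs.begin(), hs.end());
    }
  }

  return List::create(_["outcome"] = out_outcome,
                      _["n_steps"] = out_steps,
                      _["n_collisions"] = out_collisions,
                      _["points"] = out_points,
                      _["headings"] = out_headings);
}
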