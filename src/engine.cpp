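// Compiled trial engine.
//
// The per-agent behavioral semantics here mirror the R reference functions
// in R/agent.R (food-site choice, safety rules, energetics, memory
// bookkeeping) exactly; the R side is the documented contract and the test
// oracle, this side is the fast path used by run_trial(). All randomness
// comes from R's RNG stream (unif_rand), so set.seed() on the R side makes
// whole trials reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double dist2d(double ax, double ay, double bx, double by) {
  return std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by));
}

// ---- convex hull area (Andrew monotone chain) ------------------------------

struct Pt { double x, y; };

static double cross(const Pt& o, const Pt& a, const Pt& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

static double hull_area(std::vector<Pt> p) {
  size_t n = p.size();
  if (n < 3) return 0.0;
  std::sort(p.begin(), p.end(), [](const Pt& a, const Pt& b) {
    return a.x < b.x || (a.x == b.x && a.y < b.y);
  });
  std::vector<Pt> h(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {           // lower
    while (k >= 2 && cross(h[k - 2], h[k - 1], p[i]) <= 0) --k;
    h[k++] = p[i];
  }
  for (size_t i = n - 1, t = k + 1; i > 0; --i) {  // upper
    while (k >= t && cross(h[k - 2], h[k - 1], p[i - 1]) <= 0) --k;
    h[k++] = p[i - 1];
  }
  h.resize(k > 1 ? k - 1 : 0);
  if (h.size() < 3) return 0.0;
  double a = 0.0;
  for (size_t i = 0; i < h.size(); ++i) {
    size_t j = (i + 1) % h.size();
    a += h[i].x * h[j].y - h[j].x * h[i].y;
  }
  return std::fabs(a) / 2.0;
}

// [[Rcpp::export(name = ".hull_area_cpp")]]
double hull_area_cpp(NumericMatrix pos) {
  std::vector<Pt> p(pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i) p[i] = {pos(i, 0), pos(i, 1)};
  return hull_area(p);
}

// ---- recursive group centre ------------------------------------------------

// Iteratively drop the subset member farthest from the running centroid until
// >= quorum of the ORIGINAL group lies within `buffer` of the centroid.
static void group_center_core(const std::vector<double>& x,
                              const std::vector<double>& y,
                              double buffer, double quorum,
                              double& cx, double& cy, int& n_in, bool& ok) {
  int n = (int)x.size();
  std::vector<int> subset(n);
  for (int i = 0; i < n; ++i) subset[i] = i;
  ok = false;
  cx = cy = 0.0;
  n_in = 0;
  while (!subset.empty()) {
    double sx = 0, sy = 0;
    for (int i : subset) { sx += x[i]; sy += y[i]; }
    cx = sx / subset.size();
    cy = sy / subset.size();
    int cnt = 0;
    for (int i = 0; i < n; ++i)
      if (dist2d(x[i], y[i], cx, cy) <= buffer) ++cnt;
    if ((double)cnt >= quorum * n - 1e-9) {
      ok = true;
      n_in = (int)subset.size();
      return;
    }
    int far_pos = 0;
    double far_d = -1.0;
    for (size_t j = 0; j < subset.size(); ++j) {
      double d = dist2d(x[subset[j]], y[subset[j]], cx, cy);
      if (d > far_d) { far_d = d; far_pos = (int)j; }
    }
    n_in = (int)subset.size();
    subset.erase(subset.begin() + far_pos);
  }
}

// [[Rcpp::export(name = ".group_center_cpp")]]
List group_center_cpp(NumericMatrix pos, double buffer = 100.0,
                      double quorum = 0.8) {
  std::vector<double> x(pos.nrow()), y(pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  double cx, cy; int n_in; bool ok;
  group_center_core(x, y, buffer, quorum, cx, cy, n_in, ok);
  return List::create(_["center"] = NumericVector::create(cx, cy),
                      _["n_in"] = n_in, _["ok"] = ok);
}

// ---- destination choice ----------------------------------------------------

struct DestResult {
  int kind;          // 0 direct, 1 step, 2 toward, 3 explore
  int col, row;      // chosen cell (kind 0/1)
  int gcol, grow;    // goal cell (kind 0/1/2)
  double tx, ty;     // deterministic target point (kind 0/1/2)
};

struct Scene {
  const NumericMatrix* current;
  int n_cols, n_rows;
  double cell;
  double visual, social, safe_r, max_step;
};

// better-than comparator shared by goal choice and stepping-stone choice:
// smaller index, then smaller tie distance, then (row, col).
static inline bool better(double I, double d, int row, int col, double bI,
                          double bd, int brow, int bcol) {
  if (I < bI) return true;
  if (I > bI) return false;
  if (d < bd) return true;
  if (d > bd) return false;
  if (row < brow) return true;
  if (row > brow) return false;
  return col < bcol;
}

// Safety at a prospective point p for one agent. Leader rule (leader-led
// group, non-leader, leader currently sensed): leader within safe_r of p.
// Otherwise independent rule: >= desired mates within safe_r of p.
static bool safe_at(double px, double py, double ax, double ay, int desired,
                    const std::vector<double>& mx,
                    const std::vector<double>& my, bool use_leader,
                    double lx, double ly, const Scene& sc) {
  if (use_leader) {
    if (dist2d(ax, ay, lx, ly) <= sc.social)
      return dist2d(px, py, lx, ly) <= sc.safe_r;
    // leader not sensed: fall back to the independent rule
  }
  if (desired <= 0) return true;
  int cnt = 0;
  for (size_t i = 0; i < mx.size(); ++i)
    if (dist2d(mx[i], my[i], px, py) <= sc.safe_r) ++cnt;
  return cnt >= desired;
}

// Core of choose_destination (deterministic part). `rec_*` are the
// recallable remembered sites (already filtered by memory mode) with
// believed levels; visibility filtering happens here.
static DestResult choose_destination_core(
    double ax, double ay, int desired, const Scene& sc,
    const std::vector<int>& rec_col, const std::vector<int>& rec_row,
    const std::vector<double>& rec_bel,
    const std::vector<double>& mx, const std::vector<double>& my,
    bool use_leader, double lx, double ly) {
  const NumericMatrix& cur = *sc.current;
  DestResult res = {3, -1, -1, -1, -1, 0.0, 0.0};

  // visible food cells (centre within visual range, current > 0)
  int span = (int)std::ceil(sc.visual / sc.cell);
  int ac = (int)std::floor(ax / sc.cell), ar = (int)std::floor(ay / sc.cell);
  int c0 = std::max(0, ac - span), c1 = std::min(sc.n_cols - 1, ac + span);
  int r0 = std::max(0, ar - span), r1 = std::min(sc.n_rows - 1, ar + span);
  std::vector<int> vcol, vrow;
  std::vector<double> vx, vy, vr, vd;
  for (int r = r0; r <= r1; ++r)
    for (int c = c0; c <= c1; ++c) {
      double cx = (c + 0.5) * sc.cell, cy = (r + 0.5) * sc.cell;
      double d = dist2d(ax, ay, cx, cy);
      if (d <= sc.visual && cur(r, c) > 0) {
        vcol.push_back(c); vrow.push_back(r);
        vx.push_back(cx); vy.push_back(cy);
        vr.push_back(cur(r, c)); vd.push_back(d);
      }
    }

  // goal: argmin d/r over visible cells + out-of-sight recalled sites
  double bI = R_PosInf, bd = R_PosInf;
  int bcol = -1, brow = -1;
  bool goal_visible = false;
  double gx = 0, gy = 0;
  for (size_t i = 0; i < vcol.size(); ++i) {
    double I = vd[i] / vr[i];
    if (better(I, vd[i], vrow[i], vcol[i], bI, bd, brow, bcol)) {
      bI = I; bd = vd[i]; bcol = vcol[i]; brow = vrow[i];
      goal_visible = true; gx = vx[i]; gy = vy[i];
    }
  }
  for (size_t i = 0; i < rec_col.size(); ++i) {
    double cx = (rec_col[i] + 0.5) * sc.cell;
    double cy = (rec_row[i] + 0.5) * sc.cell;
    double d = dist2d(ax, ay, cx, cy);
    if (d <= sc.visual || rec_bel[i] <= 0) continue;  // in view: judged by eye
    double I = d / rec_bel[i];
    if (better(I, d, rec_row[i], rec_col[i], bI, bd, brow, bcol)) {
      bI = I; bd = d; bcol = rec_col[i]; brow = rec_row[i];
      goal_visible = false; gx = cx; gy = cy;
    }
  }
  if (bcol < 0) return res;  // explore
  res.gcol = bcol; res.grow = brow;

  if (goal_visible && bd <= sc.max_step &&
      safe_at(gx, gy, ax, ay, desired, mx, my, use_leader, lx, ly, sc)) {
    res.kind = 0; res.col = bcol; res.row = brow; res.tx = gx; res.ty = gy;
    return res;
  }

  // stepping stone: visible food cell within one step, safe, minimizing
  // d(cell, goal) / r(cell)
  double sI = R_PosInf, sd = R_PosInf;
  int scol = -1, srow = -1; double stx = 0, sty = 0;
  for (size_t i = 0; i < vcol.size(); ++i) {
    if (vd[i] > sc.max_step) continue;
    if (!safe_at(vx[i], vy[i], ax, ay, desired, mx, my, use_leader, lx, ly,
                 sc))
      continue;
    double dg = dist2d(vx[i], vy[i], gx, gy);
    double I = dg / vr[i];
    if (better(I, vd[i], vrow[i], vcol[i], sI, sd, srow, scol)) {
      sI = I; sd = vd[i]; scol = vcol[i]; srow = vrow[i];
      stx = vx[i]; sty = vy[i];
    }
  }
  if (scol >= 0) {
    res.kind = 1; res.col = scol; res.row = srow; res.tx = stx; res.ty = sty;
    return res;
  }

  // no safe stepping stone: head straight for the goal, capped at max_step
  double dd = dist2d(ax, ay, gx, gy);
  res.kind = 2;
  if (dd > sc.max_step) {
    res.tx = ax + (gx - ax) * sc.max_step / dd;
    res.ty = ay + (gy - ay) * sc.max_step / dd;
  } else {
    res.tx = gx; res.ty = gy;
  }
  return res;
}

// Test hook: the deterministic destination decision on an arbitrary scene.
// `recalled` carries columns col,row,believed (0-based cells) after
// memory-mode filtering; `leader` is numeric(0) or the leader position.
// [[Rcpp::export(name = ".choose_destination_cpp")]]
List choose_destination_cpp(NumericVector position, NumericMatrix current,
                            double cell_size, IntegerVector rec_col,
                            IntegerVector rec_row, NumericVector rec_bel,
                            NumericMatrix mates, int desired,
                            NumericVector leader, List par) {
  Scene sc;
  sc.current = &current;
  sc.n_cols = current.ncol(); sc.n_rows = current.nrow();
  sc.cell = cell_size;
  sc.visual = as<double>(par["visual_range"]);
  sc.social = as<double>(par["social_range"]);
  sc.safe_r = as<double>(par["safe_radius"]);
  sc.max_step = as<double>(par["max_step"]);
  std::vector<int> rc(rec_col.begin(), rec_col.end());
  std::vector<int> rr(rec_row.begin(), rec_row.end());
  std::vector<double> rb(rec_bel.begin(), rec_bel.end());
  std::vector<double> mx, my;
  for (int i = 0; i < mates.nrow(); ++i) {
    mx.push_back(mates(i, 0)); my.push_back(mates(i, 1));
  }
  bool use_leader = leader.size() == 2;
  double lx = use_leader ? leader[0] : 0, ly = use_leader ? leader[1] : 0;
  DestResult d = choose_destination_core(position[0], position[1], desired,
                                         sc, rc, rr, rb, mx, my, use_leader,
                                         lx, ly);
  const char* kinds[] = {"direct", "step", "toward", "explore"};
  List out = List::create(
      _["kind"] = std::string(kinds[d.kind]),
      _["cell"] = d.kind <= 1 ? IntegerVector::create(d.col, d.row)
                              : IntegerVector(0),
      _["goal"] = d.kind <= 2 ? IntegerVector::create(d.gcol, d.grow)
                              : IntegerVector(0),
      _["target"] = d.kind <= 2 ? NumericVector::create(d.tx, d.ty)
                                : NumericVector(0));
  return out;
}

// ---- full trial ------------------------------------------------------------

// [[Rcpp::export(name = ".run_trial_cpp")]]
List run_trial_cpp(NumericMatrix max_level, NumericMatrix current_in,
                   double cell_size, double grow_rate,
                   IntegerVector site_col, IntegerVector site_row,
                   NumericVector site_max, List adjacency0,
                   bool landmark_mode, bool leader_mode,
                   NumericVector x0, NumericVector y0,
                   NumericVector energy0, IntegerVector desired0,
                   List par, int days, bool record_agents) {
  int n = x0.size();
  int n_rows = max_level.nrow(), n_cols = max_level.ncol();
  int n_sites = site_col.size();
  NumericMatrix current = clone(current_in);

  Scene sc;
  sc.current = &current;
  sc.n_cols = n_cols; sc.n_rows = n_rows; sc.cell = cell_size;
  sc.visual = as<double>(par["visual_range"]);
  sc.social = as<double>(par["social_range"]);
  sc.safe_r = as<double>(par["safe_radius"]);
  sc.max_step = as<double>(par["max_step"]);
  double target_E = as<double>(par["target_energy"]);
  double decay = as<double>(par["energy_decay"]);
  double gain = as<double>(par["gain_per_feed"]);
  int steps_per_day = as<int>(par["steps_per_day"]);

  double W = n_cols * cell_size, H = n_rows * cell_size;
  const double eps = 1e-9;

  // site geometry + 0-based adjacency
  std::vector<double> site_x(n_sites), site_y(n_sites);
  for (int i = 0; i < n_sites; ++i) {
    site_x[i] = (site_col[i] + 0.5) * cell_size;
    site_y[i] = (site_row[i] + 0.5) * cell_size;
  }
  std::vector<std::vector<int>> adj(n_sites);
  for (int i = 0; i < n_sites; ++i) {
    IntegerVector a = adjacency0[i];
    adj[i].assign(a.begin(), a.end());
  }

  // agent state
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> energy(energy0.begin(), energy0.end());
  std::vector<int> desired(desired0.begin(), desired0.end());
  std::vector<bool> fed_last(n, true);  // no failure signal before step 1
  std::vector<int> landmark(n, -1);
  // per-agent beliefs, initialized to the truth at step 0
  std::vector<std::vector<double>> believed(
      n, std::vector<double>(n_sites));
  for (int a = 0; a < n; ++a)
    for (int i = 0; i < n_sites; ++i)
      believed[a][i] = current(site_row[i], site_col[i]);

  int n_steps = days * steps_per_day;
  NumericMatrix traj(n_steps, 8);
  NumericMatrix snaps = record_agents ? NumericMatrix(n_steps * n, 6)
                                      : NumericMatrix(0, 6);

  std::vector<int> order(n);
  std::vector<double> mx(n - 1 > 0 ? n - 1 : 0), my(mx.size());
  std::vector<int> rc_buf; std::vector<double> rb_buf;
  std::vector<int> rr_buf;
  std::vector<std::pair<double, int>> near_buf;

  for (int step = 0; step < n_steps; ++step) {
    // seeded shuffle of the processing order (Fisher-Yates on R's RNG)
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    for (int oi = 0; oi < n; ++oi) {
      int a = order[oi];
      // mates (current positions of everyone else)
      int k = 0;
      for (int b = 0; b < n; ++b)
        if (b != a) { mx[k] = x[b]; my[k] = y[b]; ++k; }

      // 1. adapt desired-neighbor count
      bool at_target = energy[a] >= target_E - eps;
      if (at_target) desired[a] = std::min(desired[a] + 1, n - 1);
      else if (!fed_last[a]) desired[a] = std::max(desired[a] - 1, 0);

      bool use_leader = leader_mode && a != 0;
      double lx = use_leader ? x[0] : 0, ly = use_leader ? y[0] : 0;

      // 2. movement
      bool safe = safe_at(x[a], y[a], x[a], y[a], desired[a], mx, my,
                          use_leader, lx, ly, sc);
      double nx = x[a], ny = y[a];
      if (!safe) {
        bool have_target = false;
        double tx = 0, ty = 0;
        if (use_leader && dist2d(x[a], y[a], lx, ly) <= sc.social) {
          tx = lx; ty = ly; have_target = true;
        } else {
          near_buf.clear();
          for (int i = 0; i < (int)mx.size(); ++i) {
            double d = dist2d(mx[i], my[i], x[a], y[a]);
            if (d <= sc.social) near_buf.push_back({d, i});
          }
          if (!near_buf.empty()) {
            std::sort(near_buf.begin(), near_buf.end());
            int take = std::min((int)near_buf.size(),
                                std::max(desired[a], 1));
            double sx = 0, sy = 0;
            for (int i = 0; i < take; ++i) {
              sx += mx[near_buf[i].second]; sy += my[near_buf[i].second];
            }
            tx = sx / take; ty = sy / take; have_target = true;
          }
        }
        if (have_target) {
          double dd = dist2d(x[a], y[a], tx, ty);
          if (dd > sc.max_step) {
            nx = x[a] + (tx - x[a]) * sc.max_step / dd;
            ny = y[a] + (ty - y[a]) * sc.max_step / dd;
          } else { nx = tx; ny = ty; }
        }
      } else if (energy[a] < target_E - eps) {
        // recallable remembered sites under the agent's memory mode
        rc_buf.clear(); rr_buf.clear(); rb_buf.clear();
        if (n_sites > 0) {
          if (!landmark_mode) {
            for (int i = 0; i < n_sites; ++i) {
              rc_buf.push_back(site_col[i]); rr_buf.push_back(site_row[i]);
              rb_buf.push_back(believed[a][i]);
            }
          } else if (landmark[a] >= 0) {
            for (int i : adj[landmark[a]]) {
              rc_buf.push_back(site_col[i]); rr_buf.push_back(site_row[i]);
              rb_buf.push_back(believed[a][i]);
            }
          }
        }
        DestResult d = choose_destination_core(
            x[a], y[a], desired[a], sc, rc_buf, rr_buf, rb_buf, mx, my,
            use_leader, lx, ly);
        if (d.kind <= 1) {
          // land at a uniform-random point inside the chosen cell,
          // displacement clamped at max_step
          double px = (d.col + unif_rand()) * cell_size;
          double py = (d.row + unif_rand()) * cell_size;
          double dd = dist2d(x[a], y[a], px, py);
          if (dd > sc.max_step) {
            nx = x[a] + (px - x[a]) * sc.max_step / dd;
            ny = y[a] + (py - y[a]) * sc.max_step / dd;
          } else { nx = px; ny = py; }
        } else if (d.kind == 2) {
          nx = d.tx; ny = d.ty;
        } else {
          // exploration: random heading, length uniform in (0, max_step]
          double th = unif_rand() * 2.0 * M_PI;
          double len = (1.0 - unif_rand()) * sc.max_step;
          nx = x[a] + len * std::cos(th);
          ny = y[a] + len * std::sin(th);
        }
      }  // safe & sated: rest in place

      // keep agents on the landscape
      x[a] = std::min(std::max(nx, 0.0), W - eps);
      y[a] = std::min(std::max(ny, 0.0), H - eps);

      // 3. energetics: constant decay, feed if hungry and food underfoot
      energy[a] = std::max(energy[a] - decay, 0.0);
      bool fed = false;
      if (energy[a] < target_E - eps) {
        int cc = (int)std::floor(x[a] / cell_size);
        int cr = (int)std::floor(y[a] / cell_size);
        double avail = current(cr, cc);
        if (avail > 0) {
          double rem = std::min(gain, avail);
          current(cr, cc) = avail - rem;
          energy[a] += rem;
          fed = true;
        }
      }
      fed_last[a] = fed;

      // 4. memory: sight overrides belief; out-of-sight sites mentally regrow
      int nearest = -1;
      double nearest_d = R_PosInf;
      for (int i = 0; i < n_sites; ++i) {
        double d = dist2d(x[a], y[a], site_x[i], site_y[i]);
        if (d <= sc.visual) {
          believed[a][i] = current(site_row[i], site_col[i]);
          if (d < nearest_d) { nearest_d = d; nearest = i; }
        } else {
          believed[a][i] = std::min(believed[a][i] + grow_rate, site_max[i]);
        }
      }
      if (landmark_mode && nearest >= 0) landmark[a] = nearest;
    }

    // landscape regrowth, capped per cell
    for (int r = 0; r < n_rows; ++r)
      for (int c = 0; c < n_cols; ++c)
        current(r, c) = std::min(current(r, c) + grow_rate, max_level(r, c));

    // observation: recursive group centre + convex-hull spread
    double cx, cy; int n_in; bool ok;
    group_center_core(x, y, 100.0, 0.8, cx, cy, n_in, ok);
    std::vector<Pt> pts(n);
    for (int i = 0; i < n; ++i) pts[i] = {x[i], y[i]};
    traj(step, 0) = step + 1;
    traj(step, 1) = step / steps_per_day + 1;
    traj(step, 2) = step % steps_per_day;
    traj(step, 3) = cx;
    traj(step, 4) = cy;
    traj(step, 5) = hull_area(pts);
    traj(step, 6) = n_in;
    traj(step, 7) = ok ? 1 : 0;

    if (record_agents)
      for (int i = 0; i < n; ++i) {
        int rix = step * n + i;
        snaps(rix, 0) = step + 1;
        snaps(rix, 1) = i;
        snaps(rix, 2) = x[i];
        snaps(rix, 3) = y[i];
        snaps(rix, 4) = energy[i];
        snaps(rix, 5) = desired[i];
      }
  }

  return List::create(
      _["trajectory"] = traj,
      _["snapshots"] = snaps,
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["energy"] = NumericVector(energy.begin(), energy.end()),
      _["desired"] = IntegerVector(desired.begin(), desired.end()),
      _["final_current"] = current);
}
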