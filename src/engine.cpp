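// Compiled core of the foraging simulation: angular projection fields and the
// per-timestep loop. All geometry uses the bin-center ray-casting rule so that
// the R-level ray-casting oracle and this code perform identical double
// arithmetic (no asin in the hit test, no compiler FMA at default flags).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PI2 = 2.0 * M_PI;

// wrap to (-pi, pi]
static inline double wrap_pi(double a) {
  a -= PI2 * std::floor(a / PI2);  // [0, 2*pi)
  if (a > M_PI) a -= PI2;
  return a;
}

// wrap to [0, 2*pi)
static inline double wrap_2pi(double a) {
  a -= PI2 * std::floor(a / PI2);
  if (a < 0 || a >= PI2) a = 0.0;  // guard fp edge of the reduction
  return a;
}

// Reusable 1D binary angular field with nearest-hit depth, over relative angle
// phi in [-pi, pi) split into K bins with centers phi_k = -pi + (k + 0.5) * 2pi/K.
struct ProjBuf {
  int K = 0;
  double binw = 0.0;
  std::vector<double> depth;
  std::vector<unsigned char> val, seen;
  std::vector<int> touched;

  void init(int K_) {
    K = K_;
    binw = PI2 / K;
    depth.assign(K, 0.0);
    val.assign(K, 0);
    seen.assign(K, 0);
    touched.clear();
    touched.reserve(K);
  }

  void reset() {
    for (size_t i = 0; i < touched.size(); ++i) {
      int k = touched[i];
      seen[k] = 0;
      val[k] = 0;
    }
    touched.clear();
  }

  // Project one disk of radius R at (ox, oy) onto the field of a focal agent at
  // (fx, fy) with heading ftheta. A bin is hit iff the ray cast at the bin's
  // center angle intersects the disk (proj > 0 and perp^2 <= R^2); this equals
  // the |bearing - phi| <= asin(R/d) interval for d >= R and the pi/2 clamp for
  // d < R. With use_depth, nearer disks overwrite farther ones (occlusion);
  // otherwise target bins accumulate as a union. Bins outside [kmin, kmax]
  // (field-of-view window) are never written.
  void add(double fx, double fy, double ftheta, double ox, double oy,
           double R, bool is_target, bool use_depth, int kmin, int kmax) {
    if (kmin > kmax) return;
    double dx = ox - fx, dy = oy - fy;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d <= 0.0) return;
    double phic = wrap_pi(std::atan2(dy, dx) - ftheta);
    double alpha = (d > R) ? std::asin(R / d) : M_PI_2;
    // candidate bin range, padded one bin; exact per-bin test decides
    double lo = phic - alpha - binw, hi = phic + alpha + binw;
    int kl = (int)std::floor((lo + M_PI) / binw - 0.5);
    int kh = (int)std::ceil((hi + M_PI) / binw - 0.5);
    if (kh - kl >= K) { kl = 0; kh = K - 1; }
    for (int k = kl; k <= kh; ++k) {
      int kk = k % K;
      if (kk < 0) kk += K;
      if (kk < kmin || kk > kmax) continue;
      double phi = -M_PI + (kk + 0.5) * binw;
      double a = ftheta + phi;
      double rx = std::cos(a), ry = std::sin(a);
      double proj = dx * rx + dy * ry;
      if (proj <= 0.0) continue;
      double perp = dx * ry - dy * rx;
      double rem = R * R - perp * perp;
      if (rem < 0.0) continue;
      double t = proj - std::sqrt(rem);
      if (!seen[kk]) {
        seen[kk] = 1;
        touched.push_back(kk);
        depth[kk] = t;
        val[kk] = is_target ? 1 : 0;
      } else if (use_depth) {
        if (t < depth[kk]) {
          depth[kk] = t;
          val[kk] = is_target ? 1 : 0;
        }
      } else if (is_target) {
        val[kk] = 1;
      }
    }
  }

  // Occlusion pass: darken bins already holding a target whenever this
  // (non-target) disk is hit strictly nearer along the bin's ray. Running all
  // targets first (with use_depth) and then occluders through here is
  // equivalent to a full nearest-hit depth sort, but skips every bin no
  // target covers.
  void occlude(double fx, double fy, double ftheta, double ox, double oy,
               double R, int kmin, int kmax) {
    if (kmin > kmax) return;
    double dx = ox - fx, dy = oy - fy;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d <= 0.0) return;
    double phic = wrap_pi(std::atan2(dy, dx) - ftheta);
    double alpha = (d > R) ? std::asin(R / d) : M_PI_2;
    double lo = phic - alpha - binw, hi = phic + alpha + binw;
    int kl = (int)std::floor((lo + M_PI) / binw - 0.5);
    int kh = (int)std::ceil((hi + M_PI) / binw - 0.5);
    if (kh - kl >= K) { kl = 0; kh = K - 1; }
    for (int k = kl; k <= kh; ++k) {
      int kk = k % K;
      if (kk < 0) kk += K;
      if (kk < kmin || kk > kmax) continue;
      if (!seen[kk] || !val[kk]) continue;
      double phi = -M_PI + (kk + 0.5) * binw;
      double a = ftheta + phi;
      double rx = std::cos(a), ry = std::sin(a);
      double proj = dx * rx + dy * ry;
      if (proj <= 0.0) continue;
      double perp = dx * ry - dy * rx;
      double rem = R * R - perp * perp;
      if (rem < 0.0) continue;
      double t = proj - std::sqrt(rem);
      if (t < depth[kk]) val[kk] = 0;
    }
  }
};

// index window [kmin, kmax] of bins whose center satisfies |phi_k| <= L
static inline void fov_window(double L, int K, double binw,
                              int &kmin, int &kmax) {
  kmin = (int)std::ceil((M_PI - L) / binw - 0.5);
  kmax = (int)std::floor((M_PI + L) / binw - 0.5);
  if (kmin < 0) kmin = 0;
  if (kmax > K - 1) kmax = K - 1;
}

// [[Rcpp::export]]
IntegerVector cpp_project_social(double fx, double fy, double ftheta,
                                 int fpatch,
                                 NumericVector x, NumericVector y,
                                 LogicalVector exploiting,
                                 IntegerVector patch,
                                 double agent_radius, double fov,
                                 bool occlusion, int K) {
  ProjBuf B;
  B.init(K);
  int kmin, kmax;
  fov_window(fov, K, B.binw, kmin, kmax);
  int n = x.size();
  std::vector<char> tgt(n);
  for (int j = 0; j < n; ++j) {
    double dx = x[j] - fx, dy = y[j] - fy;
    if (dx == 0.0 && dy == 0.0)
      stop("degenerate geometry: coincident agent centers");
    bool expl = (exploiting[j] == TRUE);
    bool same_patch = (fpatch != NA_INTEGER && patch[j] != NA_INTEGER &&
                       patch[j] == fpatch);
    tgt[j] = (expl && !same_patch) ? 1 : 0;
    if (tgt[j]) {
      B.add(fx, fy, ftheta, x[j], y[j], agent_radius, true, occlusion,
            kmin, kmax);
    }
  }
  if (occlusion) {
    for (int j = 0; j < n; ++j) {
      if (!tgt[j]) {
        B.occlude(fx, fy, ftheta, x[j], y[j], agent_radius, kmin, kmax);
      }
    }
  }
  IntegerVector out(K);
  for (size_t i = 0; i < B.touched.size(); ++i) {
    int k = B.touched[i];
    if (B.val[k]) out[k] = 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_proximity_field(double fx, double fy, double ftheta,
                                  NumericVector x, NumericVector y,
                                  double agent_radius, double sense_range,
                                  int K) {
  ProjBuf B;
  B.init(K);
  int n = x.size();
  double dmax = 2.0 * agent_radius + sense_range;
  for (int j = 0; j < n; ++j) {
    double dx = x[j] - fx, dy = y[j] - fy;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d == 0.0)
      stop("degenerate geometry: coincident agent centers");
    if (d > dmax) continue;
    B.add(fx, fy, ftheta, x[j], y[j], agent_radius, true, false, 0, K - 1);
  }
  IntegerVector out(K);
  for (size_t i = 0; i < B.touched.size(); ++i) {
    int k = B.touched[i];
    if (B.val[k]) out[k] = 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full simulation loop.
//
// patches0 columns: x, y, radius, units_total, units_left, quality, id
// agents0 columns:  x, y, theta, v
// States: 0 = exploration, 1 = social relocation, 2 = exploitation.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_sim(List cfg, NumericMatrix patches0, NumericMatrix agents0,
                 int T, bool record_traces) {
  const double W = cfg["arena_width"], H = cfg["arena_height"];
  const double RA = cfg["agent_radius"];
  const double v_exp = cfg["v_exp"], v_soc = cfg["v_soc"];
  const double th_exp = cfg["theta_exp_max"], th_soc = cfg["theta_soc_max"];
  const double r_stop = cfg["r_stop"], r_turn = cfg["r_turn"];
  const int Tn = cfg["novelty_length"];
  const double Bu = cfg["baseline_u"], Bw = cfg["baseline_w"];
  const double umax = cfg["u_max"], wmax = cfg["w_max"];
  const double gu = cfg["g_u"], gw = cfg["g_w"];
  const double Tu = cfg["threshold_u"], Twt = cfg["threshold_w"];
  const double epsu = cfg["eps_u"], epsw = cfg["eps_w"];
  const double Suw = cfg["s_uw"], Swu = cfg["s_wu"];
  const double fov = cfg["fov_half_angle"];
  const bool occl = cfg["occlusion"], coll = cfg["collisions"];
  const int K = cfg["resolution"], Kp = cfg["prox_resolution"];
  const double prox_range = cfg["prox_range"];
  const int max_attempts = cfg["max_place_attempts"];

  const int NA_ = agents0.nrow();
  const int NR = patches0.nrow();

  // agent state
  std::vector<double> ax(NA_), ay(NA_), ath(NA_), av(NA_);
  std::vector<double> u(NA_, 0.0), w(NA_, 0.0);
  std::vector<double> consumed_prev(NA_, 0.0), Iper(NA_, 0.0);
  std::vector<double> w_input(NA_, 0.0), Dhemi(NA_, 0.0);
  std::vector<int> state(NA_, 0), novt(NA_, 0), phere(NA_, -1);
  std::vector<int> prox_ovr(NA_, 0);
  std::vector<double> prox_dir(NA_, 0.0);
  std::vector<double> consumed_agent(NA_, 0.0);
  for (int i = 0; i < NA_; ++i) {
    ax[i] = agents0(i, 0);
    ay[i] = agents0(i, 1);
    ath[i] = agents0(i, 2);
    av[i] = agents0(i, 3);
  }

  // patch state (slot-based; ids advance on regeneration)
  std::vector<double> px(NR), py(NR), pr(NR), ptot(NR), pleft(NR), pq(NR);
  std::vector<int> pid(NR);
  int next_id = 0;
  for (int j = 0; j < NR; ++j) {
    px[j] = patches0(j, 0);
    py[j] = patches0(j, 1);
    pr[j] = patches0(j, 2);
    ptot[j] = patches0(j, 3);
    pleft[j] = patches0(j, 4);
    pq[j] = patches0(j, 5);
    pid[j] = (int)patches0(j, 6);
    if (pid[j] > next_id) next_id = pid[j];
  }

  // per-(agent, patch-lifetime) novelty bookkeeping
  std::vector<unsigned char> discovered((size_t)NA_ * std::max(NR, 1), 0);

  ProjBuf VB, PB;
  VB.init(K);
  if (coll) PB.init(Kp);
  int kmin, kmax;
  fov_window(fov, K, VB.binw, kmin, kmax);
  // central 10% window of the proximity field: |phi| <= 0.1 * pi
  int pc_min = 0, pc_max = -1;
  if (coll) fov_window(0.1 * M_PI, Kp, PB.binw, pc_min, pc_max);
  const double prox_dmax = 2.0 * RA + prox_range;

  auto patch_at = [&](double qx, double qy) -> int {
    for (int j = 0; j < NR; ++j) {
      double dx = qx - px[j], dy = qy - py[j];
      if (dx * dx + dy * dy <= pr[j] * pr[j]) return j;
    }
    return -1;
  };

  auto place_patch = [&](int slot) -> bool {
    for (int att = 0; att < max_attempts; ++att) {
      double cx = R::runif(pr[slot], W - pr[slot]);
      double cy = R::runif(pr[slot], H - pr[slot]);
      bool ok = true;
      for (int q = 0; q < NR; ++q) {
        if (q == slot) continue;
        double ddx = px[q] - cx, ddy = py[q] - cy;
        double rr = pr[q] + pr[slot];
        if (ddx * ddx + ddy * ddy < rr * rr) { ok = false; break; }
      }
      if (ok) { px[slot] = cx; py[slot] = cy; return true; }
    }
    return false;
  };

  // ledgers
  NumericVector led_consumed(T), led_units(T), led_dhat(T);
  IntegerVector led_regen(T), led_nexp(T), led_nsoc(T), led_nind(T);
  NumericMatrix tr_x, tr_y, tr_v, tr_th, tr_u, tr_w;
  IntegerMatrix tr_state;
  if (record_traces) {
    tr_x = NumericMatrix(T, NA_);
    tr_y = NumericMatrix(T, NA_);
    tr_v = NumericMatrix(T, NA_);
    tr_th = NumericMatrix(T, NA_);
    tr_u = NumericMatrix(T, NA_);
    tr_w = NumericMatrix(T, NA_);
    tr_state = IntegerMatrix(T, NA_);
  }

  double total_consumed = 0.0;
  long soc_steps = 0;
  int n_regen = 0;
  bool too_dense = false;

  for (int t = 0; t < T; ++t) {
    // --- phase 1: discovery, novelty and personal information -------------
    for (int i = 0; i < NA_; ++i) {
      int slot = patch_at(ax[i], ay[i]);
      phere[i] = slot;
      if (slot >= 0 && !discovered[(size_t)i * NR + slot]) {
        discovered[(size_t)i * NR + slot] = 1;
        novt[i] = Tn;
      }
      double Nv = 0.0;
      if (novt[i] > 0) { Nv = 1.0; novt[i]--; }
      Iper[i] = (Nv + consumed_prev[i]) * 0.5;
    }

    // --- phase 2: perception from the step-start snapshot -----------------
    int n_targets = 0;
    for (int i = 0; i < NA_; ++i)
      if (state[i] == 2 && phere[i] >= 0) n_targets++;
    bool need_social = (epsw != 0.0) && (n_targets > 0) && (kmin <= kmax);

    for (int i = 0; i < NA_; ++i) {
      w_input[i] = 0.0;
      Dhemi[i] = 0.0;
      if (need_social) {
        VB.reset();
        for (int j = 0; j < NA_; ++j) {
          if (j == i) continue;
          bool tgt = (state[j] == 2 && phere[j] >= 0 &&
                      !(phere[i] >= 0 && phere[j] == phere[i]));
          if (!tgt) continue;
          VB.add(ax[i], ay[i], ath[i], ax[j], ay[j], RA, true, occl,
                 kmin, kmax);
        }
        if (occl) {
          for (int j = 0; j < NA_; ++j) {
            if (j == i) continue;
            bool tgt = (state[j] == 2 && phere[j] >= 0 &&
                        !(phere[i] >= 0 && phere[j] == phere[i]));
            if (tgt) continue;
            VB.occlude(ax[i], ay[i], ath[i], ax[j], ay[j], RA, kmin, kmax);
          }
        }
        double s_all = 0.0, s_left = 0.0;
        for (size_t ii = 0; ii < VB.touched.size(); ++ii) {
          int k = VB.touched[ii];
          if (VB.val[k]) {
            s_all += 1.0;
            double phi = -M_PI + (k + 0.5) * VB.binw;
            if (phi > 0) s_left += 1.0;
          }
        }
        w_input[i] = s_all / K;
        Dhemi[i] = (s_left - (s_all - s_left)) / (K / 2.0);
      }
      prox_ovr[i] = 0;
      if (coll) {
        PB.reset();
        bool any_near = false;
        for (int j = 0; j < NA_; ++j) {
          if (j == i) continue;
          double dx = ax[j] - ax[i], dy = ay[j] - ay[i];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d > prox_dmax || d == 0.0) continue;
          any_near = true;
          PB.add(ax[i], ay[i], ath[i], ax[j], ay[j], RA, true, false,
                 0, Kp - 1);
        }
        if (any_near) {
          bool central = false;
          for (int k = pc_min; k <= pc_max; ++k)
            if (PB.val[k]) { central = true; break; }
          if (central) {
            double s_left = 0.0, s_right = 0.0;
            for (size_t ii = 0; ii < PB.touched.size(); ++ii) {
              int k = PB.touched[ii];
              if (PB.val[k]) {
                double phi = -M_PI + (k + 0.5) * PB.binw;
                if (phi > 0) s_left += 1.0; else s_right += 1.0;
              }
            }
            prox_ovr[i] = 1;
            prox_dir[i] = (s_left <= s_right) ? 1.0 : -1.0;
          }
        }
      }
    }

    // --- phase 3: integrate evidence, select state, move ------------------
    for (int i = 0; i < NA_; ++i) {
      double up = (u[i] > 0) ? u[i] : 0.0;
      double wp = (w[i] > 0) ? w[i] : 0.0;
      double unew = u[i] + epsu * Iper[i] - gu * (u[i] - Bu) - Swu * wp;
      double wnew = w[i] + epsw * w_input[i] - gw * (w[i] - Bw) - Suw * up;
      if (unew > umax) unew = umax;
      if (unew < 0.0) unew = 0.0;
      if (wnew > wmax) wnew = wmax;
      if (wnew < 0.0) wnew = 0.0;
      u[i] = unew;
      w[i] = wnew;

      bool aind = (unew > Tu);
      bool asoc = (!aind) && (wnew > Twt);
      double Fv, Tt;
      if (aind) {
        Fv = -r_stop * av[i];
        if (phere[i] >= 0) {
          double thg = std::atan2(py[phere[i]] - ay[i], px[phere[i]] - ax[i]);
          Tt = r_turn * wrap_pi(thg - ath[i]);
        } else {
          Tt = 0.0;
        }
      } else if (asoc) {
        Fv = v_soc - av[i];
        Tt = th_soc * Dhemi[i];
      } else {
        Fv = v_exp - av[i];
        Tt = R::runif(-th_exp, th_exp);
      }
      if (coll && prox_ovr[i]) {
        Fv = -av[i];
        Tt = prox_dir[i] * th_soc;
      }
      ath[i] = wrap_2pi(ath[i] + Tt);
      av[i] += Fv;
      if (av[i] < 0.0) av[i] = 0.0;
      ax[i] += av[i] * std::cos(ath[i]);
      ay[i] += av[i] * std::sin(ath[i]);

      // reflective walls: mirror position, reflect heading component
      for (int guard = 0; guard < 8; ++guard) {
        bool bounced = false;
        if (ax[i] < RA) {
          ax[i] = 2.0 * RA - ax[i];
          ath[i] = wrap_2pi(M_PI - ath[i]);
          bounced = true;
        } else if (ax[i] > W - RA) {
          ax[i] = 2.0 * (W - RA) - ax[i];
          ath[i] = wrap_2pi(M_PI - ath[i]);
          bounced = true;
        }
        if (ay[i] < RA) {
          ay[i] = 2.0 * RA - ay[i];
          ath[i] = wrap_2pi(-ath[i]);
          bounced = true;
        } else if (ay[i] > H - RA) {
          ay[i] = 2.0 * (H - RA) - ay[i];
          ath[i] = wrap_2pi(-ath[i]);
          bounced = true;
        }
        if (!bounced) break;
      }
      if (ax[i] < RA) ax[i] = RA;
      if (ax[i] > W - RA) ax[i] = W - RA;
      if (ay[i] < RA) ay[i] = RA;
      if (ay[i] > H - RA) ay[i] = H - RA;

      state[i] = aind ? 2 : (asoc ? 1 : 0);
    }

    // --- phase 4: consumption, sequential in ascending agent id ----------
    double step_consumed = 0.0;
    for (int i = 0; i < NA_; ++i) {
      consumed_prev[i] = 0.0;
      if (state[i] != 2) continue;
      int slot = patch_at(ax[i], ay[i]);
      if (slot < 0) continue;
      double c = pq[slot];
      if (pleft[slot] < c) c = pleft[slot];
      if (c <= 0.0) continue;
      pleft[slot] -= c;
      consumed_prev[i] = c;
      consumed_agent[i] += c;
      step_consumed += c;
    }
    total_consumed += step_consumed;

    // --- phase 5: regenerate depleted patches -----------------------------
    int regen_here = 0;
    for (int j = 0; j < NR; ++j) {
      if (pleft[j] <= 0.0) {
        if (!place_patch(j)) { too_dense = true; break; }
        pleft[j] = ptot[j];
        pid[j] = ++next_id;
        for (int i = 0; i < NA_; ++i) discovered[(size_t)i * NR + j] = 0;
        regen_here++;
        n_regen++;
      }
    }
    if (too_dense) stop("environment too dense: patch regeneration failed");

    // --- phase 6: record ---------------------------------------------------
    double usum = 0.0;
    for (int j = 0; j < NR; ++j) usum += pleft[j];
    int nexp = 0, nsoc = 0, nind = 0;
    for (int i = 0; i < NA_; ++i) {
      if (state[i] == 0) nexp++;
      else if (state[i] == 1) nsoc++;
      else nind++;
    }
    soc_steps += nsoc;
    double dh = NA_REAL;
    if (NA_ >= 2) {
      double s = 0.0;
      for (int i = 0; i < NA_; ++i)
        for (int j = i + 1; j < NA_; ++j) {
          double dx = ax[j] - ax[i], dy = ay[j] - ay[i];
          s += std::sqrt(dx * dx + dy * dy);
        }
      dh = 2.0 * s / ((double)NA_ * (NA_ - 1));
    }
    led_consumed[t] = step_consumed;
    led_units[t] = usum;
    led_regen[t] = regen_here;
    led_nexp[t] = nexp;
    led_nsoc[t] = nsoc;
    led_nind[t] = nind;
    led_dhat[t] = dh;
    if (record_traces) {
      for (int i = 0; i < NA_; ++i) {
        tr_x(t, i) = ax[i];
        tr_y(t, i) = ay[i];
        tr_v(t, i) = av[i];
        tr_th(t, i) = ath[i];
        tr_u(t, i) = u[i];
        tr_w(t, i) = w[i];
        tr_state(t, i) = state[i];
      }
    }
  }

  NumericMatrix patches_out(NR, 7);
  for (int j = 0; j < NR; ++j) {
    patches_out(j, 0) = px[j];
    patches_out(j, 1) = py[j];
    patches_out(j, 2) = pr[j];
    patches_out(j, 3) = ptot[j];
    patches_out(j, 4) = pleft[j];
    patches_out(j, 5) = pq[j];
    patches_out(j, 6) = pid[j];
  }
  NumericMatrix agents_out(NA_, 7);
  for (int i = 0; i < NA_; ++i) {
    agents_out(i, 0) = ax[i];
    agents_out(i, 1) = ay[i];
    agents_out(i, 2) = ath[i];
    agents_out(i, 3) = av[i];
    agents_out(i, 4) = u[i];
    agents_out(i, 5) = w[i];
    agents_out(i, 6) = state[i];
  }

  double denom = (double)NA_ * T;
  List out = List::create(
      _["E"] = (denom > 0) ? total_consumed / denom : NA_REAL,
      _["T_soc"] = (denom > 0) ? soc_steps / denom : NA_REAL,
      _["D_hat"] = (NA_ >= 2) ? (double)mean(led_dhat) : NA_REAL,
      _["total_consumed"] = total_consumed,
      _["n_regen"] = n_regen,
      _["consumed_agent"] = NumericVector(consumed_agent.begin(),
                                          consumed_agent.end()),
      _["led_consumed"] = led_consumed,
      _["led_units"] = led_units,
      _["led_regen"] = led_regen,
      _["led_nexp"] = led_nexp,
      _["led_nsoc"] = led_nsoc,
      _["led_nind"] = led_nind,
      _["led_dhat"] = led_dhat,
      _["patches"] = patches_out,
      _["agents"] = agents_out);
  if (record_traces) {
    out["trace_x"] = tr_x;
    out["trace_y"] = tr_y;
    out["trace_v"] = tr_v;
    out["trace_theta"] = tr_th;
    out["trace_u"] = tr_u;
    out["trace_w"] = tr_w;
    out["trace_state"] = tr_state;
  }
  return out;
}
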