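#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fast discrete-event stepper for collapse-driven community dynamics.
//
// One step = one collapse event. RNG draws come from R's generator
// (unif_rand) in a fixed, documented order so that trajectories are
// bit-reproducible and can be mirrored by the pure-R reference stepper:
//   1. between-collapse update (drift/fluct): N uniforms, slot order 1..N
//   2. victim selection: 1 uniform
//   3. newcomer parameter resampling (fitness variant): 2 uniforms
//
// Victim selection contract (shared with the R reference):
//   uniform:  v = floor(u * N), clamped to N-1
//   weighted: target = u * sum(w); v = first index with cumsum(w) > target
// For equal weights both rules coincide.

// Long-double accumulation mirrors base R's sum()/cumsum(), keeping the
// compiled stepper bit-identical to the pure-R reference.
static inline int pick_weighted(const std::vector<double> &w, double u) {
  const int n = (int)w.size();
  long double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += w[i];
  double target = u * (double)tot;
  long double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if ((double)acc > target) return i;
  }
  return n - 1;
}

static inline double ldsum(const NumericVector &x) {
  long double s = 0.0;
  for (int i = 0; i < x.size(); ++i) s += x[i];
  return (double)s;
}

// f(A) = sum_i P_i exp(Omega_i A) - 1, evaluated with overflow guard.
static inline double growth_excess(const NumericVector &P,
                                   const NumericVector &omega, double A) {
  double s = 0.0;
  const int n = P.size();
  for (int i = 0; i < n; ++i) {
    if (P[i] <= 0.0) continue;
    double e = std::log(P[i]) + omega[i] * A;
    if (e > 50.0) return 1e30;  // far above capacity; bisection will recover
    s += std::exp(e);
  }
  return s - 1.0;
}

// Solve sum_i P_i exp(Omega_i A) = 1 for the growth time-scalar A >= 0.
// Monotone in A; bracketed bisection with Newton acceleration.
static double solve_growth_scalar(const NumericVector &P,
                                  const NumericVector &omega) {
  const int n = P.size();
  double s = 0.0, omin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    s += P[i];
    if (P[i] > 0.0 && omega[i] < omin) omin = omega[i];
  }
  if (s >= 1.0) return 0.0;
  double lo = 0.0, hi = std::log(1.0 / s) / omin;
  double flo = growth_excess(P, omega, lo);
  if (flo >= 0.0) return 0.0;
  double A = 0.5 * hi;
  for (int it = 0; it < 200; ++it) {
    double f = growth_excess(P, omega, A);
    if (f > 0.0) hi = A; else lo = A;
    // Newton step from derivative sum P_i Omega_i exp(Omega_i A)
    double df = 0.0;
    if (f < 1e29) {
      for (int i = 0; i < n; ++i) {
        if (P[i] <= 0.0) continue;
        double e = std::log(P[i]) + omega[i] * A;
        if (e < 50.0) df += omega[i] * std::exp(e);
      }
    }
    double Anew;
    if (df > 0.0 && f < 1e29) {
      Anew = A - f / df;
      if (!(Anew > lo && Anew < hi)) Anew = 0.5 * (lo + hi);
    } else {
      Anew = 0.5 * (lo + hi);
    }
    if (std::fabs(Anew - A) <= 1e-14 * (1.0 + std::fabs(A))) { A = Anew; break; }
    A = Anew;
  }
  return A;
}

// [[Rcpp::export]]
List sim_engine_cpp(int N, double gamma_, int n_steps, int burn_in,
                    int victim_policy,  // 0 uniform, 1 power_weighted, 2 fitness_c
                    double sigma,
                    int collapse_mode,  // 0 replace_with_newcomer, 1 shrink_by_gamma_i
                    int growth_mode,    // 0 common, 1 per_species
                    bool equalize_at_wave_start,
                    int update_kind,    // 0 none, 1 neutral drift, 2 exp fluct
                    double update_rate, // r (drift) or n (fluct)
                    int drift_law,      // 0 linear, 1 sqrt
                    NumericVector omega_in, NumericVector c_in,
                    NumericVector gamma_i_in,
                    bool resample_on_replace,
                    double omega_lo, double omega_hi,
                    double c_lo, double c_hi,
                    double wave_threshold, double substantial_threshold,
                    double sad_lo, double sad_w, int sad_nbins,
                    bool record_events, bool record_diversity, bool record_sad,
                    bool record_snapshots, bool record_species_stats) {
  if (N < 2) stop("N must be >= 2");
  if (!(gamma_ > 0.0 && gamma_ < 1.0)) stop("gamma must be in (0,1)");
  if (update_kind == 2 && update_rate >= 1.0)
    stop("fluctuation amplitude n must be < 1");

  const bool per_species_growth = (growth_mode == 1);
  const bool has_update = (update_kind != 0);
  const bool has_omega = (omega_in.size() == N);

  NumericVector P(N), omega = clone(omega_in), cwt = clone(c_in),
                gam_i = clone(gamma_i_in);
  std::vector<double> lp(N);           // cached log10 populations
  IntegerVector sid(N), birth(N), nsub_birth(N);
  const double l10N = std::log10((double)N);
  for (int i = 0; i < N; ++i) {
    P[i] = 1.0 / N;
    lp[i] = -l10N;
    sid[i] = i;
    birth[i] = 0;
    nsub_birth[i] = N;
  }
  int next_id = N;
  const double l10gamma = std::log10(gamma_);
  const double inv_w = 1.0 / sad_w;
  const double log_olo = std::log(omega_lo), log_ohi = std::log(omega_hi);
  const double log_clo = std::log(c_lo), log_chi = std::log(c_hi);

  // recorders
  IntegerVector ev_step(0), ev_slot(0), ev_sid(0), ev_birth(0), ev_nsub(0);
  NumericVector ev_pre(0), ev_rescale(0);
  LogicalVector ev_bound(0);
  if (record_events) {
    ev_step = IntegerVector(n_steps); ev_slot = IntegerVector(n_steps);
    ev_sid = IntegerVector(n_steps); ev_birth = IntegerVector(n_steps);
    ev_nsub = IntegerVector(n_steps); ev_pre = NumericVector(n_steps);
    ev_rescale = NumericVector(n_steps); ev_bound = LogicalVector(n_steps);
  }
  NumericVector div_D(0), div_pmax(0);
  if (record_diversity) { div_D = NumericVector(n_steps); div_pmax = NumericVector(n_steps); }
  std::vector<double> sad(record_sad ? sad_nbins : 0, 0.0);
  std::vector<double> green(record_snapshots ? sad_nbins : 0, 0.0);
  std::vector<double> red(record_snapshots ? sad_nbins : 0, 0.0);
  long long sad_n = 0, snap_n = 0;
  NumericVector sp_sum(record_species_stats ? N : 0);
  IntegerVector sp_cnt(record_species_stats ? N : 0);
  std::vector<double> fl_omega, fl_c, fl_sum;
  std::vector<int> fl_cnt, fl_sid;

  std::vector<double> w(victim_policy != 0 ? N : 0);

  RNGScope rngscope;

  for (int t = 1; t <= n_steps; ++t) {
    // (1) optional between-collapse update, then renormalize
    if (has_update) {
      if (update_kind == 1) {  // neutral drift: P -> P +/- r*P*(1-P)
        for (int i = 0; i < N; ++i) {
          double u = unif_rand();
          double mag = (drift_law == 0)
                           ? update_rate * P[i] * (1.0 - P[i])
                           : update_rate * std::sqrt(P[i] * (1.0 - P[i]));
          P[i] += (u < 0.5 ? -mag : mag);
          if (P[i] < 0.0) P[i] = 0.0;
        }
      } else {  // exponential fluctuations: P -> P * (1 +/- n*Omega_i)
        for (int i = 0; i < N; ++i) {
          double u = unif_rand();
          double f = update_rate * (has_omega ? omega[i] : 1.0);
          P[i] *= (u < 0.5 ? (1.0 - f) : (1.0 + f));
        }
      }
      double r = 1.0 / ldsum(P);
      for (int i = 0; i < N; ++i) {
        P[i] *= r;
        lp[i] = (P[i] > 0.0) ? std::log10(P[i]) : sad_lo;
      }
    }

    // (2) victim selection
    double u = unif_rand();
    int v;
    if (victim_policy == 0 || (victim_policy == 1 && sigma == 0.0)) {
      v = (int)(u * N);
      if (v >= N) v = N - 1;
    } else if (victim_policy == 1) {
      if (sigma == 1.0) {
        for (int i = 0; i < N; ++i) w[i] = P[i];
      } else {
        for (int i = 0; i < N; ++i) {
          if (P[i] <= 0.0 && sigma < 0.0)
            stop("power-weighted selection with negative exponent requires strictly positive populations");
          w[i] = std::pow(P[i], sigma);
        }
      }
      v = pick_weighted(w, u);
    } else {
      for (int i = 0; i < N; ++i) w[i] = cwt[i];
      v = pick_weighted(w, u);
    }

    const double pre = P[v];
    int nsub = 0;
    for (int i = 0; i < N; ++i) if (P[i] > substantial_threshold) ++nsub;
    const bool boundary = pre > wave_threshold;

    // (3) collapse: replace victim by newcomer at gamma, or shrink in place
    int victim_sid = sid[v], victim_birth = birth[v], victim_nsub = nsub_birth[v];
    if (collapse_mode == 0) {
      if (record_species_stats && sp_cnt[v] > 0) {
        fl_omega.push_back(has_omega ? omega[v] : NA_REAL);
        fl_c.push_back(cwt.size() == N ? cwt[v] : NA_REAL);
        fl_sum.push_back(sp_sum[v]);
        fl_cnt.push_back(sp_cnt[v]);
        fl_sid.push_back(sid[v]);
        sp_sum[v] = 0.0; sp_cnt[v] = 0;
      }
      P[v] = gamma_;
      lp[v] = l10gamma;
      sid[v] = next_id++;
      birth[v] = t;
      nsub_birth[v] = nsub;
      if (resample_on_replace) {
        double u1 = unif_rand(), u2 = unif_rand();
        if (has_omega) omega[v] = std::exp(log_olo + u1 * (log_ohi - log_olo));
        if (cwt.size() == N) cwt[v] = std::exp(log_clo + u2 * (log_chi - log_clo));
      }
    } else {
      P[v] *= gam_i[v];
      lp[v] = (P[v] > 0.0) ? std::log10(P[v]) : sad_lo;
    }

    double s = ldsum(P);
    if (s <= 0.0) stop("total population vanished");
    const double rescale = 1.0 / s;

    // (4) green snapshot: wave boundary, pre-rescale
    const bool aggregate = (t > burn_in);
    if (record_snapshots && boundary && aggregate) {
      for (int i = 0; i < N; ++i) {
        int b = (int)((lp[i] - sad_lo) * inv_w);
        if (b < 0) b = 0; if (b >= sad_nbins) b = sad_nbins - 1;
        green[b] += 1.0;
      }
      ++snap_n;
    }

    // (5) saturation back to the carrying capacity
    if (equalize_at_wave_start && boundary) {
      for (int i = 0; i < N; ++i) { P[i] = 1.0 / N; lp[i] = -l10N; }
    } else if (!per_species_growth) {
      const double lr = std::log10(rescale);
      for (int i = 0; i < N; ++i) { P[i] *= rescale; lp[i] += lr; }
    } else {
      double A = solve_growth_scalar(P, omega);
      for (int i = 0; i < N; ++i) P[i] *= std::exp(omega[i] * A);
      double r2 = 1.0 / ldsum(P);  // residual cleanup, |sum-1| <= 1e-12
      for (int i = 0; i < N; ++i) {
        P[i] *= r2;
        lp[i] = (P[i] > 0.0) ? std::log10(P[i]) : sad_lo;
      }
    }

    // (6) red snapshot + aggregated recorders
    if (record_snapshots && boundary && aggregate) {
      for (int i = 0; i < N; ++i) {
        int b = (int)((lp[i] - sad_lo) * inv_w);
        if (b < 0) b = 0; if (b >= sad_nbins) b = sad_nbins - 1;
        red[b] += 1.0;
      }
    }
    if (record_sad && aggregate) {
      for (int i = 0; i < N; ++i) {
        int b = (int)((lp[i] - sad_lo) * inv_w);
        if (b < 0) b = 0; if (b >= sad_nbins) b = sad_nbins - 1;
        sad[b] += 1.0;
      }
      ++sad_n;
    }
    if (record_species_stats && aggregate)
      for (int i = 0; i < N; ++i) { sp_sum[i] += P[i]; ++sp_cnt[i]; }
    if (record_diversity) {
      long double q = 0.0;
      double pm = 0.0;
      for (int i = 0; i < N; ++i) { q += P[i] * P[i]; if (P[i] > pm) pm = P[i]; }
      div_D[t - 1] = 1.0 / (double)q;
      div_pmax[t - 1] = pm;
    }
    if (record_events) {
      ev_step[t - 1] = t; ev_slot[t - 1] = v + 1; ev_sid[t - 1] = victim_sid;
      ev_birth[t - 1] = victim_birth; ev_nsub[t - 1] = victim_nsub;
      ev_pre[t - 1] = pre; ev_rescale[t - 1] = rescale;
      ev_bound[t - 1] = boundary;
    }

    if ((t & 2047) == 0) {  // refresh cached logs; kills additive drift
      for (int i = 0; i < N; ++i)
        lp[i] = (P[i] > 0.0) ? std::log10(P[i]) : sad_lo;
      Rcpp::checkUserInterrupt();
    }
  }

  if (record_species_stats && collapse_mode == 0) {
    for (int i = 0; i < N; ++i) {
      if (sp_cnt[i] > 0) {
        fl_omega.push_back(has_omega ? omega[i] : NA_REAL);
        fl_c.push_back(cwt.size() == N ? cwt[i] : NA_REAL);
        fl_sum.push_back(sp_sum[i]);
        fl_cnt.push_back(sp_cnt[i]);
        fl_sid.push_back(sid[i]);
      }
    }
  }

  List out = List::create(
      _["final"] = List::create(
          _["populations"] = P, _["species_id"] = sid, _["birth_step"] = birth,
          _["n_substantial_at_birth"] = nsub_birth, _["step"] = n_steps,
          _["next_id"] = next_id, _["omega"] = omega, _["c"] = cwt,
          _["gamma_i"] = gam_i),
      _["sad_counts"] = NumericVector(sad.begin(), sad.end()),
      _["sad_n"] = (double)sad_n,
      _["green_counts"] = NumericVector(green.begin(), green.end()),
      _["red_counts"] = NumericVector(red.begin(), red.end()),
      _["snap_n"] = (double)snap_n);
  if (record_events)
    out["events"] = DataFrame::create(
        _["step"] = ev_step, _["victim_index"] = ev_slot,
        _["victim_species_id"] = ev_sid, _["victim_birth_step"] = ev_birth,
        _["victim_n_substantial_at_birth"] = ev_nsub,
        _["pre_collapse_size"] = ev_pre, _["rescale_factor"] = ev_rescale,
        _["is_wave_boundary"] = ev_bound);
  if (record_diversity)
    out["diversity"] = DataFrame::create(_["step"] = seq_len(n_steps),
                                         _["D"] = div_D, _["P_max"] = div_pmax);
  if (record_species_stats) {
    out["species_stats"] = DataFrame::create(
        _["species_id"] = (collapse_mode == 0)
            ? IntegerVector(fl_sid.begin(), fl_sid.end()) : sid,
        _["omega"] = (collapse_mode == 0)
            ? NumericVector(fl_omega.begin(), fl_omega.end())
            : (has_omega ? omega : NumericVector(N, NA_REAL)),
        _["c"] = (collapse_mode == 0)
            ? NumericVector(fl_c.begin(), fl_c.end())
            : (cwt.size() == N ? cwt : NumericVector(N, NA_REAL)),
        _["gamma_i"] = (collapse_mode == 0)
            ? NumericVector(fl_sid.size(), NA_REAL)
            : (gam_i.size() == N ? gam_i : NumericVector(N, NA_REAL)),
        _["sum_P"] = (collapse_mode == 0)
            ? NumericVector(fl_sum.begin(), fl_sum.end()) : sp_sum,
        _["n_obs"] = (collapse_mode == 0)
            ? IntegerVector(fl_cnt.begin(), fl_cnt.end()) : sp_cnt);
  }
  return out;
}

// [[Rcpp::export]]
double solve_growth_scalar_cpp(NumericVector P, NumericVector omega) {
  return solve_growth_scalar(P, omega);
}
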