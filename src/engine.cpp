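// Fixed-step simulation core: quasi-static (algebraic) flow resolution over
// the pneumatic circuit each step, explicit updates of the only state
// variables (reservoir pressure/composition, lung compartment volumes), and
// the six-phase PRVC valve scheduler executed at the control period.
//
// Unit conventions inside this file: pressures in Pa absolute, volumes in
// litres (lung volumes in ml where noted), flows in atmospheric-equivalent
// l/s, time in s. Calibrated pathways follow q[l/min] = a * (dp[mbar])^n.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double P_ATM = 101325.0;
static const double CMH2O = 98.0665;
static const double MBAR = 100.0;

// pathway flow, a in l/min/mbar^n, dp in Pa, result in l/s
static inline double pflow(double a, double n, double dp_pa) {
  if (dp_pa <= 0.0) return 0.0;
  return a / 60.0 * std::pow(dp_pa / MBAR, n);
}

// inverse pathway drop, q in l/s, result in Pa
static inline double pdrop(double a, double n, double q_ls) {
  if (q_ls <= 0.0) return 0.0;
  return MBAR * std::pow(60.0 * q_ls / a, 1.0 / n);
}

struct Comp {
  double r_lin;   // cmH2O/(l/s)
  double k_par;   // cmH2O/(l/s)^2
  double c;       // ml/cmH2O
  double v0;      // ml
  double stiff;   // -
  double v;       // ml above relaxed state
};

// recoil pressure, Pa gauge
static inline double lungp(const Comp& L) {
  double p = (L.v <= L.v0) ? L.v / L.c
                           : L.v0 / L.c + (L.v - L.v0) * L.stiff / L.c;
  return p * CMH2O;
}

// signed airway flow (l/s, positive into lung) from a driving drop (Pa)
static inline double compflow(const Comp& L, double dp_pa) {
  double d = dp_pa / CMH2O;
  double s = (d < 0.0) ? -1.0 : 1.0;
  d = std::fabs(d);
  double q;
  if (L.k_par <= 0.0) q = d / L.r_lin;
  else if (L.r_lin <= 0.0) q = std::sqrt(d / L.k_par);
  else q = (-L.r_lin + std::sqrt(L.r_lin * L.r_lin + 4.0 * L.k_par * d)) /
           (2.0 * L.k_par);
  return s * q;
}

// [[Rcpp::export]]
List run_engine_cpp(List par) {
  // circuit
  const double a_a = par["a_a"], a_b = par["a_b"], a_c = par["a_c"],
               a_d = par["a_d"], a_s = par["a_s"];
  const double n_i = par["n_i"], n_e = par["n_e"];
  const double p_air = par["p_air_abs"], p_ox = par["p_ox_abs"];
  const double f_air = par["f_air"], f_ox = par["f_ox"];
  const double v_res = par["v_res_l"];
  const double relief_res = par["relief_res_abs"];
  const double relief_pat_pa = CMH2O * as<double>(par["relief_pat_cm"]);

  // lungs
  NumericVector r_lin = par["r_lin"], k_par = par["k_par"], c_ml = par["c_ml"],
                v0_ml = par["v0_ml"], stiff = par["stiff"],
                v_init = par["v_init_ml"];
  const int nc = r_lin.size();
  std::vector<Comp> L(nc);
  for (int i = 0; i < nc; ++i) {
    L[i] = Comp{r_lin[i], k_par[i], c_ml[i], v0_ml[i], stiff[i], v_init[i]};
  }

  // settings
  const double vt_ml = par["vt_ml"];
  const double period = 60.0 / as<double>(par["rr"]);
  const double peep_cm = par["peep_cm"];
  const double t_in = par["t_in"];
  const double alarm_pip_cm = par["alarm_pip_cm"];
  const double fio2 = par["fio2"];

  // controller
  const double ctrl_period = par["control_period_s"];
  // guaranteed end-inspiratory hold so every breath has an equilibrated
  // plateau sample (phase 2) even when delivery runs short: the minimum
  // that yields two all-closed control ticks
  const double t_hold = 3.0 * ctrl_period;
  const double peep_margin = par["peep_margin_cm"];
  const double lambda = par["lambda"];
  const double margin_pa = par["margin_pa"];
  const bool est_parab = as<int>(par["est_parabolic"]) != 0;
  double c_est = par["c_est0"];
  double rk_est = par["rk_est0"]; // r (linear) or k (parabolic) estimate

  // sim
  const double dt = par["dt"];
  const int n_breaths = par["n_breaths"];
  const double sample_dt = par["sample_dt"];
  const bool noise_on = as<int>(par["noise_on"]) != 0;
  const double noise_p = CMH2O * as<double>(par["noise_p_cmh2o"]);
  const double noise_o2 = par["noise_o2"];
  NumericVector rec_start = par["rec_start"], rec_end = par["rec_end"];
  const bool precharge = as<int>(par["precharge"]) != 0;

  RNGScope rng;

  const double total_t = n_breaths * period;
  const long n_steps = (long)std::llround(total_t / dt);

  // reservoir state
  double p_res = par["p_res0_abs"];
  double f_res = par["f_res0"];
  int relief_events = 0, patient_relief_events = 0;

  // gas accounting, atmospheric-equivalent litres
  double acc_in_o2 = 0.0, acc_in_air = 0.0, acc_delivered = 0.0,
         acc_exhaled = 0.0, acc_relief = 0.0;

  // controller state
  bool c_open = false, d_open = false, a_open = false, b_open = false,
       exhal = false, onset = false, alarm = false, short_breath = false;
  double alarm_overshoot_cm = 0.0;
  int plat_ticks = 0;            // all-closed ticks backing the plateau
  double q_est_prev = 0.0;       // previous tick's flow estimate (trapezoid)
  double delivered = 0.0, delivered_true = 0.0;
  double target = P_ATM, corr = par["corr0"], charge_p0 = NA_REAL,
         dpo2 = 0.0;
  double p_plat_s = NA_REAL, p_start_cm = peep_cm;
  int breath = -1;
  double breath_start = 0.0, next_tick = 0.0;
  double t2 = NA_REAL, t3 = NA_REAL, t4 = NA_REAL, t5 = NA_REAL,
         t6 = NA_REAL;

  // sensed values (updated at ticks)
  double p_sys_cur = P_ATM + CMH2O * peep_cm; // physical, absolute
  double p_conn_cur = p_sys_cur;
  double q_i_cur = 0.0, q_e_cur = 0.0;
  double o2_del = f_res; // gas fraction at the O2 sensor (held when no flow)
  double p_res_s = p_res, p_sys_s = p_sys_cur, o2_s = o2_del;
  double fio2_breath = f_res;

  // logs
  std::vector<double> lg_tstart, lg_t2, lg_t3, lg_t4, lg_t5, lg_t6,
      lg_del_ctrl, lg_del_true, lg_target, lg_corr, lg_cest, lg_rkest,
      lg_fio2, lg_peep, lg_pplat;
  std::vector<int> lg_short, lg_alarm, lg_stack;

  // trace buffers
  std::vector<double> tr_t, tr_pres, tr_psys, tr_pconn, tr_plung, tr_qi,
      tr_qe, tr_o2, tr_vml;
  std::vector<int> tr_breath, tr_phase, tr_a, tr_b, tr_c, tr_d;
  double next_sample = 0.0;
  int win = 0;
  const int nwin = rec_start.size();
  {
    double est_T = 0.0;
    for (int w = 0; w < nwin; ++w)
      est_T += std::min(rec_end[w], total_t) - std::max(0.0, rec_start[w]);
    size_t n_est = (size_t)std::max(0.0, est_T / sample_dt) + 16;
    tr_t.reserve(n_est);
  }

  const double eps = 1e-9;

  // breath planner
  auto plan = [&](void) {
    double q_bar = vt_ml / 1000.0 / t_in;
    double drop_cm = est_parab ? rk_est * q_bar * q_bar : rk_est * q_bar;
    double pip_cm = peep_cm + vt_ml / c_est + drop_cm;
    target = P_ATM + pip_cm * CMH2O + P_ATM * (vt_ml / 1000.0) / v_res +
             margin_pa + corr;
    if (target > relief_res) target = relief_res;
    if (target < P_ATM) target = P_ATM;
  };

  auto finalize = [&](double t) {
    if (breath < 0) return;
    if (d_open) { t6 = t; lg_stack.push_back(1); d_open = false; }
    else lg_stack.push_back(0);
    a_open = false; b_open = false; c_open = false;
    double peep_meas = (p_sys_s - P_ATM) / CMH2O;
    // compliance estimate from this breath: the elastic excursion is the
    // plateau relative to the pressure the breath STARTED from (which can
    // differ from the end-expiratory pressure while PEEP settles)
    if (!ISNAN(p_plat_s) && p_plat_s - p_start_cm > 0.5 && delivered > 1.0 &&
        !alarm) {
      double ce = delivered / (p_plat_s - p_start_cm);
      if (ce < 2.0) ce = 2.0;
      if (ce > 200.0) ce = 200.0;
      c_est = ce;
    }
    // reservoir-target adaptation (integral on the volume shortfall,
    // each increment clipped to +/-20% of the current gauge target).
    // A breath aborted by the peak-pressure alarm means the target was too
    // HIGH: back it off rather than chasing the apparent shortfall.
    double step_pa;
    if (alarm) {
      step_pa = -CMH2O * std::max(1.0, 2.0 * alarm_overshoot_cm);
    } else {
      step_pa = lambda * (vt_ml - delivered) / 1000.0 * P_ATM / v_res;
      double cap = 0.2 * std::max(target - P_ATM, 5000.0);
      if (step_pa > cap) step_pa = cap;
      if (step_pa < -cap) step_pa = -cap;
    }
    corr += step_pa;
    if (corr < -0.5e5) corr = -0.5e5;
    if (corr > 2.0e5) corr = 2.0e5;

    lg_tstart.push_back(breath_start);
    lg_t2.push_back(t2); lg_t3.push_back(t3); lg_t4.push_back(t4);
    lg_t5.push_back(t5); lg_t6.push_back(t6);
    lg_del_ctrl.push_back(delivered);
    lg_del_true.push_back(delivered_true);
    lg_target.push_back(target);
    lg_corr.push_back(corr);
    lg_cest.push_back(c_est);
    lg_rkest.push_back(rk_est);
    lg_fio2.push_back(fio2_breath);
    lg_peep.push_back(peep_meas);
    lg_pplat.push_back(p_plat_s);
    lg_short.push_back(short_breath ? 1 : 0);
    lg_alarm.push_back(alarm ? 1 : 0);
  };

  auto start_breath = [&](double t) {
    breath += 1;
    breath_start = t;
    p_start_cm = (p_sys_cur - P_ATM) / CMH2O;
    plan();
    c_open = true; d_open = false; a_open = false; b_open = false;
    exhal = false; onset = false; alarm = false; short_breath = false;
    alarm_overshoot_cm = 0.0;
    delivered = 0.0; delivered_true = 0.0;
    plat_ticks = 0; q_est_prev = 0.0;
    p_plat_s = NA_REAL; charge_p0 = NA_REAL; dpo2 = 0.0;
    t2 = t3 = t4 = t5 = t6 = NA_REAL;
    next_tick = t;
  };

  if (precharge) {
    plan();
    p_res = std::min(target, relief_res);
    f_res = std::max(fio2, f_air);
    o2_del = f_res;
  }
  if (n_breaths > 0) start_breath(0.0);

  for (long step = 0; step < n_steps; ++step) {
    double t = step * dt;

    // breath boundary
    if (breath + 1 < n_breaths && t >= breath_start + period - dt / 2.0) {
      finalize(t);
      start_breath(t);
    }

    double tb = t - breath_start;

    // ---- controller tick -------------------------------------------------
    if (t >= next_tick - eps) {
      next_tick += ctrl_period;
      p_res_s = p_res;
      p_sys_s = p_sys_cur;
      o2_s = o2_del;
      if (noise_on) {
        p_res_s += noise_p * R::rnorm(0.0, 1.0);
        p_sys_s += noise_p * R::rnorm(0.0, 1.0);
        o2_s += noise_o2 * R::rnorm(0.0, 1.0);
      }

      if (c_open) {
        double q_est = pflow(a_c, n_i, p_res_s - p_sys_s);
        // trapezoidal flow-sensorless volume integral
        double q_lo = (delivered > 0.0) ? 0.5 * (q_est + q_est_prev) : q_est;
        delivered += q_lo * 1000.0 * ctrl_period;
        q_est_prev = q_est;
        double p_conn_est = p_sys_s - pdrop(a_s, n_i, q_est);
        if (p_conn_est - P_ATM > alarm_pip_cm * CMH2O) {
          alarm = true;
          alarm_overshoot_cm = (p_conn_est - P_ATM) / CMH2O - alarm_pip_cm;
          c_open = false; t2 = t;
          d_open = true; exhal = true; t3 = t;
          fio2_breath = o2_s;
        } else if (delivered >= vt_ml) {
          c_open = false; t2 = t;
          fio2_breath = o2_s;
        } else if (tb >= t_in - t_hold - eps) {
          c_open = false; t2 = t;
          short_breath = true;
          fio2_breath = o2_s;
        }
      }

      if (!c_open && !exhal && tb < t_in) {
        // equilibrated end-inspiratory plateau; trusted only after two
        // all-closed ticks (a flowing sample would inflate the resistance
        // estimate when delivery runs right up to T_in)
        p_plat_s = (p_sys_s - P_ATM) / CMH2O;
        plat_ticks++;
      }

      if (!exhal && tb >= t_in - eps) {
        exhal = true;
        d_open = true; t3 = t;
        if (plat_ticks < 2) p_plat_s = NA_REAL;
        onset = false;
        // charging split (oxygen first, then air)
        charge_p0 = p_res_s;
        double rise = target - charge_p0;
        if (rise > 50.0) {
          dpo2 = (fio2 * target - o2_s * charge_p0 - f_air * rise) /
                 (f_ox - f_air);
          if (dpo2 < 0.0) dpo2 = 0.0;
          if (dpo2 > rise) dpo2 = rise;
          if (dpo2 > 50.0) a_open = true;
          else b_open = true;
        }
      }

      if (exhal && d_open && t > t3 + eps) {
        // skipped on the tick D opens: the sensed p_sys is still the
        // pre-flow plateau there, which would zero the onset estimate
        double q_e_s = pflow(a_d, n_e, p_sys_s - P_ATM);
        double psg = (p_sys_s - P_ATM) / CMH2O;
        if (!onset && q_e_s > 0.01) {
          // refresh the resistance estimate only from a trusted plateau;
          // otherwise keep the previous breath's estimate
          if (!ISNAN(p_plat_s)) {
            double est = (p_plat_s - psg);
            est = est_parab ? est / (q_e_s * q_e_s) : est / q_e_s;
            if (est < 0.5) est = 0.5;
            if (est > 500.0) est = 500.0;
            rk_est = est;
          }
          onset = true;
        }
        if (onset) {
          double drop = est_parab ? rk_est * q_e_s * q_e_s : rk_est * q_e_s;
          if (psg + drop <= peep_cm + peep_margin) {
            d_open = false; t6 = t;
          }
        }
      }

      if (a_open && p_res_s >= charge_p0 + dpo2) {
        a_open = false; t4 = t;
        if (target - p_res_s > 50.0) b_open = true;
        else t5 = t;
      } else if (b_open && p_res_s >= target) {
        b_open = false; t5 = t;
      }
    }

    // ---- algebraic flow resolution --------------------------------------
    double plg[2];
    for (int i = 0; i < nc; ++i) plg[i] = P_ATM + lungp(L[i]);
    double qi[2] = {0.0, 0.0};
    double pc, psys;
    q_i_cur = 0.0; q_e_cur = 0.0;

    if (c_open && p_res > P_ATM) {
      // inhalation: valve C flow balanced against lung intake
      double lo = P_ATM - 4000.0, hi = std::max(p_res, plg[0]) + 1.0;
      for (int i = 1; i < nc; ++i) hi = std::max(hi, plg[i] + 1.0);
      for (int it = 0; it < 60; ++it) {
        pc = 0.5 * (lo + hi);
        double ql = 0.0;
        for (int i = 0; i < nc; ++i) ql += compflow(L[i], pc - plg[i]);
        double ps = pc + (ql > 0.0 ? pdrop(a_s, n_i, ql) : 0.0);
        double qv = pflow(a_c, n_i, p_res - ps);
        if (qv - ql > 0.0) lo = pc; else hi = pc;
      }
      pc = 0.5 * (lo + hi);
      double ql = 0.0;
      for (int i = 0; i < nc; ++i) {
        qi[i] = compflow(L[i], pc - plg[i]);
        ql += qi[i];
      }
      q_i_cur = std::max(ql, 0.0);
      psys = pc + (ql > 0.0 ? pdrop(a_s, n_i, ql) : 0.0);
      // reservoir discharge (atmospheric-equivalent bookkeeping)
      p_res -= P_ATM * q_i_cur * dt / v_res;
      if (p_res < P_ATM) p_res = P_ATM;
      delivered_true += q_i_cur * 1000.0 * dt;
      acc_delivered += q_i_cur * dt;
      o2_del = f_res;
    } else if (d_open) {
      // exhalation: lungs discharge through Valve D; p_sys = p_conn
      double hi = P_ATM + 10.0;
      for (int i = 0; i < nc; ++i) hi = std::max(hi, plg[i]);
      double lo = P_ATM;
      for (int it = 0; it < 60; ++it) {
        pc = 0.5 * (lo + hi);
        double qout = -pflow(a_d, n_e, pc - P_ATM);
        for (int i = 0; i < nc; ++i) qout -= compflow(L[i], pc - plg[i]);
        if (qout > 0.0) lo = pc; else hi = pc;
      }
      pc = 0.5 * (lo + hi);
      for (int i = 0; i < nc; ++i) qi[i] = compflow(L[i], pc - plg[i]);
      q_e_cur = pflow(a_d, n_e, pc - P_ATM);
      acc_exhaled += q_e_cur * dt;
      psys = pc;
    } else {
      // all closed: static (two compartments may still exchange gas)
      if (nc == 2 && std::fabs(plg[0] - plg[1]) > 1e-10) {
        double lo = std::min(plg[0], plg[1]), hi = std::max(plg[0], plg[1]);
        for (int it = 0; it < 60; ++it) {
          pc = 0.5 * (lo + hi);
          double s = compflow(L[0], pc - plg[0]) + compflow(L[1], pc - plg[1]);
          if (s > 0.0) hi = pc; else lo = pc;
        }
        pc = 0.5 * (lo + hi);
        for (int i = 0; i < nc; ++i) qi[i] = compflow(L[i], pc - plg[i]);
      } else {
        pc = plg[0];
      }
      psys = pc;
    }

    // volume updates
    for (int i = 0; i < nc; ++i) {
      L[i].v += qi[i] * 1000.0 * dt;
      if (L[i].v < 0.0) L[i].v = 0.0;
      if (std::fabs(qi[i]) > 50.0) {
        stop("numerical instability: compartment flow exceeded 50 l/s at dt = %g s; reduce dt", dt);
      }
    }
    if (plg[0] - P_ATM > relief_pat_pa) patient_relief_events++;

    // charging through A (oxygen) / B (air)
    if (a_open) {
      double q = pflow(a_a, n_i, p_ox - p_res);
      double dp = P_ATM * q * dt / v_res;
      f_res = (f_res * p_res + f_ox * dp) / (p_res + dp);
      p_res += dp;
      acc_in_o2 += q * dt;
    } else if (b_open) {
      double q = pflow(a_b, n_i, p_air - p_res);
      double dp = P_ATM * q * dt / v_res;
      f_res = (f_res * p_res + f_air * dp) / (p_res + dp);
      p_res += dp;
      acc_in_air += q * dt;
    }
    if (p_res > relief_res) {
      acc_relief += (p_res - relief_res) * v_res / P_ATM;
      p_res = relief_res;
      relief_events++;
    }

    p_sys_cur = psys;
    p_conn_cur = pc;

    // ---- sampling --------------------------------------------------------
    if (t >= next_sample - eps) {
      next_sample += sample_dt;
      bool rec = (nwin == 0);
      while (win < nwin && t >= rec_end[win] - eps) win++;
      if (win < nwin && t >= rec_start[win] - eps && t < rec_end[win]) {
        rec = true;
      }
      if (rec) {
        int phase = c_open ? 1 : (tb < t_in ? 2 :
                    (a_open ? 3 : (b_open ? 4 : (d_open ? 5 : 6))));
        tr_t.push_back(t);
        tr_breath.push_back(breath + 1);
        tr_phase.push_back(phase);
        double pr_rec = noise_on ? p_res_s : p_res;
        double ps_rec = noise_on ? p_sys_s : p_sys_cur;
        tr_pres.push_back((pr_rec - P_ATM) / CMH2O);
        tr_psys.push_back((ps_rec - P_ATM) / CMH2O);
        tr_pconn.push_back((p_conn_cur - P_ATM) / CMH2O);
        tr_plung.push_back((plg[0] - P_ATM) / CMH2O);
        tr_qi.push_back(q_i_cur * 60.0);
        tr_qe.push_back(q_e_cur * 60.0);
        tr_o2.push_back(noise_on ? o2_s : o2_del);
        double vtot = 0.0;
        for (int i = 0; i < nc; ++i) vtot += L[i].v;
        tr_vml.push_back(vtot);
        tr_a.push_back(a_open ? 1 : 0);
        tr_b.push_back(b_open ? 1 : 0);
        tr_c.push_back(c_open ? 1 : 0);
        tr_d.push_back(d_open ? 1 : 0);
      }
    }
  }
  if (n_breaths > 0) finalize(total_t);

  List trace = List::create(
    _["time"] = tr_t, _["breath"] = tr_breath, _["phase"] = tr_phase,
    _["p_res"] = tr_pres, _["p_sys"] = tr_psys, _["p_conn"] = tr_pconn,
    _["p_lung"] = tr_plung, _["q_i"] = tr_qi, _["q_e"] = tr_qe,
    _["o2_delivered"] = tr_o2, _["v_lung_ml"] = tr_vml,
    _["valve_a"] = tr_a, _["valve_b"] = tr_b, _["valve_c"] = tr_c,
    _["valve_d"] = tr_d);

  List blog = List::create(
    _["t_start"] = lg_tstart, _["t2"] = lg_t2, _["t3"] = lg_t3,
    _["t4"] = lg_t4, _["t5"] = lg_t5, _["t6"] = lg_t6,
    _["delivered_ml"] = lg_del_ctrl, _["delivered_true_ml"] = lg_del_true,
    _["p_res_target_pa"] = lg_target, _["correction_pa"] = lg_corr,
    _["c_est"] = lg_cest, _["rk_est"] = lg_rkest,
    _["fio2_delivered"] = lg_fio2, _["peep_meas"] = lg_peep,
    _["p_plat_meas"] = lg_pplat, _["short"] = lg_short,
    _["alarm"] = lg_alarm, _["stacking"] = lg_stack);

  std::vector<double> vfin(nc);
  for (int i = 0; i < nc; ++i) vfin[i] = L[i].v;

  return List::create(
    _["trace"] = trace, _["breaths"] = blog,
    _["relief_events"] = relief_events,
    _["patient_relief_events"] = patient_relief_events,
    _["p_res_final"] = p_res, _["f_res_final"] = f_res,
    _["v_final_ml"] = vfin, _["corr_final"] = corr,
    _["c_est_final"] = c_est, _["rk_est_final"] = rk_est,
    _["gas_accounting"] = List::create(
      _["in_o2_l"] = acc_in_o2, _["in_air_l"] = acc_in_air,
      _["delivered_l"] = acc_delivered, _["exhaled_l"] = acc_exhaled,
      _["relief_vented_l"] = acc_relief));
}
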