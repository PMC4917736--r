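// Carrier-resolved integrator for capacitance-driven Hodgkin-Huxley models.
//
// State variable is membrane charge density Q (nC/cm^2): Q is physically
// continuous across capacitance discontinuities at pulse edges, whereas
// Vm = Q/Cm(t) is not. Gates advance by Rush-Larsen (exact exponential
// relaxation with rates frozen over the step); charge by an RK2 midpoint
// step. Internal units: ms, mV, uA/cm^2, mS/cm^2, uF/cm^2, mM.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.33212;
static const double RGAS = 8.31446261815324;
static const double T_TAU_SCALE = 1.0 / 3.7;

struct Cell {
  double gna, gkd, gm, gt, gh, gkl, gleak;
  double vna, vk, vca, vh, vleak, vt, vx, taumax;
  int t_kind;                  // 0 none, 1 cortical T (s^2 u), 2 reticular Ts
  bool has_m, has_ih, has_kl, use_nernst, has_ca;
  double cm0, area_cm2;
  double ca_rest, ca_out, tau_ca, d_cm;
  double k1, k2, k3, k4, ginc;
  double tem;
  double iext;                 // constant external current density, uA/cm^2
};

struct State {
  double Q;
  double m, h, n, p, s, u;
  double o, oL, p1;
  double ca;
};

struct Drive {
  bool active;
  double f_khz;      // carrier cycles per ms
  double amp;        // effective amplitude (coverage-weighted), uF/cm^2
  double cm0;
  double prf_khz;    // pulses per ms
  double duty;
  double onset_ms, dur_ms;
};

struct Currents {
  double ina, ikd, im, it, ih, ikl, ileak;
  double total() const { return ina + ikd + im + it + ih + ikl + ileak; }
};

// positive remainder (x >= 0, y > 0)
static inline double pmod(double x, double y) {
  return x - std::floor(x / y) * y;
}

static inline double vtrap(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 - 0.5 * r);
  return x / (std::expm1(r));
}

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// ---- drive ----------------------------------------------------------------

static inline bool env_on(const Drive& d, double t) {
  if (!d.active) return false;
  if (t < d.onset_ms || t >= d.onset_ms + d.dur_ms) return false;
  if (d.duty >= 1.0) return true;
  double per = 1.0 / d.prf_khz;
  double ph = pmod(t - d.onset_ms, per);
  return ph < d.duty * per;
}

static inline double cm_at(const Drive& d, double t, bool on) {
  if (!on || d.amp <= 0.0) return d.cm0;
  double tp;
  if (d.duty >= 1.0) tp = t - d.onset_ms;
  else tp = pmod(t - d.onset_ms, 1.0 / d.prf_khz);
  return d.cm0 + d.amp * std::sin(2.0 * M_PI * d.f_khz * tp);
}

// next envelope transition strictly after t
static double next_toggle(const Drive& d, double t) {
  double inf = std::numeric_limits<double>::infinity();
  if (!d.active) return inf;
  double t0 = d.onset_ms, t1 = d.onset_ms + d.dur_ms;
  if (t < t0) return t0;
  if (t >= t1) return inf;
  if (d.duty >= 1.0) return t1;
  double per = 1.0 / d.prf_khz, on_len = d.duty * per;
  double k = std::floor((t - t0) / per);
  double ph = t - t0 - k * per;
  double nxt;
  if (ph < on_len) nxt = t0 + k * per + on_len;   // pulse-off edge
  else nxt = t0 + (k + 1.0) * per;                // next pulse onset
  return std::min(nxt, t1);
}

// ---- kinetics -------------------------------------------------------------

static inline double nernst_ca(const Cell& c, double ca) {
  return 1e3 * RGAS * c.tem / (2.0 * FARADAY) * std::log(c.ca_out / ca);
}

static void currents_at(const Cell& c, const State& st, double V, Currents& I) {
  I.ina = c.gna * st.m * st.m * st.m * st.h * (V - c.vna);
  I.ikd = c.gkd * st.n * st.n * st.n * st.n * (V - c.vk);
  I.im = c.has_m ? c.gm * st.p * (V - c.vk) : 0.0;
  if (c.t_kind != 0) {
    double vca = c.use_nernst ? nernst_ca(c, st.ca) : c.vca;
    I.it = c.gt * st.s * st.s * st.u * (V - vca);
  } else I.it = 0.0;
  I.ih = c.has_ih ? c.gh * (st.o + c.ginc * st.oL) * (V - c.vh) : 0.0;
  I.ikl = c.has_kl ? c.gkl * (V - c.vk) : 0.0;
  I.ileak = c.gleak * (V - c.vleak);
}

// advance all gate/pool variables by dt with rates evaluated at V.
// V is clamped to [-1500, 500] mV for rate evaluation only: every gate is
// fully saturated far inside that range, and the hyperpolarized capacitance
// dips of strong drives would otherwise overflow the exponential rates.
static void gates_step(const Cell& c, State& st, double V, double dt) {
  if (V < -1500.0) V = -1500.0;
  else if (V > 500.0) V = 500.0;
  double u0 = V - c.vt;
  double am = 0.32 * vtrap(-(u0 - 13.0), 4.0);
  double bm = 0.28 * vtrap(u0 - 40.0, 5.0);
  double ah = 0.128 * std::exp(-(u0 - 17.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(u0 - 40.0) / 5.0));
  double an = 0.032 * vtrap(-(u0 - 15.0), 5.0);
  double bn = 0.5 * std::exp(-(u0 - 10.0) / 40.0);
  st.m = clip01(am / (am + bm) + (st.m - am / (am + bm)) * std::exp(-dt * (am + bm)));
  st.h = clip01(ah / (ah + bh) + (st.h - ah / (ah + bh)) * std::exp(-dt * (ah + bh)));
  st.n = clip01(an / (an + bn) + (st.n - an / (an + bn)) * std::exp(-dt * (an + bn)));
  if (c.has_m) {
    double pinf = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
    double taup = c.taumax /
      (3.3 * std::exp((V + 35.0) / 20.0) + std::exp(-(V + 35.0) / 20.0));
    st.p = clip01(pinf + (st.p - pinf) * std::exp(-dt / taup));
  }
  if (c.t_kind == 1) {
    double v = V + c.vx;
    double sinf = 1.0 / (1.0 + std::exp(-(v + 57.0) / 6.2));
    double uinf = 1.0 / (1.0 + std::exp((v + 81.0) / 4.0));
    double taus = T_TAU_SCALE *
      (0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) + std::exp((v + 16.8) / 18.2)));
    double tauu = (v < -80.0)
      ? T_TAU_SCALE * std::exp((v + 467.0) / 66.6)
      : T_TAU_SCALE * (std::exp(-(v + 22.0) / 10.5) + 28.0);
    st.s = clip01(sinf + (st.s - sinf) * std::exp(-dt / taus));
    st.u = clip01(uinf + (st.u - uinf) * std::exp(-dt / tauu));
  } else if (c.t_kind == 2) {
    double sinf = 1.0 / (1.0 + std::exp(-(V + 52.0) / 7.4));
    double uinf = 1.0 / (1.0 + std::exp((V + 80.0) / 5.0));
    double taus = (3.0 + 1.0 / (std::exp((V + 27.0) / 10.0) +
                                std::exp(-(V + 102.0) / 15.0))) / std::pow(5.0, 1.2);
    double tauu = (85.0 + 1.0 / (std::exp((V + 48.0) / 4.0) +
                                 std::exp(-(V + 407.0) / 50.0))) / std::pow(3.0, 1.2);
    st.s = clip01(sinf + (st.s - sinf) * std::exp(-dt / taus));
    st.u = clip01(uinf + (st.u - uinf) * std::exp(-dt / tauu));
  }
  if (c.has_ih) {
    double hinf = 1.0 / (1.0 + std::exp((V + 75.0) / 5.5));
    double tauh = 20.0 + 1000.0 / (std::exp((V + 71.5) / 14.2) +
                                   std::exp(-(V + 89.0) / 11.6));
    double alpha = hinf / tauh, beta = (1.0 - hinf) / tauh;
    double ca4 = st.ca * st.ca * st.ca * st.ca;
    double dodt = alpha * (1.0 - st.o - st.oL) - beta * st.o
      - c.k3 * st.p1 * st.o + c.k4 * st.oL;
    double doL = c.k3 * st.p1 * st.o - c.k4 * st.oL;
    double dp1 = c.k1 * ca4 * (1.0 - st.p1) - c.k2 * st.p1;
    st.o = clip01(st.o + dt * dodt);
    st.oL = clip01(st.oL + dt * doL);
    st.p1 = clip01(st.p1 + dt * dp1);
    if (st.o + st.oL > 1.0) { double sc = 1.0 / (st.o + st.oL); st.o *= sc; st.oL *= sc; }
  }
  if (c.has_ca) {
    // exact step of the linear pool ODE, influx frozen at current V
    double vca = c.use_nernst ? nernst_ca(c, st.ca) : c.vca;
    double it = c.gt * st.s * st.s * st.u * (V - vca);
    double influx = (it < 0.0) ? (-it * 1e-3 / (2.0 * FARADAY * c.d_cm)) : 0.0;
    double target = c.ca_rest + c.tau_ca * influx;
    st.ca = target + (st.ca - target) * std::exp(-dt / c.tau_ca);
    if (st.ca < 1e-9) st.ca = 1e-9;
  }
}

// dQ/dt (uA/cm^2) at time t, charge Q, gates frozen; extra = synaptic density
static inline double dQdt(const Cell& c, const State& st, const Drive& d,
                          double t, bool on, double Q, double extra) {
  double V = Q / cm_at(d, t, on);
  Currents I;
  currents_at(c, st, V, I);
  return -I.total() + c.iext + extra;
}

// ---- parsing --------------------------------------------------------------

static Cell parse_cell(const List& p) {
  Cell c;
  c.gna = p["g_na"]; c.gkd = p["g_kd"]; c.gm = p["g_m"]; c.gt = p["g_t"];
  c.gh = p["g_h"]; c.gkl = p["g_kl"]; c.gleak = p["g_leak"];
  c.vna = p["v_na"]; c.vk = p["v_k"];
  c.vh = p["v_h"]; c.vleak = p["v_leak"]; c.vt = p["v_t"];
  c.taumax = p["tau_max_eff"];
  c.vx = p["v_x_eff"];
  c.vca = p["v_ca_eff"];
  c.t_kind = p["t_kind_code"];
  c.has_m = p["has_m"]; c.has_ih = p["has_ih"]; c.has_kl = p["has_kl"];
  c.use_nernst = p["use_nernst"]; c.has_ca = p["has_ca"];
  c.cm0 = p["cm0"]; c.area_cm2 = p["area_cm2"];
  c.ca_rest = p["ca_rest"]; c.ca_out = p["ca_out"]; c.tau_ca = p["tau_ca"];
  c.d_cm = p["d_cm"];
  c.k1 = p["k1"]; c.k2 = p["k2"]; c.k3 = p["k3"]; c.k4 = p["k4"];
  c.ginc = p["g_inc"]; c.tem = p["tem"];
  c.iext = p["iext_density"];
  return c;
}

static Drive parse_drive(const List& d) {
  Drive dr;
  dr.active = d["active"];
  dr.f_khz = as<double>(d["carrier_f_hz"]) * 1e-3;
  dr.amp = d["amp_eff"];
  dr.cm0 = d["cm0"];
  dr.prf_khz = as<double>(d["prf_hz"]) * 1e-3;
  dr.duty = d["duty"];
  dr.onset_ms = as<double>(d["onset_s"]) * 1e3;
  dr.dur_ms = as<double>(d["duration_s"]) * 1e3;
  return dr;
}

static State parse_state(const List& s) {
  State st;
  st.Q = s["q"];
  st.m = s["m"]; st.h = s["h"]; st.n = s["n"]; st.p = s["p"];
  st.s = s["s"]; st.u = s["u"];
  st.o = s["o"]; st.oL = s["o_l"]; st.p1 = s["p1"];
  st.ca = s["ca"];
  return st;
}

struct StepCtl {
  double dt_on, dt_off, dt_rep, t_end;   // ms
  double v_thresh, refrac;               // mV, ms
};

// ---- single neuron --------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_neuron(List cell_p, List drive_p, List init, List ctl_p) {
  Cell c = parse_cell(cell_p);
  Drive d = parse_drive(drive_p);
  State st = parse_state(init);
  StepCtl ctl;
  ctl.dt_on = ctl_p["dt_on_ms"]; ctl.dt_off = ctl_p["dt_off_ms"];
  ctl.dt_rep = ctl_p["dt_report_ms"]; ctl.t_end = ctl_p["t_end_ms"];
  ctl.v_thresh = ctl_p["v_thresh"]; ctl.refrac = ctl_p["refrac_ms"];

  int n_rep = (int)std::floor(ctl.t_end / ctl.dt_rep + 1e-9) + 1;
  NumericVector rt(n_rep), rV(n_rep), rQ(n_rep), rCm(n_rep);
  NumericMatrix rI(n_rep, 7), rG(n_rep, 6);
  NumericVector rCa(n_rep);
  std::vector<double> spikes;

  long nsteps = 0;
  double t = 0.0;
  int irep = 0;
  double v_prev = st.Q / cm_at(d, 0.0, env_on(d, 0.0));
  double last_sp = -1e9;

  auto record = [&](double tt, bool on) {
    double cm = cm_at(d, tt, on);
    double V = st.Q / cm;
    Currents I;
    currents_at(c, st, V, I);
    rt[irep] = tt * 1e-3; rV[irep] = V; rQ[irep] = st.Q; rCm[irep] = cm;
    rI(irep, 0) = I.ina; rI(irep, 1) = I.ikd; rI(irep, 2) = I.im;
    rI(irep, 3) = I.it; rI(irep, 4) = I.ih; rI(irep, 5) = I.ikl;
    rI(irep, 6) = I.ileak;
    rG(irep, 0) = st.m; rG(irep, 1) = st.h; rG(irep, 2) = st.n;
    rG(irep, 3) = st.p; rG(irep, 4) = st.s; rG(irep, 5) = st.u;
    rCa[irep] = st.ca;
    ++irep;
  };

  record(0.0, env_on(d, 0.0));
  double next_rep = ctl.dt_rep;
  const double eps = 1e-9;

  while (t < ctl.t_end - eps) {
    bool on = env_on(d, t + eps);
    double tog = next_toggle(d, t + eps);
    double t_seg = std::min(std::min(next_rep, tog), ctl.t_end);
    double span = t_seg - t;
    double dt_target = on ? ctl.dt_on : ctl.dt_off;
    int nsub = (int)std::ceil(span / dt_target - 1e-9);
    if (nsub < 1) nsub = 1;
    double dt = span / nsub;
    for (int i = 0; i < nsub; ++i) {
      double V = st.Q / cm_at(d, t, on);
      if (!std::isfinite(V))
        stop("non-finite membrane potential at t = %g ms", t);
      gates_step(c, st, V, dt);
      double k1 = dQdt(c, st, d, t, on, st.Q, 0.0);
      double km = dQdt(c, st, d, t + 0.5 * dt, on, st.Q + 0.5 * dt * k1, 0.0);
      st.Q += dt * km;
      t += dt;
      ++nsteps;
      double v_new = st.Q / cm_at(d, t, on);
      if (v_prev < ctl.v_thresh && v_new >= ctl.v_thresh &&
          t - last_sp >= ctl.refrac) {
        double frac = (ctl.v_thresh - v_prev) / (v_new - v_prev);
        spikes.push_back((t - dt + frac * dt) * 1e-3);
        last_sp = t;
      }
      v_prev = v_new;
    }
    t = t_seg;
    if (std::fabs(t - next_rep) < 1e-6 && irep < n_rep) {
      record(t, env_on(d, t + eps));
      next_rep += ctl.dt_rep;
    }
  }

  colnames(rI) = CharacterVector::create("i_na", "i_kd", "i_m", "i_t",
                                         "i_h", "i_kl", "i_leak");
  colnames(rG) = CharacterVector::create("m", "h", "n", "p", "s", "u");
  return List::create(
    _["time_s"] = rt[Range(0, irep - 1)],
    _["vm_mV"] = rV[Range(0, irep - 1)],
    _["q_nC_cm2"] = rQ[Range(0, irep - 1)],
    _["cm_uF_cm2"] = rCm[Range(0, irep - 1)],
    _["currents"] = rI, _["gates"] = rG,
    _["ca_mM"] = rCa[Range(0, irep - 1)],
    _["n_recorded"] = irep,
    _["spikes_s"] = NumericVector(spikes.begin(), spikes.end()),
    _["n_steps"] = (double)nsteps);
}

// ---- network --------------------------------------------------------------

struct Syn {
  int pre, post;
  double gbar, vrev, t1, t2, knorm;
  bool has_f, has_d;
  double f, tauf, d1, taud1, d2, taud2;
  double A, B, F, D1, D2;
};

// [[Rcpp::export]]
List cpp_simulate_network(List cells_p, List drive_p, List inits, List syns_p,
                          List ctl_p) {
  int nc = cells_p.size();
  std::vector<Cell> cells(nc);
  std::vector<State> sts(nc);
  for (int i = 0; i < nc; ++i) {
    cells[i] = parse_cell(cells_p[i]);
    sts[i] = parse_state(inits[i]);
  }
  Drive d = parse_drive(drive_p);
  StepCtl ctl;
  ctl.dt_on = ctl_p["dt_on_ms"]; ctl.dt_off = ctl_p["dt_off_ms"];
  ctl.dt_rep = ctl_p["dt_report_ms"]; ctl.t_end = ctl_p["t_end_ms"];
  ctl.v_thresh = ctl_p["v_thresh"]; ctl.refrac = ctl_p["refrac_ms"];

  int ns = syns_p.size();
  if (ns > 16) stop("at most 16 synapses are supported");
  std::vector<Syn> syns(ns);
  for (int j = 0; j < ns; ++j) {
    List sp = syns_p[j];
    Syn& s = syns[j];
    s.pre = sp["pre"]; s.post = sp["post"];
    s.gbar = sp["g_bar"]; s.vrev = sp["v_rev"];
    s.t1 = sp["t1_ms"]; s.t2 = sp["t2_ms"];
    double tpk = s.t1 * s.t2 / (s.t2 - s.t1) * std::log(s.t2 / s.t1);
    s.knorm = std::exp(-tpk / s.t2) - std::exp(-tpk / s.t1);
    s.has_f = sp["has_f"]; s.has_d = sp["has_d"];
    s.f = sp["f"]; s.tauf = sp["tau_f"];
    s.d1 = sp["d1"]; s.taud1 = sp["tau_d1"];
    s.d2 = sp["d2"]; s.taud2 = sp["tau_d2"];
    s.A = 0.0; s.B = 0.0; s.F = 1.0; s.D1 = 1.0; s.D2 = 1.0;
  }

  int n_rep = (int)std::floor(ctl.t_end / ctl.dt_rep + 1e-9) + 1;
  NumericVector rt(n_rep);
  NumericMatrix rV(n_rep, nc), rQ(n_rep, nc), rSyn(n_rep, nc);
  std::vector<std::vector<double>> spikes(nc);
  std::vector<double> v_prev(nc), last_sp(nc, -1e9);

  // synaptic current density into each postsynaptic cell (uA/cm^2)
  auto syn_density = [&](int post, double Vpost) {
    double tot = 0.0;
    for (int j = 0; j < ns; ++j) {
      const Syn& s = syns[j];
      if (s.post != post) continue;
      double sopen = (s.A - s.B) / s.knorm;
      double i_nA = s.gbar * (s.F * s.D1 * s.D2) * sopen * (Vpost - s.vrev);
      tot += i_nA * 1e-3 / cells[post].area_cm2;
    }
    return tot;
  };

  double t = 0.0;
  int irep = 0;
  bool on0 = env_on(d, 0.0);
  auto record = [&](double tt, bool on) {
    double cm = cm_at(d, tt, on);
    rt[irep] = tt * 1e-3;
    for (int i = 0; i < nc; ++i) {
      double V = sts[i].Q / cm;
      rV(irep, i) = V; rQ(irep, i) = sts[i].Q;
      rSyn(irep, i) = syn_density(i, V);
    }
    ++irep;
  };
  record(0.0, on0);
  for (int i = 0; i < nc; ++i) v_prev[i] = sts[i].Q / cm_at(d, 0.0, on0);

  double next_rep = ctl.dt_rep;
  const double eps = 1e-9;
  long nsteps = 0;

  while (t < ctl.t_end - eps) {
    bool on = env_on(d, t + eps);
    double tog = next_toggle(d, t + eps);
    double t_seg = std::min(std::min(next_rep, tog), ctl.t_end);
    double span = t_seg - t;
    double dt_target = on ? ctl.dt_on : ctl.dt_off;
    int nsub = (int)std::ceil(span / dt_target - 1e-9);
    if (nsub < 1) nsub = 1;
    double dt = span / nsub;
    double eA[16], eB[16], eF[16], eD1[16], eD2[16];
    for (int j = 0; j < ns; ++j) {
      eA[j] = std::exp(-dt / syns[j].t2);
      eB[j] = std::exp(-dt / syns[j].t1);
      eF[j] = syns[j].has_f ? std::exp(-dt / syns[j].tauf) : 1.0;
      eD1[j] = syns[j].has_d ? std::exp(-dt / syns[j].taud1) : 1.0;
      eD2[j] = syns[j].has_d ? std::exp(-dt / syns[j].taud2) : 1.0;
    }
    for (int i = 0; i < nsub; ++i) {
      double cm_t = cm_at(d, t, on);
      // neuron states
      for (int k = 0; k < nc; ++k) {
        double V = sts[k].Q / cm_t;
        if (!std::isfinite(V))
          stop("non-finite membrane potential (cell %d) at t = %g ms", k + 1, t);
        gates_step(cells[k], sts[k], V, dt);
        // syn_density is the outward synaptic current density, entering the
        // charge equation with a minus sign like every other outward current
        double isyn = syn_density(k, V);
        double k1 = dQdt(cells[k], sts[k], d, t, on, sts[k].Q, -isyn);
        double km = dQdt(cells[k], sts[k], d, t + 0.5 * dt, on,
                         sts[k].Q + 0.5 * dt * k1, -isyn);
        sts[k].Q += dt * km;
      }
      // synapse decay
      for (int j = 0; j < ns; ++j) {
        Syn& s = syns[j];
        s.A *= eA[j]; s.B *= eB[j];
        if (s.has_f) s.F = 1.0 + (s.F - 1.0) * eF[j];
        if (s.has_d) {
          s.D1 = 1.0 + (s.D1 - 1.0) * eD1[j];
          s.D2 = 1.0 + (s.D2 - 1.0) * eD2[j];
        }
      }
      t += dt;
      ++nsteps;
      // spikes & synaptic events
      double cm_n = cm_at(d, t, on);
      for (int k = 0; k < nc; ++k) {
        double v_new = sts[k].Q / cm_n;
        if (v_prev[k] < ctl.v_thresh && v_new >= ctl.v_thresh &&
            t - last_sp[k] >= ctl.refrac) {
          double frac = (ctl.v_thresh - v_prev[k]) / (v_new - v_prev[k]);
          spikes[k].push_back((t - dt + frac * dt) * 1e-3);
          last_sp[k] = t;
          for (int j = 0; j < ns; ++j) {
            Syn& s = syns[j];
            if (s.pre != k) continue;
            s.A += 1.0; s.B += 1.0;
            if (s.has_f) s.F += s.f;
            if (s.has_d) { s.D1 *= s.d1; s.D2 *= s.d2; }
          }
        }
        v_prev[k] = v_new;
      }
    }
    t = t_seg;
    if (std::fabs(t - next_rep) < 1e-6 && irep < n_rep) {
      record(t, env_on(d, t + eps));
      next_rep += ctl.dt_rep;
    }
  }

  List sp(nc);
  for (int k = 0; k < nc; ++k)
    sp[k] = NumericVector(spikes[k].begin(), spikes[k].end());
  return List::create(
    _["time_s"] = rt[Range(0, irep - 1)],
    _["vm_mV"] = rV, _["q_nC_cm2"] = rQ, _["isyn_uA_cm2"] = rSyn,
    _["n_recorded"] = irep,
    _["spikes_s"] = sp,
    _["n_steps"] = (double)nsteps);
}
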