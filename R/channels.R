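# Voltage-gated channel kinetics (reference R implementations).
#
# The compiled integrator in src/ carries its own copies of these rate
# functions for speed; the R versions are the readable reference and are
# cross-checked against the compiled path in the test suite.
#
# Units: Vm in mV, time constants in ms, rates in 1/ms.

#' Temperature scaling of the T-type gate time constants
#'
#' The T-type gate time constants were measured at 24 C; the models run at
#' 36 C, so they are divided by a Q10 = 3 factor, 3^((36-24)/10) ~ 3.7.
#' The prefactor is exposed as a constant so the scaling is explicit.
#'
#' @format A single number, 1/3.7.
#' @export
T_TAU_SCALE <- 1 / 3.7

# x/(exp(x/y) - 1) with the removable singularity at x = 0 handled
.vtrap <- function(x, y) {
  ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (expm1(x / y)))
}

#' Sodium and potassium channel rate functions (cortical/thalamic)
#'
#' Traub-type transition rates for the fast sodium (gates m, h) and
#' delayed-rectifier potassium (gate n) channels, shifted by the per-cell
#' spike-threshold adjustment parameter `v_t`. Used by every neuron model in
#' the package.
#'
#' @param vm Membrane potential (mV).
#' @param v_t Spike-threshold adjustment parameter (mV).
#' @return A list of rate vectors (1/ms): `a_m`, `b_m`, `a_h`, `b_h`,
#'   `a_n`, `b_n`.
#' @export
na_k_rates <- function(vm, v_t) {
  u <- vm - v_t
  list(
    a_m = 0.32 * .vtrap(-(u - 13), 4),
    b_m = 0.28 * .vtrap(u - 40, 5),
    a_h = 0.128 * exp(-(u - 17) / 18),
    b_h = 4 / (1 + exp(-(u - 40) / 5)),
    a_n = 0.032 * .vtrap(-(u - 15), 5),
    b_n = 0.5 * exp(-(u - 10) / 40)
  )
}

#' Slow non-inactivating potassium (M) current gate
#'
#' Steady state and time constant of the single activation gate p of the
#' M current responsible for spike-frequency adaptation in the cortical
#' models.
#'
#' @param vm Membrane potential (mV).
#' @param tau_max Adaptation decay time constant (ms).
#' @return A list with `p_inf` and `tau_p` (ms).
#' @export
m_gate <- function(vm, tau_max) {
  list(
    p_inf = 1 / (1 + exp(-(vm + 35) / 10)),
    tau_p = tau_max / (3.3 * exp((vm + 35) / 20) + exp(-(vm + 35) / 20))
  )
}

#' T-type calcium channel steady-state gate values
#'
#' Steady-state open probabilities of the activation (S) and inactivation
#' (U) gates of the low-threshold T-type calcium channel used by the LTS and
#' TC models. `v_x` is a uniform voltage-shift factor: -7 mV for the default
#' LTS model, -2 mV for its alternative-species preset, 0 for TC.
#'
#' @param vm Membrane potential (mV).
#' @param v_x Voltage shift factor (mV).
#' @return A list with `s_inf` (increasing in vm) and `u_inf` (decreasing).
#' @export
t_gate_steady <- function(vm, v_x) {
  v <- vm + v_x
  list(
    s_inf = 1 / (1 + exp(-(v + 57) / 6.2)),
    u_inf = 1 / (1 + exp((v + 81) / 4))
  )
}

#' T-type calcium channel gate time constants
#'
#' Voltage-dependent time constants of the S and U gates, scaled from 24 C
#' to 36 C by [T_TAU_SCALE]. The U-gate time constant is piecewise, with an
#' exponential branch below `vm + v_x = -80` mV.
#'
#' @inheritParams t_gate_steady
#' @param prefactor Temperature scaling prefactor; [T_TAU_SCALE] by default.
#' @return A list with `tau_s` and `tau_u` (ms), both strictly positive.
#' @export
t_gate_tau <- function(vm, v_x, prefactor = T_TAU_SCALE) {
  v <- vm + v_x
  tau_s <- prefactor *
    (0.612 + 1 / (exp(-(v + 132) / 16.7) + exp((v + 16.8) / 18.2)))
  tau_u <- ifelse(v < -80,
                  prefactor * exp((v + 467) / 66.6),
                  prefactor * (exp(-(v + 22) / 10.5) + 28))
  list(tau_s = tau_s, tau_u = tau_u)
}

#' T-type calcium current density
#'
#' `I_T = g_t * s^2 * u * (vm - v_ca)`, in uA/cm^2.
#'
#' @param vm Membrane potential (mV).
#' @param s,u Open probabilities of the S and U gates, in `[0, 1]`.
#' @param g_t Maximal conductance (mS/cm^2).
#' @param v_ca Calcium reversal potential (mV).
#' @return Current density (uA/cm^2); negative is inward.
#' @export
t_current <- function(vm, s, u, g_t, v_ca) {
  stopifnot(all(s >= 0 & s <= 1), all(u >= 0 & u <= 1))
  g_t * s^2 * u * (vm - v_ca)
}

#' Reticular T-type (Ts) channel kinetics
#'
#' Steady states and time constants of the thalamic reticular neuron's
#' low-threshold calcium channel variant, at 36 C (activation Q10 = 5,
#' inactivation Q10 = 3, from 24 C).
#'
#' @param vm Membrane potential (mV).
#' @return A list with `s_inf`, `u_inf`, `tau_s`, `tau_u`.
#' @export
ts_gate <- function(vm) {
  phi_s <- 5^1.2
  phi_u <- 3^1.2
  list(
    s_inf = 1 / (1 + exp(-(vm + 52) / 7.4)),
    u_inf = 1 / (1 + exp((vm + 80) / 5)),
    tau_s = (3 + 1 / (exp((vm + 27) / 10) + exp(-(vm + 102) / 15))) / phi_s,
    tau_u = (85 + 1 / (exp((vm + 48) / 4) + exp(-(vm + 407) / 50))) / phi_u
  )
}

#' Hyperpolarization-activated current (I_h) voltage kinetics
#'
#' Voltage-dependent activation of the TC neuron's mixed cationic I_h
#' current: steady-state activation and time constant of the closed <-> open
#' transition. The calcium-regulation scheme on top of this is handled by
#' [ih_equilibrium()] and the integrator.
#'
#' @param vm Membrane potential (mV).
#' @return A list with `h_inf` and `tau_h` (ms).
#' @export
ih_rates <- function(vm) {
  list(
    h_inf = 1 / (1 + exp((vm + 75) / 5.5)),
    tau_h = 20 + 1000 / (exp((vm + 71.5) / 14.2) + exp(-(vm + 89) / 11.6))
  )
}

#' Equilibrium of the I_h calcium-regulation scheme
#'
#' The I_h channel has a closed <-> open voltage-dependent transition plus a
#' calcium-bound "locked open" state: a regulating factor binds four calcium
#' ions (rates k1 [Ca]^4 forward, k2 back) and the bound factor locks open
#' channels (k3 forward, k4 back). The locked state conducts `g_inc` (= 2)
#' times the open state. This returns the steady state of the scheme at
#' fixed membrane potential and calcium concentration.
#'
#' @param vm Membrane potential (mV).
#' @param ca_i Intracellular calcium concentration (mM).
#' @param k1,k2,k3,k4 Regulation rate factors (see [param_registry()]).
#' @return A list with fractions `o` (open), `o_l` (locked open), `p1`
#'   (bound regulating factor); all in `[0, 1]`, with `o + o_l <= 1`.
#' @export
ih_equilibrium <- function(vm, ca_i, k1 = 2.5e7, k2 = 4e-4, k3 = 0.1,
                           k4 = 1e-3) {
  r <- ih_rates(vm)
  alpha <- r$h_inf / r$tau_h
  beta <- (1 - r$h_inf) / r$tau_h
  p1 <- k1 * ca_i^4 / (k1 * ca_i^4 + k2)
  lock <- k3 * p1 / k4
  o <- alpha / (alpha * (1 + lock) + beta)
  list(o = o, o_l = lock * o, p1 = p1)
}

#' Nernst potential of calcium
#'
#' @param ca_i Intracellular concentration (mM), > 0.
#' @param ca_o Extracellular concentration (mM).
#' @param tem Temperature (K).
#' @return Reversal potential (mV).
#' @export
nernst_ca <- function(ca_i, ca_o = 2, tem = 309.15) {
  stopifnot(all(ca_i > 0), ca_o > 0)
  1e3 * 8.31446261815324 * tem / (2 * 96485.33212) * log(ca_o / ca_i)
}

#' Single first-order gate relaxation step
#'
#' Advances a gate variable by `dt` toward its steady state with the exact
#' exponential solution of `dx/dt = (x_inf - x)/tau` (steady state and time
#' constant frozen over the step), clipping the result to `[0, 1]`.
#'
#' @param x Current open probability.
#' @param x_inf Steady-state open probability.
#' @param tau Time constant (ms), > 0.
#' @param dt Step (ms), > 0.
#' @return Updated open probability in `[0, 1]`.
#' @export
gate_step <- function(x, x_inf, tau, dt) {
  stopifnot(all(tau > 0), dt > 0)
  pmin(1, pmax(0, x_inf + (x - x_inf) * exp(-dt / tau)))
}

#' Intracellular calcium pool update
#'
#' Submembrane calcium pool of the thalamic models: inward T-type current
#' through a shell of depth `d` drives influx, and the concentration decays
#' first-order to its resting value. One step of the exact solution of the
#' resulting linear ODE (current frozen over the step):
#' `dCa/dt = max(0, -I_T) / (2 F d) + (ca_rest - Ca) / tau_ca`.
#'
#' @param pool List with `ca_i` (mM), `d_nm` (shell depth, nm), `tau_ca`
#'   (ms), `ca_rest` (mM), `ca_out` (mM).
#' @param i_t T-type current density (uA/cm^2); only inward (negative)
#'   current contributes influx.
#' @param dt Step (ms), > 0.
#' @return The pool with updated `ca_i`.
#' @export
calcium_pool_step <- function(pool, i_t, dt) {
  stopifnot(dt > 0, pool$ca_i > 0)
  influx <- ca_influx_rate(i_t, pool$d_nm)
  target <- pool$ca_rest + pool$tau_ca * influx
  pool$ca_i <- target + (pool$ca_i - target) * exp(-dt / pool$tau_ca)
  pool$ca_i <- max(pool$ca_i, 1e-9)
  pool
}

#' Calcium influx rate from a T-type current
#'
#' @param i_t Current density (uA/cm^2).
#' @param d_nm Shell depth (nm).
#' @return Influx rate in mM/ms (>= 0; outward current contributes nothing).
#' @export
ca_influx_rate <- function(i_t, d_nm = 100) {
  d_cm <- d_nm * 1e-7
  pmax(0, -i_t) * 1e-3 / (2 * 96485.33212 * d_cm)
}
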