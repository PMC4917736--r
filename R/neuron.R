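#' Construct a single-compartment neuron model
#'
#' Builds one of the five neuron models (RS, FS, LTS cortical; TC, RE
#' thalamic) from its channel set (see [build_channel_set()]). The returned
#' object carries everything the integrator needs: conductances, reversals,
#' gate composition flags, membrane area and the calcium pool / I_h
#' regulation parameters where applicable.
#'
#' @inheritParams build_channel_set
#' @return An object of class `nice_neuron`.
#' @export
#' @examples
#' nice_neuron("LTS")
nice_neuron <- function(cell_type = c("RS", "FS", "LTS", "TC", "RE"),
                        preset = c("default", "fig7")) {
  cs <- build_channel_set(cell_type, preset)
  ch <- cs$channels
  n <- structure(list(
    cell_type = cs$cell_type, preset = cs$preset,
    g_na = ch[['Na']]$g, g_kd = ch[['Kd']]$g,
    g_m = if (!is.null(ch[['M']])) ch[['M']]$g else 0,
    g_t = if (!is.null(ch[['T']])) ch[['T']]$g else if (!is.null(ch[['Ts']])) ch[['Ts']]$g else 0,
    g_h = if (!is.null(ch[['h']])) ch[['h']]$g else 0,
    g_kl = if (!is.null(ch[['KL']])) ch[['KL']]$g else 0,
    g_leak = ch[['Leak']]$g,
    v_na = cs$v_na, v_k = cs$v_k, v_h = cs$v_h,
    v_leak = ch[['Leak']]$v_rev, v_t = cs$v_t, v_x = cs$v_x,
    v_ca = if (!is.null(ch[['T']])) ch[['T']]$v_rev else NA_real_,
    tau_max = cs$tau_max,
    t_kind = if (!is.null(ch[['T']])) "ct" else if (!is.null(ch[['Ts']])) "re" else "none",
    has_m = !is.null(ch[['M']]), has_ih = !is.null(ch[['h']]), has_kl = !is.null(ch[['KL']]),
    use_nernst = cs$cell_type %in% c("TC", "RE"),
    has_ca = cs$cell_type %in% c("TC", "RE"),
    cm0 = cs$cm0, area_um2 = cs$area_um2,
    ca_depth_nm = cs$ca_depth_nm, ca_out = cs$ca_out,
    tau_ca = cs$tau_ca, ca_rest = cs$ca_rest,
    k1 = cs$k1, k2 = cs$k2, k3 = cs$k3, k4 = cs$k4, g_inc = cs$g_inc,
    tem = cs$tem, v_m0_ref = cs$v_m0_ref
  ), class = "nice_neuron")
  n
}

#' @export
print.nice_neuron <- function(x, ...) {
  chans <- c("Na", "Kd",
             if (x$has_m) "M",
             if (x$t_kind == "ct") "T", if (x$t_kind == "re") "Ts",
             if (x$has_ih) "h", if (x$has_kl) "KL", "Leak")
  cat(sprintf("<nice_neuron> %s (%s preset): channels %s; area %g um^2\n",
              x$cell_type, x$preset, paste(chans, collapse = ", "),
              x$area_um2))
  invisible(x)
}

#' Add a channel to a neuron model (chimeric manipulation)
#'
#' Appends a T-type calcium channel to a model that lacks one, e.g. the
#' "RS+"/"FS+" chimeras used to show that T-type channels confer the
#' low-duty-cycle hypersensitivity independently of the other LTS
#' properties. Defaults are the LTS T-channel parameters (g = 0.4 mS/cm^2,
#' fixed 120 mV calcium reversal, -7 mV gate shift).
#'
#' @param neuron A [nice_neuron()].
#' @param type Channel type; only `"T"` is supported.
#' @param g Maximal conductance (mS/cm^2).
#' @param v_ca Calcium reversal potential (mV).
#' @param v_x Gate voltage-shift factor (mV).
#' @return A new `nice_neuron`; the input is not modified.
#' @export
add_channel <- function(neuron, type = "T", g = 0.4, v_ca = 120, v_x = -7) {
  stopifnot(inherits(neuron, "nice_neuron"))
  if (type != "T") stop("only T-type channel addition is supported")
  if (neuron$t_kind != "none")
    stop(sprintf("%s already has a T-type channel", neuron$cell_type))
  neuron$t_kind <- "ct"
  neuron$g_t <- g
  neuron$v_ca <- v_ca
  neuron$v_x <- v_x
  neuron$cell_type <- paste0(neuron$cell_type, "+")
  neuron
}

# --- steady state ------------------------------------------------------------

# equilibrium calcium concentration at fixed vm (TC/RE): fixed point of
# ca = ca_rest + tau_ca * influx(I_T(vm, V_Ca(ca)))
.ca_equilibrium <- function(neuron, vm, s_inf, u_inf) {
  if (s_inf^2 * u_inf < 1e-30) return(neuron$ca_rest)
  ca <- neuron$ca_rest
  for (i in 1:200) {
    v_ca <- nernst_ca(ca, neuron$ca_out, neuron$tem)
    i_t <- neuron$g_t * s_inf^2 * u_inf * (vm - v_ca)
    ca_new <- neuron$ca_rest +
      neuron$tau_ca * ca_influx_rate(i_t, neuron$ca_depth_nm)
    ca_new <- min(ca_new, neuron$ca_out)  # pool cannot exceed extracellular
    if (abs(ca_new - ca) < 1e-12) { ca <- ca_new; break }
    ca <- 0.5 * ca + 0.5 * ca_new
  }
  ca
}

# all gating variables at their voltage-dependent steady states
.steady_gates <- function(neuron, vm) {
  r <- na_k_rates(vm, neuron$v_t)
  g <- list(m = r$a_m / (r$a_m + r$b_m),
            h = r$a_h / (r$a_h + r$b_h),
            n = r$a_n / (r$a_n + r$b_n),
            p = 0, s = 0, u = 0, o = 0, o_l = 0, p1 = 0,
            ca = neuron$ca_rest)
  if (neuron$has_m) g$p <- m_gate(vm, neuron$tau_max)$p_inf
  if (neuron$t_kind == "ct") {
    ss <- t_gate_steady(vm, neuron$v_x)
    g$s <- ss$s_inf; g$u <- ss$u_inf
  } else if (neuron$t_kind == "re") {
    ss <- ts_gate(vm)
    g$s <- ss$s_inf; g$u <- ss$u_inf
  }
  if (neuron$has_ca && neuron$t_kind != "none")
    g$ca <- .ca_equilibrium(neuron, vm, g$s, g$u)
  if (neuron$has_ih) {
    eq <- ih_equilibrium(vm, g$ca, neuron$k1, neuron$k2, neuron$k3, neuron$k4)
    g$o <- eq$o; g$o_l <- eq$o_l; g$p1 <- eq$p1
  }
  g
}

#' Total steady-state membrane current
#'
#' Summed ionic current density with every gate (and, for the thalamic
#' models, the calcium pool and I_h regulation scheme) at its steady state
#' for the given membrane potential. Zero crossings of this function are the
#' candidate resting states.
#'
#' @param neuron A [nice_neuron()].
#' @param vm Membrane potential(s), mV.
#' @return Outward current density (uA/cm^2).
#' @export
steady_current <- function(neuron, vm) {
  vapply(vm, function(v) {
    g <- .steady_gates(neuron, v)
    v_ca <- if (neuron$use_nernst && neuron$t_kind != "none")
      nernst_ca(g$ca, neuron$ca_out, neuron$tem) else neuron$v_ca
    i <- neuron$g_na * g$m^3 * g$h * (v - neuron$v_na) +
      neuron$g_kd * g$n^4 * (v - neuron$v_k) +
      neuron$g_leak * (v - neuron$v_leak)
    if (neuron$has_m) i <- i + neuron$g_m * g$p * (v - neuron$v_k)
    if (neuron$t_kind != "none")
      i <- i + neuron$g_t * g$s^2 * g$u * (v - v_ca)
    if (neuron$has_ih)
      i <- i + neuron$g_h * (g$o + neuron$g_inc * g$o_l) * (v - neuron$v_h)
    if (neuron$has_kl) i <- i + neuron$g_kl * (v - neuron$v_k)
    i
  }, numeric(1))
}

#' Resting state of a neuron model
#'
#' Finds the resting membrane potential as a root of the zero-current
#' condition ([steady_current()]) over [-100, 0] mV with all gates at their
#' voltage-dependent steady states. If several stable roots exist the most
#' hyperpolarized one is returned (with the others reported in
#' `$all_roots`). A root is stable when the current-voltage slope there is
#' positive.
#'
#' @param neuron A [nice_neuron()].
#' @return A list with `v_m0` (mV), `gates` (all gate variables), `ca_i`
#'   (mM), `v_ca` (mV, the effective calcium reversal), and `all_roots`.
#' @export
#' @examples
#' resting_state(nice_neuron("RS"))$v_m0 # ~ -71.9
resting_state <- function(neuron) {
  stopifnot(inherits(neuron, "nice_neuron"))
  grid <- seq(-100, 0, by = 0.25)
  iv <- steady_current(neuron, grid)
  sgn <- sign(iv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0)
    stop("no resting state found in [-100, 0] mV")
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(v) steady_current(neuron, v),
                   c(grid[i], grid[i + 1]), tol = 1e-10)$root
  }, numeric(1))
  stable <- vapply(roots, function(r) {
    dv <- 0.01
    (steady_current(neuron, r + dv) - steady_current(neuron, r - dv)) > 0
  }, logical(1))
  if (!any(stable)) stable <- rep(TRUE, length(roots))
  v0 <- min(roots[stable])
  g <- .steady_gates(neuron, v0)
  v_ca <- if (neuron$use_nernst && neuron$t_kind != "none")
    nernst_ca(g$ca, neuron$ca_out, neuron$tem) else neuron$v_ca
  list(v_m0 = v0, gates = g, ca_i = g$ca, v_ca = v_ca, all_roots = roots)
}

# --- simulation --------------------------------------------------------------

.cell_cpp_params <- function(neuron, i_ext_nA = 0) {
  area_cm2 <- neuron$area_um2 * 1e-8
  list(
    g_na = neuron$g_na, g_kd = neuron$g_kd, g_m = neuron$g_m,
    g_t = neuron$g_t, g_h = neuron$g_h, g_kl = neuron$g_kl,
    g_leak = neuron$g_leak,
    v_na = neuron$v_na, v_k = neuron$v_k, v_h = neuron$v_h,
    v_leak = neuron$v_leak, v_t = neuron$v_t,
    tau_max_eff = if (is.na(neuron$tau_max)) 1 else neuron$tau_max,
    v_x_eff = if (is.na(neuron$v_x)) 0 else neuron$v_x,
    v_ca_eff = if (is.na(neuron$v_ca)) 0 else neuron$v_ca,
    t_kind_code = switch(neuron$t_kind, none = 0L, ct = 1L, re = 2L),
    has_m = neuron$has_m, has_ih = neuron$has_ih, has_kl = neuron$has_kl,
    use_nernst = neuron$use_nernst && neuron$t_kind != "none",
    has_ca = neuron$has_ca && neuron$t_kind != "none",
    cm0 = neuron$cm0, area_cm2 = area_cm2,
    ca_rest = neuron$ca_rest, ca_out = neuron$ca_out,
    tau_ca = neuron$tau_ca, d_cm = neuron$ca_depth_nm * 1e-7,
    k1 = neuron$k1, k2 = neuron$k2, k3 = neuron$k3, k4 = neuron$k4,
    g_inc = neuron$g_inc, tem = neuron$tem,
    iext_density = i_ext_nA * 1e-3 / area_cm2
  )
}

.drive_cpp_params <- function(drive, train, cm0) {
  if (is.null(train) || is.null(drive)) {
    return(list(active = FALSE, carrier_f_hz = 1e6, amp_eff = 0, cm0 = cm0,
                prf_hz = 100, duty = 1, onset_s = 0, duration_s = 0))
  }
  stopifnot(inherits(drive, "sinusoidal_drive"), inherits(train, "pulse_train"))
  # a zero-amplitude drive does not perturb the dynamics: skip the
  # carrier-resolved stepping it would otherwise force
  list(active = drive$coverage * drive$c_amp > 0,
       carrier_f_hz = train$carrier_f,
       amp_eff = drive$coverage * drive$c_amp, cm0 = drive$cm0,
       prf_hz = train$prf, duty = train$duty,
       onset_s = train$onset, duration_s = train$duration)
}

.init_cpp_state <- function(neuron, rest = NULL) {
  if (is.null(rest)) rest <- resting_state(neuron)
  g <- rest$gates
  list(q = rest$v_m0 * neuron$cm0,
       m = g$m, h = g$h, n = g$n, p = g$p, s = g$s, u = g$u,
       o = g$o, o_l = g$o_l, p1 = g$p1, ca = g$ca)
}

.ctl_cpp_params <- function(neuron, train, duration, dt_off, dt_report,
                            dt_scale, v_thresh, refractory) {
  dt_on_ms <- if (!is.null(train)) 0.025e-3 / (train$carrier_f * 1e-6)
    else dt_off * 1e3
  list(dt_on_ms = dt_on_ms * dt_scale,
       dt_off_ms = dt_off * 1e3 * dt_scale,
       dt_report_ms = dt_report * 1e3,
       t_end_ms = duration * 1e3,
       v_thresh = v_thresh, refrac_ms = refractory * 1e3)
}

#' Simulate a neuron under a capacitance drive
#'
#' Integrates the charge-balance membrane equation `dQ/dt = -(sum of ionic
#' currents) + I_ext` with `Vm = Q/Cm(t)`, which is algebraically equivalent
#' to the current-balance equation with the capacitive displacement-current
#' term `Vm dCm/dt`. Integration is carrier-resolved: the maximum step is
#' 0.025/f us while the ultrasound envelope is on (40 steps per carrier
#' cycle) and `dt_off` while it is off. Gates advance by exact exponential
#' relaxation, charge by a midpoint step. Spikes are detected inside the
#' integration loop as upward crossings of `v_thresh` with a refractory
#' floor.
#'
#' @param neuron A [nice_neuron()].
#' @param train A [pulse_train()], or `NULL` for no ultrasound.
#' @param drive A [sinusoidal_drive()], or `NULL` for no ultrasound.
#' @param duration Total simulated time (s).
#' @param i_ext_nA Constant external current (nA), converted to a density
#'   with the cell's membrane area.
#' @param dt_off Maximum step while the envelope is off (s); default 10 us.
#' @param dt_report Reporting grid spacing (s); independent of the internal
#'   steps.
#' @param dt_scale Multiplier on both internal step caps (used for
#'   refinement checks).
#' @param v_thresh Spike detection threshold (mV).
#' @param refractory Spike refractory floor (s).
#' @param init Initial state; defaults to the computed resting state, so
#'   simulations are fully deterministic.
#' @return An object of class `nice_sim`: a list with `trace` (data.frame on
#'   the reporting grid: time, Vm, Q, Cm, per-channel current densities,
#'   gate values, calcium), `spikes` (spike times, s), and `stats`.
#' @export
#' @examples
#' \donttest{
#' lts <- nice_neuron("LTS")
#' tr <- pulse_train(0.69e6, prf = 100, duty = 0.05, duration = 0.1)
#' sim <- simulate_neuron(lts, tr, sinusoidal_drive(0.8), duration = 0.12)
#' length(sim$spikes)
#' }
simulate_neuron <- function(neuron, train = NULL, drive = NULL, duration,
                            i_ext_nA = 0, dt_off = 1e-5, dt_report = 5e-5,
                            dt_scale = 1, v_thresh = 0, refractory = 1e-3,
                            init = NULL) {
  stopifnot(inherits(neuron, "nice_neuron"), duration > 0)
  if (xor(is.null(train), is.null(drive)))
    stop("supply both `train` and `drive`, or neither")
  cell <- .cell_cpp_params(neuron, i_ext_nA)
  drv <- .drive_cpp_params(drive, train, neuron$cm0)
  st0 <- .init_cpp_state(neuron, init)
  ctl <- .ctl_cpp_params(neuron, train, duration, dt_off, dt_report,
                         dt_scale, v_thresh, refractory)
  res <- cpp_simulate_neuron(cell, drv, st0, ctl)
  n <- res$n_recorded
  trace <- data.frame(
    time_s = res$time_s, vm_mV = res$vm_mV, q_nC_cm2 = res$q_nC_cm2,
    cm_uF_cm2 = res$cm_uF_cm2,
    res$currents[seq_len(n), , drop = FALSE],
    res$gates[seq_len(n), , drop = FALSE],
    ca_mM = res$ca_mM)
  structure(list(
    trace = trace, spikes = as.numeric(res$spikes_s),
    neuron = neuron, train = train, drive = drive,
    stats = list(n_steps = res$n_steps, duration_s = duration,
                 dt_report_s = dt_report, v_thresh = v_thresh,
                 refractory_s = refractory)
  ), class = "nice_sim")
}

#' @export
print.nice_sim <- function(x, ...) {
  cat(sprintf("<nice_sim> %s, %g ms, %d spikes, %g internal steps\n",
              x$neuron$cell_type, 1e3 * x$stats$duration_s,
              length(x$spikes), x$stats$n_steps))
  invisible(x)
}

#' Detect spikes in a sampled membrane-potential trace
#'
#' A spike is an upward crossing of the threshold with a refractory floor
#' between successive spikes. This operates on a stored trace; simulations
#' additionally detect spikes inside the integration loop at full temporal
#' resolution.
#'
#' @param trace A data.frame with columns `time_s` and `vm_mV`, or a
#'   `nice_sim` object.
#' @param v_thresh Threshold (mV).
#' @param refractory Refractory floor (s).
#' @return Numeric vector of spike times (s), strictly increasing.
#' @export
detect_spikes <- function(trace, v_thresh = 0, refractory = 1e-3) {
  if (inherits(trace, "nice_sim")) trace <- trace$trace
  v <- trace$vm_mV
  t <- trace$time_s
  up <- which(v[-1] >= v_thresh & v[-length(v)] < v_thresh)
  if (length(up) == 0) return(numeric(0))
  tc <- t[up] + (t[up + 1] - t[up]) *
    (v_thresh - v[up]) / (v[up + 1] - v[up])
  out <- numeric(0)
  last <- -Inf
  for (x in tc) {
    if (x - last >= refractory) {
      out <- c(out, x)
      last <- x
    }
  }
  out
}

#' Mean firing rate over a time window
#'
#' @param spikes Numeric vector of spike times (s).
#' @param window Length-2 numeric, `(t_start, t_end)` in seconds with
#'   `t_end > t_start`. Spikes in `[t_start, t_end)` are counted.
#' @return Rate in Hz.
#' @export
#' @examples
#' firing_rate(seq(0, 0.49, by = 0.01), c(0, 0.5)) # 100 Hz
firing_rate <- function(spikes, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  sum(spikes >= window[1] & spikes < window[2]) / (window[2] - window[1])
}
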