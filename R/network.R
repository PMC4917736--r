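#' Dynamic synapse specification
#'
#' A conductance-based synapse with a bi-exponential open-probability kernel
#' and optional short-term plasticity. Each presynaptic spike adds a kernel
#' `(exp(-t/t2) - exp(-t/t1))`, normalized to unit peak; the synaptic current
#' is `g_bar * P(t) * s(t) * (v - v_rev)`, where the instantaneous plasticity
#' factor `P(t) = F * D1 * D2` scales the whole conductance. Between spikes
#' the facilitation factor F and the depression factors D1, D2 relax
#' exponentially to 1; on each presynaptic spike F jumps by `f` and each D
#' is multiplied by its `d`.
#'
#' @param pre,post Cell identifiers (e.g. `"RS"`, `"FS"`, `"LTS"`).
#' @param g_bar Total maximal synaptic conductance (uS).
#' @param v_rev Reversal potential (mV): 0 for AMPA, -85 for GABA-A.
#' @param t1,t2 Rise and decay time constants (ms), `t2 > t1 > 0`.
#' @param f,tau_f Facilitation jump and decay time constant (ms); `NULL`
#'   for a non-facilitating synapse.
#' @param d1,tau_d1,d2,tau_d2 Depression multipliers and time constants
#'   (ms); `NULL` for a non-depressing synapse.
#' @return An object of class `synapse_spec`.
#' @export
synapse_spec <- function(pre, post, g_bar, v_rev, t1, t2,
                         f = NULL, tau_f = NULL,
                         d1 = NULL, tau_d1 = NULL, d2 = NULL, tau_d2 = NULL) {
  stopifnot(g_bar >= 0, t1 > 0, t2 > t1)
  has_f <- !is.null(f)
  has_d <- !is.null(d1)
  if (has_f) stopifnot(f > 0, tau_f > 0)
  if (has_d) stopifnot(d1 > 0, d1 <= 1, d2 > 0, d2 <= 1, tau_d1 > 0, tau_d2 > 0)
  structure(list(pre = pre, post = post, g_bar = g_bar, v_rev = v_rev,
                 t1 = t1, t2 = t2, has_f = has_f, has_d = has_d,
                 f = if (has_f) f else 0, tau_f = if (has_f) tau_f else 1,
                 d1 = if (has_d) d1 else 1, tau_d1 = if (has_d) tau_d1 else 1,
                 d2 = if (has_d) d2 else 1, tau_d2 = if (has_d) tau_d2 else 1),
            class = "synapse_spec")
}

#' Bi-exponential synaptic open probability
#'
#' The unit-peak normalized kernel of a single presynaptic spike,
#' `s(t) = (exp(-t/t2) - exp(-t/t1)) / k_peak` for `t >= 0` (0 before the
#' spike), superposed linearly over a vector of spike times.
#'
#' @param t Time(s) since stimulus start (ms).
#' @param spec A [synapse_spec()].
#' @param spike_times Presynaptic spike times (ms).
#' @return Open probability s(t); a single kernel peaks at exactly 1.
#' @export
syn_open_prob <- function(t, spec, spike_times = 0) {
  tpk <- syn_peak_time(spec)
  kpk <- exp(-tpk / spec$t2) - exp(-tpk / spec$t1)
  vapply(t, function(tt) {
    dt <- tt - spike_times
    dt <- dt[dt >= 0]
    sum(exp(-dt / spec$t2) - exp(-dt / spec$t1)) / kpk
  }, numeric(1))
}

#' @rdname syn_open_prob
#' @return `syn_peak_time`: the time of the kernel maximum,
#'   `t1 t2 / (t2 - t1) * log(t2 / t1)` (ms).
#' @export
syn_peak_time <- function(spec) {
  spec$t1 * spec$t2 / (spec$t2 - spec$t1) * log(spec$t2 / spec$t1)
}

#' Short-term plasticity state updates
#'
#' `plasticity_on_spike` applies the on-spike update (F jumps by f, each D
#' multiplies by its d); `plasticity_decay` relaxes all factors toward 1
#' over `dt` ms. The composite scale `P(t) = F * D1 * D2` multiplies the
#' synaptic conductance continuously.
#'
#' @param state List with `F`, `D1`, `D2` (use `plasticity_init()`).
#' @param spec A [synapse_spec()].
#' @param dt Elapsed time (ms).
#' @return Updated state.
#' @export
plasticity_on_spike <- function(state, spec) {
  if (spec$has_f) state$F <- state$F + spec$f
  if (spec$has_d) {
    state$D1 <- state$D1 * spec$d1
    state$D2 <- state$D2 * spec$d2
  }
  state
}

#' @rdname plasticity_on_spike
#' @export
plasticity_decay <- function(state, spec, dt) {
  stopifnot(dt >= 0)
  state$F <- 1 + (state$F - 1) * exp(-dt / spec$tau_f)
  state$D1 <- 1 + (state$D1 - 1) * exp(-dt / spec$tau_d1)
  state$D2 <- 1 + (state$D2 - 1) * exp(-dt / spec$tau_d2)
  state
}

#' @rdname plasticity_on_spike
#' @export
plasticity_init <- function() list(F = 1, D1 = 1, D2 = 1)

#' Synaptic current
#'
#' `I = g_bar * P * s * (v_post - v_rev)` in nA (uS times mV); positive is
#' outward. Divide by the postsynaptic membrane area for the density entering
#' the membrane equation.
#'
#' @param spec A [synapse_spec()].
#' @param s Open probability.
#' @param v_post Postsynaptic membrane potential (mV).
#' @param P Plasticity scale.
#' @return Current in nA.
#' @export
syn_current <- function(spec, s, v_post, P = 1) {
  spec$g_bar * P * s * (v_post - spec$v_rev)
}

#' The three-population cortical microcircuit
#'
#' Builds the RS-FS-LTS network: one neuron per population, eight synapses
#' (RS->RS, RS->FS, RS->LTS AMPA; FS->RS, FS->FS, FS->LTS, LTS->RS, LTS->FS
#' GABA-A; no LTS->LTS connection), thalamic DC input to RS and FS (none to
#' LTS) with `I_Th-FS = r_th * I_Th-RS`. The excitatory synapses onto the
#' interneurons are dynamic: RS->FS facilitating plus two depression
#' processes, RS->LTS facilitating.
#'
#' @param i_th_rs Thalamic DC current to the RS neuron (nA); the default
#'   0.17 nA produces the ~7 Hz baseline pyramidal rate of lightly
#'   anesthetized cortex.
#' @param r_th FS/RS thalamic input ratio.
#' @param preset Neuron parameter preset, passed to [nice_neuron()].
#' @return An object of class `nice_network`.
#' @export
cortical_network <- function(i_th_rs = 0.17, r_th = 1.4, preset = "default") {
  neurons <- list(RS = nice_neuron("RS", preset),
                  FS = nice_neuron("FS", preset),
                  LTS = nice_neuron("LTS", preset))
  ampa <- function(pre, post, g, ...)
    synapse_spec(pre, post, g, v_rev = 0, t1 = 0.1, t2 = 3, ...)
  gaba_fs <- function(post, g)
    synapse_spec("FS", post, g, v_rev = -85, t1 = 0.5, t2 = 8)
  gaba_lts <- function(post, g)
    synapse_spec("LTS", post, g, v_rev = -85, t1 = 0.5, t2 = 50)
  synapses <- list(
    ampa("RS", "RS", 0.002),
    ampa("RS", "FS", 0.04, f = 0.5, tau_f = 94,
         d1 = 0.46, tau_d1 = 380, d2 = 0.975, tau_d2 = 9200),
    ampa("RS", "LTS", 0.09, f = 0.2, tau_f = 200),
    gaba_fs("RS", 0.015),
    gaba_fs("FS", 0.135),
    gaba_fs("LTS", 0.86),
    gaba_lts("RS", 0.135),
    gaba_lts("FS", 0.02)
  )
  structure(list(neurons = neurons, synapses = synapses,
                 i_th_rs = i_th_rs, r_th = r_th),
            class = "nice_network")
}

#' @export
print.nice_network <- function(x, ...) {
  cat(sprintf(
    "<nice_network> RS-FS-LTS microcircuit, %d synapses, I_Th-RS = %g nA (ratio %g)\n",
    length(x$synapses), x$i_th_rs, x$r_th))
  invisible(x)
}

.syn_cpp_params <- function(spec, idx_of) {
  list(pre = idx_of[[spec$pre]] - 1L, post = idx_of[[spec$post]] - 1L,
       g_bar = spec$g_bar, v_rev = spec$v_rev,
       t1_ms = spec$t1, t2_ms = spec$t2,
       has_f = spec$has_f, has_d = spec$has_d,
       f = spec$f, tau_f = spec$tau_f,
       d1 = spec$d1, tau_d1 = spec$tau_d1,
       d2 = spec$d2, tau_d2 = spec$tau_d2)
}

#' Simulate the cortical network under a capacitance drive
#'
#' Co-integrates the three neurons and eight synapses. The drive (if any) is
#' applied identically to all three neurons; thalamic DC input goes to RS
#' and FS only. Spikes detected inside the loop trigger the synaptic kernels
#' and plasticity updates. Fully deterministic: identical configurations
#' give identical spike trains.
#'
#' @param net A [cortical_network()].
#' @param train,drive A [pulse_train()] and [sinusoidal_drive()], or both
#'   `NULL` for drive-free baseline activity.
#' @param duration Total simulated time (s).
#' @param dt_off,dt_report,dt_scale,v_thresh,refractory As in
#'   [simulate_neuron()]. The default network reporting grid is 0.25 ms.
#' @return An object of class `nice_network_sim`: `trace` (data.frame with
#'   time and per-population Vm, Q and synaptic current density), `spikes`
#'   (named list of spike-time vectors), `stats`.
#' @export
simulate_network <- function(net, train = NULL, drive = NULL, duration,
                             dt_off = 1e-5, dt_report = 2.5e-4, dt_scale = 1,
                             v_thresh = 0, refractory = 1e-3) {
  stopifnot(inherits(net, "nice_network"), duration > 0)
  if (xor(is.null(train), is.null(drive)))
    stop("supply both `train` and `drive`, or neither")
  nms <- names(net$neurons)
  idx_of <- as.list(seq_along(nms))
  names(idx_of) <- nms
  i_th <- c(RS = net$i_th_rs, FS = net$i_th_rs * net$r_th, LTS = 0)
  cells <- lapply(nms, function(nm)
    .cell_cpp_params(net$neurons[[nm]], i_ext_nA = i_th[[nm]]))
  inits <- lapply(nms, function(nm) .init_cpp_state(net$neurons[[nm]]))
  syns <- lapply(net$synapses, .syn_cpp_params, idx_of = idx_of)
  drv <- .drive_cpp_params(drive, train, net$neurons[[1]]$cm0)
  ctl <- .ctl_cpp_params(net$neurons[[1]], train, duration, dt_off,
                         dt_report, dt_scale, v_thresh, refractory)
  res <- cpp_simulate_network(cells, drv, inits, syns, ctl)
  n <- res$n_recorded
  trace <- data.frame(time_s = res$time_s)
  for (k in seq_along(nms)) {
    trace[[paste0("vm_", nms[k])]] <- res$vm_mV[seq_len(n), k]
    trace[[paste0("q_", nms[k])]] <- res$q_nC_cm2[seq_len(n), k]
    trace[[paste0("isyn_", nms[k])]] <- res$isyn_uA_cm2[seq_len(n), k]
  }
  spikes <- lapply(res$spikes_s, as.numeric)
  names(spikes) <- nms
  structure(list(trace = trace, spikes = spikes, net = net,
                 train = train, drive = drive,
                 stats = list(n_steps = res$n_steps, duration_s = duration,
                              v_thresh = v_thresh,
                              refractory_s = refractory)),
            class = "nice_network_sim")
}

#' @export
print.nice_network_sim <- function(x, ...) {
  rates <- vapply(x$spikes, function(s)
    firing_rate(s, c(0, x$stats$duration_s)), numeric(1))
  cat(sprintf("<nice_network_sim> %g s; rates (Hz): %s\n",
              x$stats$duration_s,
              paste(sprintf("%s %.1f", names(rates), rates), collapse = ", ")))
  invisible(x)
}
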