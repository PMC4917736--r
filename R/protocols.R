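#' Single-neuron stimulation threshold search
#'
#' Bisects the capacitance-drive amplitude for the smallest drive that makes
#' the neuron fire at least one spike under the given pulse waveform
#' (the single-spike threshold criterion; at long durations "at least one
#' spike" is used). Thresholds are defined natively in drive-amplitude space
#' (uF/cm^2); a nominal intensity label can be attached afterwards through
#' [amplitude_from_intensity()]'s inverse mapping, which is approximate and
#' flagged as such. Fully deterministic.
#'
#' @param neuron A [nice_neuron()].
#' @param train A [pulse_train()]; its duration is the stimulus duration
#'   (simulation runs 50 ms longer to catch offset spikes).
#' @param bracket Initial amplitude bracket (uF/cm^2); auto-expanded up to
#'   `amp_max`.
#' @param amp_max Largest admissible amplitude; just below `cm0` so the
#'   capacitance stays positive.
#' @param tol Relative bisection tolerance on amplitude.
#' @param coverage Sonophore coverage fraction of the drive.
#' @param n_spikes Criterion: at least this many spikes.
#' @param ... Passed to [simulate_neuron()] (e.g. `dt_off`).
#' @return An object of class `threshold_result`: `threshold` (uF/cm^2, or
#'   `NA` with `status = "no threshold in range"`), `bracket_history`,
#'   `cell_type`, and the waveform.
#' @export
find_threshold <- function(neuron, train, bracket = c(0.01, 0.8),
                           amp_max = 0.999, tol = 0.02, coverage = 1,
                           n_spikes = 1, ...) {
  stopifnot(inherits(neuron, "nice_neuron"), inherits(train, "pulse_train"))
  fires <- function(amp) {
    sim <- simulate_neuron(neuron, train, sinusoidal_drive(amp, coverage = coverage),
                           duration = train$onset + train$duration + 0.05, ...)
    length(sim$spikes) >= n_spikes
  }
  lo <- bracket[1]; hi <- bracket[2]
  hist <- list()
  # expand upward until the criterion fires (or the admissible range ends)
  while (!fires(hi)) {
    hist[[length(hist) + 1]] <- c(lo = hi, hi = NA)
    lo <- hi
    hi <- min(2 * hi, amp_max)
    if (lo >= amp_max) {
      return(structure(list(threshold = NA_real_,
                            status = "no threshold in range",
                            cell_type = neuron$cell_type, train = train,
                            bracket_history = hist),
                       class = "threshold_result"))
    }
  }
  # shrink downward until the criterion stops firing at lo
  while (fires(lo)) {
    hi <- lo
    lo <- lo / 2
    if (lo < 1e-6) break
  }
  while ((hi - lo) / hi > tol) {
    mid <- sqrt(lo * hi)   # geometric bisection: thresholds span decades
    hist[[length(hist) + 1]] <- c(lo = lo, hi = hi)
    if (fires(mid)) hi <- mid else lo <- mid
  }
  structure(list(threshold = hi, status = "ok",
                 cell_type = neuron$cell_type, train = train,
                 bracket_history = hist),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("<threshold_result> %s: %s\n", x$cell_type, x$status))
  } else {
    cat(sprintf(
      "<threshold_result> %s: amplitude %.4g uF/cm^2 (duty %g%%, PRF %g Hz, %g ms)\n",
      x$cell_type, x$threshold, 100 * x$train$duty, x$train$prf,
      1e3 * x$train$duration))
  }
  invisible(x)
}

#' Duty-cycle by amplitude phase diagram
#'
#' Simulates each cell type over a grid of duty cycles and drive amplitudes
#' and labels each grid cell by which types fire: `"none"`, `"LTS-only"`
#' (only T-channel-bearing inhibitory cells fire: the suppression zone), or
#' `"joint"` (the excitatory RS fires too: the activation zone).
#'
#' @param cells Named list of [nice_neuron()] objects; must include `"RS"`
#'   and `"LTS"` for zone labelling.
#' @param duties Ascending duty-cycle fractions.
#' @param amps Ascending drive amplitudes (uF/cm^2).
#' @param carrier_f Carrier frequency (Hz).
#' @param prf Pulse repetition frequency (Hz).
#' @param duration Stimulus duration (s); the protocol default is 500 ms.
#' @param ... Passed to [simulate_neuron()].
#' @return An object of class `phase_diagram`: a data.frame `grid` with one
#'   row per (duty, amp) holding per-cell spike counts and the zone label.
#' @export
phase_diagram <- function(cells, duties, amps, carrier_f = 0.69e6, prf = 100,
                          duration = 0.5, ...) {
  stopifnot(!is.unsorted(duties), !is.unsorted(amps))
  rows <- list()
  for (duty in duties) {
    for (amp in amps) {
      counts <- vapply(cells, function(n) {
        if (amp <= 0) return(0L)
        train <- pulse_train(carrier_f, prf = prf, duty = duty,
                             duration = duration)
        sim <- simulate_neuron(n, train, sinusoidal_drive(amp),
                               duration = duration + 0.05, ...)
        length(sim$spikes)
      }, integer(1))
      zone <- if (counts[["RS"]] > 0) "joint"
        else if (counts[["LTS"]] > 0) "LTS-only" else "none"
      rows[[length(rows) + 1]] <- data.frame(
        duty = duty, amp = amp, t(counts), zone = zone,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(grid = do.call(rbind, rows), duties = duties, amps = amps,
                 prf = prf, carrier_f = carrier_f, duration = duration),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d x %d grid (duty x amplitude), PRF %g Hz\n",
              length(x$duties), length(x$amps), x$prf))
  print(table(x$grid$zone))
  invisible(x)
}

#' Thalamic duty-cycle response curve
#'
#' Firing rate of a thalamic neuron (TC or RE) versus stimulus duty cycle,
#' following the thalamic protocol: 1.5 s pulsed stimulus, rate computed
#' over the last 0.5 s (so purely transient responses count as zero).
#'
#' @param neuron A [nice_neuron()], normally TC or RE.
#' @param duties Duty-cycle fractions.
#' @param amp Drive amplitude (uF/cm^2); the default 0.84 is the package's
#'   calibration of the stronger thalamic-protocol stimulus (see the methods
#'   vignette).
#' @param carrier_f,prf Waveform parameters (Hz).
#' @param duration Stimulus duration (s).
#' @param window Rate window (s); default the last 0.5 s.
#' @param ... Passed to [simulate_neuron()].
#' @return A data.frame with `duty`, `rate_hz`, `n_spikes_total`.
#' @export
duty_response <- function(neuron, duties, amp = 0.84, carrier_f = 0.69e6,
                          prf = 100, duration = 1.5,
                          window = c(duration - 0.5, duration), ...) {
  rows <- lapply(duties, function(duty) {
    train <- pulse_train(carrier_f, prf = prf, duty = duty,
                         duration = duration)
    sim <- simulate_neuron(neuron, train, sinusoidal_drive(amp),
                           duration = duration, ...)
    data.frame(duty = duty, rate_hz = firing_rate(sim$spikes, window),
               n_spikes_total = length(sim$spikes))
  })
  do.call(rbind, rows)
}

#' Thalamic-input sweep of network activation/suppression thresholds
#'
#' For each thalamic input level, bisects the drive amplitude for (a) the
#' network suppression threshold: the smallest amplitude at which the LTS
#' population is recruited by a low-duty-cycle stimulus, and (b) the network
#' activation threshold: the smallest amplitude at which the RS rate during
#' a high-duty-cycle stimulus exceeds its own no-drive baseline by
#' `activation_margin` Hz.
#'
#' @param levels Thalamic input levels, `I_Th-RS` in nA (>= 2 values).
#' @param r_th FS/RS input ratio.
#' @param carrier_f Carrier frequency (Hz).
#' @param supp_train,act_train Pulse trains for the suppression (default 5%
#'   duty, PRF 100, 1 s — the network-protocol stimulus) and activation
#'   (default 50% duty, PRF 10, 0.5 s) probes; both applied after a settling
#'   period.
#' @param settle Baseline settling time before stimulus onset (s).
#' @param activation_margin Rate increase over the population's own no-drive
#'   baseline counting as activation/recruitment (Hz); applied to RS for the
#'   activation threshold and to LTS for the suppression threshold.
#' @param tol Relative bisection tolerance.
#' @param amp_max Largest admissible amplitude.
#' @param ... Passed to [simulate_network()].
#' @return A data.frame with one row per level: `i_th_rs`,
#'   `suppression_threshold`, `activation_threshold` (uF/cm^2; `NA` if not
#'   reached below `amp_max`).
#' @export
thalamic_sweep <- function(levels, r_th = 1.4, carrier_f = 0.69e6,
                           supp_train = NULL, act_train = NULL,
                           settle = 0.5, activation_margin = 5,
                           tol = 0.02, amp_max = 0.999, ...) {
  stopifnot(length(levels) >= 2)
  if (is.null(supp_train))
    supp_train <- pulse_train(carrier_f, prf = 100, duty = 0.05,
                              duration = 1, onset = settle)
  if (is.null(act_train))
    act_train <- pulse_train(carrier_f, prf = 10, duty = 0.5,
                             duration = 0.5, onset = settle)
  probe <- function(net, train, amp, pop) {
    sim <- simulate_network(net, train, sinusoidal_drive(amp),
                            duration = train$onset + train$duration, ...)
    firing_rate(sim$spikes[[pop]],
                c(train$onset, train$onset + train$duration))
  }
  bisect <- function(fires) {
    lo <- 0.02; hi <- 0.16
    while (!fires(hi)) {
      lo <- hi; hi <- min(2 * hi, amp_max)
      if (lo >= amp_max) return(NA_real_)
    }
    while (fires(lo)) { hi <- lo; lo <- lo / 2; if (lo < 1e-4) break }
    while ((hi - lo) / hi > tol) {
      mid <- sqrt(lo * hi)
      if (fires(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  rows <- lapply(levels, function(lv) {
    net <- cortical_network(i_th_rs = lv, r_th = r_th)
    base <- simulate_network(net, duration = settle + 1, ...)
    rs_base <- firing_rate(base$spikes$RS, c(settle, settle + 1))
    lts_base <- firing_rate(base$spikes$LTS, c(settle, settle + 1))
    supp <- bisect(function(a)
      probe(net, supp_train, a, "LTS") > lts_base + activation_margin)
    act <- bisect(function(a)
      probe(net, act_train, a, "RS") > rs_base + activation_margin)
    data.frame(i_th_rs = lv, rs_baseline_hz = rs_base,
               lts_baseline_hz = lts_base,
               suppression_threshold = supp, activation_threshold = act)
  })
  do.call(rbind, rows)
}
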