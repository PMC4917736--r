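#' Pulsed ultrasound stimulus timing
#'
#' Describes the pulse structure of an ultrasound stimulus: carrier
#' frequency, pulse repetition frequency (PRF), duty cycle, total duration
#' and onset. `duty = 1` is continuous-wave (CW) stimulation. The on-time of
#' each repetition period is `duty / prf`, and must contain at least one
#' carrier cycle.
#'
#' @param carrier_f Carrier frequency (Hz).
#' @param prf Pulse repetition frequency (Hz). Ignored when `duty = 1`.
#' @param duty Duty-cycle fraction in (0, 1].
#' @param duration Total stimulus duration (s).
#' @param onset Stimulus start time (s).
#' @return An object of class `pulse_train`.
#' @export
#' @examples
#' pulse_train(carrier_f = 0.69e6, prf = 100, duty = 0.05, duration = 0.3)
pulse_train <- function(carrier_f, prf = 100, duty = 1, duration, onset = 0) {
  stopifnot(carrier_f > 0, prf > 0, duration > 0, onset >= 0)
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  if (duty < 1) {
    if (prf > carrier_f) stop("prf must not exceed the carrier frequency")
    if (duty / prf < 1 / carrier_f)
      stop("pulse on-time is shorter than one carrier period")
  }
  structure(list(carrier_f = carrier_f, prf = prf, duty = duty,
                 duration = duration, onset = onset),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "<pulse_train> carrier %g MHz, PRF %g Hz, duty %g%%, %g ms from t = %g ms\n",
    x$carrier_f / 1e6, x$prf, 100 * x$duty, 1e3 * x$duration, 1e3 * x$onset))
  invisible(x)
}

#' Pulse envelope indicator
#'
#' Whether the ultrasound carrier is on at time `t`: `t` must lie inside the
#' stimulus window `[onset, onset + duration)` and, for pulsed stimuli,
#' within the first `duty / prf` seconds of the current repetition period.
#' Periods are anchored at the stimulus onset.
#'
#' @param t Time(s) in seconds, >= 0.
#' @param train A [pulse_train()].
#' @return Logical vector, `TRUE` where the carrier is on.
#' @export
envelope <- function(t, train) {
  stopifnot(inherits(train, "pulse_train"))
  inside <- t >= train$onset & t < train$onset + train$duration
  if (train$duty >= 1) return(inside)
  phase <- (t - train$onset) %% (1 / train$prf)
  inside & phase < train$duty / train$prf
}

#' Sinusoidal capacitance drive
#'
#' The reduced representation of the ultrasound-membrane interaction used
#' throughout this package: during each pulse the membrane capacitance of the
#' sonicated membrane fraction follows
#' `Cm_s(t) = Cm0 + C_Amp * sin(2 pi f (t - t_pulse))`, with the phase
#' restarting at zero at each pulse onset, and the whole-cell capacitance is
#' the coverage-weighted mean `Cm = fs * Cm_s + (1 - fs) * Cm0`. The default
#' amplitude 0.8 uF/cm^2 is the calibration at which the capacitance dips by
#' 80% of its resting value, matching the full intramembrane-cavitation
#' mechanics at 0.69 MHz and 3.3 W/cm^2. A mechanics backend satisfying the
#' same contract (Cm, dCm/dt as functions of time) can replace this drive
#' without touching the neuron models.
#'
#' @param c_amp Modulation amplitude (uF cm^-2); must satisfy
#'   `0 <= c_amp < cm0` so the capacitance stays positive.
#' @param cm0 Resting capacitance per unit area (uF cm^-2).
#' @param coverage Active sonophore area fraction in `[0, 1]`.
#' @return An object of class `sinusoidal_drive`.
#' @export
sinusoidal_drive <- function(c_amp = 0.8, cm0 = 1, coverage = 1) {
  stopifnot(cm0 > 0, coverage >= 0, coverage <= 1)
  if (c_amp < 0 || c_amp >= cm0)
    stop("c_amp must be in [0, cm0) so that capacitance stays positive")
  structure(list(c_amp = c_amp, cm0 = cm0, coverage = coverage),
            class = "sinusoidal_drive")
}

#' @export
print.sinusoidal_drive <- function(x, ...) {
  cat(sprintf(
    "<sinusoidal_drive> Cm0 = %g uF/cm^2, C_Amp = %g uF/cm^2, coverage = %g\n",
    x$cm0, x$c_amp, x$coverage))
  invisible(x)
}

#' Capacitance waveform and its derivative
#'
#' Evaluates the membrane capacitance and its exact analytic time derivative
#' under a sinusoidal drive gated by a pulse train. Outside pulses (and with
#' zero coverage) the capacitance is the resting `cm0` and the derivative is
#' zero.
#'
#' @param t Time(s) in seconds.
#' @param drive A [sinusoidal_drive()].
#' @param train A [pulse_train()].
#' @return A list with numeric vectors `cm` (uF cm^-2) and
#'   `dcm_dt` (uF cm^-2 s^-1).
#' @export
drive_capacitance <- function(t, drive, train) {
  stopifnot(inherits(drive, "sinusoidal_drive"), inherits(train, "pulse_train"))
  on <- envelope(t, train)
  amp <- drive$coverage * drive$c_amp
  cm <- rep(drive$cm0, length(t))
  dcm <- numeric(length(t))
  if (any(on) && amp > 0) {
    # time since the onset of the current pulse (CW: since stimulus onset)
    if (train$duty >= 1) {
      tp <- t[on] - train$onset
    } else {
      tp <- (t[on] - train$onset) %% (1 / train$prf)
    }
    w <- 2 * pi * train$carrier_f
    cm[on] <- drive$cm0 + amp * sin(w * tp)
    dcm[on] <- amp * w * cos(w * tp)
  }
  list(cm = cm, dcm_dt = dcm)
}

#' Drive amplitude from nominal acoustic intensity
#'
#' Maps an acoustic intensity to a capacitance modulation amplitude. Only a
#' single calibration point is physically anchored: 3.3 W/cm^2 at 0.69 MHz
#' corresponds to `c_amp = 0.8` uF/cm^2 (an 80% capacitance decline). Away
#' from that point the default mapping scales the amplitude with the pressure
#' amplitude, i.e. proportional to `sqrt(I)`; it is an approximation, and all
#' intensity-labelled outputs should state it. Amplitudes that would reach or
#' exceed `cm0` are clipped just below `cm0` with a warning.
#'
#' @param I_wcm2 Intensity in W cm^-2, > 0.
#' @param cm0 Resting capacitance (uF cm^-2), the clipping ceiling.
#' @param anchor_I Calibration intensity (W cm^-2).
#' @param anchor_amp Calibration amplitude (uF cm^-2).
#' @param exponent Exponent of the power-law mapping; 0.5 is proportionality
#'   to pressure amplitude.
#' @return Amplitude(s) in uF cm^-2.
#' @export
#' @examples
#' amplitude_from_intensity(3.3)   # 0.8
#' amplitude_from_intensity(0.825) # 0.4 (half the pressure amplitude)
amplitude_from_intensity <- function(I_wcm2, cm0 = 1, anchor_I = 3.3,
                                     anchor_amp = 0.8, exponent = 0.5) {
  if (any(I_wcm2 <= 0)) stop("intensity must be positive")
  amp <- anchor_amp * (I_wcm2 / anchor_I)^exponent
  hi <- amp >= cm0
  if (any(hi)) {
    warning(sprintf(
      "%d amplitude value(s) clipped below cm0 = %g uF/cm^2; the sqrt(I) mapping is only anchored at %g W/cm^2",
      sum(hi), cm0, anchor_I))
    amp[hi] <- 0.999 * cm0
  }
  amp
}
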