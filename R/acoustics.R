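#' Acoustic medium parameters
#'
#' Properties of the medium surrounding the neuronal membrane, used for
#' converting between pressure amplitude and spatial-peak pulse-average
#' intensity of a propagating planar ultrasound wave. Defaults are the
#' standard physiological values used throughout the simulator: density
#' 1028 kg/m^3, sound speed 1515 m/s, static pressure 1e5 Pa, temperature
#' 309.15 K (36 C).
#'
#' @param rho_l Mass density of the surrounding medium (kg m^-3).
#' @param c Speed of sound in the medium (m s^-1).
#' @param P0 Static pressure (Pa).
#' @param Tem Temperature (K).
#' @return An object of class `medium_params`.
#' @export
#' @examples
#' medium_params()
medium_params <- function(rho_l = 1028, c = 1515, P0 = 1e5, Tem = 309.15) {
  stopifnot(rho_l > 0, c > 0, P0 > 0, Tem > 0)
  structure(list(rho_l = rho_l, c = c, P0 = P0, Tem = Tem),
            class = "medium_params")
}

#' @export
print.medium_params <- function(x, ...) {
  cat(sprintf(
    "<medium_params> rho_l = %g kg/m^3, c = %g m/s, P0 = %g Pa, Tem = %g K\n",
    x$rho_l, x$c, x$P0, x$Tem))
  invisible(x)
}

#' Convert pressure amplitude to acoustic intensity
#'
#' Spatial-peak pulse-average intensity of a propagating planar ultrasound
#' wave, I = P_A^2 / (2 rho_l c).
#'
#' @param P_A Acoustic pressure amplitude (Pa). Must be >= 0.
#' @param medium A [medium_params()] object.
#' @return Intensity in W m^-2. Use [W_m2_to_W_cm2()] for reporting.
#' @export
#' @examples
#' W_m2_to_W_cm2(pressure_to_intensity(320e3)) # ~3.3 W/cm^2
pressure_to_intensity <- function(P_A, medium = medium_params()) {
  if (any(P_A < 0)) stop("pressure amplitude must be non-negative")
  P_A^2 / (2 * medium$rho_l * medium$c)
}

#' Convert acoustic intensity to pressure amplitude
#'
#' Inverse of [pressure_to_intensity()]: P_A = sqrt(2 rho_l c I).
#'
#' @param I Intensity (W m^-2). Must be >= 0.
#' @inheritParams pressure_to_intensity
#' @return Pressure amplitude in Pa.
#' @export
intensity_to_pressure <- function(I, medium = medium_params()) {
  if (any(I < 0)) stop("intensity must be non-negative")
  sqrt(2 * medium$rho_l * medium$c * I)
}

#' Unit helpers for acoustic reporting
#'
#' The simulator works in SI units internally (Pa, W m^-2); results are
#' conventionally reported in kPa and W cm^-2.
#'
#' @param x Value(s) to convert.
#' @return Converted value(s).
#' @export
W_m2_to_W_cm2 <- function(x) x / 1e4

#' @rdname W_m2_to_W_cm2
#' @export
W_cm2_to_W_m2 <- function(x) x * 1e4

#' @rdname W_m2_to_W_cm2
#' @export
Pa_to_kPa <- function(x) x / 1e3

#' @rdname W_m2_to_W_cm2
#' @export
kPa_to_Pa <- function(x) x * 1e3
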