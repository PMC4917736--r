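# Biophysical parameter registry for the five neuron models.
#
# All conductances in mS/cm^2, potentials in mV, time constants in ms,
# areas in um^2, capacitance in uF/cm^2, calcium concentrations in mM.
# The "fig7" presets are the alternative species parameter sets (ferret
# visual cortex RS/FS, cat association cortex LTS); they exist only for
# the three cortical cell types.

.cell_param_table <- function() {
  list(
    RS = list(
      default = list(g_na = 56, g_kd = 6, g_m = 0.075, g_t = 0, g_h = 0,
                     g_kl = 0, g_leak = 0.0205, v_leak = -70.3, v_t = -56.2,
                     tau_max = 608, v_x = NA_real_, v_ca = NA_real_,
                     area_um2 = 11.88e3, v_m0_ref = -71.9),
      fig7 = list(g_na = 50, g_kd = 5, g_m = 0.07, g_t = 0, g_h = 0,
                  g_kl = 0, g_leak = 0.1, v_leak = -70, v_t = -55,
                  tau_max = 1000, v_x = NA_real_, v_ca = NA_real_,
                  area_um2 = 11.88e3, v_m0_ref = -70.4)
    ),
    FS = list(
      default = list(g_na = 58, g_kd = 3.9, g_m = 0.0787, g_t = 0, g_h = 0,
                     g_kl = 0, g_leak = 0.038, v_leak = -70.4, v_t = -57.9,
                     tau_max = 502, v_x = NA_real_, v_ca = NA_real_,
                     area_um2 = 10.17e3, v_m0_ref = -71.4),
      fig7 = list(g_na = 50, g_kd = 10, g_m = 0, g_t = 0, g_h = 0,
                  g_kl = 0, g_leak = 0.15, v_leak = -70, v_t = -55,
                  tau_max = 1000, v_x = NA_real_, v_ca = NA_real_,
                  area_um2 = 10.17e3, v_m0_ref = -70)
    ),
    LTS = list(
      default = list(g_na = 50, g_kd = 4, g_m = 0.028, g_t = 0.4, g_h = 0,
                     g_kl = 0, g_leak = 0.019, v_leak = -50, v_t = -50,
                     tau_max = 4000, v_x = -7, v_ca = 120,
                     area_um2 = 25e3, v_m0_ref = -54),
      fig7 = list(g_na = 50, g_kd = 5, g_m = 0.03, g_t = 0.4, g_h = 0,
                  g_kl = 0, g_leak = 0.01, v_leak = -85, v_t = -55,
                  tau_max = 1000, v_x = -2, v_ca = 120,
                  area_um2 = 25e3, v_m0_ref = -84.6)
    ),
    TC = list(
      default = list(g_na = 90, g_kd = 10, g_m = 0, g_t = 2, g_h = 0.0175,
                     g_kl = 0.0138, g_leak = 0.01, v_leak = -70, v_t = -52,
                     tau_max = NA_real_, v_x = 0, v_ca = NA_real_,
                     area_um2 = 29e3, v_m0_ref = -63.4)
    ),
    RE = list(
      default = list(g_na = 200, g_kd = 20, g_m = 0, g_t = 3, g_h = 0,
                     g_kl = 0, g_leak = 0.05, v_leak = -90, v_t = -67,
                     tau_max = NA_real_, v_x = NA_real_, v_ca = NA_real_,
                     area_um2 = 14e3, v_m0_ref = -89.5)
    )
  )
}

# Shared constants (same for every cell type that uses them)
.shared_params <- function() {
  list(
    v_na = 50, v_k = -90, v_h = -40, cm0 = 1,
    # calcium pool (TC, RE)
    ca_depth_nm = 100, ca_out = 2, tau_ca = 5, ca_rest = 5e-5,
    # I_h calcium regulation (TC)
    k1 = 2.5e7, k2 = 4e-4, k3 = 0.1, k4 = 1e-3, g_inc = 2,
    tem = 309.15
  )
}

#' Channel composition of a neuron model
#'
#' Assembles the full voltage-gated/leak channel collection of one of the
#' five neuron models, with its conductances, reversal potentials and gate
#' composition. Cortical types (RS, FS, LTS) carry Na, delayed-rectifier K,
#' slow non-inactivating K (M) and leak; LTS adds the low-threshold T-type
#' calcium channel with a fixed calcium reversal. The thalamocortical (TC)
#' model carries Na, Kd, T (calcium-pool Nernst reversal), the
#' hyperpolarization-activated mixed cationic current I_h with its calcium
#' regulation scheme, a potassium leak and a nonspecific leak; the thalamic
#' reticular (RE) model carries Na, Kd, the reticular T-type variant (Ts)
#' and leak.
#'
#' @param cell_type One of `"RS"`, `"FS"`, `"LTS"`, `"TC"`, `"RE"`.
#' @param preset `"default"`, or `"fig7"` for the alternative-species
#'   cortical parameter sets (not available for TC/RE).
#' @return A list of class `channel_set` with one record per channel
#'   (`g` in mS/cm^2, `v_rev` in mV, `gates` description) plus the shared
#'   kinetic parameters (`v_t`, `v_x`, `tau_max`, calcium pool, I_h
#'   regulation).
#' @export
#' @examples
#' build_channel_set("LTS")
build_channel_set <- function(cell_type = c("RS", "FS", "LTS", "TC", "RE"),
                              preset = c("default", "fig7")) {
  cell_type <- match.arg(cell_type)
  preset <- match.arg(preset)
  tab <- .cell_param_table()[[cell_type]]
  if (!preset %in% names(tab))
    stop(sprintf("no '%s' preset exists for cell type %s", preset, cell_type))
  p <- tab[[preset]]
  sh <- .shared_params()

  channels <- list(
    Na = list(g = p$g_na, v_rev = sh$v_na, gates = "m^3 h"),
    Kd = list(g = p$g_kd, v_rev = sh$v_k, gates = "n^4"),
    Leak = list(g = p$g_leak, v_rev = p$v_leak, gates = "none")
  )
  if (p$g_m > 0 || cell_type %in% c("RS", "FS", "LTS"))
    channels$M <- list(g = p$g_m, v_rev = sh$v_k, gates = "p")
  if (cell_type %in% c("LTS", "TC"))
    channels$T <- list(g = p$g_t, v_rev = p$v_ca, gates = "s^2 u")
  if (cell_type == "RE")
    channels$Ts <- list(g = p$g_t, v_rev = NA_real_, gates = "s^2 u")
  if (cell_type == "TC") {
    channels$h <- list(g = p$g_h, v_rev = sh$v_h, gates = "o + 2 oL")
    channels$KL <- list(g = p$g_kl, v_rev = sh$v_k, gates = "none")
  }

  structure(c(list(cell_type = cell_type, preset = preset,
                   channels = channels,
                   v_t = p$v_t, v_x = p$v_x, tau_max = p$tau_max,
                   area_um2 = p$area_um2, v_m0_ref = p$v_m0_ref),
              sh),
            class = "channel_set")
}

#' Parameter registry
#'
#' A data frame mirroring the full biophysical parameter table used by the
#' simulator: one row per (parameter, cell type, preset), with units. Useful
#' for inspection and for config overrides.
#'
#' @return A data.frame with columns `parameter`, `cell_type`, `preset`,
#'   `value`, `unit`.
#' @export
param_registry <- function() {
  tab <- .cell_param_table()
  units <- c(g_na = "mS/cm^2", g_kd = "mS/cm^2", g_m = "mS/cm^2",
             g_t = "mS/cm^2", g_h = "mS/cm^2", g_kl = "mS/cm^2",
             g_leak = "mS/cm^2", v_leak = "mV", v_t = "mV", tau_max = "ms",
             v_x = "mV", v_ca = "mV", area_um2 = "um^2", v_m0_ref = "mV")
  rows <- list()
  for (ct in names(tab)) {
    for (pr in names(tab[[ct]])) {
      p <- tab[[ct]][[pr]]
      for (nm in names(p)) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = nm, cell_type = ct, preset = pr,
          value = as.numeric(p[[nm]]), unit = unname(units[nm]),
          stringsAsFactors = FALSE)
      }
    }
  }
  sh <- .shared_params()
  shu <- c(v_na = "mV", v_k = "mV", v_h = "mV", cm0 = "uF/cm^2",
           ca_depth_nm = "nm", ca_out = "mM", tau_ca = "ms", ca_rest = "mM",
           k1 = "mM^-4 ms^-1", k2 = "ms^-1", k3 = "ms^-1", k4 = "ms^-1",
           g_inc = "-", tem = "K")
  for (nm in names(sh)) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = nm, cell_type = "all", preset = "all",
      value = as.numeric(sh[[nm]]), unit = unname(shu[nm]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
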