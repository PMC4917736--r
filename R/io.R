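# Configuration schema, scenario registry, structured outputs.
#
# Scenarios are fully self-contained named bundles (no external data): each
# encodes one of the standard figure protocols. Config files are YAML with
# a strict schema: unknown keys are errors, omitted keys take defaults.

.config_defaults <- function() {
  list(
    name = NULL,                      # required
    kind = NULL,                      # required: neuron|network|threshold|duty_response
    cell_types = list("RS"),
    preset = "default",
    add_t_channel = FALSE,
    network = list(i_th_rs = 0.17, r_th = 1.4),
    drive = list(c_amp_uF_cm2 = NULL, intensity_W_cm2 = NULL,
                 coverage_fs = 1),
    train = list(carrier_f_hz = 0.69e6, prf_hz = 100, duty = 1,
                 duration_s = NULL, onset_s = 0),
    duration_s = NULL,
    duties = list(),                  # duty_response / threshold protocols
    solver = list(dt_off_s = 1e-5, dt_report_s = NULL, dt_scale = 1),
    notes = ""
  )
}

.KINDS <- c("neuron", "network", "threshold", "duty_response")

# merge user config into defaults, erroring on unknown keys (with path)
.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- paste0(path, key)
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key: %s", here))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       paste0(here, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  for (req in c("name", "kind"))
    if (is.null(cfg[[req]])) stop(sprintf("missing required field: %s", req))
  if (!cfg$kind %in% .KINDS)
    stop(sprintf("kind must be one of %s", paste(.KINDS, collapse = ", ")))
  if (is.null(cfg$duration_s) && is.null(cfg$train$duration_s))
    stop("missing required field: duration_s (or train.duration_s)")
  if (!is.null(cfg$drive$c_amp_uF_cm2) && !is.null(cfg$drive$intensity_W_cm2))
    stop("drive: give c_amp_uF_cm2 or intensity_W_cm2, not both")
  cfg
}

#' Load a scenario configuration
#'
#' Reads a YAML scenario file, fills defaults, and validates it (unknown
#' keys are errors, with the offending path named). Loading a saved
#' configuration reproduces it exactly.
#'
#' @param path Path to a YAML file.
#' @return A validated `scenario_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user) || length(user) == 0) stop("missing required field: name")
  cfg <- .validate_config(.merge_config(.config_defaults(), user))
  class(cfg) <- "scenario_config"
  cfg
}

#' @rdname load_config
#' @param cfg A `scenario_config`.
#' @export
save_config <- function(cfg, path) {
  # NULL-valued fields are defaults; drop them so YAML round-trips exactly
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_nulls)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(drop_nulls(unclass(cfg)), path)
  invisible(path)
}

#' Built-in scenario registry
#'
#' Named, fully self-contained protocols mirroring the figure experiments:
#' continuous-wave versus low-duty-cycle cortical stimulation, the chimeric
#' threshold comparison, the three network conditions, the thalamic
#' duty-cycle response, the alternative-species presets, partial sonophore
#' coverage and the bare sinusoidal-drive demonstration.
#'
#' @return A named list of `scenario_config` objects.
#' @export
scenario_registry <- function() {
  mk <- function(...) {
    cfg <- .validate_config(.merge_config(.config_defaults(), list(...)))
    class(cfg) <- "scenario_config"
    cfg
  }
  list(
    fig2a_cw = mk(
      name = "fig2a_cw", kind = "neuron",
      cell_types = list("RS", "FS", "LTS"),
      drive = list(c_amp_uF_cm2 = 0.8),
      train = list(duty = 1, duration_s = 0.05),
      duration_s = 0.08,
      notes = "50 ms continuous-wave stimulus at the 3.3 W/cm^2 calibration amplitude excites all three cortical types"),
    fig2b_pulsed = mk(
      name = "fig2b_pulsed", kind = "neuron",
      cell_types = list("RS", "FS", "LTS"),
      drive = list(c_amp_uF_cm2 = 0.8),
      train = list(prf_hz = 100, duty = 0.05, duration_s = 0.3),
      duration_s = 0.35,
      notes = "300 ms pulsed stimulus (PRF 100 Hz, duty 5%): only the LTS neuron fires"),
    fig3d_chimeric = mk(
      name = "fig3d_chimeric", kind = "threshold",
      cell_types = list("RS", "RS+", "FS", "FS+", "LTS"),
      train = list(prf_hz = 100, duty = 0.05, duration_s = 0.3),
      notes = "single-spike threshold amplitudes, native vs chimeric T-channel addition"),
    fig5a_network = mk(
      name = "fig5a_network", kind = "network",
      drive = list(intensity_W_cm2 = 0.1),
      train = list(prf_hz = 100, duty = 0.05, duration_s = 1, onset_s = 0.5),
      duration_s = 1.6,
      notes = "low-intensity 5% duty stimulus: no significant network response"),
    fig5b_network = mk(
      name = "fig5b_network", kind = "network",
      drive = list(intensity_W_cm2 = 3.3),
      train = list(prf_hz = 100, duty = 0.05, duration_s = 1, onset_s = 0.5),
      duration_s = 1.6,
      notes = "calibration-intensity 5% duty stimulus: LTS activation suppresses RS/FS baseline activity"),
    fig5c_network = mk(
      name = "fig5c_network", kind = "network",
      drive = list(intensity_W_cm2 = 3.3),
      train = list(prf_hz = 10, duty = 0.5, duration_s = 1, onset_s = 0.5),
      duration_s = 1.6,
      notes = "50% duty, PRF 10 Hz: strong RS/FS activation, LTS fires only at pulse onsets"),
    fig6_thalamic = mk(
      name = "fig6_thalamic", kind = "duty_response",
      cell_types = list("TC", "RE"),
      drive = list(c_amp_uF_cm2 = 0.84),
      train = list(prf_hz = 100, duty = 0.05, duration_s = 1.5),
      duties = list(0.05, 0.06, 0.07),
      notes = "thalamic duty-cycle response; rate over the last 0.5 s of a 1.5 s stimulus"),
    fig7_species_presets = mk(
      name = "fig7_species_presets", kind = "neuron",
      cell_types = list("RS", "FS", "LTS"), preset = "fig7",
      drive = list(c_amp_uF_cm2 = 0.8),
      train = list(prf_hz = 100, duty = 0.05, duration_s = 1.5),
      duration_s = 1.5,
      notes = "alternative-species cortical parameter sets under pulsed stimulation: only LTS responds"),
    fig8_coverage = mk(
      name = "fig8_coverage", kind = "neuron",
      cell_types = list("RS", "LTS"),
      drive = list(c_amp_uF_cm2 = 0.8, coverage_fs = 0.75),
      train = list(duty = 1, duration_s = 0.05),
      duration_s = 0.08,
      notes = "75% sonophore coverage: reduced potential oscillations, responses preserved"),
    fig9_sinusoid = mk(
      name = "fig9_sinusoid", kind = "neuron",
      cell_types = list("RS", "LTS"),
      drive = list(c_amp_uF_cm2 = 0.8),
      train = list(prf_hz = 100, duty = 0.05, duration_s = 0.3),
      duration_s = 0.35,
      notes = "the purely sinusoidal capacitive drive itself (the package's base drive model)")
  )
}

.resolve_amp <- function(cfg) {
  if (!is.null(cfg$drive$c_amp_uF_cm2)) return(cfg$drive$c_amp_uF_cm2)
  if (!is.null(cfg$drive$intensity_W_cm2))
    return(suppressWarnings(amplitude_from_intensity(cfg$drive$intensity_W_cm2)))
  NULL
}

.resolve_cell <- function(label, preset) {
  if (grepl("\\+$", label)) {
    add_channel(nice_neuron(sub("\\+$", "", label), preset))
  } else {
    nice_neuron(label, preset)
  }
}

#' Run a scenario
#'
#' Executes a scenario by name (from [scenario_registry()]), from a loaded
#' `scenario_config`, or from a YAML path, optionally writing the structured
#' outputs (trace CSVs, spike-train JSONs, a summary JSON and a run
#' manifest) to a directory. All outputs are deterministic: the scenario
#' alone determines them.
#'
#' @param scenario A scenario name, a `scenario_config`, or a YAML path.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list with `results` (per-cell simulations or protocol tables),
#'   `summary`, and `manifest` (invisibly returns it after writing).
#' @export
run_scenario <- function(scenario, out_dir = NULL) {
  if (is.character(scenario)) {
    reg <- scenario_registry()
    cfg <- if (scenario %in% names(reg)) reg[[scenario]]
      else load_config(scenario)
  } else cfg <- scenario
  stopifnot(inherits(cfg, "scenario_config"))
  t0 <- Sys.time()
  warn <- character(0)
  amp <- .resolve_amp(cfg)
  train <- NULL
  if (!is.null(cfg$train$duration_s) && !is.null(amp)) {
    train <- pulse_train(cfg$train$carrier_f_hz, prf = cfg$train$prf_hz,
                         duty = cfg$train$duty,
                         duration = cfg$train$duration_s,
                         onset = cfg$train$onset_s)
  }
  drive <- if (!is.null(amp))
    sinusoidal_drive(amp, coverage = cfg$drive$coverage_fs) else NULL
  dur <- if (!is.null(cfg$duration_s)) cfg$duration_s
    else cfg$train$onset_s + cfg$train$duration_s
  dt_rep <- cfg$solver$dt_report_s

  results <- list()
  summary <- list(scenario = cfg$name, kind = cfg$kind)
  if (cfg$kind == "neuron") {
    for (label in unlist(cfg$cell_types)) {
      neuron <- .resolve_cell(label, cfg$preset)
      sim <- simulate_neuron(neuron, train, drive, duration = dur,
                             dt_off = cfg$solver$dt_off_s,
                             dt_report = if (is.null(dt_rep)) 5e-5 else dt_rep,
                             dt_scale = cfg$solver$dt_scale)
      results[[label]] <- sim
      summary$rates_hz[[label]] <- firing_rate(sim$spikes, c(0, dur))
      summary$n_spikes[[label]] <- length(sim$spikes)
    }
  } else if (cfg$kind == "network") {
    net <- cortical_network(cfg$network$i_th_rs, cfg$network$r_th, cfg$preset)
    sim <- simulate_network(net, train, drive, duration = dur,
                            dt_off = cfg$solver$dt_off_s,
                            dt_report = if (is.null(dt_rep)) 2.5e-4 else dt_rep,
                            dt_scale = cfg$solver$dt_scale)
    results$network <- sim
    win <- if (!is.null(train)) c(train$onset, train$onset + train$duration)
      else c(0, dur)
    summary$stim_window_s <- win
    for (nm in names(sim$spikes)) {
      summary$rates_hz[[nm]] <- firing_rate(sim$spikes[[nm]], win)
      summary$n_spikes[[nm]] <- length(sim$spikes[[nm]])
    }
  } else if (cfg$kind == "threshold") {
    for (label in unlist(cfg$cell_types)) {
      neuron <- .resolve_cell(label, cfg$preset)
      th <- find_threshold(neuron,
                           pulse_train(cfg$train$carrier_f_hz,
                                       prf = cfg$train$prf_hz,
                                       duty = cfg$train$duty,
                                       duration = cfg$train$duration_s))
      results[[label]] <- th
      summary$threshold_uF_cm2[[label]] <- th$threshold
      summary$status[[label]] <- th$status
    }
  } else if (cfg$kind == "duty_response") {
    for (label in unlist(cfg$cell_types)) {
      neuron <- .resolve_cell(label, cfg$preset)
      dr <- duty_response(neuron, unlist(cfg$duties), amp = amp,
                          carrier_f = cfg$train$carrier_f_hz,
                          prf = cfg$train$prf_hz,
                          duration = cfg$train$duration_s)
      results[[label]] <- dr
      summary$rates_hz[[label]] <- as.list(stats::setNames(dr$rate_hz,
                                                           paste0("duty_", dr$duty)))
    }
  }
  manifest <- list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("nicesim")),
    deterministic = TRUE,
    intensity_mapping = if (!is.null(cfg$drive$intensity_W_cm2))
      "sqrt(I) proportional, anchored 3.3 W/cm^2 -> 0.8 uF/cm^2 (approximate)"
      else "none (amplitude given directly)",
    warnings = warn,
    wall_time_s = as.numeric(Sys.time() - t0, units = "secs")
  )
  out <- list(results = results, summary = summary, manifest = manifest)
  if (!is.null(out_dir)) write_outputs(out, out_dir)
  out
}

#' Write structured scenario outputs
#'
#' Writes trace CSVs (one per cell/population; stable column order, full
#' float precision), spike-train JSONs, a summary JSON and the run manifest
#' into a directory. Rerunning a scenario overwrites the files
#' deterministically.
#'
#' @param out A [run_scenario()] result.
#' @param out_dir Directory (created if missing).
#' @return The vector of files written, invisibly.
#' @export
write_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(x, f) {
    p <- file.path(out_dir, f)
    if (is.data.frame(x)) {
      utils::write.csv(format(x, digits = 17, trim = TRUE), p,
                       row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null")
    }
    files <<- c(files, p)
  }
  for (nm in names(out$results)) {
    r <- out$results[[nm]]
    if (inherits(r, "nice_sim") || inherits(r, "nice_network_sim")) {
      wr(r$trace, paste0("trace_", nm, ".csv"))
      sp <- if (inherits(r, "nice_sim")) list(spikes_s = r$spikes)
        else lapply(r$spikes, function(s) s)
      wr(sp, paste0("spikes_", nm, ".json"))
    } else if (inherits(r, "threshold_result")) {
      wr(list(cell_type = r$cell_type, threshold_uF_cm2 = r$threshold,
              status = r$status), paste0("threshold_", nm, ".json"))
    } else if (is.data.frame(r)) {
      wr(r, paste0(nm, ".csv"))
    }
  }
  wr(out$summary, "summary.json")
  wr(out$manifest, "manifest.json")
  invisible(files)
}
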