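#' Default run configuration
#'
#' The full configuration tree of an end-to-end run, in bench units at
#' the boundary (uL/h, um, ms) and SI internally. Every field has a
#' default, so an empty YAML file is a valid configuration.
#'
#' @return Nested list of class `adls_run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    optics = list(
      enabled = FALSE,
      wavelength_nm = 473, na = 0.4, nt = 1.0,
      pupil_radius_mm = 2.5, grid_size = 512L, pad_factor = 4,
      n_beams = 9L, spacing_um = 1.5, tan_alpha = 3.46e-3,
      stripe_width = 1L, z_center_um = 100, z_halfspan_um = 5,
      n_planes = 11L, roi_x_um = 4),
    channel = list(h_um = 10, w_um = 50, jet_um = 15),
    fluid = list(rho = 1000, mu = 1e-3),
    flow = list(qj_ul_h = 1, qs_ul_h = 1, k = 0.83,
                velocity_model = "mean_channel"),
    simulation = list(
      mode = "single", population = "micropillar", beta = 1,
      concentration_per_ml = 1e7, duration_s = 1, gain = "medium",
      adc_bits = 16L, baseline = 1000, noise_sd = 350,
      velocity_cv = 0.15, sheet_thickness_um = 0.8),
    pipeline = list(threshold_k = 5, lowpass_hz = 1e5, ma_window = 5L,
                    width_gate_ms = c(0.05, 20),
                    baseline_window = 50001L),
    analysis = list(boundary_um = 2, bins = 64L,
                    size_bin_edges_um = c(0.2, 0.4, 0.6, 0.8, 1.0)),
    output = list(write_trace = FALSE)),
    class = "adls_run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, fills unset fields with their defaults, rejects
#' unknown keys with an error naming them, and validates value ranges.
#' An empty file yields the documented defaults.
#'
#' @param path YAML file path.
#' @return An `adls_run_config` list.
#' @export
load_run_config <- function(path) {
  stopif(!file.exists(path), sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user, "")
  class(cfg) <- "adls_run_config"
  validate_run_config(cfg)
  cfg
}

merge_config <- function(base, user, prefix) {
  unknown <- setdiff(names(user), names(base))
  stopif(length(unknown) > 0,
         sprintf("unknown configuration key(s): %s",
                 paste0(prefix, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      stopif(!is.list(user[[k]]),
             sprintf("configuration section '%s%s' must be a mapping",
                     prefix, k))
      base[[k]] <- merge_config(base[[k]], user[[k]],
                                paste0(prefix, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  chk <- function(ok, msg) stopif(!ok, paste0("invalid config: ", msg))
  chk(cfg$flow$qj_ul_h > 0 && cfg$flow$qs_ul_h > 0,
      "flow rates must be positive")
  chk(cfg$flow$k > 0 && cfg$flow$k <= 1, "k must be in (0, 1]")
  chk(cfg$flow$velocity_model %in% c("mean_channel", "corrected"),
      "velocity_model must be mean_channel or corrected")
  chk(cfg$channel$h_um > 0 && cfg$channel$w_um > 0 &&
        cfg$channel$jet_um > 0, "channel dimensions must be positive")
  chk(cfg$channel$jet_um <= cfg$channel$w_um,
      "jet width cannot exceed channel width")
  chk(cfg$fluid$rho > 0 && cfg$fluid$mu > 0,
      "fluid properties must be positive")
  chk(cfg$simulation$mode %in% c("single", "mixture"),
      "simulation mode must be single or mixture")
  chk(cfg$simulation$concentration_per_ml > 0 &&
        cfg$simulation$duration_s > 0,
      "concentration and duration must be positive")
  chk(cfg$simulation$beta > 0, "beta must be positive")
  chk(cfg$pipeline$lowpass_hz > 0, "lowpass corner must be positive")
  chk(length(cfg$pipeline$width_gate_ms) == 2 &&
        cfg$pipeline$width_gate_ms[2] > cfg$pipeline$width_gate_ms[1],
      "width gate must be an increasing pair")
  chk(cfg$analysis$boundary_um > 0, "boundary must be positive")
  invisible(cfg)
}

#' Save a run configuration to YAML
#'
#' @param cfg An `adls_run_config`.
#' @param path Output path.
#' @return `path`, invisibly. `load_run_config(save_run_config(cfg, f))`
#'   round-trips the configuration.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# constructors from a config tree
config_geom <- function(cfg) {
  channel_geometry(cfg$channel$h_um * 1e-6, cfg$channel$w_um * 1e-6,
                   cfg$channel$jet_um * 1e-6)
}

config_flow <- function(cfg) {
  flow_config(cfg$flow$qj_ul_h, cfg$flow$qs_ul_h, cfg$flow$k,
              cfg$flow$velocity_model)
}

config_fluid <- function(cfg) {
  fluid_props(cfg$fluid$rho, cfg$fluid$mu)
}

config_trace_cfg <- function(cfg) {
  s <- cfg$simulation
  trace_config(duration = s$duration_s, gain = s$gain,
               adc_bits = s$adc_bits, baseline = s$baseline,
               noise_sd = s$noise_sd,
               sheet_thickness = s$sheet_thickness_um * 1e-6)
}

config_filter_cfg <- function(cfg) {
  p <- cfg$pipeline
  filter_config(threshold_k = p$threshold_k, lowpass = p$lowpass_hz,
                ma_window = p$ma_window,
                width_gate = p$width_gate_ms * 1e-3,
                baseline_window = p$baseline_window)
}

config_pupil <- function(cfg) {
  o <- cfg$optics
  pupil_spec(o$wavelength_nm * 1e-9, o$na, o$nt, o$pupil_radius_mm * 1e-3,
             o$grid_size, o$pad_factor)
}
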