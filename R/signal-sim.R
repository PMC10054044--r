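#' PMT amplifier gain presets
#'
#' The detection chain offers three gain settings: low (1e5), medium (1e6)
#' and high (1e7), applied as a linear multiplier on the fluorescence flux
#' before digitization.
#'
#' @param gain `"low"`, `"medium"`, `"high"`, or a positive number used
#'   directly.
#' @return Numeric gain multiplier.
#' @export
gain_value <- function(gain) {
  if (is.numeric(gain)) {
    stopif(gain <= 0, "numeric gain must be positive")
    return(gain)
  }
  switch(match.arg(gain, c("low", "medium", "high")),
         low = 1e5, medium = 1e6, high = 1e7)
}

#' Acquisition settings for simulated PMT traces
#'
#' Defaults mirror the reference acquisition chain: 500 kHz sampling, a
#' 16-bit ADC saturating at 65535 counts, and selectable PMT gain. Noise
#' is additive white Gaussian (in ADC counts, after amplification) plus an
#' optional sinusoidal baseline drift and random single-sample spikes. The
#' default noise level (350 counts rms about a 1000-count baseline) puts a
#' 0.39 um micropillar at medium gain near peak SNR 5, the smallest
#' pulse class the pipeline is expected to resolve.
#'
#' @param sampling_rate Samples per second (default 5e5).
#' @param duration Trace length in seconds.
#' @param gain Gain preset or numeric multiplier, see [gain_value()].
#' @param adc_bits ADC depth, 8..24 (default 16).
#' @param baseline Mean baseline in counts.
#' @param noise_sd White-noise standard deviation in counts.
#' @param drift_amplitude,drift_period Sinusoidal baseline drift (counts,
#'   seconds); amplitude 0 disables it.
#' @param spike_rate Expected spurious single-sample spikes per second.
#' @param spike_amplitude Spike height in counts.
#' @param sheet_thickness Light-sheet thickness d_s (m) shaping the pulse
#'   rise time.
#' @param shape Pulse shape model, see [pulse_shape()].
#' @return An object of class `adls_trace_config`.
#' @export
trace_config <- function(sampling_rate = 5e5, duration = 1,
                         gain = "medium", adc_bits = 16, baseline = 1000,
                         noise_sd = 350, drift_amplitude = 0,
                         drift_period = 1, spike_rate = 0,
                         spike_amplitude = 2000,
                         sheet_thickness = 0.8e-6,
                         shape = c("cosine", "gaussian")) {
  stopif(sampling_rate <= 0 || duration < 0, "bad sampling rate/duration")
  stopif(!(adc_bits %in% 8:24), "adc_bits must be in 8..24")
  stopif(noise_sd < 0 || baseline < 0, "noise and baseline must be >= 0")
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 gain = gain, adc_bits = as.integer(adc_bits),
                 baseline = baseline, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude,
                 sheet_thickness = sheet_thickness,
                 shape = match.arg(shape)),
            class = "adls_trace_config")
}

#' Fluorescent particle population presets
#'
#' Two stock populations: polystyrene fluorescent micropillars (streamwise
#' extents drawn from a lognormal truncated to the manufacturer's
#' 0.4-1 um length range, median 0.7 um) and 5 um fluorescent
#' microspheres (normal, 5% nominal coefficient of variation). Brightness
#' scales with dp^2 as a cross-section proxy; the per-population
#' coefficients are calibrated so that a 1.09 um pillar at medium gain
#' peaks near 1.38e4 counts and a 5 um sphere at low gain near 3.68e4
#' counts (the reference system's worked pulses). At medium gain a 5 um
#' sphere therefore saturates the 16-bit ADC, reproducing the
#' width-overestimation mechanism seen in mixed-population runs.
#'
#' @param name `"micropillar"` or `"microsphere"`.
#' @return List with `label`, `brightness_coef` (counts per unit gain per
#'   um^2) and `size_sampler(n)` returning diameters in metres.
#' @export
particle_preset <- function(name = c("micropillar", "microsphere")) {
  switch(match.arg(name),
    micropillar = list(
      label = "micropillar",
      brightness_coef = 1.16e-2,
      size_sampler = function(n) {
        rtrunc(n, 0.4e-6, 1.0e-6,
               function(m) stats::rlnorm(m, log(0.7e-6), 0.25))
      }),
    microsphere = list(
      label = "microsphere",
      brightness_coef = 1.47e-2,
      size_sampler = function(n) {
        rtrunc(n, 1e-6, Inf,
               function(m) stats::rnorm(m, 5e-6, 0.25e-6))
      }))
}

# rejection sampler on [lo, hi]
rtrunc <- function(n, lo, hi, rfun) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rfun(max(n, 16))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Expected number of particles crossing the sheet
#'
#' The arrival rate of a well-mixed suspension at concentration C carried
#' by a jet of flow rate Q_j is C Q_j; in time T the expected count is
#' C Q_j T.
#'
#' @param concentration_per_ml Particle concentration per millilitre.
#' @param flow An `adls_flow` object (only the jet rate enters).
#' @param duration Observation time in seconds.
#' @return Expected event count (not rounded).
#' @examples
#' expected_event_count(1e7, flow_config(1, 1), 300)  # 833.3 in 5 min
#' @export
expected_event_count <- function(concentration_per_ml, flow, duration) {
  stopif(concentration_per_ml < 0 || duration < 0,
         "concentration and duration must be >= 0")
  concentration_per_ml * (flow$qj * 1e6) * duration
}

#' Draw a particle population crossing the sheet
#'
#' Arrivals follow a Poisson process with rate C Q_j; sizes are i.i.d.
#' from the preset's size distribution; each event's velocity jitters
#' around the jet velocity with relative standard deviation `velocity_cv`
#' (the reference system shows ~15% velocity fluctuation at 1 uL/h).
#'
#' @inheritParams expected_event_count
#' @param preset A preset name for [particle_preset()], a preset list, or
#'   a function(n) returning diameters in metres (then `brightness_coef`
#'   must be given).
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @param geom Channel geometry for the velocity model.
#' @param velocity_model Passed to [jet_velocity()].
#' @param velocity_cv Relative SD of per-event velocity jitter.
#' @param brightness_coef Override of the preset brightness coefficient.
#' @return Data frame of class `adls_particles` with columns `time` (s,
#'   strictly increasing), `dp` (m), `brightness` (flux in counts per unit
#'   gain), `velocity` (m/s) and `label`.
#' @export
sample_population <- function(concentration_per_ml, flow, duration,
                              preset = "micropillar", seed = NULL,
                              geom = channel_geometry(),
                              velocity_model = flow$velocity_model,
                              velocity_cv = 0.15,
                              brightness_coef = NULL) {
  if (is.character(preset)) preset <- particle_preset(preset)
  if (is.function(preset)) {
    preset <- list(label = "custom", size_sampler = preset,
                   brightness_coef = brightness_coef)
  }
  stopif(is.null(preset$brightness_coef), "brightness_coef required")
  with_seed(seed, {
    n <- stats::rpois(1, expected_event_count(concentration_per_ml, flow,
                                              duration))
    if (n == 0 || duration == 0) {
      return(empty_particles())
    }
    up <- jet_velocity(flow, geom, velocity_model)
    times <- sort(stats::runif(n, 0, duration))
    dp <- preset$size_sampler(n)
    v <- up * rtrunc(n, 0.2, Inf, function(m)
      stats::rnorm(m, 1, velocity_cv))
    out <- data.frame(time = times, dp = dp,
                      brightness = preset$brightness_coef * (dp * 1e6)^2,
                      velocity = v,
                      label = preset$label,
                      stringsAsFactors = FALSE)
    class(out) <- c("adls_particles", "data.frame")
    out
  })
}

empty_particles <- function() {
  out <- data.frame(time = numeric(0), dp = numeric(0),
                    brightness = numeric(0), velocity = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)
  class(out) <- c("adls_particles", "data.frame")
  out
}

#' Time-domain pulse of one particle crossing the sheet
#'
#' The default `"cosine"` model is a unit plateau with raised-cosine
#' (sin^2) edges: total half-maximum width exactly (dp + d_s)/u_p and
#' edge rise time d_s/u_p set by the sheet crossing. Its half-maximum
#' level coincides with the inflection point of the edge, so linearly
#' interpolated FWHM estimates are third-order accurate — the shape is
#' chosen so that the transit-time sizing relation dp = u_p tau - d_s is
#' exact by construction. The `"gaussian"` model is the physical
#' convolution of a top-hat particle profile with a Gaussian sheet profile
#' of FWHM d_s; its half-maximum width is smaller than (dp + d_s)/u_p for
#' small particles, which biases sizing (see the package vignette).
#'
#' @param dp Particle diameter (m).
#' @param up Particle speed (m/s).
#' @param ds Sheet thickness (m).
#' @param brightness Peak flux in counts per unit gain.
#' @param sampling_rate Samples per second.
#' @param shape `"cosine"` or `"gaussian"`.
#' @return Numeric vector of flux samples with attributes `center` (index
#'   of the pulse centre within the vector) and `sampling_rate`.
#' @export
pulse_shape <- function(dp, up, ds, brightness = 1, sampling_rate = 5e5,
                        shape = c("cosine", "gaussian")) {
  stopif(dp < 0 || up <= 0 || ds <= 0 || brightness < 0,
         "pulse parameters must be positive")
  shape <- match.arg(shape)
  tau0 <- (dp + ds) / up
  dt <- 1 / sampling_rate
  if (shape == "cosine") {
    t_edge <- min(ds / up, 0.9 * tau0)
    half_span <- (tau0 + t_edge) / 2
    t <- seq(-half_span, half_span, by = dt)
    a <- abs(t)
    y <- numeric(length(t))
    flat <- a <= (tau0 - t_edge) / 2
    edge <- !flat & a <= half_span
    y[flat] <- 1
    y[edge] <- sin(pi / 2 * (half_span - a[edge]) / t_edge)^2
  } else {
    sigma <- (ds / up) / (2 * sqrt(2 * log(2)))
    th <- dp / up
    half_span <- th / 2 + 5 * sigma
    t <- seq(-half_span, half_span, by = dt)
    raw <- stats::pnorm((t + th / 2) / sigma) -
      stats::pnorm((t - th / 2) / sigma)
    y <- raw / (2 * stats::pnorm(th / 2 / sigma) - 1)
  }
  out <- brightness * y
  attr(out, "center") <- which.min(abs(t))
  attr(out, "sampling_rate") <- sampling_rate
  out
}

#' Render a particle event list into a digitized PMT trace
#'
#' Pulses are scaled by the PMT gain, summed onto the baseline, corrupted
#' with white Gaussian noise (plus optional drift and spikes), and
#' quantized to the ADC depth with saturation at 2^bits - 1. The
#' ground-truth event list rides along in the trace object for validation
#' but is never consulted by the detection pipeline.
#'
#' @param events An `adls_particles` data frame (may be empty).
#' @param cfg An `adls_trace_config`; `cfg$duration` must cover the
#'   events.
#' @param seed Integer seed; identical `(events, cfg, seed)` give
#'   identical traces.
#' @return An object of class `adls_trace`: integer `samples`, the
#'   config, and the ground-truth `truth` event table.
#' @export
generate_trace <- function(events, cfg, seed = NULL) {
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  stopif(n < 1, "trace duration too short for the sampling rate")
  g <- gain_value(cfg$gain)
  y <- rep(cfg$baseline, n)
  if (nrow(events) > 0) {
    stopif(any(events$time < 0 | events$time > cfg$duration),
           "events must lie within the trace duration")
    for (i in seq_len(nrow(events))) {
      p <- pulse_shape(events$dp[i], events$velocity[i],
                       cfg$sheet_thickness, events$brightness[i] * g,
                       fs, cfg$shape)
      stopif(length(p) > n, "pulse longer than the trace")
      c0 <- round(events$time[i] * fs) - attr(p, "center") + 1
      idx <- seq_along(p) + c0 - 1
      keep <- idx >= 1 & idx <= n
      y[idx[keep]] <- y[idx[keep]] + p[keep]
    }
  }
  with_seed(seed, {
    if (cfg$noise_sd > 0) y <- y + stats::rnorm(n, 0, cfg$noise_sd)
    if (cfg$drift_amplitude > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      y <- y + cfg$drift_amplitude *
        sin(2 * pi * seq_len(n) / (cfg$drift_period * fs) + ph)
    }
    if (cfg$spike_rate > 0) {
      k <- stats::rpois(1, cfg$spike_rate * cfg$duration)
      if (k > 0) {
        at <- sample.int(n, k, replace = TRUE)
        y[at] <- y[at] + cfg$spike_amplitude
      }
    }
    adc_max <- 2^cfg$adc_bits - 1
    samples <- pmin(pmax(round(y), 0), adc_max)
    structure(list(samples = as.integer(samples), config = cfg,
                   truth = events),
              class = "adls_trace")
  })
}

#' @export
print.adls_trace <- function(x, ...) {
  cat(sprintf(paste0("PMT trace: %d samples at %g kHz (%.3g s), ",
                     "gain %s, %d-bit ADC, %d ground-truth events\n"),
              length(x$samples), x$config$sampling_rate / 1e3,
              x$config$duration, as.character(x$config$gain),
              x$config$adc_bits, nrow(x$truth)))
  invisible(x)
}

#' Simulate a two-population mixture trace
#'
#' Micropillars and microspheres at a number-density ratio
#' beta = C_pillar / C_sphere and total concentration
#' `total_concentration_per_ml` are drawn independently, merged in time
#' order, and rendered into a single trace at one gain (as in a mixed-run
#' measurement, where one gain must serve both populations).
#'
#' @param beta Pillar-to-sphere concentration ratio (> 0).
#' @param total_concentration_per_ml Combined concentration per mL.
#' @param flow,cfg,seed,geom As in [sample_population()] /
#'   [generate_trace()].
#' @param duration Trace duration in seconds (overrides `cfg$duration`).
#' @param velocity_cv Per-event velocity jitter.
#' @return An `adls_trace` whose `truth` table carries per-event labels.
#' @export
simulate_mixture <- function(beta, total_concentration_per_ml, flow,
                             duration, cfg, seed = NULL,
                             geom = channel_geometry(),
                             velocity_cv = 0.15) {
  stopif(beta <= 0, "beta must be positive")
  cfg$duration <- duration
  with_seed(seed, {
    c_pi <- total_concentration_per_ml * beta / (1 + beta)
    c_s <- total_concentration_per_ml - c_pi
    pillars <- sample_population(c_pi, flow, duration, "micropillar",
                                 seed = NULL, geom = geom,
                                 velocity_cv = velocity_cv)
    spheres <- sample_population(c_s, flow, duration, "microsphere",
                                 seed = NULL, geom = geom,
                                 velocity_cv = velocity_cv)
    all <- rbind(pillars, spheres)
    all <- all[order(all$time), , drop = FALSE]
    rownames(all) <- NULL
    class(all) <- c("adls_particles", "data.frame")
    generate_trace(all, cfg, seed = NULL)
  })
}
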