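#' Detection-pipeline settings
#'
#' Parameters of the five-step pulse pipeline: (1) baseline removal and
#' zero-phase band limiting with threshold-based region picking, (2)
#' moving-average smoothing and local-maxima search, (3) edge
#' determination with width-gate validation, (4) linearly interpolated
#' FWHM, (5) event statistics. The acquisition chain publishes no filter
#' constants, so all of them live here with defaults sized to pulse
#' durations of roughly 0.05-20 ms.
#'
#' @param threshold Absolute detection threshold in counts above baseline,
#'   or `NULL` to use `threshold_k` times the robust (MAD) noise SD of the
#'   filtered trace.
#' @param threshold_k Multiplier for the automatic threshold (default 5).
#' @param threshold_floor Lower bound on the automatic threshold in
#'   counts, so that essentially noise-free traces (MAD near zero) do not
#'   flag every numerical ripple (default 10, a few ADC steps).
#' @param lowpass Low-pass corner frequency in Hz (zero-phase Butterworth,
#'   order 3). Must be below Nyquist.
#' @param ma_window Moving-average window in samples (odd, >= 1).
#' @param width_gate Two-element vector: admissible pulse FWHM range in
#'   seconds; pulses outside it are discarded and logged.
#' @param baseline_window Window (samples) of the rolling-median baseline
#'   estimate; should be much longer than the longest pulse.
#' @param region_pad Padding added around each above-threshold run, as a
#'   multiple of the run length (plus a few smoothing windows), so that
#'   half-maximum crossings below threshold stay inside the region.
#' @param valley_frac Two local maxima within a region are merged into one
#'   pulse unless the valley between them drops below this fraction of the
#'   lower peak (default 0.5, i.e. resolvable at half maximum).
#' @return An object of class `adls_filter_config`.
#' @export
filter_config <- function(threshold = NULL, threshold_k = 5,
                          threshold_floor = 10, lowpass = 1e5,
                          ma_window = 5, width_gate = c(5e-5, 2e-2),
                          baseline_window = 50001, region_pad = 3,
                          valley_frac = 0.5) {
  stopif(!is.null(threshold) && threshold <= 0, "threshold must be > 0")
  stopif(threshold_k <= 0, "threshold_k must be > 0")
  stopif(lowpass <= 0, "lowpass corner must be > 0")
  stopif(ma_window < 1, "ma_window must be >= 1")
  if (ma_window %% 2 == 0) ma_window <- ma_window + 1
  stopif(length(width_gate) != 2 || width_gate[1] < 0 ||
           width_gate[2] <= width_gate[1], "bad width gate")
  structure(list(threshold = threshold, threshold_k = threshold_k,
                 threshold_floor = threshold_floor,
                 lowpass = lowpass, ma_window = as.integer(ma_window),
                 width_gate = width_gate,
                 baseline_window = baseline_window,
                 region_pad = region_pad, valley_frac = valley_frac),
            class = "adls_filter_config")
}

# rolling baseline via block medians interpolated back to full length;
# robust to sparse pulses and far cheaper than a dense running median
estimate_baseline <- function(x, window) {
  n <- length(x)
  if (n <= 2 * window) return(rep(stats::median(x), n))
  nb <- ceiling(n / window)
  starts <- floor(seq(1, n - window + 1, length.out = nb))
  centers <- starts + window / 2
  meds <- vapply(starts, function(s)
    stats::median(x[s:(s + window - 1)]), numeric(1))
  stats::approx(centers, meds, xout = seq_len(n), rule = 2)$y
}

# centered moving average with shrinking windows at the boundaries
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  h <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Step 1: denoise a trace and pick candidate pulse regions
#'
#' Removes the baseline with a rolling block median (the high-pass side of
#' the band limit, robust to pulse asymmetry), applies a zero-phase
#' forward-backward Butterworth low-pass (so pulse widths are not skewed
#' by filter lag), estimates the residual noise SD from the median
#' absolute deviation, and returns the maximal runs above threshold,
#' padded and merged into candidate regions.
#'
#' @param trace An `adls_trace`, or a numeric vector (then
#'   `sampling_rate` must be given).
#' @param cfg An `adls_filter_config`.
#' @param sampling_rate Samples per second when `trace` is a bare vector.
#' @return An object of class `adls_denoised`: `filtered` (baseline-free,
#'   band-limited signal), `smoothed` (after the moving average),
#'   `baseline` estimate, `noise_sd`, `threshold`, and `regions` (data
#'   frame of start/end sample indices).
#' @export
denoise <- function(trace, cfg = filter_config(), sampling_rate = NULL) {
  if (inherits(trace, "adls_trace")) {
    x <- as.numeric(trace$samples)
    fs <- trace$config$sampling_rate
  } else {
    x <- as.numeric(trace)
    stopif(is.null(sampling_rate), "sampling_rate required for a vector")
    fs <- sampling_rate
  }
  stopif(length(x) < 8, "trace too short")
  stopif(cfg$lowpass >= fs / 2,
         "lowpass corner must be below the Nyquist frequency")
  base <- estimate_baseline(x, min(cfg$baseline_window,
                                   max(3, length(x) %/% 2)))
  xf <- x - base
  bw <- signal::butter(3, cfg$lowpass / (fs / 2), type = "low")
  xf <- signal::filtfilt(bw, xf)
  sm <- moving_average(xf, cfg$ma_window)
  noise_sd <- stats::mad(xf)
  thr <- if (!is.null(cfg$threshold)) cfg$threshold
         else max(cfg$threshold_k * noise_sd, cfg$threshold_floor)
  regions <- find_regions(xf > thr, cfg$region_pad, cfg$ma_window,
                          length(x))
  structure(list(filtered = xf, smoothed = sm, baseline = base,
                 noise_sd = noise_sd, threshold = thr, regions = regions,
                 sampling_rate = fs, trace = trace),
            class = "adls_denoised")
}

find_regions <- function(above, pad_mult, ma_window, n) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  s <- starts[keep]; e <- ends[keep]
  pad <- pmax(ceiling(pad_mult * (e - s + 1)), 3 * ma_window)
  s <- pmax(s - pad, 1)
  e <- pmin(e + pad, n)
  # merge overlaps after padding
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Step 2: smooth candidate regions and locate pulse peaks
#'
#' Searches the moving-average-smoothed signal for local maxima above
#' threshold inside each candidate region. Plateaus of equal samples
#' (e.g. ADC saturation) yield a single peak at the plateau centre.
#' Adjacent maxima are merged into one pulse unless the valley between
#' them drops below `valley_frac` of the lower peak, which is what limits
#' the minimum resolvable event interval.
#'
#' @param den An `adls_denoised` object.
#' @param cfg The `adls_filter_config` used in [denoise()].
#' @return Data frame with one row per retained peak: `region`, `index`
#'   (sample), `value` (smoothed counts above baseline).
#' @export
smooth_and_peaks <- function(den, cfg = filter_config()) {
  s <- den$smoothed
  out <- list()
  for (ri in seq_len(nrow(den$regions))) {
    a <- den$regions$start[ri]; b <- den$regions$end[ri]
    pk <- local_maxima(s[a:b])
    pk <- pk[s[a:b][pk] >= den$threshold]
    if (!length(pk)) next
    pk <- merge_peaks(s[a:b], pk, cfg$valley_frac)
    out[[length(out) + 1]] <- data.frame(region = ri,
                                         index = pk + a - 1,
                                         value = s[pk + a - 1])
  }
  if (!length(out)) {
    return(data.frame(region = integer(0), index = integer(0),
                      value = numeric(0)))
  }
  do.call(rbind, out)
}

# strict local maxima; plateaus resolved to their centre sample
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  left <- c(-Inf, y[-n])
  starts <- which(y > left)
  res <- integer(0)
  for (i in starts) {
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1
    right <- if (j < n) y[j + 1] else -Inf
    if (right < y[i] && i > 1) res <- c(res, (i + j) %/% 2)
  }
  res
}

merge_peaks <- function(y, pk, valley_frac) {
  pk <- sort(pk)
  repeat {
    if (length(pk) < 2) return(pk)
    merged <- FALSE
    for (i in seq_len(length(pk) - 1)) {
      valley <- min(y[pk[i]:pk[i + 1]])
      lower <- min(y[pk[i]], y[pk[i + 1]])
      if (valley > valley_frac * lower) {
        drop <- if (y[pk[i]] < y[pk[i + 1]]) i else i + 1
        pk <- pk[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(pk)
  }
}

#' Steps 3-4: pulse edges, interpolated FWHM and saturation flags
#'
#' For each peak the half-maximum level is half the (baseline-free)
#' smoothed peak value; the rising and falling crossings are found by
#' walking outward from the peak, bounded by the valleys towards
#' neighbouring peaks, and refined by linear interpolation between the
#' bracketing samples, giving sub-sample FWHM. Pulses whose crossings are
#' not found inside their region are rejected with a flag. A pulse is
#' flagged saturated when any raw sample in its span reaches the ADC
#' ceiling.
#'
#' @param den An `adls_denoised` object.
#' @param peaks Output of [smooth_and_peaks()].
#' @return Data frame of class `adls_pulses`: `time` (s, at the peak),
#'   `peak_index`, `ifp` (peak value in raw ADC counts, i.e. including
#'   the local baseline), `fwhm` (s), `start`, `end` (interpolated edge
#'   samples), `saturated`. Rejected candidates are counted in the
#'   attribute `n_edge_rejected`.
#' @export
measure_pulses <- function(den, peaks) {
  s <- den$smoothed
  fs <- den$sampling_rate
  raw <- if (inherits(den$trace, "adls_trace")) den$trace$samples else
    den$trace
  adc_max <- if (inherits(den$trace, "adls_trace"))
    2^den$trace$config$adc_bits - 1 else Inf
  rows <- list()
  rejected <- 0L
  for (ri in unique(peaks$region)) {
    p <- peaks[peaks$region == ri, , drop = FALSE]
    a <- den$regions$start[ri]; b <- den$regions$end[ri]
    for (k in seq_len(nrow(p))) {
      pk <- p$index[k]
      lb <- if (k > 1) valley_index(s, p$index[k - 1], pk) else a
      rb <- if (k < nrow(p)) valley_index(s, pk, p$index[k + 1]) else b
      half <- s[pk] / 2
      lc <- cross_left(s, pk, lb, half)
      rc <- cross_right(s, pk, rb, half)
      if (is.na(lc) || is.na(rc)) {
        rejected <- rejected + 1L
        next
      }
      span <- floor(lc):ceiling(rc)
      rows[[length(rows) + 1]] <- data.frame(
        time = (pk - 1) / fs,
        peak_index = pk,
        ifp = s[pk] + den$baseline[pk],
        fwhm = (rc - lc) / fs,
        start = lc, end = rc,
        saturated = any(raw[span] >= adc_max))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(0), peak_index = integer(0),
               ifp = numeric(0), fwhm = numeric(0), start = numeric(0),
               end = numeric(0), saturated = logical(0))
  class(out) <- c("adls_pulses", "data.frame")
  attr(out, "n_edge_rejected") <- rejected
  out
}

valley_index <- function(s, i, j) i + which.min(s[i:j]) - 1

cross_left <- function(s, pk, lb, half) {
  if (pk <= lb) return(NA_real_)
  for (i in seq(pk - 1, lb)) {
    if (s[i] < half) return(i + (half - s[i]) / (s[i + 1] - s[i]))
  }
  NA_real_
}

cross_right <- function(s, pk, rb, half) {
  if (pk >= rb) return(NA_real_)
  for (i in seq(pk + 1, rb)) {
    if (s[i] < half) return(i - (half - s[i]) / (s[i - 1] - s[i]))
  }
  NA_real_
}

#' Step 3b: validate pulses against the width gate
#'
#' @param pulses An `adls_pulses` data frame.
#' @param width_gate Admissible FWHM range in seconds.
#' @return The retained pulses; attribute `rejections` counts pulses
#'   discarded as too short or too long (plus edge rejections carried
#'   over).
#' @export
validate_pulses <- function(pulses, width_gate = c(5e-5, 2e-2)) {
  too_short <- pulses$fwhm < width_gate[1]
  too_long <- pulses$fwhm > width_gate[2]
  out <- pulses[!(too_short | too_long), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("adls_pulses", "data.frame")
  attr(out, "rejections") <- list(
    edge = attr(pulses, "n_edge_rejected") %||% 0L,
    too_short = sum(too_short), too_long = sum(too_long))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Step 5: convert validated pulses into a sized event table
#'
#' @param pulses Validated `adls_pulses`.
#' @param flow,geom Flow and channel configuration for the velocity.
#' @param ds Sheet thickness (m).
#' @param velocity_model Velocity model passed to [jet_velocity()].
#' @return An `adls_events` data frame: `time` (s), `fwhm` (s), `ifp`
#'   (counts), `dp` (m), `saturated`, `subresolution`; run metadata in
#'   attributes (`velocity`, `rejections`).
#' @export
size_events <- function(pulses, flow, geom = channel_geometry(),
                        ds = 0.8e-6, velocity_model = flow$velocity_model) {
  up <- jet_velocity(flow, geom, velocity_model)
  dp <- particle_diameter(up, pulses$fwhm, ds)
  out <- data.frame(time = pulses$time, fwhm = pulses$fwhm,
                    ifp = pulses$ifp, dp = as.numeric(dp),
                    saturated = pulses$saturated,
                    subresolution = attr(dp, "subresolution") %||%
                      logical(nrow(pulses)))
  class(out) <- c("adls_events", "data.frame")
  attr(out, "velocity") <- up
  attr(out, "rejections") <- attr(pulses, "rejections")
  out
}

#' Run the full five-step detection pipeline on a trace
#'
#' @param trace An `adls_trace` or numeric vector.
#' @param cfg An `adls_filter_config`.
#' @param flow,geom,ds,velocity_model Sizing configuration, see
#'   [size_events()].
#' @param sampling_rate Needed when `trace` is a bare vector.
#' @return An `adls_events` table; attribute `counts` reports events in
#'   and out of each stage.
#' @export
detect_events <- function(trace, cfg = filter_config(), flow,
                          geom = channel_geometry(), ds = 0.8e-6,
                          velocity_model = flow$velocity_model,
                          sampling_rate = NULL) {
  den <- denoise(trace, cfg, sampling_rate)
  peaks <- smooth_and_peaks(den, cfg)
  pulses <- measure_pulses(den, peaks)
  valid <- validate_pulses(pulses, cfg$width_gate)
  ev <- size_events(valid, flow, geom, ds, velocity_model)
  attr(ev, "counts") <- list(regions = nrow(den$regions),
                             peaks = nrow(peaks),
                             measured = nrow(pulses),
                             validated = nrow(valid))
  ev
}

#' Minimum resolvable interval between two identical pulses
#'
#' Sweeps the separation between two identical pulses rendered into a
#' clean trace at the stated settings and reports the smallest separation
#' from which the pipeline consistently detects two events — the
#' temporal-resolution limit that caps the event rate at 1/min(delta-tau).
#'
#' @param separations Peak-to-peak separations to test (s), ascending.
#' @param flow,geom Flow settings fixing the particle speed.
#' @param trace_cfg Acquisition settings (noise included if nonzero).
#' @param filter_cfg Pipeline settings.
#' @param dp Particle diameter of the test pulses (m).
#' @param seed Seed for the noise realizations.
#' @return List with `min_resolvable` (s; `NA` if none), `max_rate`
#'   (events/s) and the sweep `table` (separation, events detected).
#' @export
resolve_delta_tau <- function(separations,
                              flow = flow_config(20, 20),
                              geom = channel_geometry(),
                              trace_cfg = NULL, filter_cfg = NULL,
                              dp = 0.5e-6, seed = 1) {
  if (is.null(trace_cfg)) {
    trace_cfg <- trace_config(duration = 0.2, noise_sd = 100)
  }
  if (is.null(filter_cfg)) {
    # admit pulses down to a few samples: the sweep probes the resolution
    # limit, so the gate must not be what rejects close doublets
    filter_cfg <- filter_config(width_gate = c(1e-5, 2e-3))
  }
  up <- jet_velocity(flow, geom)
  coef <- particle_preset("micropillar")$brightness_coef
  n_det <- vapply(separations, function(sep) {
    t0 <- trace_cfg$duration / 2
    ev <- data.frame(time = c(t0, t0 + sep), dp = dp,
                     brightness = coef * (dp * 1e6)^2, velocity = up,
                     label = "test", stringsAsFactors = FALSE)
    class(ev) <- c("adls_particles", "data.frame")
    tr <- generate_trace(ev, trace_cfg, seed = seed)
    nrow(detect_events(tr, filter_cfg, flow, geom,
                       ds = trace_cfg$sheet_thickness))
  }, numeric(1))
  resolved <- n_det >= 2
  # smallest separation above which every tested separation resolves
  min_res <- NA_real_
  if (any(resolved)) {
    ok_from <- rev(cumprod(rev(resolved))) == 1
    if (any(ok_from)) min_res <- separations[which(ok_from)[1]]
  }
  list(min_resolvable = min_res,
       max_rate = if (is.na(min_res)) NA_real_ else 1 / min_res,
       table = data.frame(separation = separations, events = n_det))
}
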