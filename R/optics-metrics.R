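#' Full width at half maximum of a sampled profile
#'
#' Locates the global maximum and walks outward to the first samples below
#' the half-maximum level on each side; the crossing positions are refined
#' by linear interpolation between the bracketing samples, giving
#' sub-sample resolution. This is the single FWHM primitive used for both
#' optical profiles and time-domain pulses.
#'
#' @param y Numeric profile (>= 3 samples).
#' @param dx Sample spacing (any unit; the result carries it).
#' @param baseline Baseline level subtracted before halving.
#' @return FWHM in units of `dx`, or `NA` if either crossing is missing
#'   (e.g. a peak at the edge of the window).
#' @export
profile_fwhm <- function(y, dx = 1, baseline = 0) {
  n <- length(y)
  if (n < 3) return(NA_real_)
  m <- which.max(y)
  half <- baseline + (y[m] - baseline) / 2
  left <- NA_real_
  for (i in seq(m - 1, 1)) {
    if (m == 1) break
    if (y[i] < half) {
      left <- i + (half - y[i]) / (y[i + 1] - y[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(m + 1, n)) {
    if (m == n) break
    if (y[i] < half) {
      right <- i - (half - y[i]) / (y[i - 1] - y[i])
      break
    }
  }
  (right - left) * dx
}

#' Light-sheet dimensions from an intensity stack
#'
#' The stack axes are (x, y, z) with x the thin axis of the sheet, y its
#' width and z the propagation (height) axis. At every (y, z) position
#' whose intensity column exceeds `floor_frac` of the stack maximum, the
#' thickness is the FWHM of the x profile; the sheet thickness is reported
#' as the median of these samples with their standard deviation. Width and
#' height are the FWHMs of the maximum-projected envelopes along y and z.
#' All half-maximum crossings use linear interpolation.
#'
#' @param stack An `adls_stack` from [focal_intensity()], or a plain 3D
#'   array (then `dx`, and optionally `dy`/`dz`, must be given).
#' @param dx,dy,dz Sampling along x, y, z. `dy` defaults to `dx`; `dz`
#'   defaults to the spacing of the stack's z planes.
#' @param floor_frac Intensity floor as a fraction of the stack maximum
#'   below which (y, z) columns are ignored.
#' @return An object of class `adls_sheet_metrics` with fields
#'   `thickness_fwhm`, `thickness_sd`, `width`, `height` (metres; `height`
#'   is `NA` for single-plane stacks) and `uniformity_profile`, a data
#'   frame of per-(y, z) thickness samples.
#' @export
measure_sheet <- function(stack, dx = NULL, dy = NULL, dz = NULL,
                          floor_frac = 0.1) {
  if (inherits(stack, "adls_stack")) {
    I <- stack$I
    dx <- stack$dx
    if (is.null(dy)) dy <- stack$dx
    if (is.null(dz) && length(stack$z) > 1) dz <- diff(stack$z)[1]
  } else {
    I <- stack
    stopif(is.null(dx), "dx must be supplied for a plain array")
    if (is.null(dy)) dy <- dx
  }
  if (length(dim(I)) == 2) I <- array(I, dim = c(dim(I), 1))
  peak <- max(I)
  stopif(peak <= 0, "stack has no intensity above zero")
  floor_level <- floor_frac * peak
  cols <- which(apply(I, c(2, 3), max) >= floor_level, arr.ind = TRUE)
  stopif(nrow(cols) == 0, "no sample above the intensity floor")
  th <- vapply(seq_len(nrow(cols)), function(i) {
    profile_fwhm(I[, cols[i, 1], cols[i, 2]], dx)
  }, numeric(1))
  prof <- data.frame(iy = cols[, 1], iz = cols[, 2], thickness = th)
  th_ok <- th[is.finite(th)]
  stopif(length(th_ok) == 0, "no measurable thickness profile")
  env_y <- apply(I, 2, max)
  width <- profile_fwhm(env_y, dy)
  height <- NA_real_
  if (dim(I)[3] > 2 && !is.null(dz)) {
    height <- profile_fwhm(apply(I, 3, max), dz)
  }
  structure(list(thickness_fwhm = stats::median(th_ok),
                 thickness_sd = stats::sd(th_ok),
                 width = width, height = height,
                 uniformity_profile = prof),
            class = "adls_sheet_metrics")
}

#' @export
print.adls_sheet_metrics <- function(x, ...) {
  um <- function(v) if (is.na(v)) "NA" else sprintf("%.2f um", v * 1e6)
  cat("Light-sheet metrics\n",
      "  thickness (FWHM, median): ", um(x$thickness_fwhm),
      " (sd ", um(x$thickness_sd), ")\n",
      "  width:  ", um(x$width), "\n",
      "  height: ", um(x$height), "\n", sep = "")
  invisible(x)
}

#' Gaussian pupil illumination profile
#'
#' The Bessel-Gaussian beam is an axicon-phase beam under Gaussian
#' illumination; the soft envelope suppresses the hard-aperture ripple of
#' the focal segment, which is what makes the core width drift smoothly
#' (and slowly) along z. Waist is given as a fraction of the pupil
#' radius.
#'
#' @param spec An `adls_pupil` object.
#' @param waist_frac 1/e amplitude waist as a fraction of the pupil
#'   radius (default 0.5).
#' @return A `grid_size`-square amplitude matrix for the `amplitude`
#'   argument of [debye_focus()] / [focal_intensity()].
#' @export
gaussian_amplitude <- function(spec, waist_frac = 0.5) {
  stopif(waist_frac <= 0, "waist_frac must be positive")
  g <- pupil_grids(spec)
  exp(-(g$fr / (waist_frac * g$fmax))^2)
}

# central-lobe FWHM of a single on-axis axicon beam at one z plane
beam_fwhm_at <- function(spec, tan_alpha, z, roi = 4e-6,
                         amplitude = gaussian_amplitude(spec), ...) {
  mask <- axicon_phase(spec, tan_alpha)
  st <- focal_intensity(mask, z = z, roi_x = roi, roi_y = roi,
                        amplitude = amplitude, ...)
  profile_fwhm(st$I[, which.min(abs(st$y)), 1], st$dx)
}

#' Central-lobe FWHM of an axicon beam along the focal segment
#'
#' @param spec An `adls_pupil` object.
#' @param tan_alpha Axicon slope.
#' @param z Vector of axial positions (m).
#' @param roi Lateral half-width of the measurement crop (m).
#' @param ... Passed to [focal_intensity()] (e.g. `apodization`).
#' @param amplitude Pupil illumination (default Gaussian, see
#'   [gaussian_amplitude()]).
#' @return Data frame with columns `z` and `fwhm` (m).
#' @export
beam_fwhm_profile <- function(spec, tan_alpha, z, roi = 4e-6,
                              amplitude = gaussian_amplitude(spec), ...) {
  mask <- axicon_phase(spec, tan_alpha)
  st <- focal_intensity(mask, z = z, roi_x = roi, roi_y = roi,
                        amplitude = amplitude, ...)
  iy0 <- which.min(abs(st$y))
  fw <- vapply(seq_along(z), function(iz) {
    profile_fwhm(st$I[, iy0, iz], st$dx)
  }, numeric(1))
  data.frame(z = z, fwhm = fw)
}

#' Tune the axicon slope to a target sheet thickness
#'
#' The apex angle of the conical phase is a free design parameter; this
#' helper root-finds tan(alpha) so that the central-lobe FWHM of a single
#' on-axis beam, measured at the working plane `z_focus`, equals
#' `target_fwhm`. Larger slopes push the dominant pupil annulus outward at
#' fixed z and therefore sharpen the core, so the objective is monotone.
#'
#' @param spec An `adls_pupil` object.
#' @param target_fwhm Target central-lobe FWHM in metres (default 0.8 um).
#' @param z_focus Working-plane position in metres. The default 100 um
#'   places the sheet deep in the focal segment where the core width
#'   changes slowly with z.
#' @param bracket Search interval for tan(alpha).
#' @param tol Absolute tolerance on the FWHM match (m).
#' @param ... Passed to the underlying propagation.
#' @return List with `tan_alpha`, the achieved `fwhm` (m), and `z_focus`.
#' @export
calibrate_axicon <- function(spec, target_fwhm = 0.8e-6, z_focus = 100e-6,
                             bracket = NULL, tol = 2e-9, ...) {
  stopif(target_fwhm <= 0, "target_fwhm must be positive")
  if (is.null(bracket)) {
    # paraxial estimate: dominant pupil fraction u at (slope, z) is
    # u = R tan(alpha) / (NA^2 z); bracket around u in [0.25, 0.95]
    a0 <- spec$na^2 * z_focus / spec$pupil_radius
    bracket <- a0 * c(0.25, 0.95)
  }
  f <- function(a) beam_fwhm_at(spec, a, z_focus, ...) - target_fwhm
  root <- stats::uniroot(f, interval = bracket, tol = tol / 10,
                         extendInt = "downX")
  list(tan_alpha = root$root,
       fwhm = root$f.root + target_fwhm,
       z_focus = z_focus)
}

#' Analytic width of a Gaussian focus away from its waist
#'
#' Reference curve for the anti-diffraction comparison: a Gaussian beam
#' whose focal FWHM equals `fwhm0` broadens as
#' w(z) = w0 sqrt(1 + (z / z_R)^2) with z_R = pi w0^2 n / lambda.
#'
#' @param fwhm0 Focal-plane intensity FWHM in metres.
#' @param z Axial offsets from the waist (m).
#' @param wavelength Wavelength (m).
#' @param nt Refractive index.
#' @return Data frame with `z`, `fwhm` (m).
#' @export
gaussian_focus_fwhm <- function(fwhm0, z, wavelength = 473e-9, nt = 1) {
  w0 <- fwhm0 / sqrt(2 * log(2))
  zr <- pi * w0^2 * nt / wavelength
  data.frame(z = z, fwhm = fwhm0 * sqrt(1 + (z / zr)^2))
}

#' Anti-diffraction figure of merit of an axicon beam
#'
#' Measures the central-lobe FWHM of the Bessel-type beam over the z range
#' in which an ordinary Gaussian focus of equal waist broadens by the
#' stated factor, and reports the relative variation of the Bessel core
#' over that same range.
#'
#' @inheritParams beam_fwhm_profile
#' @param z_center Centre of the working range (m).
#' @param broadening_factor Gaussian width multiple defining the range
#'   (default 2: the range over which the Gaussian at least doubles).
#' @param n_planes Number of z samples across the range.
#' @return List with the measured `fwhm0` at `z_center`, the half-range
#'   `z_half` (m), the Bessel `variation` (max - min)/mean, the Gaussian
#'   `gaussian_broadening` over the same range, and the `profile` data
#'   frame.
#' @export
antidiffraction_check <- function(spec, tan_alpha, z_center = 100e-6,
                                  broadening_factor = 2, n_planes = 13,
                                  roi = 4e-6, ...) {
  fwhm0 <- beam_fwhm_at(spec, tan_alpha, z_center, roi = roi, ...)
  w0 <- fwhm0 / sqrt(2 * log(2))
  zr <- pi * w0^2 * spec$nt / spec$wavelength
  z_half <- zr * sqrt(broadening_factor^2 - 1) * 1.02  # just past doubling
  z <- seq(z_center - z_half, z_center + z_half, length.out = n_planes)
  prof <- beam_fwhm_profile(spec, tan_alpha, z, roi = roi, ...)
  fw <- prof$fwhm[is.finite(prof$fwhm)]
  gauss <- gaussian_focus_fwhm(fwhm0, z - z_center, spec$wavelength,
                               spec$nt)
  list(fwhm0 = fwhm0, z_half = z_half,
       variation = (max(fw) - min(fw)) / mean(fw),
       gaussian_broadening = max(gauss$fwhm) / fwhm0 - 1,
       profile = prof)
}
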