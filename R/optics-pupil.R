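#' Pupil specification for Fourier-Debye focusing
#'
#' Describes the back-pupil grid on which spatial-light-modulator phase
#' maps are defined and from which the focal field is computed by inverse
#' Fourier transform. The pupil disk (spatial-frequency radius NA/lambda)
#' occupies `1/pad_factor` of the grid half-width, so the focal-plane
#' sampling is `lambda / (2 NA pad_factor)` per pixel and the unaliased
#' focal field of view is `grid_size` such pixels.
#'
#' The physical pupil radius `pupil_radius` fixes the mapping between
#' metric SLM coordinates and spatial frequency: a pupil point at radius r
#' carries transverse frequency f_r = (r/R) NA / lambda, i.e. convergence
#' angle theta = asin(r NA / (R n_t)).
#'
#' @param wavelength Vacuum wavelength lambda in metres (default 473 nm).
#' @param na Numerical aperture of the objective (default 0.4, the 20x
#'   lens of the reference system).
#' @param nt Refractive index of the immersion medium (default 1, air).
#' @param pupil_radius Physical radius R of the back pupil in metres.
#' @param grid_size Samples per grid side (even, >= 64).
#' @param pad_factor Ratio of grid half-width to pupil radius (>= 1).
#' @return An object of class `adls_pupil`.
#' @export
pupil_spec <- function(wavelength = 473e-9, na = 0.4, nt = 1.0,
                       pupil_radius = 2.5e-3, grid_size = 512,
                       pad_factor = 4) {
  stopif(wavelength <= 0 || na <= 0 || nt <= 0 || pupil_radius <= 0,
         "wavelength, na, nt and pupil_radius must be positive")
  stopif(na / nt >= 1, "NA/nt must be < 1")
  stopif(grid_size < 64 || grid_size %% 2 != 0,
         "grid_size must be an even integer >= 64")
  stopif(pad_factor < 1, "pad_factor must be >= 1 so the pupil fits")
  spec <- structure(list(wavelength = wavelength, na = na, nt = nt,
                         pupil_radius = pupil_radius,
                         grid_size = as.integer(grid_size),
                         pad_factor = pad_factor),
                    class = "adls_pupil")
  if (focal_sampling(spec) > wavelength / (4 * na)) {
    warning("focal grid coarser than lambda/(4 NA); ",
            "diffraction-limited structure will be undersampled")
  }
  spec
}

#' Focal-plane sampling pitch of a pupil grid
#' @param spec An `adls_pupil` object.
#' @return Metres per focal-grid sample.
#' @export
focal_sampling <- function(spec) {
  spec$wavelength / (2 * spec$na * spec$pad_factor)
}

# centered grid coordinate in samples: -N/2 .. N/2-1
grid_coord <- function(n) seq_len(n) - 1 - n %/% 2

# spatial-frequency grids (cycles/m) and pupil geometry, memo-free
pupil_grids <- function(spec) {
  n <- spec$grid_size
  df <- 1 / (n * focal_sampling(spec))
  f <- grid_coord(n) * df
  fx <- matrix(f, n, n)          # varies along dim 1 (rows = x)
  fy <- matrix(f, n, n, byrow = TRUE)
  fr <- sqrt(fx^2 + fy^2)
  fmax <- spec$na / spec$wavelength
  list(fx = fx, fy = fy, fr = fr, fmax = fmax, df = df,
       mask = fr <= fmax,
       # physical pupil radial coordinate (m): r = R f_r / f_max
       r = fr * spec$pupil_radius / fmax)
}

new_phase_map <- function(phi, spec) {
  g <- pupil_grids(spec)
  structure(list(phase = phi, mask = g$mask, spec = spec),
            class = "adls_phase")
}

#' Beam specification: lateral offset and axicon slope
#'
#' Each multiplexed beam is described by its target lateral displacement at
#' focus (imposed by a blazed-grating phase ramp) and the slope tan(alpha)
#' of its conical axicon phase (alpha is the apex-angle parameter; 0 means
#' no axicon, i.e. an ordinary focused spot).
#'
#' @param dx,dy Lateral offsets at focus in metres.
#' @param axicon_slope tan(alpha), dimensionless, >= 0.
#' @return An object of class `adls_beam`.
#' @export
beam_spec <- function(dx = 0, dy = 0, axicon_slope = 0) {
  stopif(!is.finite(dx) || !is.finite(dy), "offsets must be finite")
  stopif(axicon_slope < 0, "axicon_slope must be >= 0")
  structure(list(dx = dx, dy = dy, axicon_slope = axicon_slope),
            class = "adls_beam")
}

#' Blazed-grating phase ramp displacing the focus laterally
#'
#' A linear phase ramp over the pupil shifts the focal intensity by
#' (dx, dy) via the Fourier shift theorem. The ramp is expressed in the
#' Fourier-conjugate coordinates of the focal plane,
#' Phi_1 = 2 pi (f_x dx + f_y dy), which on the physical pupil is
#' Phi_1 = (2 pi / lambda) (NA / R) (x' dx + y' dy) — a ramp of one cycle
#' per lambda R / (NA dx) of SLM aperture.
#'
#' @param spec An `adls_pupil` object.
#' @param dx,dy Requested focal displacements in metres. Must stay within
#'   half the unaliased field of view `grid_size * focal_sampling(spec)`.
#' @return An `adls_phase` object (phase in radians, unwrapped).
#' @export
blazed_grating_phase <- function(spec, dx = 0, dy = 0) {
  fov <- spec$grid_size * focal_sampling(spec)
  stopif(abs(dx) >= fov / 2 || abs(dy) >= fov / 2,
         sprintf(paste0("requested shift exceeds the unaliased field of ",
                        "view; |shift| must be < %.3g m"), fov / 2))
  g <- pupil_grids(spec)
  new_phase_map(2 * pi * (g$fx * dx + g$fy * dy), spec)
}

#' Conical (axicon) phase, Phi_2 = 2 pi r tan(alpha) / lambda
#'
#' A phase increasing linearly with the physical pupil radius
#' r = sqrt(x'^2 + y'^2). Under Fourier-Debye focusing it stretches the
#' focus into an extended Bessel-type focal segment: the near-axis field in
#' the segment is a J0 core whose width resists diffractive spreading.
#'
#' @param spec An `adls_pupil` object.
#' @param tan_alpha Slope tan(alpha) >= 0 of the conical phase.
#' @return An `adls_phase` object.
#' @export
axicon_phase <- function(spec, tan_alpha) {
  stopif(tan_alpha < 0, "tan_alpha must be >= 0")
  g <- pupil_grids(spec)
  new_phase_map(2 * pi * g$r * tan_alpha / spec$wavelength, spec)
}

#' Combine the phases of a single beam (grating + axicon)
#' @param beam An `adls_beam` object.
#' @param spec An `adls_pupil` object.
#' @return An `adls_phase` object with Phi = Phi_1 + Phi_2.
#' @export
beam_phase <- function(beam, spec) {
  p1 <- blazed_grating_phase(spec, beam$dx, beam$dy)
  p2 <- axicon_phase(spec, beam$axicon_slope)
  new_phase_map(p1$phase + p2$phase, spec)
}

#' Stripe-split multiplexing of several beams onto one pupil
#'
#' Partitions the pupil into parallel stripes (rows of the grid, i.e.
#' constant-x' bands) of `stripe_width` samples, assigned cyclically to the
#' beams in list order; each stripe carries the full grating + axicon phase
#' of its beam. Stripe sampling of each beam's aperture produces replica
#' ("ghost") orders displaced along the stripe-stacking axis by the grid
#' field of view divided by the stripe period; with single-sample stripes
#' these fall far outside the sheet region and are excluded from metrology
#' by the region-of-interest crop.
#'
#' @param beams List of `adls_beam` objects (at least one).
#' @param spec An `adls_pupil` object.
#' @param stripe_width Stripe width in grid samples (>= 1).
#' @return An `adls_phase` object.
#' @export
ssp_multiplex <- function(beams, spec, stripe_width = 1) {
  stopif(length(beams) < 1, "need at least one beam")
  stopif(stripe_width < 1, "stripe_width must be >= 1")
  if (inherits(beams, "adls_beam")) beams <- list(beams)
  n <- spec$grid_size
  nb <- length(beams)
  assignment <- (((seq_len(n) - 1) %/% stripe_width) %% nb) + 1
  phi <- matrix(0, n, n)
  for (b in seq_len(nb)) {
    rows <- which(assignment == b)
    if (!length(rows)) next
    phi[rows, ] <- beam_phase(beams[[b]], spec)$phase[rows, ]
  }
  new_phase_map(phi, spec)
}

#' Stripe-to-beam assignment used by [ssp_multiplex()]
#' @inheritParams ssp_multiplex
#' @param n_beams Number of multiplexed beams.
#' @return Integer vector of length `grid_size`: beam index per row.
#' @export
ssp_assignment <- function(spec, n_beams, stripe_width = 1) {
  (((seq_len(spec$grid_size) - 1) %/% stripe_width) %% n_beams) + 1
}

#' Phase map for a full Bessel-Gaussian array light sheet
#'
#' Convenience constructor: `n_beams` axicon beams offset along y at
#' `spacing` apart (centred on zero), stripe-split multiplexed, with an
#' optional common carrier offset along x that displaces the whole sheet
#' away from the unmodulated zeroth-order spot.
#'
#' @param spec An `adls_pupil` object.
#' @param tan_alpha Axicon slope shared by all beams (see
#'   [calibrate_axicon()] for tuning it to a target sheet thickness).
#' @param n_beams Number of beams (default 9).
#' @param spacing Beam-to-beam offset in metres. The default 1.5 um gives
#'   a 9-beam array spanning 12 um.
#' @param stripe_width Stripe width in samples.
#' @param carrier_dx Common x-offset of all beams in metres.
#' @return An `adls_phase` object.
#' @export
adls_sheet_phase <- function(spec, tan_alpha, n_beams = 9,
                             spacing = 1.5e-6, stripe_width = 1,
                             carrier_dx = 0) {
  stopif(n_beams < 1, "need at least one beam")
  offs <- (seq_len(n_beams) - (n_beams + 1) / 2) * spacing
  beams <- lapply(offs, function(dy)
    beam_spec(dx = carrier_dx, dy = dy, axicon_slope = tan_alpha))
  ssp_multiplex(beams, spec, stripe_width)
}

#' Wrap a phase array to [0, 2 pi)
#' @param phi Phase in radians.
#' @return Wrapped phase.
#' @export
wrap_phase <- function(phi) phi %% (2 * pi)
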