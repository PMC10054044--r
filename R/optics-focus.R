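# swap quadrants so the DC sample (index N/2 + 1 of a centered grid) moves
# to array position 1; its own inverse for even N
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)),
    c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))]
}

# unitary centered 2D transform, kernel exp(-2 pi i f x):
# sum |out|^2 == sum |in|^2, and a pupil phase +2 pi f dx moves the focal
# pattern to +dx
ifft2c <- function(m) {
  fftshift2(stats::fft(fftshift2(m))) / length(m)^0.5
}

# angular factors over the pupil; cos(theta) = k_z / k
pupil_angles <- function(spec, g = pupil_grids(spec)) {
  sin_t <- pmin(g$fr * spec$wavelength / spec$nt, 1)
  cos_t <- sqrt(pmax(1 - sin_t^2, 0))
  list(sin_t = sin_t, cos_t = cos_t, phi = atan2(g$fy, g$fx))
}

# Richards-Wolf polarization factors for x-polarized input
vector_factors <- function(ang) {
  cp <- cos(ang$phi); sp <- sin(ang$phi)
  list(Ex = ang$cos_t * cp^2 + sp^2,
       Ey = (ang$cos_t - 1) * cp * sp,
       Ez = -ang$sin_t * cp)
}

# complex pupil function common to all z planes (no defocus term)
base_pupil <- function(mask, spec, apodization, amplitude, zero_order) {
  g <- pupil_grids(spec)
  ang <- pupil_angles(spec, g)
  amp <- g$mask * amplitude
  # Debye integrand factor p(theta)/cos(theta); "none" is the plain
  # scalar-Fourier limit (no angular factors at all)
  fac <- switch(apodization,
                sqrt_cos = 1 / sqrt(pmax(ang$cos_t, 1e-12)),
                none = 1)
  u <- amp * exp(1i * mask$phase) * fac
  if (zero_order > 0) u <- u + zero_order * amp * fac
  list(u = u, ang = ang, g = g)
}

#' Focal field by the Fourier form of the Debye integral
#'
#' For each requested z plane the field is the two-dimensional inverse
#' Fourier transform of the pupil function
#' \deqn{A e^{i\Phi}\, p(\theta)\, E_t(\theta,\varphi)\, e^{i k_z z} /
#'   \cos\theta,}{A exp(i Phi) p(theta) Et exp(i kz z)/cos(theta),}
#' evaluated on the disk k_x^2 + k_y^2 <= k^2 with
#' k_z = sqrt(k^2 - k_x^2 - k_y^2), k = 2 pi n_t / lambda; evanescent
#' components are zeroed by construction (NA/nt < 1 keeps the pupil inside
#' the propagating disk). The transform is unitary, so the summed pupil
#' energy equals the summed focal-plane energy at every z.
#'
#' @param mask An `adls_phase` object.
#' @param z Numeric vector of axial plane positions in metres (>= 1).
#' @param polarization `"scalar"` treats the field as a single component
#'   (E_t = 1); `"vector_x"` applies the Richards-Wolf basis for linearly
#'   x-polarized input and returns Ex, Ey, Ez.
#' @param apodization `"sqrt_cos"` for the aplanatic factor sqrt(cos
#'   theta), `"none"` for plain Fourier optics (the scalar limit).
#' @param amplitude Pupil amplitude: a scalar or a `grid_size`-square
#'   matrix (e.g. a Gaussian illumination profile); the pupil disk mask is
#'   applied on top.
#' @param zero_order Relative amplitude of unmodulated (zeroth-order)
#'   light added with zero phase; it focuses at the grid origin.
#' @return An object of class `adls_field`: complex component arrays of
#'   dimension `(grid, grid, length(z))`, the z planes, and the lateral
#'   sampling in metres per pixel.
#' @export
debye_focus <- function(mask, z = 0,
                        polarization = c("scalar", "vector_x"),
                        apodization = c("sqrt_cos", "none"),
                        amplitude = 1, zero_order = 0) {
  stopif(length(z) < 1, "z must contain at least one plane")
  polarization <- match.arg(polarization)
  apodization <- match.arg(apodization)
  spec <- mask$spec
  bp <- base_pupil(mask, spec, apodization, amplitude, zero_order)
  kz <- 2 * pi * (spec$nt / spec$wavelength) * bp$ang$cos_t
  comp_factors <- if (polarization == "scalar") list(Ex = 1)
                  else vector_factors(bp$ang)
  n <- spec$grid_size
  out <- lapply(comp_factors, function(f) {
    arr <- array(0i, dim = c(n, n, length(z)))
    for (iz in seq_along(z)) {
      arr[, , iz] <- ifft2c(bp$u * f * exp(1i * kz * z[iz]))
    }
    arr
  })
  structure(list(components = out, z = z, dx = focal_sampling(spec),
                 spec = spec, polarization = polarization),
            class = "adls_field")
}

#' Intensity of a focal field, I = sum_c |E_c|^2
#' @param field An `adls_field` object.
#' @return Numeric array `(x, y, z)` of non-negative intensities.
#' @export
field_intensity <- function(field) {
  Reduce(`+`, lapply(field$components, function(e) Mod(e)^2))
}

#' Intensity stack computed plane by plane with optional cropping
#'
#' Memory-lean front end to [debye_focus()] for metrology scans: computes
#' each z plane, takes the intensity immediately, and keeps only the
#' requested region of interest. Cropping also excludes zeroth-order light
#' and stripe-multiplexing ghost orders from sheet measurements.
#'
#' @inheritParams debye_focus
#' @param roi_x,roi_y Half-widths (m) of a centered crop along x and y, or
#'   `NULL` to keep the full axis. The crop may be recentred with
#'   `center_x`/`center_y` (m).
#' @param center_x,center_y Crop centre coordinates in metres.
#' @return A list of class `adls_stack`: intensity array `I` with
#'   dimensions `(x, y, z)`, axis coordinate vectors `x`, `y` (m), plane
#'   positions `z` (m), and sampling `dx`.
#' @export
focal_intensity <- function(mask, z = 0,
                            polarization = c("scalar", "vector_x"),
                            apodization = c("sqrt_cos", "none"),
                            amplitude = 1, zero_order = 0,
                            roi_x = NULL, roi_y = NULL,
                            center_x = 0, center_y = 0) {
  stopif(length(z) < 1, "z must contain at least one plane")
  polarization <- match.arg(polarization)
  apodization <- match.arg(apodization)
  spec <- mask$spec
  bp <- base_pupil(mask, spec, apodization, amplitude, zero_order)
  kz <- 2 * pi * (spec$nt / spec$wavelength) * bp$ang$cos_t
  comp_factors <- if (polarization == "scalar") list(1)
                  else vector_factors(bp$ang)
  dx <- focal_sampling(spec)
  coords <- grid_coord(spec$grid_size) * dx
  ix <- crop_index(coords, roi_x, center_x)
  iy <- crop_index(coords, roi_y, center_y)
  I <- array(0, dim = c(length(ix), length(iy), length(z)))
  for (iz in seq_along(z)) {
    defocus <- exp(1i * kz * z[iz])
    plane <- 0
    for (f in comp_factors) {
      e <- ifft2c(bp$u * f * defocus)
      plane <- plane + Mod(e[ix, iy])^2
    }
    I[, , iz] <- plane
  }
  structure(list(I = I, x = coords[ix], y = coords[iy], z = z, dx = dx),
            class = "adls_stack")
}

crop_index <- function(coords, half_width, center) {
  if (is.null(half_width)) return(seq_along(coords))
  idx <- which(abs(coords - center) <= half_width)
  stopif(length(idx) < 3, "region of interest too small for the grid")
  idx
}
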