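test_that("profile FWHM recovers the closed form of a Gaussian slab", {
  # sigma = 0.34 um gives FWHM = 2.355 sigma = 0.80 um
  dx <- 0.05e-6
  x <- seq(-5e-6, 5e-6, by = dx)
  sigma <- 0.34e-6
  I <- array(rep(exp(-x^2 / (2 * sigma^2)), 4), dim = c(length(x), 2, 2))
  m <- measure_sheet(I, dx = dx)
  expect_equal(m$thickness_fwhm, 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 1e-3)
  expect_lt(m$thickness_sd, 1e-12)
})

test_that("a uniform cube measures its own side length", {
  dx <- 0.1e-6
  n <- 81
  side <- 21  # samples
  I <- array(0, dim = c(n, n, 3))
  ctr <- (n + 1) / 2
  idx <- (ctr - (side - 1) / 2):(ctr + (side - 1) / 2)
  I[idx, idx, ] <- 1
  m <- measure_sheet(I, dx = dx)
  expect_lt(abs(m$thickness_fwhm - side * dx), dx)
  expect_lt(abs(m$width - side * dx), dx)
})

test_that("a synthetic multi-lobe sheet reports the programmed lobe span", {
  dx <- 0.1e-6
  x <- seq(-10e-6, 10e-6, by = dx)
  centers <- (-4:4) * 1.5e-6   # outer-lobe span 12 um
  prof <- rowSums(sapply(centers, function(c0)
    exp(-(x - c0)^2 / (2 * (0.4e-6)^2))))
  # sheet: thin Gaussian along x, lobed profile along y
  thin <- exp(-x^2 / (2 * (0.34e-6)^2))
  I <- array(outer(thin, prof), dim = c(length(x), length(x), 1))
  m <- measure_sheet(I, dx = dx, floor_frac = 0.2)
  span <- diff(range(centers))
  # FWHM of the lobed envelope: outer-lobe span plus one lobe width
  expect_equal(m$width, span + 2 * sqrt(2 * log(2)) * 0.4e-6 * 0.8,
               tolerance = 0.1)
  expect_lt(m$thickness_fwhm, m$width)
})

test_that("an empty stack and an all-dark floor raise errors", {
  expect_error(measure_sheet(array(0, dim = c(8, 8, 1)), dx = 1e-7),
               "no intensity")
})

test_that("the Bessel core sharpens monotonically with axicon slope", {
  spec <- pupil_spec()
  z <- 100e-6
  a <- spec$na^2 * z / spec$pupil_radius
  fw <- vapply(a * c(0.4, 0.55, 0.7), function(ta)
    adlscyto:::beam_fwhm_at(spec, ta, z), numeric(1))
  expect_true(all(diff(fw) < 0))
})

test_that("the analytic Gaussian reference doubles at sqrt(3) Rayleigh ranges", {
  fwhm0 <- 0.8e-6
  w0 <- fwhm0 / sqrt(2 * log(2))
  zr <- pi * w0^2 / 473e-9
  g <- gaussian_focus_fwhm(fwhm0, c(0, zr, sqrt(3) * zr))
  expect_equal(g$fwhm, fwhm0 * c(1, sqrt(2), 2))
})
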