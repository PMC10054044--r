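test_that("an empty pupil focuses to a null field", {
  spec <- pupil_spec(grid_size = 64, pad_factor = 2)
  f <- debye_focus(blazed_grating_phase(spec, 0, 0), c(0, 5e-6),
                   amplitude = 0)
  expect_true(all(Mod(f$components$Ex) == 0))
  expect_true(all(field_intensity(f) == 0))
  expect_error(debye_focus(blazed_grating_phase(spec, 0, 0), numeric(0)),
               "at least one plane")
})

test_that("the scalar focus of a flat pupil is the Airy spot, FWHM ~ 0.51 lambda/NA", {
  spec <- pupil_spec(grid_size = 256, pad_factor = 4)
  st <- focal_intensity(blazed_grating_phase(spec, 0, 0), 0,
                        apodization = "none")
  prof <- st$I[, which.min(abs(st$y)), 1]
  fw <- profile_fwhm(prof, st$dx)
  expect_equal(fw, 0.514 * spec$wavelength / spec$na, tolerance = 0.05)
})

test_that("the FFT propagation matches a directly coded Fourier sum", {
  spec <- pupil_spec(grid_size = 64, pad_factor = 2)
  mask <- beam_phase(beam_spec(dx = 1e-6, axicon_slope = 1e-3), spec)
  g <- adlscyto:::pupil_grids(spec)
  for (z in c(0, 3e-6)) {
    ang <- adlscyto:::pupil_angles(spec, g)
    kz <- 2 * pi * (spec$nt / spec$wavelength) * ang$cos_t
    pupil <- g$mask * exp(1i * mask$phase) * exp(1i * kz * z)
    oracle <- direct_focal_field(pupil)
    f <- debye_focus(mask, z, apodization = "none")
    expect_equal(f$components$Ex[, , 1], oracle, tolerance = 1e-10)
  }
})

test_that("pupil and focal energies agree and are z-independent", {
  spec <- pupil_spec(grid_size = 128, pad_factor = 2)
  mask <- beam_phase(beam_spec(dy = 2e-6, axicon_slope = 2e-3), spec)
  g <- adlscyto:::pupil_grids(spec)
  # plain scalar mode: Parseval against the pupil mask energy
  f <- debye_focus(mask, c(-5e-6, 0, 7e-6), apodization = "none")
  en <- apply(Mod(f$components$Ex)^2, 3, sum)
  expect_equal(en, rep(sum(g$mask), 3), tolerance = 1e-9)
  # aplanatic mode: energy still z-independent (phase-only defocus)
  fa <- debye_focus(mask, c(-5e-6, 0, 7e-6), apodization = "sqrt_cos")
  ena <- apply(Mod(fa$components$Ex)^2, 3, sum)
  expect_lt(max(abs(ena / ena[2] - 1)), 0.01)
})

test_that("intensity is the component-wise modulus square, non-negative", {
  spec <- pupil_spec(grid_size = 64, pad_factor = 2)
  f <- debye_focus(blazed_grating_phase(spec, 0, 0), 0)
  I <- field_intensity(f)
  expect_equal(I, Mod(f$components$Ex)^2)
  expect_true(all(I >= 0))
  fv <- debye_focus(blazed_grating_phase(spec, 0, 0), 0,
                    polarization = "vector_x")
  Iv <- field_intensity(fv)
  expect_equal(Iv, Mod(fv$components$Ex)^2 + Mod(fv$components$Ey)^2 +
                 Mod(fv$components$Ez)^2)
  # the axial component of a focused x-polarized beam is not negligible
  expect_gt(sum(Mod(fv$components$Ez)^2), 0)
})

test_that("an on-axis axicon focus is rotationally symmetric", {
  spec <- pupil_spec(grid_size = 128, pad_factor = 2)
  st <- focal_intensity(axicon_phase(spec, 2e-3), 20e-6,
                        amplitude = gaussian_amplitude(spec))
  I <- st$I[, , 1]
  # 90-degree rotation invariance (transpose for a symmetric grid)
  expect_equal(I, t(I), tolerance = 1e-8)
  # inversion symmetry away from the unpaired -N/2 edge row/column
  Ic <- I[-1, -1]
  expect_equal(Ic, Ic[rev(seq_len(nrow(Ic))), ][, rev(seq_len(ncol(Ic)))],
               tolerance = 1e-8)
})

test_that("cropping keeps coordinates and intensities consistent", {
  spec <- pupil_spec(grid_size = 128, pad_factor = 2)
  mask <- blazed_grating_phase(spec, 0, 0)
  full <- focal_intensity(mask, 0)
  crop <- focal_intensity(mask, 0, roi_x = 2e-6, roi_y = 3e-6)
  ix <- which(abs(full$x) <= 2e-6)
  iy <- which(abs(full$y) <= 3e-6)
  expect_equal(crop$I[, , 1], full$I[ix, iy, 1])
  expect_equal(crop$x, full$x[ix])
})
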