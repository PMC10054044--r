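spec_s <- pupil_spec(grid_size = 256, pad_factor = 4)

test_that("zero-offset grating and zero-slope axicon give zero phase", {
  expect_true(all(blazed_grating_phase(spec_s, 0, 0)$phase == 0))
  expect_true(all(axicon_phase(spec_s, 0)$phase == 0))
  expect_error(axicon_phase(spec_s, -1), "tan_alpha")
})

test_that("axicon phase is 2 pi r tan(alpha)/lambda on the pupil", {
  ta <- 2e-3
  ph <- axicon_phase(spec_s, ta)
  g <- adlscyto:::pupil_grids(spec_s)
  expect_equal(ph$phase, 2 * pi * g$r * ta / spec_s$wavelength)
  # one full cycle is accumulated at pupil radius lambda/tan(alpha)
  r1 <- spec_s$wavelength / ta
  i <- which.min(abs(g$r[, 129] - r1))
  expect_equal(ph$phase[i, 129] / (2 * pi), g$r[i, 129] / r1,
               tolerance = 1e-12)
})

test_that("a grating ramp shifts the focal centroid by the programmed offset", {
  m <- blazed_grating_phase(spec_s, 2e-6, 0)
  st <- focal_intensity(m, 0, apodization = "none")
  cx <- sum(st$x * rowSums(st$I[, , 1])) / sum(st$I)
  expect_lt(abs(cx - 2e-6), st$dx / 2)
  # and along y independently
  m2 <- blazed_grating_phase(spec_s, 0, -3e-6)
  st2 <- focal_intensity(m2, 0, apodization = "none")
  cy <- sum(st2$y * colSums(st2$I[, , 1])) / sum(st2$I)
  expect_lt(abs(cy + 3e-6), st2$dx / 2)
})

test_that("a one-sample shift equals a circular shift of the pattern", {
  dx <- focal_sampling(spec_s)
  f0 <- debye_focus(blazed_grating_phase(spec_s, 0, 0), 0,
                    apodization = "none")
  f1 <- debye_focus(blazed_grating_phase(spec_s, dx, 0), 0,
                    apodization = "none")
  i0 <- Mod(f0$components$Ex[, , 1])^2
  i1 <- Mod(f1$components$Ex[, , 1])^2
  shifted <- i0[c(nrow(i0), seq_len(nrow(i0) - 1)), ]
  expect_equal(i1, shifted, tolerance = 1e-9)
})

test_that("shifts beyond the unaliased field of view are refused", {
  fov <- spec_s$grid_size * focal_sampling(spec_s)
  expect_error(blazed_grating_phase(spec_s, fov, 0), "field of view")
  expect_silent(blazed_grating_phase(spec_s, fov / 2 - 1e-9, 0))
})

test_that("stripe multiplexing degenerates to the plain sum for one beam", {
  b <- beam_spec(dx = 1e-6, dy = -2e-6, axicon_slope = 1e-3)
  mux <- ssp_multiplex(list(b), spec_s, stripe_width = 3)
  expect_equal(mux$phase, beam_phase(b, spec_s)$phase)
  expect_error(ssp_multiplex(list(), spec_s), "at least one beam")
})

test_that("stripe assignment cycles through beams row by row", {
  a1 <- ssp_assignment(spec_s, n_beams = 2, stripe_width = 1)
  expect_equal(a1[1:6], c(1, 2, 1, 2, 1, 2))
  a2 <- ssp_assignment(spec_s, n_beams = 3, stripe_width = 2)
  expect_equal(a2[1:8], c(1, 1, 2, 2, 3, 3, 1, 1))
  # full pupil covered
  expect_equal(length(a1), spec_s$grid_size)
})

test_that("a 9-beam multiplexed grating makes 9 spots at the programmed offsets", {
  s <- 2e-6
  offs <- (-4:4) * s
  beams <- lapply(offs, function(dy) beam_spec(dy = dy))
  mask <- ssp_multiplex(beams, spec_s, stripe_width = 1)
  # ghost replicas sit along x at multiples of FOV/9; crop them away
  ghost <- spec_s$grid_size * focal_sampling(spec_s) / 9
  st <- focal_intensity(mask, 0, apodization = "none",
                        roi_x = 0.45 * ghost)
  prof <- apply(st$I[, , 1], 2, max)
  pk <- which(prof > 0.3 * max(prof) &
                prof >= c(-Inf, prof[-length(prof)]) &
                prof > c(prof[-1], -Inf))
  expect_equal(length(pk), 9)
  # centroid of each spot within one sample of its programmed offset
  for (k in seq_along(pk)) {
    win <- max(1, pk[k] - 3):min(length(prof), pk[k] + 3)
    cy <- sum(st$y[win] * prof[win]) / sum(prof[win])
    expect_lt(abs(cy - offs[k]), st$dx)
  }
})

test_that("phase wrapping lands in [0, 2 pi) and preserves the phase modulo 2 pi", {
  phi <- seq(-10, 10, by = 0.37)
  w <- wrap_phase(phi)
  expect_true(all(w >= 0 & w < 2 * pi))
  expect_equal(exp(1i * w), exp(1i * phi), tolerance = 1e-12)
})
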