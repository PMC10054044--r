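up_bench <- mean_channel_velocity(bench_flow(), bench_geom())

test_that("pulse half-maximum width is exactly (dp + ds)/up across sizes", {
  fs <- 5e5
  for (dp in c(0.2, 0.4, 1, 5, 10) * 1e-6) {
    p <- pulse_shape(dp, up_bench, 0.8e-6, brightness = 1000,
                     sampling_rate = fs)
    fw <- profile_fwhm(as.numeric(p), 1 / fs)
    expect_lt(abs(fw - (dp + 0.8e-6) / up_bench), 1 / fs / 1e3)
  }
})

test_that("the point-particle limit of the erf shape is a Gaussian of FWHM ds/up", {
  fs <- 5e6   # dense sampling for the shape comparison
  ds <- 0.8e-6
  p <- pulse_shape(1e-9, up_bench, ds, sampling_rate = fs,
                   shape = "gaussian")
  fw <- profile_fwhm(as.numeric(p), 1 / fs)
  expect_equal(fw, ds / up_bench, tolerance = 1e-3)
})

test_that("pulse area scales linearly with brightness", {
  p1 <- pulse_shape(1e-6, up_bench, 0.8e-6, brightness = 1)
  p3 <- pulse_shape(1e-6, up_bench, 0.8e-6, brightness = 3)
  expect_equal(sum(p3), 3 * sum(p1))
})

test_that("expected arrival counts follow C Qj T", {
  flow <- bench_flow()
  expect_equal(expected_event_count(1e7, flow, 300), 833.33,
               tolerance = 1e-4)
  expect_equal(round(expected_event_count(1e7, flow, 300)), 833)
  expect_equal(expected_event_count(8e4, flow, 300), 6.667,
               tolerance = 1e-3)
  expect_equal(round(expected_event_count(8e4, flow, 300)), 7)
})

test_that("population draws are reproducible, time-ordered and preset-bounded", {
  flow <- bench_flow()
  a <- sample_population(1e7, flow, 60, "micropillar", seed = 5)
  b <- sample_population(1e7, flow, 60, "micropillar", seed = 5)
  expect_identical(a, b)
  expect_true(all(diff(a$time) > 0))
  expect_true(all(a$dp >= 0.4e-6 & a$dp <= 1.0e-6))
  s <- sample_population(1e6, flow, 60, "microsphere", seed = 5)
  expect_true(all(s$dp > 1e-6))
  expect_equal(nrow(sample_population(1e7, flow, 0)), 0)
})

test_that("arrival counts are Poisson-dispersed across seeds", {
  flow <- bench_flow()
  counts <- vapply(1:500, function(s)
    nrow(sample_population(2.4e5, flow, 300, seed = s)), numeric(1))
  # expectation ~20; index of dispersion near 1
  expect_equal(mean(counts), expected_event_count(2.4e5, flow, 300),
               tolerance = 0.1)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("traces are deterministic under a seed and bounded by the ADC", {
  cfg <- trace_config(duration = 0.05, noise_sd = 300, spike_rate = 100,
                      drift_amplitude = 200, drift_period = 0.01)
  ev <- make_particles(0.025, 1e-6, up_bench)
  t1 <- generate_trace(ev, cfg, seed = 9)
  t2 <- generate_trace(ev, cfg, seed = 9)
  expect_identical(t1$samples, t2$samples)
  expect_true(all(t1$samples >= 0 & t1$samples <= 65535))
  # no events, no noise: flat baseline
  t0 <- generate_trace(make_particles(numeric(0), numeric(0),
                                      numeric(0)),
                       trace_config(duration = 0.01, noise_sd = 0))
  expect_true(all(t0$samples == 1000))
})

test_that("a bright sphere saturates the ADC and widens, monotonically in gain", {
  coef <- particle_preset("microsphere")$brightness_coef
  ev <- make_particles(0.05, 5e-6, up_bench,
                       brightness = coef * 25, label = "microsphere")
  widths <- vapply(c(1e5, 1e6, 1e7), function(g) {
    cfg <- trace_config(duration = 0.1, gain = g, noise_sd = 0)
    tr <- generate_trace(ev, cfg)
    profile_fwhm(as.numeric(tr$samples) - 1000, 1 / cfg$sampling_rate)
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))       # saturation never narrows
  expect_gt(widths[3], widths[1] * 1.05)    # clipped top visibly wider
  cfg_m <- trace_config(duration = 0.1, gain = "medium", noise_sd = 0)
  tr_m <- generate_trace(ev, cfg_m)
  expect_equal(max(tr_m$samples), 65535)    # medium gain already clips
})

test_that("mixtures hold the programmed pillar/sphere ratio", {
  flow <- fast_flow()
  cfg <- trace_config(duration = 0.2)
  n_pi <- 0; n_s <- 0
  for (s in 1:40) {
    tr <- simulate_mixture(3, 2e7, flow, 0.2, cfg, seed = s)
    n_pi <- n_pi + sum(tr$truth$label == "micropillar")
    n_s <- n_s + sum(tr$truth$label == "microsphere")
  }
  # pooled binomial check of the 3:1 ratio
  p_hat <- n_pi / (n_pi + n_s)
  se <- sqrt(0.75 * 0.25 / (n_pi + n_s))
  expect_lt(abs(p_hat - 0.75), 4 * se)
  expect_error(simulate_mixture(0, 1e7, flow, 1, cfg), "beta")
})

test_that("events outside the trace or oversized pulses are refused", {
  cfg <- trace_config(duration = 0.01)
  expect_error(generate_trace(make_particles(0.02, 1e-6, up_bench), cfg),
               "within the trace")
  # a pulse lasting longer than the whole trace
  expect_error(generate_trace(make_particles(0.005, 1e-6, 1e-4),
                              trace_config(duration = 0.01)),
               "longer than the trace")
})
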