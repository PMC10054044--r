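test_that("hydraulic diameter follows 2hw/(h+w)", {
  expect_equal(hydraulic_diameter(channel_geometry(10e-6, 10e-6, 5e-6)),
               10e-6)
  expect_equal(hydraulic_diameter(bench_geom()), 2 * 10 * 50 / 60 * 1e-6)
  # homogeneity: scaling both dimensions scales Dh
  g1 <- channel_geometry(8e-6, 40e-6, 8e-6)
  g2 <- channel_geometry(3 * 8e-6, 3 * 40e-6, 8e-6)
  expect_equal(hydraulic_diameter(g2), 3 * hydraulic_diameter(g1))
})

test_that("channel Reynolds number matches the bench value and is linear", {
  geom <- bench_geom()
  um <- mean_channel_velocity(bench_flow(), geom)
  re <- reynolds_number(um, hydraulic_diameter(geom))
  expect_equal(re, 2.78e-2, tolerance = 0.01e-2 / 2.78e-2)
  expect_equal(reynolds_number(0, hydraulic_diameter(geom)), 0)
  # exact linearity in each argument
  set.seed(4)
  for (i in 1:20) {
    v <- runif(1, 1e-4, 1e-1); d <- runif(1, 1e-6, 1e-4)
    p <- fluid_props(runif(1, 500, 2000), runif(1, 5e-4, 5e-3))
    expect_equal(reynolds_number(2 * v, d, p),
                 2 * reynolds_number(v, d, p))
    expect_equal(reynolds_number(v, 2 * d, p),
                 2 * reynolds_number(v, d, p))
  }
})

test_that("jet velocities follow Q_all/(h w) with and without correction", {
  geom <- bench_geom()
  f1 <- flow_config(1, 1, k = 1)
  expect_equal(mean_channel_velocity(f1, geom), 1.6667e-3,
               tolerance = 1e-4)
  f083 <- bench_flow()
  expect_equal(particle_speed(f083, geom), 0.83 * 3e-9 / 3600 / 5e-10)
  expect_equal(jet_velocity(f083, geom, "corrected"), 1.3833e-3,
               tolerance = 1e-4)
  expect_equal(jet_velocity(f083, geom, "mean_channel"),
               mean_channel_velocity(f083, geom))
  expect_equal(jet_velocity(f083, geom, 2.5e-3), 2.5e-3)
  expect_error(flow_config(1, 1, k = 0), "k must")
})

test_that("flow-rate unit conversions round-trip to machine precision", {
  x <- c(0.3, 1, 3, 20, 1000)
  expect_equal(m3_s_to_ul_per_h(ul_per_h_to_m3_s(x)), x)
  expect_equal(per_m3_to_per_ml(per_ml_to_per_m3(x)), x)
})

test_that("transit-time sizing reproduces the worked diameters", {
  up <- mean_channel_velocity(bench_flow(), bench_geom())
  expect_equal(as.numeric(particle_diameter(up, 3.46e-3)), 4.98e-6,
               tolerance = 0.02e-6 / 4.98e-6)
  expect_equal(as.numeric(particle_diameter(up, 1.13e-3)), 1.09e-6,
               tolerance = 0.02e-6 / 1.09e-6)
  # point-particle limit
  expect_equal(as.numeric(particle_diameter(up, 0.8e-6 / up)), 0)
})

test_that("sub-resolution widths clamp to zero with a flag, not an error", {
  dp <- particle_diameter(1e-3, c(2e-4, 1e-3, 2e-3), ds = 0.8e-6)
  expect_equal(as.numeric(dp)[1], 0)
  expect_equal(attr(dp, "subresolution"), c(TRUE, FALSE, FALSE))
  expect_true(all(as.numeric(dp) >= 0))
})
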