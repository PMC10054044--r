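test_that("the 2D probability density is normalized and non-negative", {
  set.seed(8)
  ev <- make_event_table(runif(400, 0.3e-6, 6e-6), runif(400, 1e3, 6e4))
  d <- density2d(ev)
  expect_equal(sum(d$pd), 1, tolerance = 1e-9)
  expect_true(all(d$pd >= 0))
  # degenerate input: everything in one bin
  one <- density2d(make_event_table(rep(1e-6, 5), rep(1e4, 5)))
  expect_equal(max(one$pd), 1)
  expect_error(density2d(make_event_table(numeric(0), numeric(0))),
               "at least one")
})

test_that("density marginals equal independently computed 1D histograms", {
  set.seed(12)
  dp <- c(rnorm(300, 0.7e-6, 0.1e-6), rnorm(200, 5e-6, 0.3e-6))
  ifp <- c(rnorm(300, 1e4, 1e3), rnorm(200, 5e4, 2e3))
  ev <- make_event_table(dp, ifp)
  d <- density2d(ev, bins = 32, log_ifp = FALSE)
  # oracle: direct binning with the same edges
  h_dp <- tabulate(findInterval(dp, d$dp_edges, rightmost.closed = TRUE),
                   nbins = 32)
  h_ifp <- tabulate(findInterval(ifp, d$ifp_edges,
                                 rightmost.closed = TRUE), nbins = 32)
  expect_equal(rowSums(d$pd) * 500, h_dp)
  expect_equal(colSums(d$pd) * 500, h_ifp)
})

test_that("a bimodal mixture shows two well-separated density modes", {
  set.seed(3)
  dp <- c(rnorm(400, 0.7e-6, 0.1e-6), rnorm(400, 5.3e-6, 0.4e-6))
  ifp <- c(rnorm(400, 1e4, 2e3), rep(65535, 400))
  d <- density2d(make_event_table(dp, ifp), bins = 64)
  marg <- rowSums(d$pd)
  mids <- (d$dp_edges[-1] + d$dp_edges[-65]) / 2
  pk <- which(marg > 0.02 & marg >= c(-Inf, marg[-length(marg)]) &
                marg > c(marg[-1], -Inf))
  modes <- mids[pk[order(marg[pk], decreasing = TRUE)][1:2]]
  expect_gt(abs(diff(modes)), 3e-6)
})

test_that("splitting at the boundary estimates beta within binomial error", {
  set.seed(31)
  n <- 500
  lab <- runif(n) < 0.5   # true beta = 1
  dp <- ifelse(lab, rnorm(n, 0.7e-6, 0.15e-6), rnorm(n, 5e-6, 0.4e-6))
  sp <- split_and_ratio(make_event_table(dp, rep(1e4, n)))
  p <- sp$n_small / n
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
  expect_equal(sp$beta, sp$n_small / sp$n_large)
  expect_gt(abs(sp$modal_dp_large - sp$modal_dp_small), 3e-6)
})

test_that("one-sided splits report beta as undefined", {
  sp <- split_and_ratio(make_event_table(rep(0.5e-6, 10), rep(1e4, 10)))
  expect_true(is.na(sp$beta))
  expect_equal(sp$n_large, 0)
})

test_that("detection efficiency reproduces the bench percentages", {
  expect_equal(round(detection_efficiency(736, 833.33), 1), 88.3)
  expect_equal(round(detection_efficiency(7.3, 7), 1), 104.3)
  expect_equal(round(detection_efficiency(42, 42), 1), 100.0)
  expect_error(detection_efficiency(1, 0), "positive")
})

test_that("the dilution arithmetic gives the beta = 15 preset exactly", {
  # both stocks dilute to a common 8e5/mL working concentration (12500x
  # pillars, 100x spheres); rediluted 500x and 60x and mixed 1:1
  expect_equal(mixture_ratio_from_dilution(8e5 * 12500, 500,
                                           8e5 * 100, 60), 15)
})

test_that("size fractions cover all events and sum to one", {
  set.seed(77)
  dp <- runif(1e5, 0.2e-6, 1.0e-6)
  fr <- size_fractions(make_event_table(dp, rep(1e4, length(dp))))
  expect_equal(sum(fr$fraction), 1)
  # uniform draw: each interior 0.2 um bin holds ~25%
  interior <- fr$fraction[2:5]
  expect_true(all(abs(interior - 0.25) < 0.01))
  # under/overflow land in the edge bins
  fr2 <- size_fractions(make_event_table(c(0.1e-6, 1.5e-6), c(1, 1)))
  expect_equal(fr2$fraction[c(1, 6)], c(0.5, 0.5))
  one <- size_fractions(make_event_table(rep(0.5e-6, 7), rep(1, 7)))
  expect_equal(one$fraction[3], 1)
})
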