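# shared fixtures: all built in code at test time

# hand-built particle event list (bypasses the Poisson sampler)
make_particles <- function(time, dp, velocity, brightness = NULL,
                           label = "test") {
  coef <- particle_preset("micropillar")$brightness_coef
  if (is.null(brightness)) brightness <- coef * (dp * 1e6)^2
  ev <- data.frame(time = time, dp = dp,
                   brightness = rep_len(brightness, length(time)),
                   velocity = velocity,
                   label = rep_len(label, length(time)),
                   stringsAsFactors = FALSE)
  class(ev) <- c("adls_particles", "data.frame")
  ev
}

# hand-built event table for the population-analysis layer
make_event_table <- function(dp, ifp) {
  ev <- data.frame(time = as.numeric(seq_along(dp)),
                   fwhm = rep_len(1e-3, length(dp)), ifp = ifp, dp = dp,
                   saturated = rep_len(FALSE, length(dp)),
                   subresolution = rep_len(FALSE, length(dp)))
  class(ev) <- c("adls_events", "data.frame")
  ev
}

# reference flows/geometry of the bench configuration
bench_flow <- function() flow_config(1, 1)
fast_flow <- function() flow_config(20, 20)
bench_geom <- function() channel_geometry()

# width gate matched to the fast-flow pulse range (tau ~ 0.02-2 ms)
fast_gate <- function() filter_config(width_gate = c(2e-5, 2e-3))

# brute-force centered DFT with kernel exp(-2 pi i (x f)) via explicit
# matrix products -- the independent oracle for the FFT focusing path
direct_focal_field <- function(pupil) {
  n <- nrow(pupil)
  idx <- seq_len(n) - 1 - n %/% 2
  w <- exp(-2i * pi * outer(idx, idx) / n)
  (w %*% pupil %*% w) / n
}
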