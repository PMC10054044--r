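#' Two-dimensional probability density over (dp, Ifp)
#'
#' Normalized 2D histogram of events in the diameter / peak-intensity
#' plane, the representation in which mixed populations separate into
#' clusters. The intensity axis is log10-scaled by default because PMT
#' gains span 1e5-1e7.
#'
#' @param events An `adls_events` table (>= 1 row).
#' @param bins Number of bins per axis (scalar or length 2: dp, Ifp).
#' @param log_ifp Log10-scale the intensity axis.
#' @param dp_range,ifp_range Optional axis limits (m, counts).
#' @return An object of class `adls_density`: matrix `pd` (rows: dp bins,
#'   columns: Ifp bins, summing to 1), bin edge vectors `dp_edges` (m) and
#'   `ifp_edges` (counts or log10 counts), and the scaling flag.
#' @export
density2d <- function(events, bins = 64, log_ifp = TRUE,
                      dp_range = NULL, ifp_range = NULL) {
  stopif(nrow(events) < 1, "need at least one event")
  bins <- rep(bins, length.out = 2)
  dp <- events$dp
  ifp <- if (log_ifp) log10(pmax(events$ifp, 1)) else events$ifp
  dpr <- if (is.null(dp_range)) range(dp) else dp_range
  ifr <- if (is.null(ifp_range)) range(ifp) else ifp_range
  dpr <- widen_if_degenerate(dpr)
  ifr <- widen_if_degenerate(ifr)
  dp_edges <- seq(dpr[1], dpr[2], length.out = bins[1] + 1)
  ifp_edges <- seq(ifr[1], ifr[2], length.out = bins[2] + 1)
  ix <- cut_index(dp, dp_edges)
  iy <- cut_index(ifp, ifp_edges)
  keep <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0, bins[1], bins[2])
  for (k in which(keep)) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  }
  structure(list(pd = counts / sum(counts), dp_edges = dp_edges,
                 ifp_edges = ifp_edges, log_ifp = log_ifp,
                 n = sum(keep)),
            class = "adls_density")
}

widen_if_degenerate <- function(r) {
  if (diff(r) <= 0) r + c(-1, 1) * max(abs(r[1]) * 1e-6, 1e-12) else r
}

cut_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

#' Split events at a diameter boundary and report the population ratio
#'
#' For a bimodal small/large mixture the populations separate cleanly in
#' dp, so a fixed boundary (default 2 um, between submicron pillars and
#' 5 um spheres) partitions the events; beta is the small-to-large count
#' ratio. If either side is empty, beta is reported as undefined (`NA`)
#' rather than infinite.
#'
#' @param events An `adls_events` table.
#' @param boundary Diameter boundary in metres.
#' @return An object of class `adls_population_summary`: counts, modal dp
#'   and Ifp per side, and `beta`.
#' @export
split_and_ratio <- function(events, boundary = 2e-6) {
  small <- events[events$dp < boundary, , drop = FALSE]
  large <- events[events$dp >= boundary, , drop = FALSE]
  beta <- if (nrow(small) > 0 && nrow(large) > 0)
    nrow(small) / nrow(large) else NA_real_
  structure(list(
    boundary = boundary,
    n_small = nrow(small), n_large = nrow(large),
    modal_dp_small = mode_of(small$dp),
    modal_dp_large = mode_of(large$dp),
    modal_ifp_small = mode_of(small$ifp),
    modal_ifp_large = mode_of(large$ifp),
    beta = beta),
    class = "adls_population_summary")
}

# histogram mode with interpolation-free bin centre (deterministic)
mode_of <- function(x, bins = 64) {
  if (!length(x)) return(NA_real_)
  if (length(unique(x)) == 1) return(x[1])
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' @export
print.adls_population_summary <- function(x, ...) {
  cat(sprintf(paste0("Population split at %.2f um: %d small / %d large",
                     " events, beta = %s\n"),
              x$boundary * 1e6, x$n_small, x$n_large,
              if (is.na(x$beta)) "undefined" else sprintf("%.3f", x$beta)))
  invisible(x)
}

#' Detection efficiency delta = 100 x measured / theoretical
#'
#' @param measured Measured event count (may be a non-integer average
#'   over repeated runs).
#' @param theoretical Theoretically injected count (> 0).
#' @return Efficiency in percent, full precision; round to one decimal at
#'   the reporting layer.
#' @examples
#' detection_efficiency(736, 833.33)  # 88.3% after report rounding
#' detection_efficiency(7.3, 7)       # 104.3%
#' @export
detection_efficiency <- function(measured, theoretical) {
  stopif(any(theoretical <= 0), "theoretical count must be positive")
  stopif(any(measured < 0), "measured count must be >= 0")
  100 * measured / theoretical
}

#' Theoretical mixing ratio from stock concentrations and dilutions
#'
#' beta = (C_small / dilution_small) / (C_large / dilution_large); mixing
#' the two diluted solutions in equal volume halves both concentrations
#' and leaves the ratio unchanged.
#'
#' @param stock_small,stock_large Stock concentrations (any common unit).
#' @param dilution_small,dilution_large Dilution factors (> 0).
#' @return The number-density ratio beta.
#' @examples
#' # stocks back-computed from a common 8e5/mL working concentration at
#' # 12500x and 100x dilution, then rediluted 500x and 60x:
#' mixture_ratio_from_dilution(8e5 * 12500, 500, 8e5 * 100, 60)  # 15
#' @export
mixture_ratio_from_dilution <- function(stock_small, dilution_small,
                                        stock_large, dilution_large) {
  stopif(any(c(stock_small, stock_large, dilution_small,
               dilution_large) <= 0), "all inputs must be positive")
  (stock_small / dilution_small) / (stock_large / dilution_large)
}

#' Size-fraction table over diameter bins
#'
#' Fractions of events falling into consecutive diameter bins, with an
#' underflow bin below the first edge and an overflow bin above the last;
#' fractions always sum to one. Default edges follow the submicron report
#' bins 0.2-0.4-0.6-0.8-1.0 um.
#'
#' @param events An `adls_events` table (>= 1 row).
#' @param edges Ascending bin edges in metres.
#' @return Data frame with `bin` labels, `lower`, `upper` (m) and
#'   `fraction`.
#' @export
size_fractions <- function(events,
                           edges = c(0.2, 0.4, 0.6, 0.8, 1.0) * 1e-6) {
  stopif(nrow(events) < 1, "need at least one event")
  stopif(is.unsorted(edges, strictly = TRUE), "edges must be ascending")
  full <- c(-Inf, edges, Inf)
  idx <- findInterval(events$dp, full, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(full) - 1)
  lab <- c(sprintf("<%.1f", edges[1] * 1e6),
           sprintf("%.1f-%.1f", edges[-length(edges)] * 1e6,
                   edges[-1] * 1e6),
           sprintf(">%.1f", edges[length(edges)] * 1e6))
  data.frame(bin = lab, lower = full[-length(full)], upper = full[-1],
             fraction = counts / sum(counts))
}
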