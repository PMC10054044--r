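#' Unit conversions between bench units and SI
#'
#' Flow rates are quoted in microlitres per hour at the instrument and held
#' in cubic metres per second internally; concentrations are quoted per
#' millilitre and held per cubic metre.
#'
#' @param x Numeric vector of values to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' ul_per_h_to_m3_s(1)                    # 2.78e-13 m^3/s
#' m3_s_to_ul_per_h(ul_per_h_to_m3_s(3))  # 3, exact round trip
#' @export
ul_per_h_to_m3_s <- function(x) x * 1e-9 / 3600

#' @rdname ul_per_h_to_m3_s
#' @export
m3_s_to_ul_per_h <- function(x) x * 3600 / 1e-9

#' @rdname ul_per_h_to_m3_s
#' @export
per_ml_to_per_m3 <- function(x) x * 1e6

#' @rdname ul_per_h_to_m3_s
#' @export
per_m3_to_per_ml <- function(x) x * 1e-6

# run `code` with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

stopif <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
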