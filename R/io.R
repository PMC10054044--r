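#' Write and read PMT traces as two-column CSV
#'
#' Interchange format for traces: `time_s`, `adc_counts`. Reading back
#' reconstructs the sampling rate from the time column; ground-truth
#' metadata is not carried by the CSV (it is simulator-internal).
#'
#' @param trace An `adls_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  fs <- trace$config$sampling_rate
  df <- data.frame(time_s = (seq_along(trace$samples) - 1) / fs,
                   adc_counts = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param adc_bits ADC depth assumed for the read trace.
#' @param gain Gain annotation for the read trace.
#' @export
read_trace_csv <- function(path, adc_bits = 16, gain = "medium") {
  df <- utils::read.csv(path)
  stopif(!all(c("time_s", "adc_counts") %in% names(df)),
         "trace CSV needs columns time_s, adc_counts")
  stopif(nrow(df) < 2, "trace CSV too short")
  fs <- 1 / stats::median(diff(df$time_s))
  cfg <- trace_config(sampling_rate = fs, duration = nrow(df) / fs,
                      gain = gain, adc_bits = adc_bits)
  structure(list(samples = as.integer(df$adc_counts), config = cfg,
                 truth = empty_particles()),
            class = "adls_trace")
}

#' Write and read event tables as CSV
#'
#' Columns: `time_s`, `fwhm_s`, `ifp_counts`, `dp_um`, `saturated`,
#' `subresolution`. Values are written with full precision so that
#' identical runs produce byte-identical files.
#'
#' @param events An `adls_events` table.
#' @param path File path.
#' @return `path` (write) or an `adls_events` table (read).
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(time_s = format_num(events$time),
                   fwhm_s = format_num(events$fwhm),
                   ifp_counts = format_num(events$ifp),
                   dp_um = format_num(events$dp * 1e6),
                   saturated = events$saturated,
                   subresolution = events$subresolution)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_num <- function(x) sprintf("%.10g", x)

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(time = df$time_s, fwhm = df$fwhm_s,
                    ifp = df$ifp_counts, dp = df$dp_um * 1e-6,
                    saturated = df$saturated,
                    subresolution = df$subresolution)
  class(out) <- c("adls_events", "data.frame")
  out
}

#' Export a phase map as an 8-bit grayscale PNG
#'
#' Phase is wrapped to [0, 2 pi) and mapped linearly to gray levels
#' 0..255, the upload format of typical phase-only SLMs. Points outside
#' the pupil disk are written as 0.
#'
#' @param mask An `adls_phase` object.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_phase_png <- function(mask, path) {
  phi <- wrap_phase(mask$phase) * mask$mask
  img <- phi / (2 * pi)
  png::writePNG(img, path)
  invisible(path)
}

#' Export an intensity stack as multi-page TIFF (requires the tiff
#' package)
#'
#' @param stack An `adls_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the tiff package is required for TIFF export", call. = FALSE)
  }
  I <- stack$I / max(stack$I)
  pages <- lapply(seq_len(dim(I)[3]), function(iz) I[, , iz])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a JSON report
#' @param x A list of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
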