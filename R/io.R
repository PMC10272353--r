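#' Write a raw recording to disk
#'
#' Flat little-endian signed 16-bit binary with channel-interleaved frames
#' (`trace.int16`), plus a JSON sidecar (`recording.json`) carrying the
#' sampling rate, the microvolts-per-bit scaling, the channel table and the
#' trial schedule. Ground-truth spikes, when supplied, are written as CSV.
#'
#' @param rec a `raw_recording`.
#' @param dir output directory (created if needed).
#' @param uv_per_bit quantization step, microvolts per integer unit.
#' @param truth_spikes optional data.frame (`channel`, `trial`, `time`).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir, uv_per_bit = 0.195, truth_spikes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- round(t(rec$trace) / uv_per_bit)   # channel-interleaved frames
  q <- pmin(pmax(q, -32768), 32767)
  con <- file(file.path(dir, "trace.int16"), "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  meta <- list(sample_rate_hz = rec$sample_rate, uv_per_bit = uv_per_bit,
               n_channels = ncol(rec$trace), n_samples = nrow(rec$trace),
               channels = rec$channels, schedule = rec$schedule,
               animal = rec$animal)
  jsonlite::write_json(meta, file.path(dir, "recording.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  if (!is.null(truth_spikes))
    utils::write.csv(truth_spikes, file.path(dir, "truth_spikes.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a raw recording written by [write_recording()]
#'
#' @param dir directory holding `trace.int16` and `recording.json`.
#' @return a `raw_recording` (trace in microvolts).
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  n <- meta$n_samples * meta$n_channels
  con <- file(file.path(dir, "trace.int16"), "rb")
  on.exit(close(con))
  q <- readBin(con, integer(), n = n, size = 2L, endian = "little",
               signed = TRUE)
  trace <- t(matrix(q * meta$uv_per_bit, meta$n_channels, meta$n_samples))
  structure(list(trace = trace, sample_rate = meta$sample_rate_hz,
                 channels = as.data.frame(meta$channels),
                 schedule = as.data.frame(meta$schedule),
                 duration_s = meta$n_samples / meta$sample_rate_hz,
                 animal = meta$animal),
            class = "raw_recording")
}
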