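# Minimal RIFF/WAVE I/O. Supports the two encodings the pipeline writes:
# IEEE float32 (format tag 3) and PCM16 (format tag 1), any channel count.
# Waveforms are stored in memory in pascals; on disk full scale = 20 Pa.

#' Write a waveform matrix to a WAV file
#'
#' Samples are interpreted in pascals and scaled so that digital full scale
#' corresponds to 20 Pa (the package's SPL calibration convention, giving a
#' 120 dB SPL full-scale sine). Multichannel input is one column per channel.
#'
#' @param x Numeric vector (mono) or matrix with one column per channel, in Pa.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @param bits 32 (IEEE float, default) or 16 (PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate, bits = 32) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(is.matrix(x), sample_rate > 0, bits %in% c(16L, 32L))
  n_ch <- ncol(x)
  n <- nrow(x)
  scaled <- x / WAV_FULL_SCALE_PA
  con <- file(path, "wb")
  on.exit(close(con))
  fmt_tag <- if (bits == 32) 3L else 1L
  bytes_per <- bits / 8L
  data_bytes <- n * n_ch * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  interleaved <- as.numeric(t(scaled))
  if (bits == 32) {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(interleaved, 1), -1) * 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return List with `samples` (matrix, one column per channel, in Pa) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_tag <- readBin(con, "integer", size = 2, endian = "little")
      n_ch <- readBin(con, "integer", size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      fmt <- list(tag = fmt_tag, n_ch = n_ch, rate = rate, bits = bits)
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      n_samp <- sz / (fmt$bits / 8)
      raw_vals <- if (fmt$tag == 3) {
        readBin(con, "numeric", n = n_samp, size = 4, endian = "little")
      } else if (fmt$tag == 1 && fmt$bits == 16) {
        readBin(con, "integer", n = n_samp, size = 2, signed = TRUE,
                endian = "little") / 32767
      } else {
        stop("unsupported WAV encoding (format tag ", fmt$tag, ")")
      }
      samples <- matrix(raw_vals * WAV_FULL_SCALE_PA,
                        ncol = fmt$n_ch, byrow = TRUE)
      return(list(samples = samples, sample_rate = fmt$rate))
    } else {
      readBin(con, "raw", n = sz + (sz %% 2))
    }
  }
}
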