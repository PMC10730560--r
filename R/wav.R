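# Minimal RIFF/WAVE I/O for calibrated single-channel bench audio.
# Supports 16-bit PCM and 32-bit IEEE float. Float is the default writer
# format so calibrated pressures in Pa survive the round trip unscaled.

#' Write a mono WAV file
#'
#' @param samples numeric vector. For `format = "pcm16"` values are clipped to
#'   \[-1, 1\] and quantized; `"float32"` stores them verbatim.
#' @param path output file.
#' @param rate sampling rate in Hz.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, rate, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (format == "float32") {
    fmt_tag <- 3L; bits <- 32L; data_bytes <- 4L * n
  } else {
    fmt_tag <- 1L; bits <- 16L; data_bytes <- 2L * n
  }
  block_align <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path WAV file (16-bit PCM or 32-bit float, single channel).
#' @return list with `samples` (numeric) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt_tag <- NA_integer_; rate <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      if (channels != 1L) stop("only mono WAV supported")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", n = extra))
    } else if (id == "data") {
      if (fmt_tag == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", n = size %/% 4L, size = 4,
                           endian = "little")
      } else if (fmt_tag == 1L && bits == 16L) {
        samples <- readBin(con, "integer", n = size %/% 2L, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else {
        stop("unsupported WAV encoding (format ", fmt_tag, ", ", bits, " bit)")
      }
      break
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, rate = rate)
}
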