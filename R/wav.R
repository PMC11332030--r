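# Minimal RIFF/WAVE I/O (PCM 16/24/32-bit and IEEE float32), mono or multi-
# channel. Kept deliberately small: the package only needs to read stimulus
# loopback / motor-response recordings and write listening checks.

#' Read a WAV file
#'
#' Supports PCM 16/24/32-bit integer and 32-bit IEEE float, any channel
#' count. Samples are returned as doubles scaled to \[-1, 1\].
#'
#' @param path file path.
#' @return list with `samples` (numeric matrix, one column per channel),
#'   `fs` (sample rate, Hz), `bit_depth` and `n_channels`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop_invalid("not a WAVE file: ", path)
  }
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        fs = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_invalid("missing fmt or data chunk in ", path)
  }
  bytes <- fmt$bits / 8
  n_frames <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", n_frames * fmt$n_channels, 4,
                 endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits %in% c(16L, 32L)) {
    x <- readBin(data_raw, "integer", n_frames * fmt$n_channels, bytes,
                 signed = TRUE, endian = "little") / (2^(fmt$bits - 1))
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else {
    stop_invalid("unsupported WAV format (format tag ", fmt$audio_format,
                 ", ", fmt$bits, " bits)")
  }
  samples <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = samples, fs = fmt$fs, bit_depth = fmt$bits,
       n_channels = fmt$n_channels)
}

#' Write a WAV file (16-bit PCM)
#'
#' @param samples numeric vector or matrix (columns = channels) in \[-1, 1\].
#' @param fs sample rate in Hz.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  n_ch <- ncol(samples)
  x <- as.integer(round(pmax(pmin(t(samples), 1), -1) * 32767))
  data_size <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")          # PCM
  writeBin(n_ch, con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * n_ch * 2), con, 4, endian = "little")
  writeBin(as.integer(n_ch * 2), con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  invisible(path)
}
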