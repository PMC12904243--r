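#' Construct an audio signal
#'
#' Lightweight container for a mono sampled pressure waveform. Samples are
#' dimensionless full-scale units: the representable peak is +/- 1, so dB FS
#' levels are relative to an RMS of 1.
#'
#' @param samples Numeric vector of samples.
#' @param rate Sample rate in Hz.
#' @return An object of class `audio_signal` with fields `samples` and `rate`.
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples)) stop("samples must be numeric", call. = FALSE)
  stopifnot_scalar(rate)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), RMS %.4g>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (length(x$samples)) rms(x$samples) else 0))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param audio An `audio_signal`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(audio) length(audio$samples) / audio$rate

#' Read a mono WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float-32 encodings. Multichannel
#' files are rejected: the processing chain is defined for a single microphone
#' signal.
#'
#' @param path Path to a WAV file.
#' @return An [audio_signal()] with samples scaled to [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path, call. = FALSE)
  if (fmt$n_channels != 1L) {
    stop(sprintf("expected mono audio, got %d channels", fmt$n_channels), call. = FALSE)
  }
  samples <- switch(
    as.character(fmt$audio_format),
    "1" = {
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                endian = "little", signed = TRUE) / 32768
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) / 3
        b <- matrix(as.integer(data_raw), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v[v >= 8388608] <- v[v >= 8388608] - 16777216
        v / 8388608
      } else {
        stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
      }
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4, size = 4, endian = "little"),
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")", call. = FALSE)
  )
  audio_signal(samples, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param audio An [audio_signal()].
#' @param path Output path.
#' @param bits Bit depth: 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16L) {
  stopifnot(inherits(audio, "audio_signal"))
  x <- audio$samples
  if (bits == 16L) {
    pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    bytes_per <- 2L
    fmt_tag <- 1L
  } else if (bits == 32L) {
    bytes_per <- 4L
    fmt_tag <- 3L
  } else {
    stop("bits must be 16 or 32", call. = FALSE)
  }
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(audio$rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
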