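#' Normalize a signal to a target RMS level
#'
#' Scales the whole signal so its root-mean-square level equals
#' `target_dbfs` dB relative to full scale (RMS of 1.0 = 0 dB FS).
#'
#' @param audio An [audio_signal()].
#' @param target_dbfs Target RMS level in dB FS (default -20).
#' @return The rescaled [audio_signal()].
#' @export
normalize_rms <- function(audio, target_dbfs = -20) {
  stopifnot(inherits(audio, "audio_signal"))
  r <- rms(audio$samples)
  if (r == 0) stop("cannot normalize silence", call. = FALSE)
  target <- 10^(target_dbfs / 20)
  audio_signal(audio$samples * (target / r), audio$rate)
}

# First-order Chebyshev type II high-pass coefficients by bilinear transform.
# At order one the type II prototype has no finite zero, so the design
# reduces to a single-pole high-pass whose attenuation at the stopband edge
# equals rs_db exactly (verified analytically in preemph_response()).
preemph_coefs <- function(fs, stopband_hz, rs_db) {
  if (stopband_hz >= fs / 2) {
    stop("stopband edge must be below the Nyquist frequency", call. = FALSE)
  }
  omega <- 2 * fs * tan(pi * stopband_hz / fs)   # prewarped edge, rad/s
  a_an <- omega * sqrt(10^(rs_db / 10) - 1)      # analog pole location
  b <- c(2 * fs, -2 * fs)
  a <- c(2 * fs + a_an, a_an - 2 * fs)
  list(b = b / a[1], a = a / a[1])
}

#' Pre-emphasis high-pass filter
#'
#' Applies the front-end pre-emphasis filter: a first-order Chebyshev type II
#' high-pass with a given stopband edge and stopband attenuation. The default
#' design places the stopband edge at 4 kHz with 3 dB of attenuation; an
#' alternate edge (e.g. 8 kHz, usable only when the sample rate exceeds
#' 16 kHz) can be selected via `stopband_hz`.
#'
#' @param audio An [audio_signal()] with sample rate >= 16 kHz.
#' @param stopband_hz Stopband edge frequency, Hz (default 4000).
#' @param rs_db Stopband attenuation at the edge, dB (default 3).
#' @return The filtered [audio_signal()].
#' @export
pre_emphasize <- function(audio, stopband_hz = 4000, rs_db = 3) {
  stopifnot(inherits(audio, "audio_signal"))
  if (audio$rate < 16000) stop("sample rate must be >= 16 kHz", call. = FALSE)
  co <- preemph_coefs(audio$rate, stopband_hz, rs_db)
  y <- as.numeric(signal::filter(co$b, co$a, audio$samples))
  audio_signal(y, audio$rate)
}

#' Analytic frequency response of the pre-emphasis filter
#'
#' @param freqs_hz Frequencies at which to evaluate, Hz.
#' @param fs Sample rate, Hz.
#' @inheritParams pre_emphasize
#' @return Complex response at `freqs_hz`.
#' @export
preemph_response <- function(freqs_hz, fs = 16000, stopband_hz = 4000, rs_db = 3) {
  co <- preemph_coefs(fs, stopband_hz, rs_db)
  z1 <- exp(-1i * 2 * pi * freqs_hz / fs)
  (co$b[1] + co$b[2] * z1) / (co$a[1] + co$a[2] * z1)
}

#' Loudness-growth compression configuration
#'
#' @param base Envelope level mapped to 0 (default 0).
#' @param saturation Envelope level mapped to 1 (default 0.39).
#' @param rho Steepness of the logarithmic growth (default 416.2, the
#'   conventional coder default; the published map settings fix base and
#'   saturation but not rho).
#' @return A `compression_config` list.
#' @export
compression_config <- function(base = 0, saturation = 0.39, rho = 416.2) {
  if (saturation <= base) stop("saturation must exceed base", call. = FALSE)
  if (rho <= 0) stop("rho must be positive", call. = FALSE)
  structure(list(base = base, saturation = saturation, rho = rho),
            class = "compression_config")
}

#' Loudness growth function
#'
#' Maps a band envelope magnitude onto the normalized electrical dynamic
#' range: `v = log(1 + rho*(p - base)/(saturation - base)) / log(1 + rho)`,
#' clipped to [0, 1] outside [base, saturation].
#'
#' @param p Envelope magnitude(s), finite and >= 0 (negative or non-finite
#'   values clip with a warning).
#' @param cfg A [compression_config()].
#' @return Compressed magnitude(s) in [0, 1].
#' @export
compress_lgf <- function(p, cfg = compression_config()) {
  stopifnot(inherits(cfg, "compression_config"))
  if (any(!is.finite(p) | p < 0)) {
    warning("non-finite or negative envelope values clipped before compression")
    p[!is.finite(p)] <- 0
    p <- pmax(p, 0)
  }
  x <- (p - cfg$base) / (cfg$saturation - cfg$base)
  v <- log1p(cfg$rho * pmax(pmin(x, 1), 0)) / log1p(cfg$rho)
  pmin(pmax(v, 0), 1)
}

#' Default filterbank band allocation
#'
#' Builds the band table for an FFT filterbank: 128-point FFT at 16 kHz
#' (125 Hz bin spacing), with the conventional 22-band allocation spanning
#' roughly 188 Hz to 8 kHz (per-band bin counts 1,1,...,7,8 over FFT bins
#' 2..63). For maps with fewer channels the 22 bands are merged into
#' contiguous groups spanning the full range. Bands in the table run from low
#' to high frequency and are assigned to electrodes from apical to basal.
#'
#' @param electrodes Active electrode ids (apical = high number = low band).
#' @param fft_n FFT length (default 128).
#' @param fs Analysis sample rate, Hz (default 16000).
#' @return A data.frame with one row per channel: `channel`, `electrode`,
#'   `bin_lo`, `bin_hi` (1-based FFT bin indices excluding DC), `f_lo_hz`,
#'   `f_hi_hz`.
#' @export
default_band_allocation <- function(electrodes, fft_n = 128, fs = 16000) {
  n_ch <- length(electrodes)
  counts22 <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 4, 4, 5, 5, 6, 7, 8)
  if (n_ch > 22) stop("at most 22 analysis bands are defined", call. = FALSE)
  # merge the 22 bands into n_ch contiguous groups, sizes differing by <= 1
  sizes <- rep(22 %/% n_ch, n_ch)
  extra <- 22 %% n_ch
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  grp <- rep(seq_len(n_ch), times = sizes)
  band_counts <- as.integer(tapply(counts22, grp, sum))
  first_bin <- 2L                       # 0-based bin 2 -> 250 Hz center
  hi <- first_bin + cumsum(band_counts) - 1L
  lo <- hi - band_counts + 1L
  bin_hz <- fs / fft_n
  # electrodes sorted descending: most apical (highest id) takes lowest band
  el_sorted <- sort(as.integer(electrodes), decreasing = TRUE)
  data.frame(
    channel = seq_len(n_ch),
    electrode = el_sorted,
    bin_lo = lo, bin_hi = hi,
    f_lo_hz = (lo - 0.5) * bin_hz,
    f_hi_hz = (hi + 0.5) * bin_hz
  )
}

# Polyphase-free rational resampler: delegates to signal::resample with the
# rational approximation of the rate ratio.
resample_audio <- function(audio, target_fs) {
  if (audio$rate == target_fs) return(audio)
  frac <- target_fs / audio$rate
  # continued-fraction rational approximation with denominator <= 1000
  pq <- c(round(frac * 1000), 1000)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(pq[1], pq[2])
  y <- signal::resample(audio$samples, pq[1] / d, pq[2] / d)
  audio_signal(as.numeric(y), target_fs)
}

#' Extract per-channel band envelopes
#'
#' Runs the filterbank stage of the coding chain: the signal is resampled to
#' the analysis rate, cut into 128-sample frames at the per-channel
#' stimulation rate, windowed (periodic Hann) and transformed; the envelope
#' of each channel combines the FFT bins assigned to its band by
#' root-sum-of-squares of the bin magnitudes (power combining, as FFT
#' filterbank coders do; a coherent complex sum would cancel bin-centered
#' tones under the Hann bin pattern), scaled so a sine at a band-interior bin
#' center yields an envelope close to its amplitude. The signal is
#' zero-padded at the end so every frame start within the signal duration
#' yields a frame.
#'
#' @param audio An [audio_signal()].
#' @param map A [channel_map()]; its `band_table` (or the default allocation)
#'   defines the channel bands.
#' @param fft_n FFT length (default 128).
#' @param fs Analysis sample rate, Hz (default 16000).
#' @return An `envelope_frames` object: list with `values` (channel x frame
#'   matrix of non-negative envelopes), `frame_rate` (= map rate),
#'   `band_table`, `map`.
#' @export
analyze_envelopes <- function(audio, map, fft_n = 128, fs = 16000) {
  stopifnot(inherits(audio, "audio_signal"), inherits(map, "channel_map"))
  audio <- resample_audio(audio, fs)
  x <- audio$samples
  if (length(x) < fft_n) {
    stop(sprintf("audio shorter than one analysis block (%d samples)", fft_n),
         call. = FALSE)
  }
  bt <- map$band_table
  if (is.null(bt)) bt <- default_band_allocation(map$electrodes, fft_n, fs)
  dur <- length(x) / fs
  n_frames <- ceiling(dur * map$rate - 1e-9)
  starts <- (seq_len(n_frames) - 1) / map$rate
  idx0 <- round(starts * fs)                       # 0-based start sample
  x_pad <- c(x, numeric(fft_n))
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(fft_n - 1)) / fft_n)  # periodic Hann
  scale <- 2 / sum(win)
  frames <- vapply(idx0, function(i0) x_pad[(i0 + 1):(i0 + fft_n)] * win,
                   numeric(fft_n))
  spec <- stats::mvfft(frames)                     # fft_n x n_frames
  n_ch <- nrow(bt)
  vals <- matrix(0, nrow = n_ch, ncol = n_frames)
  for (ch in seq_len(n_ch)) {
    bins <- (bt$bin_lo[ch]:bt$bin_hi[ch]) + 1L     # +1: R's 1-based, keep DC row 1
    block <- spec[bins, , drop = FALSE]
    vals[ch, ] <- sqrt(colSums(Mod(block)^2)) * scale
  }
  # FFT round-off leaves ~1e-16 dust in silent bands; anything 200 dB below
  # the frame maximum is numerically zero, not stimulation
  frame_max <- apply(vals, 2, max)
  vals[vals < rep(frame_max, each = n_ch) * 1e-10] <- 0
  structure(list(values = vals, frame_rate = map$rate, band_table = bt,
                 map = map),
            class = "envelope_frames")
}

#' @export
print.envelope_frames <- function(x, ...) {
  cat(sprintf("<envelope_frames: %d channels x %d frames @ %g frames/s>\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}
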