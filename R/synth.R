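#' Default speech-shaped third-octave reference spectrum
#'
#' A synthetic stand-in for the long-term average spectrum of running speech
#' (sexes combined): third-octave band levels in dB (arbitrary reference)
#' over 125 Hz to 8 kHz, peaking in the 250 to 500 Hz region and rolling off
#' toward high frequency. The matrix-sentence spectrum used in listening
#' studies is not published, so this curve claims only the qualitative shape
#' of a long-term speech spectrum.
#'
#' @return A data.frame with `freq_hz` (third-octave centers) and `level_db`.
#' @export
speech_spectrum_default <- function() {
  data.frame(
    freq_hz = c(125, 160, 200, 250, 315, 400, 500, 630, 800, 1000,
                1250, 1600, 2000, 2500, 3150, 4000, 5000, 6300, 8000),
    level_db = c(51.2, 57.7, 60.0, 60.4, 59.0, 57.7, 56.8, 55.4, 53.6, 53.0,
                 52.0, 50.9, 49.8, 49.4, 49.3, 49.2, 48.2, 46.0, 43.5)
  )
}

#' Noise specification
#'
#' @param kind `"SSN"` (speech-shaped stationary noise), `"BABBLE"`
#'   (multi-talker babble proxy) or `"WHITE"`.
#' @param reference_spectrum Third-octave reference spectrum (data.frame with
#'   `freq_hz`, `level_db`) for SSN; default [speech_spectrum_default()].
#' @param n_talkers Number of talkers for babble (default 20).
#' @param seed RNG seed; every generator is a pure function of (spec, seed).
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(kind = c("SSN", "BABBLE", "WHITE"),
                       reference_spectrum = speech_spectrum_default(),
                       n_talkers = 20, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_talkers >= 1, all(is.finite(reference_spectrum$level_db)))
  structure(list(kind = kind, reference_spectrum = reference_spectrum,
                 n_talkers = as.integer(n_talkers), seed = seed),
            class = "noise_spec")
}

#' Generate a pure tone
#'
#' @param freq_hz Tone frequency, Hz.
#' @param duration Duration, seconds.
#' @param rate Sample rate, Hz.
#' @param amplitude Peak amplitude (default 0.5).
#' @param ramp_s Raised-cosine on/off ramp, seconds (default 5 ms).
#' @return An [audio_signal()].
#' @export
gen_tone <- function(freq_hz, duration, rate = 16000, amplitude = 0.5,
                     ramp_s = 0.005) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- amplitude * sin(2 * pi * freq_hz * t)
  nr <- min(round(ramp_s * rate), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  audio_signal(x, rate)
}

#' Generate a click train
#'
#' @param click_rate_hz Clicks per second.
#' @param duration Duration, seconds.
#' @param rate Sample rate, Hz.
#' @param amplitude Click amplitude (default 0.9).
#' @return An [audio_signal()].
#' @export
gen_click_train <- function(click_rate_hz, duration, rate = 16000,
                            amplitude = 0.9) {
  n <- round(duration * rate)
  x <- numeric(n)
  idx <- round(seq(0, duration, by = 1 / click_rate_hz) * rate) + 1
  idx <- idx[idx <= n]
  x[idx] <- amplitude
  audio_signal(x, rate)
}

#' Generate speech-shaped stationary noise
#'
#' Gaussian noise spectrally shaped in the FFT domain to a third-octave
#' reference spectrum (levels interpolated linearly in log-frequency and dB,
#' held constant beyond the tabulated range). The output is normalized to
#' unit RMS; for durations of a few seconds or more the measured long-term
#' third-octave band levels match the reference shape within about 1 dB.
#'
#' @param spec A [noise_spec()] (its `reference_spectrum` and `seed` are
#'   used).
#' @param duration Duration, seconds.
#' @param rate Sample rate, Hz.
#' @return An [audio_signal()] with unit RMS.
#' @export
gen_ssn <- function(spec = noise_spec("SSN"), duration = 5, rate = 16000) {
  stopifnot(inherits(spec, "noise_spec"), duration > 0)
  n <- round(duration * rate)
  x <- with_seed(spec$seed, stats::rnorm(n))
  ref <- spec$reference_spectrum
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)                      # fold to [0, Nyquist]
  lf <- log(pmax(f, ref$freq_hz[1] / 2))
  gain_db <- stats::approx(log(ref$freq_hz), ref$level_db, xout = lf,
                           rule = 2)$y
  # amplitude gain per bin; third-octave bandwidth grows as f, so dividing
  # the band level by sqrt(f) converts band levels to spectral density shape
  g <- 10^(gain_db / 20) / sqrt(pmax(f, ref$freq_hz[1] / 2))
  g[1] <- 0                                   # no DC
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  audio_signal(y / rms(y), rate)
}

#' Generate white Gaussian noise
#'
#' @param duration Duration, seconds.
#' @param rate Sample rate, Hz.
#' @param seed RNG seed.
#' @return An [audio_signal()] with unit RMS.
#' @export
gen_white <- function(duration = 5, rate = 16000, seed = 1) {
  n <- round(duration * rate)
  x <- with_seed(seed, stats::rnorm(n))
  audio_signal(x / rms(x), rate)
}

#' Generate a speech-like token
#'
#' A synthetic stand-in for a spoken sentence: a sequence of syllables at 3
#' to 5 per second, each either voiced (a harmonic complex on a randomized
#' fundamental of 100 to 250 Hz with two or three formant-like spectral
#' peaks) or an unvoiced high-frequency noise burst, separated by brief
#' pauses, with a raised-cosine envelope per syllable. The result has the
#' 2 to 8 Hz modulation-spectrum peak characteristic of speech but is not
#' intelligible.
#'
#' @param seed RNG seed.
#' @param duration Duration, seconds.
#' @param rate Sample rate, Hz.
#' @return An [audio_signal()] with unit RMS.
#' @export
gen_speech_token <- function(seed = 1, duration = 2, rate = 16000) {
  stopifnot(duration > 0)
  n_total <- round(duration * rate)
  with_seed(seed, {
    f0 <- stats::runif(1, 100, 250)
    x <- numeric(n_total)
    pos <- 1
    while (pos < n_total) {
      syll_rate <- stats::runif(1, 3, 5)
      syll_n <- round(rate / syll_rate * stats::runif(1, 0.55, 0.75))
      pause_n <- round(rate / syll_rate) - syll_n
      syll_n <- min(syll_n, n_total - pos + 1)
      if (syll_n < rate * 0.02) break
      t <- (seq_len(syll_n) - 1) / rate
      if (stats::runif(1) < 0.75) {
        # voiced: harmonic complex with formant-shaped amplitudes
        f0_j <- f0 * stats::runif(1, 0.9, 1.1)
        formants <- c(stats::runif(1, 300, 800), stats::runif(1, 900, 2200),
                      stats::runif(1, 2400, 3200))
        bw <- c(90, 120, 160)
        harm <- seq(f0_j, min(4000, rate / 2 - 100), by = f0_j)
        amp <- rowSums(vapply(seq_along(formants), function(k)
          exp(-((harm - formants[k]) / bw[k])^2), numeric(length(harm))))
        amp <- amp + 0.05
        ph <- stats::runif(length(harm), 0, 2 * pi)
        s <- colSums(amp * sin(outer(2 * pi * harm, t) + ph))
      } else {
        # unvoiced: high-pass-tilted noise burst
        s <- stats::rnorm(syll_n)
        s <- diff(c(0, s))                    # first difference tilts +6 dB/oct
      }
      env <- sin(pi * (seq_len(syll_n) - 0.5) / syll_n)^0.7
      x[pos:(pos + syll_n - 1)] <- s / max(rms(s), 1e-12) * env *
        stats::runif(1, 0.6, 1)
      pos <- pos + syll_n + max(pause_n, 1)
    }
    if (rms(x) == 0) stop("degenerate token; try another seed", call. = FALSE)
    audio_signal(x / rms(x), rate)
  })
}

#' Generate multi-talker babble
#'
#' A proxy for recorded multi-talker babble: `n_talkers` independent
#' speech-like streams (see [gen_speech_token()]) with random onsets are
#' summed and normalized to unit RMS. As the talker count grows the summed
#' envelope modulation flattens and the amplitude distribution approaches
#' Gaussian, the qualitative statistics that make babble an effective masker.
#'
#' @param spec A [noise_spec()] (`n_talkers` and `seed` are used).
#' @param duration Duration, seconds.
#' @param rate Sample rate, Hz.
#' @return An [audio_signal()] with unit RMS.
#' @export
gen_babble <- function(spec = noise_spec("BABBLE"), duration = 5,
                       rate = 16000) {
  stopifnot(inherits(spec, "noise_spec"), duration > 0)
  n <- round(duration * rate)
  mix <- numeric(n)
  for (k in seq_len(spec$n_talkers)) {
    tk <- gen_speech_token(seed = spec$seed * 1000 + k,
                           duration = duration + 0.5, rate = rate)
    off <- with_seed(spec$seed * 1000 + k + 500,
                     sample.int(round(0.5 * rate), 1))
    mix <- mix + tk$samples[off:(off + n - 1)]
  }
  audio_signal(mix / rms(mix), rate)
}

#' Generate noise from a specification
#'
#' Dispatcher over [gen_ssn()], [gen_babble()] and [gen_white()].
#'
#' @param spec A [noise_spec()].
#' @param duration Duration, seconds.
#' @param rate Sample rate, Hz.
#' @return An [audio_signal()].
#' @export
gen_noise <- function(spec, duration = 5, rate = 16000) {
  switch(spec$kind,
         SSN = gen_ssn(spec, duration, rate),
         BABBLE = gen_babble(spec, duration, rate),
         WHITE = gen_white(duration, rate, spec$seed))
}

#' Mix speech and noise at a target SNR
#'
#' The speech is left untouched; a random segment of the noise (at least as
#' long as the speech) is drawn and scaled so that
#' `RMS(speech)/RMS(noise) = snr_db`, then added.
#'
#' @param speech,noise [audio_signal()]s at the same sample rate; `noise`
#'   must be at least as long as `speech`.
#' @param snr_db Target signal-to-noise ratio, dB.
#' @param seed Seed for the noise-segment draw.
#' @return The mixture as an [audio_signal()].
#' @export
mix_at_snr <- function(speech, noise, snr_db, seed = 1) {
  stopifnot(inherits(speech, "audio_signal"), inherits(noise, "audio_signal"))
  if (speech$rate != noise$rate) stop("sample rates differ", call. = FALSE)
  ns <- length(speech$samples)
  nn <- length(noise$samples)
  if (nn < ns) stop("noise shorter than speech", call. = FALSE)
  off <- if (nn == ns) 1L else with_seed(seed, sample.int(nn - ns + 1L, 1))
  seg <- noise$samples[off:(off + ns - 1)]
  target_noise_rms <- rms(speech$samples) * 10^(-snr_db / 20)
  seg <- seg * (target_noise_rms / rms(seg))
  audio_signal(speech$samples + seg, speech$rate)
}

#' Measure third-octave band levels
#'
#' Long-term band levels from the periodogram, integrated over standard
#' third-octave bands.
#'
#' @param audio An [audio_signal()].
#' @param centers_hz Band center frequencies (default the standard centers
#'   from 125 Hz to 8 kHz).
#' @return A data.frame with `freq_hz` and `level_db` (10*log10 band power).
#' @export
third_octave_levels <- function(audio,
                                centers_hz = speech_spectrum_default()$freq_hz) {
  x <- audio$samples
  n <- length(x)
  X <- stats::fft(x)
  pw <- Mod(X[seq_len(floor(n / 2))])^2 / n
  f <- (seq_len(floor(n / 2)) - 1) / n * audio$rate
  lev <- vapply(centers_hz, function(fc) {
    lo <- fc / 2^(1 / 6)
    hi <- fc * 2^(1 / 6)
    10 * log10(sum(pw[f >= lo & f < hi]) + 1e-30)
  }, numeric(1))
  data.frame(freq_hz = centers_hz, level_db = lev)
}
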