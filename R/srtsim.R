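#' Model listener for SRT simulation
#'
#' A psychometric stand-in for a human listener in the matrix sentence test:
#' the probability of reporting a word correctly is a logistic function of
#' the SNR, parameterized by the true 50%-correct threshold (`srt50`) and the
#' psychometric slope at threshold, with an optional lapse rate.
#'
#' @param srt50 True speech-reception threshold, dB SNR.
#' @param slope Psychometric slope at threshold, proportion correct per dB
#'   (default 0.15).
#' @param lapse Lapse probability in [0, 0.5) (default 0).
#' @param words_per_trial Words scored per sentence (default 5: name, verb,
#'   number, adjective, noun).
#' @return A `listener_model` object.
#' @export
listener_model <- function(srt50, slope = 0.15, lapse = 0,
                           words_per_trial = 5) {
  stopifnot(slope > 0, lapse >= 0, lapse < 0.5, words_per_trial >= 1)
  structure(list(srt50 = srt50, slope = slope, lapse = lapse,
                 words_per_trial = as.integer(words_per_trial)),
            class = "listener_model")
}

#' Per-word probability correct at a given SNR
#'
#' `(1 - lapse) * logistic((snr - srt50) * 4 * slope)`: the logistic is
#' scaled so its derivative at threshold equals `slope` (before the lapse
#' factor), and with `lapse = 0` the probability at `snr = srt50` is exactly
#' 0.5.
#'
#' @param listener A [listener_model()].
#' @param snr SNR(s), dB.
#' @return Probability of a correct word report.
#' @export
listener_prob <- function(listener, snr) {
  stopifnot(inherits(listener, "listener_model"))
  (1 - listener$lapse) *
    stats::plogis((snr - listener$srt50) * 4 * listener$slope)
}

#' Adaptive-track configuration
#'
#' The measurement protocol: tracks start at 0 dB SNR, presented SNRs are
#' clamped to [-15, +30] dB, each track presents `trials_per_track` sentences
#' (two 10-sentence lists by default), the SRT is the mean SNR at the last
#' `reversals_for_srt` reversals, and a third track is run when the first two
#' SRTs differ by more than `retest_delta` dB or a track under-reverses.
#'
#' The SNR update is word-score proportional,
#' `dSNR = -step * (proportion correct - 0.5) / 0.5`, with the step halving
#' after each of the first `n_step_reversals` reversals from `step_init_db`
#' down to no less than `step_min_db`. These update constants are a
#' documented stand-in for the adaptive rule used with human listeners, whose
#' exact constants are not part of this package's sources.
#'
#' @param start_snr Initial SNR, dB (default 0).
#' @param snr_bounds Length-2 presented-SNR bounds, dB (default c(-15, 30)).
#' @param trials_per_track Sentences per track (default 20).
#' @param reversals_for_srt Reversals averaged for the SRT (default 8).
#' @param retest_delta Track-difference threshold for a third track, dB
#'   (default 4).
#' @param step_init_db,step_min_db,n_step_reversals Step schedule (defaults
#'   5 dB, 1 dB, 4).
#' @return A `track_config` object.
#' @export
track_config <- function(start_snr = 0, snr_bounds = c(-15, 30),
                         trials_per_track = 20, reversals_for_srt = 8,
                         retest_delta = 4, step_init_db = 5,
                         step_min_db = 1, n_step_reversals = 4) {
  stopifnot(length(snr_bounds) == 2, snr_bounds[1] < snr_bounds[2],
            reversals_for_srt >= 2, trials_per_track >= 2,
            step_init_db > 0, step_min_db > 0, retest_delta > 0)
  structure(list(start_snr = start_snr, snr_bounds = snr_bounds,
                 trials_per_track = as.integer(trials_per_track),
                 reversals_for_srt = as.integer(reversals_for_srt),
                 retest_delta = retest_delta, step_init_db = step_init_db,
                 step_min_db = step_min_db,
                 n_step_reversals = as.integer(n_step_reversals)),
            class = "track_config")
}

#' Run one adaptive track
#'
#' Presents `trials_per_track` simulated sentences: the word score of each
#' trial is binomial around [listener_prob()], the SNR moves against the
#' score by the word-score-proportional rule, and a reversal is a sign change
#' between consecutive nonzero SNR updates. The SRT estimate is the mean
#' presented SNR at the last `reversals_for_srt` reversals; if fewer
#' reversals occurred the track is flagged under-reversed and all available
#' reversals are averaged (the track mean is used if there were none).
#'
#' @param listener A [listener_model()].
#' @param cfg A [track_config()].
#' @param seed RNG seed; fixed seed gives an identical track.
#' @return A list: `snr` (presented SNRs), `score` (words correct per
#'   trial), `reversal_snr`, `srt`, `under_reversed`, `n_reversals`.
#' @export
run_track <- function(listener, cfg = track_config(), seed = 1) {
  stopifnot(inherits(listener, "listener_model"), inherits(cfg, "track_config"))
  with_seed(seed, {
    snr <- numeric(cfg$trials_per_track)
    score <- integer(cfg$trials_per_track)
    reversal_snr <- numeric(0)
    cur <- min(max(cfg$start_snr, cfg$snr_bounds[1]), cfg$snr_bounds[2])
    step <- cfg$step_init_db
    last_sign <- 0
    n_rev <- 0L
    for (i in seq_len(cfg$trials_per_track)) {
      snr[i] <- cur
      p <- listener_prob(listener, cur)
      score[i] <- stats::rbinom(1, listener$words_per_trial, p)
      prop <- score[i] / listener$words_per_trial
      upd <- -step * (prop - 0.5) / 0.5
      s <- sign(upd)
      if (s != 0) {
        if (last_sign != 0 && s != last_sign) {
          n_rev <- n_rev + 1L
          reversal_snr <- c(reversal_snr, snr[i])
          if (n_rev <= cfg$n_step_reversals) {
            step <- max(step / 2, cfg$step_min_db)
          }
        }
        last_sign <- s
      }
      cur <- min(max(cur + upd, cfg$snr_bounds[1]), cfg$snr_bounds[2])
    }
    under <- n_rev < cfg$reversals_for_srt
    srt <- if (n_rev == 0) {
      mean(snr)
    } else {
      k <- min(cfg$reversals_for_srt, n_rev)
      mean(utils::tail(reversal_snr, k))
    }
    list(snr = snr, score = score, reversal_snr = reversal_snr, srt = srt,
         under_reversed = under, n_reversals = n_rev)
  })
}

#' Measure a final SRT from repeated adaptive tracks
#'
#' Runs two adaptive tracks and averages their SRTs. If the two estimates
#' differ by more than `cfg$retest_delta` dB, or either track under-reversed,
#' a third track is run and all three estimates are averaged.
#'
#' @param listener A [listener_model()].
#' @param cfg A [track_config()].
#' @param seed RNG seed; track k uses `seed * 10 + k`.
#' @return A list: `srt` (final estimate, dB), `track_srts`, `retested`,
#'   `retest_reason` (`"delta"`, `"under_reversed"` or `NA`), `tracks`.
#' @export
measure_srt <- function(listener, cfg = track_config(), seed = 1) {
  t1 <- run_track(listener, cfg, seed * 10 + 1)
  t2 <- run_track(listener, cfg, seed * 10 + 2)
  delta_fired <- abs(t1$srt - t2$srt) > cfg$retest_delta
  under_fired <- t1$under_reversed || t2$under_reversed
  if (delta_fired || under_fired) {
    t3 <- run_track(listener, cfg, seed * 10 + 3)
    srts <- c(t1$srt, t2$srt, t3$srt)
    tracks <- list(t1, t2, t3)
    reason <- if (delta_fired) "delta" else "under_reversed"
  } else {
    srts <- c(t1$srt, t2$srt)
    tracks <- list(t1, t2)
    reason <- NA_character_
  }
  list(srt = mean(srts), track_srts = srts,
       retested = delta_fired || under_fired, retest_reason = reason,
       tracks = tracks)
}
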