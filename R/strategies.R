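#' Maximum number of interleavable channels per stimulation cycle
#'
#' At a per-channel rate of `rate` pulses/s, one stimulation cycle lasts
#' `1e6/rate` microseconds. Each biphasic pulse occupies
#' `2*phase_us + ipg_us + overhead_us` microseconds (two phases, inter-phase
#' gap, and per-pulse scheduling overhead), so the number of channels that can
#' be stimulated sequentially within one cycle is the floor of the ratio. At
#' 900 pps with 62 us phases and an 8 us gap this yields 7 channels, which is
#' why long-phase clinical maps cannot drive a full 8-electrode montage.
#'
#' @param rate Per-channel stimulation rate, pulses/s.
#' @param phase_us Phase duration, microseconds.
#' @param ipg_us Inter-phase gap, microseconds.
#' @param overhead_us Per-pulse scheduling overhead, microseconds (default 7).
#' @return Integer channel capacity.
#' @export
max_channels_per_cycle <- function(rate, phase_us, ipg_us, overhead_us = 7) {
  stopifnot(rate > 0, phase_us > 0, ipg_us >= 0, overhead_us >= 0)
  as.integer(floor((1e6 / rate) / (2 * phase_us + ipg_us + overhead_us)))
}

#' Encode envelopes with the CIS strategy
#'
#' Continuous interleaved sampling: every active channel receives exactly one
#' pulse per stimulation cycle, with magnitude equal to the compressed band
#' envelope. Pulses are interleaved within the cycle in the map's stimulation
#' order (apex to base by default). Frames whose envelope compresses to 0
#' still emit a timing slot with magnitude 0, flagged non-stimulating.
#'
#' @param env An `envelope_frames` object from [analyze_envelopes()].
#' @param map A [channel_map()]; defaults to the map attached to `env`.
#' @param compression A [compression_config()] applied to the envelopes.
#' @param emit_zero_slots Emit magnitude-0 slots for sub-threshold frames
#'   (default `TRUE`); if `FALSE` they are dropped from the sequence.
#' @return A `pulse_sequence`.
#' @export
encode_cis <- function(env, map = env$map, compression = compression_config(),
                       emit_zero_slots = TRUE) {
  stopifnot(inherits(env, "envelope_frames"), inherits(map, "channel_map"))
  n_ch <- nrow(env$values)
  if (n_ch != length(map$electrodes)) {
    stop("envelope channel count does not match the map", call. = FALSE)
  }
  feasible <- max_channels_per_cycle(map$rate, map$phase_us, map$ipg_us,
                                     map$cycle_overhead_us)
  if (n_ch > feasible) {
    stop(sprintf(paste0(
      "CIS needs one pulse per channel per cycle but only %d of %d channels ",
      "fit; see max_channels_per_cycle()"), feasible, n_ch), call. = FALSE)
  }
  mags <- compress_lgf(env$values, compression)  # channel x frame
  build_interleaved(mags, map, env$band_table, emit_zero_slots)
}

#' Select the N largest-magnitude channels in a frame
#'
#' The N-of-M maxima selection at the heart of ACE. Ties are broken
#' deterministically in favour of the lower electrode number.
#'
#' @param magnitudes Named numeric vector (names = electrode ids) or plain
#'   vector of per-channel magnitudes.
#' @param n Number of channels to select.
#' @param electrodes Electrode ids corresponding to `magnitudes` (defaults to
#'   names or index).
#' @return Integer vector of selected electrode ids.
#' @export
select_maxima <- function(magnitudes, n, electrodes = NULL) {
  if (is.null(electrodes)) {
    electrodes <- if (!is.null(names(magnitudes))) {
      as.integer(names(magnitudes))
    } else {
      seq_along(magnitudes)
    }
  }
  if (n > length(magnitudes)) {
    stop("n exceeds the number of channels", call. = FALSE)
  }
  o <- order(-magnitudes, electrodes)
  sort(electrodes[o[seq_len(n)]])
}

#' Encode envelopes with the ACE (N-of-M) strategy
#'
#' In every stimulation cycle the `n_maxima` channels with the largest
#' envelope are selected and stimulated; unselected channels are silent. The
#' per-frame pulse count is exactly `n_maxima` (selected channels whose
#' envelope compresses to 0 emit non-stimulating slots).
#'
#' @inheritParams encode_cis
#' @param n_maxima Number of maxima; defaults to the map's `n_maxima`.
#' @return A `pulse_sequence`.
#' @export
encode_ace <- function(env, map = env$map, n_maxima = map$n_maxima,
                       compression = compression_config(),
                       emit_zero_slots = TRUE) {
  stopifnot(inherits(env, "envelope_frames"), inherits(map, "channel_map"))
  n_ch <- nrow(env$values)
  if (n_ch != length(map$electrodes)) {
    stop("envelope channel count does not match the map", call. = FALSE)
  }
  if (n_maxima > n_ch) stop("n_maxima exceeds the channel count", call. = FALSE)
  band_el <- env$band_table$electrode
  mags <- compress_lgf(env$values, compression)
  keep <- matrix(FALSE, nrow = n_ch, ncol = ncol(mags))
  for (f in seq_len(ncol(mags))) {
    sel <- select_maxima(env$values[, f], n_maxima, electrodes = band_el)
    keep[match(sel, band_el), f] <- TRUE
  }
  mags[!keep] <- NA  # NA = not selected; distinct from selected-but-zero
  build_interleaved(mags, map, env$band_table, emit_zero_slots)
}

# Shared pulse-timing construction: frame k starts at k/rate; within the
# cycle, selected channels fire in the map's stimulation order at consecutive
# slot offsets. `mags` is channel x frame; NA entries are unselected.
build_interleaved <- function(mags, map, band_table, emit_zero_slots) {
  n_frames <- ncol(mags)
  slot <- slot_seconds(map)
  frame_t <- (seq_len(n_frames) - 1) / map$rate
  # stimulation order positions for each band row
  row_el <- band_table$electrode
  stim_pos <- match(row_el, map$stim_order)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    m <- mags[, f]
    sel <- which(!is.na(m))
    if (!length(sel)) next
    sel <- sel[order(stim_pos[sel])]
    out[[f]] <- data.frame(
      time = frame_t[f] + (seq_along(sel) - 1) * slot,
      channel = row_el[sel],
      magnitude = m[sel]
    )
  }
  pulses <- do.call(rbind, out)
  if (!is.null(pulses) && !emit_zero_slots) {
    pulses <- pulses[pulses$magnitude > 0, , drop = FALSE]
  }
  make_sequence(pulses, map, validate_interleaving = FALSE)
}
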