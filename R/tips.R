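#' Temporal-integrator masking window
#'
#' The TI window `W(t)` models forward and backward masking around a probe
#' pulse at `t = 0`, where `t` is the time of a masker relative to the probe.
#' For maskers preceding the probe (`t < 0`) a double exponential with time
#' constants `tau_b1` and `tau_b2` (weight `r` on the slow tail) models
#' forward masking; for maskers at or after the probe (`t >= 0`) a single
#' exponential with time constant `tau_a` models backward masking. `W(0) = 1`
#' and the window is continuous at 0, strictly decaying on both sides, and
#' zero outside `+/- half_support`.
#'
#' @param tau_b1,tau_b2 Forward-masking time constants, seconds (defaults
#'   4.6 ms and 16.6 ms).
#' @param tau_a Backward-masking time constant, seconds (default 3.5 ms).
#' @param r Weight of the slow forward-masking tail, in [0, 1] (default 0.17).
#' @param half_support Support half-width, seconds (default 75 ms each side;
#'   the backward side is the look-ahead a causal implementation would need).
#' @param dt Sampling step for gridded evaluation, seconds; `NULL` (default)
#'   means one stimulation period of the map being processed.
#' @return A `ti_window` object.
#' @export
ti_window <- function(tau_b1 = 4.6e-3, tau_b2 = 16.6e-3, tau_a = 3.5e-3,
                      r = 0.17, half_support = 75e-3, dt = NULL) {
  stopifnot(tau_b1 > 0, tau_b2 > 0, tau_a > 0, r >= 0, r <= 1,
            half_support > 0)
  structure(list(tau_b1 = tau_b1, tau_b2 = tau_b2, tau_a = tau_a, r = r,
                 half_support = half_support, dt = dt),
            class = "ti_window")
}

#' Evaluate the TI window
#'
#' @param t Time(s) of a masker relative to the probe, seconds.
#' @param w A [ti_window()].
#' @return `W(t)`, zero outside the support.
#' @export
window_value <- function(t, w = ti_window()) {
  stopifnot(inherits(w, "ti_window"))
  v <- ifelse(t < 0,
              (1 - w$r) * exp(t / w$tau_b1) + w$r * exp(t / w$tau_b2),
              exp(-t / w$tau_a))
  # tolerant support test so grid points landing exactly on +/- half_support
  # are inside regardless of floating-point representation
  v[abs(t) > w$half_support * (1 + 1e-9)] <- 0
  v
}

#' Decision-device configuration
#'
#' Governs how the per-pulse detectability statistic is computed: the log
#' convention, the domain in which pulse contributions superpose, the floor
#' applied to the reference (pulse-removed) output before taking logs, and
#' whether pruning decisions are made against the original pattern (`batch`)
#' or the progressively pruned one (`sequential`).
#'
#' @param criterion_db Decision criterion in dB; pulses whose statistic does
#'   not exceed it are removed. `-Inf`/`+Inf` are valid sentinels.
#' @param log_mult Log multiplier: 10 (intensity-style dB, default) or 20.
#' @param domain `"intensity"` (pulse magnitudes squared before integration,
#'   default) or `"magnitude"`.
#' @param floor_eps Floor applied to the without-pulse integrator output
#'   before the log (default 1e-12).
#' @param scan_mode `"batch"` (default) or `"sequential"`.
#' @return A `decision_config` object.
#' @export
decision_config <- function(criterion_db = 1.3, log_mult = 10,
                            domain = c("intensity", "magnitude"),
                            floor_eps = 1e-12,
                            scan_mode = c("batch", "sequential")) {
  domain <- match.arg(domain)
  scan_mode <- match.arg(scan_mode)
  stopifnot(floor_eps > 0, log_mult %in% c(10, 20))
  if (is.na(criterion_db)) stop("criterion_db must not be NA", call. = FALSE)
  structure(list(criterion_db = criterion_db, log_mult = log_mult,
                 domain = domain, floor_eps = floor_eps,
                 scan_mode = scan_mode),
            class = "decision_config")
}

# magnitudes -> integration domain
to_domain <- function(mag, cfg) if (cfg$domain == "intensity") mag^2 else mag

#' Sliding temporal-integrator output of a gridded pulse train
#'
#' The integrator output at time `t` sums each pulse at time `t_p` with
#' weight `W(t_p - t)`: a pulse preceding `t` contributes through the
#' forward-masking branch of the window, a pulse after `t` through the
#' backward-masking branch. Superposition is exact in the chosen domain.
#'
#' @param train Non-negative pulse magnitudes on a regular time grid.
#' @param w A [ti_window()] with `dt` set (grid step, seconds).
#' @param domain `"intensity"` or `"magnitude"`.
#' @return A list with `values` (output on the grid extended by the window
#'   half-support on each side) and `t` (grid times, with `t = 0` at the
#'   first train sample).
#' @export
integrator_output <- function(train, w, domain = c("intensity", "magnitude")) {
  domain <- match.arg(domain)
  stopifnot(inherits(w, "ti_window"), !is.null(w$dt), all(train >= 0))
  y <- if (domain == "intensity") train^2 else train
  K <- window_half_bins(w)
  wsamp <- window_value((-K:K) * w$dt, w)
  n <- length(y)
  if (n == 0) return(list(values = numeric(0), t = numeric(0)))
  vals <- conv_correlate(y, wsamp)
  list(values = vals, t = ((1 - K):(n + K) - 1) * w$dt)
}

window_half_bins <- function(w) as.integer(floor(w$half_support / w$dt + 1e-9))

# O[g] = sum_j y[j] * wsamp[(j - g) + K + 1] for g = 1-K .. n+K, via FFT
# convolution. wsamp has length 2K+1 centered at K+1.
conv_correlate <- function(y, wsamp) {
  n <- length(y)
  K <- (length(wsamp) - 1L) %/% 2L
  if (n == 1L) return(y[1] * rev(wsamp))
  out <- stats::convolve(y, wsamp, type = "open")
  # convolve(a, b, type="open") computes sum_j a[j] b[k-j+1] with b reversed
  # relative to standard convolution, which is exactly the correlation above.
  pmax(out, 0)  # FFT round-off can leave tiny negatives
}

# Per-pulse detectability statistics for all stimulating pulses, computed
# against the full original pattern (batch semantics). Returns a data.frame
# with the row index into seq$pulses, the channel, and the statistic in dB.
# Fast path: channel pulses are snapped to a regular grid (step dt = one
# stimulation period unless the window specifies one) and the integrator
# output is obtained by a single convolution per channel.
tips_statistics <- function(seq, w = ti_window(), cfg = decision_config()) {
  stopifnot(inherits(seq, "pulse_sequence"))
  dt <- if (is.null(w$dt)) 1 / seq$map$rate else w$dt
  w$dt <- dt
  K <- window_half_bins(w)
  wsamp <- window_value((-K:K) * dt, w)
  wrev <- rev(wsamp)
  p <- seq$pulses
  stim_rows <- which(p$magnitude > 0)
  out <- vector("list", length(seq$map$electrodes))
  names(out) <- as.character(seq$map$electrodes)
  for (ch in seq$map$electrodes) {
    rows <- stim_rows[p$channel[stim_rows] == ch]
    if (!length(rows)) next
    tt <- p$time[rows]
    t0 <- tt[1]
    g <- round((tt - t0) / dt)
    snap_err <- abs((tt - t0) - g * dt)
    if (any(snap_err > dt * 1e-3)) {
      warning(sprintf(
        "channel %d: %d pulse(s) off the %.4g-ms grid by up to %.3g ms; snapped",
        ch, sum(snap_err > dt * 1e-3), dt * 1e3, max(snap_err) * 1e3))
    }
    g <- as.integer(g) + 1L
    if (anyDuplicated(g)) {
      stop(sprintf("channel %d has two pulses in the same stimulation period", ch),
           call. = FALSE)
    }
    x2 <- to_domain(p$magnitude[rows], cfg)
    y <- numeric(max(g))
    y[g] <- x2
    O <- conv_correlate(y, wsamp)         # grid g = 1-K .. max(g)+K -> index g+K
    win_len <- 2L * K + 1L
    idx <- outer(0:(2L * K), g, "+")      # columns: c-indices g .. g+2K
    Ow <- matrix(O[idx], nrow = win_len)
    contrib <- outer(wrev, x2)
    Owo <- pmax(Ow - contrib, 0)
    D <- cfg$log_mult * log10(Ow / pmax(Owo, cfg$floor_eps))
    D[Owo <= cfg$floor_eps] <- -Inf    # reference at the floor: excluded
    tD <- t(D)
    im <- max.col(tD, ties.method = "first")
    stat <- tD[cbind(seq_along(rows), im)]
    stat[stat == -Inf] <- Inf          # floored everywhere: isolated sentinel
    out[[as.character(ch)]] <- data.frame(row = rows, channel = ch, stat = stat)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(row = integer(0), channel = integer(0),
                                      stat = numeric(0))
  rownames(res) <- NULL
  res
}

#' Detectability statistic of a single pulse
#'
#' Computes the decision-device statistic for one pulse: the TI window is
#' applied to the same-channel pattern with and without the target pulse, and
#' the statistic is the maximum, over grid times within one support
#' half-width of the target, of the dB level difference between the two
#' integrator outputs. Grid points where the without-pulse output lies at or
#' below `cfg$floor_eps` carry no masking energy and are excluded from the
#' maximum; when that holds across the whole window (no other same-channel
#' pulse in range) the pulse is isolated, the statistic is `+Inf`, and the
#' pulse is unconditionally kept. A larger statistic means the pulse is more
#' detectable.
#'
#' Pulse times are used exactly; the evaluation grid is centered on the
#' target with step `w$dt` (one stimulation period if unset).
#'
#' @param seq A `pulse_sequence`.
#' @param index Row index of the target pulse in `seq$pulses`.
#' @param w A [ti_window()].
#' @param cfg A [decision_config()].
#' @return The statistic in dB (possibly `+Inf`).
#' @export
decision_statistic <- function(seq, index, w = ti_window(),
                               cfg = decision_config()) {
  stopifnot(inherits(seq, "pulse_sequence"))
  p <- seq$pulses
  if (index < 1 || index > nrow(p)) stop("pulse index out of range", call. = FALSE)
  dt <- if (is.null(w$dt)) 1 / seq$map$rate else w$dt
  w$dt <- dt
  ch_rows <- which(p$channel == p$channel[index] & p$magnitude > 0)
  statistic_exact(p$time[ch_rows], to_domain(p$magnitude[ch_rows], cfg),
                  p$time[index], to_domain(p$magnitude[index], cfg), w, cfg)
}

# Exact-time statistic: target at time t_i with domain-magnitude x2i against
# same-channel context (times tt, domain-magnitudes x2; may include the
# target itself, which is removed by position match).
statistic_exact <- function(tt, x2, t_i, x2i, w, cfg) {
  if (x2i <= 0) return(-Inf)
  K <- window_half_bins(w)
  grid <- t_i + (-K:K) * w$dt
  near <- which(abs(tt - t_i) <= 2 * w$half_support)
  tt <- tt[near]; x2 <- x2[near]
  # window weight of each context pulse at each grid time
  Wm <- outer(tt, grid, function(a, b) window_value(a - b, w))
  Ow <- as.numeric(crossprod(Wm, x2))
  is_target <- abs(tt - t_i) < w$dt * 1e-9 & x2 == x2i
  if (any(is_target)) {
    # remove one copy of the target from the reference
    j <- which(is_target)[1]
    Owo <- Ow - x2[j] * Wm[j, ]
  } else {
    Owo <- Ow
  }
  Ow_with <- Owo + x2i * window_value(t_i - grid, w)
  Owo <- pmax(Owo, 0)
  valid <- Owo > cfg$floor_eps
  if (!any(valid)) return(Inf)
  max(cfg$log_mult * log10(Ow_with[valid] / Owo[valid]))
}

#' Prune a pulse pattern with the TIPS decision device
#'
#' Every stimulating pulse is tested for detectability with
#' [decision_statistic()] and removed when its statistic does not exceed
#' `cfg$criterion_db`. In `batch` mode (default) all statistics are computed
#' against the original pattern, so decisions are order-independent; in
#' `sequential` mode pulses are scanned in time order and each statistic is
#' computed against the already-pruned pattern. Kept pulses retain their
#' original times and magnitudes; magnitude-0 timing slots pass through
#' untouched. Isolated pulses (statistic `+Inf`) are never removed.
#'
#' @param seq A `pulse_sequence`.
#' @param w A [ti_window()].
#' @param cfg A [decision_config()]; `cfg$criterion_db` is the criterion.
#' @return A list with `sequence` (the pruned `pulse_sequence`) and `report`
#'   (a `removal_report`: per-channel kept/removed counts, overall removal
#'   fraction, criterion and convention fields, and summary statistics of the
#'   per-pulse decisions).
#' @export
apply_tips <- function(seq, w = ti_window(), cfg = decision_config()) {
  stopifnot(inherits(seq, "pulse_sequence"), inherits(cfg, "decision_config"))
  p <- seq$pulses
  crit <- cfg$criterion_db
  if (cfg$scan_mode == "batch") {
    st <- tips_statistics(seq, w, cfg)
    removed_rows <- st$row[is.finite(st$stat) & st$stat <= crit]
    stats_all <- st$stat
    stat_ch <- st$channel
  } else {
    dt <- if (is.null(w$dt)) 1 / seq$map$rate else w$dt
    w$dt <- dt
    removed_rows <- integer(0)
    stats_all <- numeric(0); stat_ch <- integer(0)
    for (ch in seq$map$electrodes) {
      rows <- which(p$channel == ch & p$magnitude > 0)
      if (!length(rows)) next
      alive <- rep(TRUE, length(rows))
      for (k in seq_along(rows)) {
        ctx <- rows[alive]
        s <- statistic_exact(p$time[ctx], to_domain(p$magnitude[ctx], cfg),
                             p$time[rows[k]],
                             to_domain(p$magnitude[rows[k]], cfg), w, cfg)
        stats_all <- c(stats_all, s); stat_ch <- c(stat_ch, ch)
        if (is.finite(s) && s <= crit) alive[k] <- FALSE
      }
      removed_rows <- c(removed_rows, rows[!alive])
    }
  }
  keep_mask <- rep(TRUE, nrow(p))
  keep_mask[removed_rows] <- FALSE
  pruned <- make_sequence(p[keep_mask, , drop = FALSE], seq$map,
                          validate_interleaving = FALSE)
  stim_mask <- p$magnitude > 0
  per_ch <- data.frame(channel = seq$map$electrodes)
  per_ch$stimulating <- vapply(per_ch$channel, function(ch)
    sum(stim_mask & p$channel == ch), integer(1))
  per_ch$removed <- vapply(per_ch$channel, function(ch)
    sum(p$channel[removed_rows] == ch), integer(1))
  per_ch$kept <- per_ch$stimulating - per_ch$removed
  n_stim <- sum(stim_mask)
  report <- structure(list(
    per_channel = per_ch,
    n_stimulating = n_stim,
    n_removed = length(removed_rows),
    n_kept = n_stim - length(removed_rows),
    removal_fraction = if (n_stim) length(removed_rows) / n_stim else 0,
    criterion_db = crit,
    log_mult = cfg$log_mult, domain = cfg$domain, scan_mode = cfg$scan_mode,
    stat_summary = if (length(stats_all)) {
      fin <- stats_all[is.finite(stats_all)]
      list(n_infinite = sum(is.infinite(stats_all)),
           min = if (length(fin)) min(fin) else NA_real_,
           median = if (length(fin)) stats::median(fin) else NA_real_,
           max = if (length(fin)) max(fin) else NA_real_)
    } else NULL
  ), class = "removal_report")
  list(sequence = pruned, report = report)
}

#' @export
print.removal_report <- function(x, ...) {
  cat(sprintf("<removal_report: removed %d of %d stimulating pulses (%.1f%%) at criterion %.4g dB [%s, %s, %d*log10]>\n",
              x$n_removed, x$n_stimulating, 100 * x$removal_fraction,
              x$criterion_db, x$scan_mode, x$domain, x$log_mult))
  print(x$per_channel, row.names = FALSE)
  invisible(x)
}

#' Write a removal report as JSON
#'
#' @param report A `removal_report` from [apply_tips()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(report, path) {
  stopifnot(inherits(report, "removal_report"))
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Calibrate the decision criterion to a target removal fraction
#'
#' Inverts the criterion-to-removal-fraction map for a given pattern. In
#' `batch` mode the criterion is set to the empirical quantile of the
#' per-pulse statistics: the k-th smallest finite statistic with
#' `k = round(target_fraction * n)`, so that exactly k pulses satisfy
#' `statistic <= criterion` (up to ties). In `sequential` mode the criterion
#' is found by bisection until the achieved fraction is within 0.005 of the
#' target or 40 iterations elapse.
#'
#' @param seq A `pulse_sequence` (a warning is issued below 100 stimulating
#'   pulses).
#' @param target_fraction Desired removal fraction in [0, 1).
#' @param w A [ti_window()].
#' @param cfg A [decision_config()] fixing the convention and scan mode.
#' @return The criterion in dB.
#' @export
calibrate_criterion <- function(seq, target_fraction, w = ti_window(),
                                cfg = decision_config()) {
  stopifnot(inherits(seq, "pulse_sequence"))
  if (target_fraction < 0 || target_fraction >= 1) {
    stop("target_fraction must be in [0, 1)", call. = FALSE)
  }
  n_stim <- sum(seq$pulses$magnitude > 0)
  if (n_stim == 0) stop("sequence has no stimulating pulses", call. = FALSE)
  if (n_stim < 100) {
    warning(sprintf("only %d stimulating pulses; calibration will be coarse",
                    n_stim))
  }
  st <- tips_statistics(seq, w, cfg)
  s <- st$stat
  fin <- sort(s[is.finite(s)])
  n <- length(s)
  k <- round(target_fraction * n)
  if (k > length(fin)) {
    stop(sprintf(paste0("target unreachable: isolated pulses cannot be removed ",
                        "(%d of %d statistics are finite)"),
                 length(fin), n), call. = FALSE)
  }
  if (cfg$scan_mode == "batch") {
    if (k == 0) return(if (length(fin)) fin[1] - 1 else -Inf)
    return(fin[k])
  }
  # sequential: achieved fraction is monotone in the criterion; bisect
  lo <- fin[1] - 1
  hi <- fin[length(fin)] + 1
  achieved <- function(crit) {
    cfg$criterion_db <- crit
    apply_tips(seq, w, cfg)$report$removal_fraction
  }
  for (it in seq_len(40)) {
    mid <- (lo + hi) / 2
    a <- achieved(mid)
    if (abs(a - target_fraction) <= 0.005) return(mid)
    if (a < target_fraction) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
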