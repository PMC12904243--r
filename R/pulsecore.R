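#' Define a channel map
#'
#' A channel map describes the electrode configuration a pulse pattern is
#' built for: which electrodes are active, the per-channel stimulation rate,
#' the biphasic pulse geometry, and the per-electrode threshold (T) and
#' comfortable (C) levels in clinical current units (CU).
#'
#' Electrode numbering follows device convention: electrode 22 is the most
#' apical (lowest frequency), electrode 1 the most basal. The default
#' within-cycle stimulation order is apex to base (descending electrode
#' number); it can be overridden via `stim_order`.
#'
#' @param electrodes Integer vector of active electrode ids.
#' @param rate Per-channel stimulation rate, pulses/s.
#' @param phase_us Phase duration of the biphasic pulse, microseconds.
#' @param ipg_us Inter-phase gap, microseconds.
#' @param t_levels,c_levels Per-electrode T and C levels (CU). Scalars are
#'   recycled across electrodes.
#' @param mode Stimulation-mode label (metadata only, e.g. "MP1+2").
#' @param n_maxima Number of maxima for N-of-M selection (ACE).
#' @param band_table Optional band table as returned by
#'   [default_band_allocation()]; built on demand if `NULL`.
#' @param stim_order Electrode ids in within-cycle stimulation order; default
#'   apex to base.
#' @param cycle_overhead_us Per-pulse scheduling overhead used by the timing
#'   feasibility check, microseconds.
#' @return An object of class `channel_map`.
#' @export
channel_map <- function(electrodes, rate, phase_us, ipg_us = 8,
                        t_levels = 100, c_levels = 200, mode = "MP1+2",
                        n_maxima = length(electrodes), band_table = NULL,
                        stim_order = NULL, cycle_overhead_us = 7) {
  electrodes <- as.integer(electrodes)
  if (anyDuplicated(electrodes)) stop("duplicate electrode ids", call. = FALSE)
  stopifnot_scalar(rate); stopifnot_scalar(phase_us); stopifnot_scalar(ipg_us)
  if (rate <= 0 || phase_us <= 0 || ipg_us < 0 || cycle_overhead_us < 0) {
    stop("rate and phase_us must be > 0; ipg_us and overhead >= 0", call. = FALSE)
  }
  m <- length(electrodes)
  t_levels <- rep_len(as.numeric(t_levels), m)
  c_levels <- rep_len(as.numeric(c_levels), m)
  if (any(c_levels < t_levels)) {
    stop("c_levels must be >= t_levels for every electrode", call. = FALSE)
  }
  if (n_maxima < 1 || n_maxima > m) {
    stop("n_maxima must be between 1 and the number of electrodes", call. = FALSE)
  }
  # Feasibility binds the pulses actually scheduled per cycle: all m channels
  # for CIS (checked again by encode_cis), n_maxima for ACE.
  feasible <- max_channels_per_cycle(rate, phase_us, ipg_us, cycle_overhead_us)
  if (n_maxima > feasible) {
    stop(sprintf(paste0(
      "map schedules %d pulses per cycle but only %d fit ",
      "(rate %g pps, phase %g us, ipg %g us, overhead %g us); ",
      "see max_channels_per_cycle()"), n_maxima, feasible, rate, phase_us,
      ipg_us, cycle_overhead_us), call. = FALSE)
  }
  if (is.null(stim_order)) {
    stim_order <- sort(electrodes, decreasing = TRUE)  # apex (22) first
  } else {
    stim_order <- as.integer(stim_order)
    if (!setequal(stim_order, electrodes) || length(stim_order) != m) {
      stop("stim_order must be a permutation of electrodes", call. = FALSE)
    }
  }
  structure(list(
    electrodes = electrodes, rate = rate, phase_us = phase_us, ipg_us = ipg_us,
    t_levels = t_levels, c_levels = c_levels, mode = mode,
    n_maxima = as.integer(n_maxima), band_table = band_table,
    stim_order = stim_order, cycle_overhead_us = cycle_overhead_us
  ), class = "channel_map")
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("<channel_map: %d electrodes [%s], %g pps, phase %g us, ipg %g us, n_maxima %d, mode %s>\n",
              length(x$electrodes), paste(x$electrodes, collapse = ","),
              x$rate, x$phase_us, x$ipg_us, x$n_maxima, x$mode))
  invisible(x)
}

# Width of one pulse slot in seconds: biphasic pulse + inter-phase gap +
# scheduler overhead.
slot_seconds <- function(map) {
  (2 * map$phase_us + map$ipg_us + map$cycle_overhead_us) * 1e-6
}

#' Assemble and validate a pulse sequence
#'
#' A pulse sequence (electrodogram) is the time-ordered list of electrical
#' stimulation pulses produced by a coding strategy. Magnitudes are
#' post-compression normalized amplitudes in [0, 1]; a magnitude of exactly 0
#' marks a non-stimulating timing slot (the cycle position exists but no
#' current is delivered).
#'
#' @param pulses A data.frame with columns `time` (seconds, >= 0), `channel`
#'   (electrode id belonging to `map`), `magnitude` (in [0, 1]) and optionally
#'   `cu` (integer clinical current units).
#' @param map A [channel_map()].
#' @param validate_interleaving If `TRUE` (default), reject sequences in which
#'   pulses on distinct channels overlap in time given the pulse geometry.
#' @return An object of class `pulse_sequence`: the pulse data.frame sorted by
#'   time (ties broken by within-cycle stimulation order), with the map
#'   attached and `duration` = last pulse time + one stimulation period.
#' @export
make_sequence <- function(pulses, map, validate_interleaving = TRUE) {
  stopifnot(inherits(map, "channel_map"))
  if (is.null(pulses) || nrow(as.data.frame(pulses)) == 0L) {
    pulses <- data.frame(time = numeric(0), channel = integer(0),
                         magnitude = numeric(0), cu = integer(0))
    return(structure(list(pulses = pulses, map = map, duration = 0),
                     class = "pulse_sequence"))
  }
  pulses <- as.data.frame(pulses)
  required <- c("time", "channel", "magnitude")
  missing_cols <- setdiff(required, names(pulses))
  if (length(missing_cols)) {
    stop("pulses is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"cu" %in% names(pulses)) pulses$cu <- NA_integer_
  if (any(!is.finite(pulses$time)) || any(pulses$time < 0)) {
    stop("pulse times must be finite and >= 0", call. = FALSE)
  }
  bad_mag <- which(!is.finite(pulses$magnitude) |
                     pulses$magnitude < 0 | pulses$magnitude > 1)
  if (length(bad_mag)) {
    stop(sprintf("pulse %d has magnitude %g outside [0, 1]",
                 bad_mag[1], pulses$magnitude[bad_mag[1]]), call. = FALSE)
  }
  unknown <- setdiff(unique(pulses$channel), map$electrodes)
  if (length(unknown)) {
    stop("pulse channel(s) not in map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ord_rank <- match(pulses$channel, map$stim_order)
  o <- order(pulses$time, ord_rank)
  pulses <- pulses[o, , drop = FALSE]
  rownames(pulses) <- NULL
  seq_out <- structure(
    list(pulses = pulses, map = map,
         duration = max(pulses$time) + 1 / map$rate),
    class = "pulse_sequence")
  if (validate_interleaving) validate_sequence(seq_out)
  seq_out
}

#' Validate the interleaving constraint of a pulse sequence
#'
#' Consecutive pulses on distinct channels must be separated by at least the
#' biphasic pulse width (2*phase + inter-phase gap); equal-time pulses on
#' distinct channels always violate it. Errors on the first violation.
#'
#' @param seq A `pulse_sequence`.
#' @return `seq`, invisibly.
#' @export
validate_sequence <- function(seq) {
  p <- seq$pulses
  if (nrow(p) < 2L) return(invisible(seq))
  width <- (2 * seq$map$phase_us + seq$map$ipg_us) * 1e-6
  gap <- diff(p$time)
  distinct <- p$channel[-1L] != p$channel[-nrow(p)]
  bad <- which(distinct & gap < width - 1e-12)
  if (length(bad)) {
    stop(sprintf(paste0(
      "interleaving violation: pulses at %.6f s (channel %d) and %.6f s ",
      "(channel %d) overlap given pulse width %.1f us"),
      p$time[bad[1]], p$channel[bad[1]],
      p$time[bad[1] + 1], p$channel[bad[1] + 1], width * 1e6), call. = FALSE)
  }
  invisible(seq)
}

#' @export
print.pulse_sequence <- function(x, ...) {
  n_stim <- sum(x$pulses$magnitude > 0)
  cat(sprintf("<pulse_sequence: %d pulses (%d stimulating) on %d channels, %.3f s>\n",
              nrow(x$pulses), n_stim, length(unique(x$pulses$channel)),
              x$duration))
  invisible(x)
}

#' Read a channel map from a YAML configuration file
#'
#' The file carries the [channel_map()] fields (`electrodes`, `rate`,
#' `phase_us`, `ipg_us`, `t_levels`, `c_levels`, `mode`, `n_maxima`,
#' optionally `stim_order` and `cycle_overhead_us`).
#'
#' @param path Path to the YAML file.
#' @return A [channel_map()].
#' @export
read_channel_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("electrodes", "rate", "phase_us")
  missing_f <- setdiff(required, names(cfg))
  if (length(missing_f)) {
    stop("map config is missing fields: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  args <- cfg[intersect(names(cfg), names(formals(channel_map)))]
  do.call(channel_map, args)
}

#' Map a normalized magnitude onto the clinical dynamic range
#'
#' Linear interpolation between the threshold (T) and comfortable (C) level,
#' rounded to an integer clinical current unit: magnitude 0 maps to T, 1 to C.
#'
#' @param magnitude Normalized magnitude(s) in [0, 1].
#' @param t_level,c_level T and C levels in CU; `c_level >= t_level`.
#' @return Integer CU level(s).
#' @export
to_cu <- function(magnitude, t_level, c_level) {
  if (any(c_level < t_level)) {
    stop("c_level must be >= t_level", call. = FALSE)
  }
  if (any(magnitude < 0 | magnitude > 1)) {
    stop("magnitude must be in [0, 1]", call. = FALSE)
  }
  as.integer(round(t_level + magnitude * (c_level - t_level)))
}

#' Per-channel and total pulse counts
#'
#' Counts refer to stimulating pulses (magnitude > 0) by default; magnitude-0
#' timing slots are structural and carry no charge.
#'
#' @param seq A `pulse_sequence`.
#' @param stimulating_only Count only pulses with magnitude > 0 (default).
#' @return A list with `per_channel` (named integer vector over the map's
#'   electrodes) and `total`.
#' @export
pulse_counts <- function(seq, stimulating_only = TRUE) {
  stopifnot(inherits(seq, "pulse_sequence"))
  p <- seq$pulses
  if (stimulating_only) p <- p[p$magnitude > 0, , drop = FALSE]
  per <- table(factor(p$channel, levels = seq$map$electrodes))
  per <- stats::setNames(as.integer(per), names(per))
  list(per_channel = per, total = sum(per))
}

#' Write an electrodogram to a TSV file
#'
#' One pulse per row with columns `time_us` (integer microseconds), `channel`,
#' `magnitude` (6 decimal places) and `cu`; `#`-prefixed metadata lines carry
#' the map parameters needed to rebuild the sequence. The round trip through
#' [read_electrodogram()] is lossless at this resolution.
#'
#' @param seq A `pulse_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_electrodogram <- function(seq, path) {
  stopifnot(inherits(seq, "pulse_sequence"))
  m <- seq$map
  meta <- c(
    sprintf("# rate\t%.10g", m$rate),
    sprintf("# phase_us\t%.10g", m$phase_us),
    sprintf("# ipg_us\t%.10g", m$ipg_us),
    sprintf("# cycle_overhead_us\t%.10g", m$cycle_overhead_us),
    sprintf("# mode\t%s", m$mode),
    sprintf("# n_maxima\t%d", m$n_maxima),
    sprintf("# electrodes\t%s", paste(m$electrodes, collapse = ",")),
    sprintf("# stim_order\t%s", paste(m$stim_order, collapse = ",")),
    sprintf("# t_levels\t%s", paste(format(m$t_levels, digits = 10), collapse = ",")),
    sprintf("# c_levels\t%s", paste(format(m$c_levels, digits = 10), collapse = ","))
  )
  p <- seq$pulses
  rows <- sprintf("%d\t%d\t%.6f\t%s",
                  as.integer(round(p$time * 1e6)), p$channel, p$magnitude,
                  ifelse(is.na(p$cu), "NA", as.character(p$cu)))
  writeLines(c(meta, "time_us\tchannel\tmagnitude\tcu", rows), path)
  invisible(path)
}

#' Read an electrodogram TSV file
#'
#' @param path Path written by [write_electrodogram()].
#' @param map Optional [channel_map()]; if `NULL`, rebuilt from the file's
#'   metadata lines.
#' @return A `pulse_sequence`.
#' @export
read_electrodogram <- function(path, map = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L || !grepl("^time_us\t", body[1])) {
    stop("electrodogram file has no header line", call. = FALSE)
  }
  if (is.null(map)) {
    kv <- strsplit(sub("^#\\s*", "", meta_lines), "\t")
    meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    num_list <- function(s) as.numeric(strsplit(s, ",")[[1]])
    map <- channel_map(
      electrodes = as.integer(num_list(meta[["electrodes"]])),
      rate = as.numeric(meta[["rate"]]),
      phase_us = as.numeric(meta[["phase_us"]]),
      ipg_us = as.numeric(meta[["ipg_us"]]),
      t_levels = num_list(meta[["t_levels"]]),
      c_levels = num_list(meta[["c_levels"]]),
      mode = meta[["mode"]],
      n_maxima = as.integer(meta[["n_maxima"]]),
      stim_order = as.integer(num_list(meta[["stim_order"]])),
      cycle_overhead_us = as.numeric(meta[["cycle_overhead_us"]])
    )
  }
  rows <- body[-1L]
  if (length(rows) == 0L) return(make_sequence(NULL, map))
  parts <- strsplit(rows, "\t")
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    stop(sprintf("parse error at line %d: expected 4 tab-separated fields",
                 which(nf != 4L)[1] + length(meta_lines) + 1L), call. = FALSE)
  }
  fields <- do.call(rbind, parts)
  time_us <- suppressWarnings(as.numeric(fields[, 1]))
  if (anyNA(time_us)) {
    stop(sprintf("parse error at line %d: non-numeric time field",
                 which(is.na(time_us))[1] + length(meta_lines) + 1L),
         call. = FALSE)
  }
  cu <- suppressWarnings(as.integer(fields[, 4]))
  make_sequence(data.frame(
    time = time_us * 1e-6,
    channel = as.integer(fields[, 2]),
    magnitude = as.numeric(fields[, 3]),
    cu = cu
  ), map)
}
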