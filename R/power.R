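#' Power-model configuration
#'
#' The implant power model: a fixed fraction of total device power (default
#' 90%) is delivered to the RF coil and scales linearly with the stimulation
#' level; the remainder keeps the implant electronics running and is
#' unaffected by the coding strategy. One clinical current unit corresponds
#' to a 0.157 dB step in charge: the device current step is a factor of
#' `100^(1/255)` per CU, i.e. exactly `40/255` dB (0.156863, usually quoted
#' rounded to 0.157). The exact value is the default so that integer-CU
#' arithmetic reproduces printed charge percentages at two decimals.
#'
#' @param coil_fraction Fraction of total power allocated to the RF coil,
#'   in (0, 1] (default 0.9).
#' @param cu_step_db dB of charge per clinical current unit (default
#'   `40/255`).
#' @return A `power_model_config` object.
#' @export
power_model_config <- function(coil_fraction = 0.9, cu_step_db = 40 / 255) {
  stopifnot(coil_fraction > 0, coil_fraction <= 1, cu_step_db > 0)
  structure(list(coil_fraction = coil_fraction, cu_step_db = cu_step_db),
            class = "power_model_config")
}

#' Linear charge ratio of a clinical-current-unit step
#'
#' A change of `n_cu` clinical current units corresponds to a linear charge
#' ratio of `10^(n_cu * cu_step_db / 20)`; e.g. +14 CU is a +28.77% charge
#' increase.
#'
#' @param n_cu Number of CU steps (may be negative or fractional).
#' @param cfg A [power_model_config()].
#' @return A list with `ratio` (linear) and `percent` (percentage change,
#'   `100 * (ratio - 1)`, rounded half-up to 2 decimals).
#' @export
cu_ratio <- function(n_cu, cfg = power_model_config()) {
  ratio <- 10^(n_cu * cfg$cu_step_db / 20)
  list(ratio = ratio, percent = round_half_up(100 * (ratio - 1), 2))
}

#' Net power saving from pulse removal and charge change
#'
#' With a fraction `fraction_kept` of stimulation pulses retained and a
#' fractional per-pulse charge change `delta_q` (e.g. 0.0557 for a +5.57%
#' global C-level increase), the coil power scales to
#' `fraction_kept * (1 + delta_q)` of its baseline, and the net device-level
#' saving is `coil_fraction * (1 - fraction_kept * (1 + delta_q))` of total
#' power.
#'
#' @param fraction_kept Fraction of pulses retained, in (0, 1].
#' @param delta_q Fractional charge change; `1 + delta_q` must be positive.
#' @param cfg A [power_model_config()].
#' @param digits Decimals for the reported percentage (default 2, half-up;
#'   `NULL` for the raw value).
#' @return Net power saving as a percentage of total device power.
#' @export
net_power_saving <- function(fraction_kept, delta_q,
                             cfg = power_model_config(), digits = 2) {
  stopifnot(all(fraction_kept > 0), all(fraction_kept <= 1),
            all(1 + delta_q > 0))
  pct <- cfg$coil_fraction * (1 - fraction_kept * (1 + delta_q)) * 100
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Published charge-increase percentages for the three TIPS conditions
#'
#' Per-participant charge increases of the global C-level (percent) required
#' to restore comfortable loudness after TIPS, for the three strategy
#' conditions: TIPS removing 50% of pulses from a CIS baseline, and TIPS
#' removing 33% (one third) or 50% of pulses from an ACE baseline. `NA` marks
#' participants not tested in a condition.
#'
#' @return A data.frame with columns `id`, `cis_tips50`, `ace_tips33`,
#'   `ace_tips50`.
#' @export
table2_charges <- function() {
  data.frame(
    id = c("C27", "C30", "C37", "C39", "C40", "C41", "C42", "C43",
           "C44", "C45", "C50", "C51", "C52", "C53", "C54", "C55"),
    cis_tips50 = c(0.00, 0.00, 1.82, 11.44, NA, NA, NA, 15.54,
                   0.00, 13.48, 5.57, 3.68, 1.82, NA, 3.68, 15.54),
    ace_tips33 = c(5.57, NA, 5.57, 28.77, 11.44, 5.57, 15.54, 5.57,
                   7.49, 33.50, 13.48, NA, -3.55, 28.77, NA, NA),
    ace_tips50 = c(11.44, NA, 7.49, 43.50, 19.79, 21.98, 51.49, 9.45,
                   11.44, 46.12, 26.46, NA, 7.49, 48.78, NA, NA)
  )
}

#' Per-participant power savings from printed charge columns
#'
#' Applies [net_power_saving()] row-wise to per-participant charge-increase
#' percentages for the three TIPS conditions (pulse fractions kept 0.5, 2/3
#' and 0.5 respectively) and reports per-row savings plus column averages
#' over the available rows. The one-third condition uses a retained fraction
#' of exactly 2/3.
#'
#' @param charges A data.frame as returned by [table2_charges()] (the
#'   default): columns `cis_tips50`, `ace_tips33`, `ace_tips50` holding
#'   charge-change percentages, `NA` for missing entries.
#' @param cfg A [power_model_config()].
#' @return A list with `rows` (data.frame of per-participant savings, %) and
#'   `averages` (named vector of column means, rounded half-up to 2
#'   decimals).
#' @export
table2_report <- function(charges = table2_charges(),
                          cfg = power_model_config()) {
  cols <- c(cis_tips50 = 0.5, ace_tips33 = 2 / 3, ace_tips50 = 0.5)
  missing_cols <- setdiff(names(cols), names(charges))
  if (length(missing_cols)) {
    stop("charges is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (cn in names(cols)) {
    v <- charges[[cn]]
    if (!is.numeric(v)) stop("non-numeric charge entries in ", cn, call. = FALSE)
    if (any(is.finite(v) & (1 + v / 100) <= 0)) {
      stop("charge decrease of 100% or more in ", cn, call. = FALSE)
    }
  }
  rows <- data.frame(id = charges$id)
  for (cn in names(cols)) {
    v <- charges[[cn]]
    out <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    out[ok] <- net_power_saving(cols[[cn]], v[ok] / 100, cfg)
    rows[[paste0("power_", cn)]] <- out
  }
  averages <- vapply(names(cols), function(cn)
    round_half_up(mean(rows[[paste0("power_", cn)]], na.rm = TRUE), 2),
    numeric(1))
  names(averages) <- names(cols)
  list(rows = rows, averages = averages)
}
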