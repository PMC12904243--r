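# Shared fixtures and independent oracles. The oracles re-derive expected
# behaviour with plain loops and inline formulas so they share no code path
# with the package internals they check.

rms <- function(x) sqrt(mean(x^2))

fix_map8 <- function(rate = 900, phase_us = 25, ipg_us = 8) {
  channel_map(electrodes = c(6, 8, 10, 12, 14, 16, 18, 20), rate = rate,
              phase_us = phase_us, ipg_us = ipg_us)
}

fix_map1 <- function(rate = 10000) {
  channel_map(electrodes = 1L, rate = rate, phase_us = 20, ipg_us = 8,
              cycle_overhead_us = 2)
}

# Brute-force decision statistic: loops over the evaluation grid, window
# formula written out inline (intensity domain, 10*log10, floor 1e-12).
oracle_statistic <- function(times, mags, target, dt,
                             hs = 0.075, eps = 1e-12) {
  wfun <- function(t) {
    if (abs(t) > hs) return(0)
    if (t < 0) 0.83 * exp(t / 0.0046) + 0.17 * exp(t / 0.0166)
    else exp(-t / 0.0035)
  }
  t_i <- times[target]
  K <- floor(hs / dt + 1e-9)
  best <- -Inf
  any_valid <- FALSE
  for (k in -K:K) {
    tg <- t_i + k * dt
    ow <- 0
    for (j in seq_along(times)) ow <- ow + mags[j]^2 * wfun(times[j] - tg)
    owo <- ow - mags[target]^2 * wfun(t_i - tg)
    if (owo < 0) owo <- 0
    if (owo > eps) {
      any_valid <- TRUE
      d <- 10 * log10(ow / owo)
      if (d > best) best <- d
    }
  }
  if (!any_valid) Inf else best
}

# Brute-force batch pruning of a single-channel pulse set: statistic of every
# pulse against the original pattern, removed iff finite and <= criterion.
oracle_prune <- function(times, mags, criterion, dt) {
  keep <- logical(length(times))
  for (i in seq_along(times)) {
    s <- oracle_statistic(times, mags, i, dt)
    keep[i] <- !(is.finite(s) && s <= criterion)
  }
  keep
}

# A short CIS-encoded speech-shaped stimulus used by several TIPS tests.
fix_cis_sequence <- function(duration = 1, seed = 42) {
  a <- gen_ssn(noise_spec("SSN", seed = seed), duration = duration)
  a <- pre_emphasize(normalize_rms(a, -20))
  encode_cis(analyze_envelopes(a, fix_map8()))
}
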