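test_that("TI window matches its closed form and decays from a peak of 1", {
  w <- ti_window()
  expect_equal(window_value(0, w), 1)
  expect_equal(window_value(3.5e-3, w), exp(-1), tolerance = 1e-12)
  expect_equal(window_value(-4.6e-3, w),
               0.83 * exp(-1) + 0.17 * exp(-4.6 / 16.6), tolerance = 1e-12)
  # continuity at 0 and strict decay away from it, on a dense grid
  tneg <- seq(-75e-3, -1e-6, length.out = 4000)
  tpos <- seq(1e-6, 75e-3, length.out = 4000)
  expect_equal(window_value(-1e-9, w), 1, tolerance = 1e-6)
  expect_true(all(diff(window_value(tneg, w)) > 0))
  expect_true(all(diff(window_value(tpos, w)) < 0))
  vals <- window_value(c(tneg, 0, tpos), w)
  expect_true(all(vals > 0 & vals <= 1))
  expect_equal(window_value(c(-0.0751, 0.0751, 1), w), c(0, 0, 0))
})

test_that("integrator output superposes shifted window copies exactly", {
  w <- ti_window(dt = 1e-3)
  z <- integrator_output(numeric(50), w)
  expect_true(all(z$values == 0))

  one <- numeric(50); one[20] <- 1
  out <- integrator_output(one, w, domain = "magnitude")
  # pulse at grid 20 (t = 19 ms): output(t) = W(t_p - t)
  expect_equal(out$values, window_value(19e-3 - out$t, w), tolerance = 1e-9)

  two <- numeric(50); two[20] <- 0.7; two[26] <- 0.4
  o2 <- integrator_output(two, w, domain = "magnitude")
  ref <- 0.7 * window_value(19e-3 - o2$t, w) + 0.4 * window_value(25e-3 - o2$t, w)
  expect_equal(o2$values, ref, tolerance = 1e-9)

  # intensity domain squares before integrating
  oi <- integrator_output(two, w, domain = "intensity")
  refi <- 0.49 * window_value(19e-3 - oi$t, w) + 0.16 * window_value(25e-3 - oi$t, w)
  expect_equal(oi$values, refi, tolerance = 1e-9)
})

test_that("decision statistic reproduces brute-force masking increments", {
  map <- fix_map1()
  w <- ti_window(dt = 1e-4)
  # weak pulse 1.1 ms after a strong masker: masked (~0.053 dB)
  s <- make_sequence(data.frame(time = c(0.2, 0.2011), channel = 1L,
                                magnitude = c(1, 0.1)), map)
  got <- decision_statistic(s, 2, w)
  oracle <- oracle_statistic(s$pulses$time, s$pulses$magnitude, 2, dt = 1e-4)
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(got, 0.0531, tolerance = 1e-3)
  expect_lt(got, 1.3)

  # equal pulse 1.1 ms after an equal masker: detectable (~3.48 dB)
  s2 <- make_sequence(data.frame(time = c(0.2, 0.2011), channel = 1L,
                                 magnitude = c(1, 1)), map)
  got2 <- decision_statistic(s2, 2, w)
  expect_equal(got2, oracle_statistic(s2$pulses$time, s2$pulses$magnitude, 2,
                                      dt = 1e-4), tolerance = 1e-9)
  expect_equal(got2, 3.48, tolerance = 1e-2)
  expect_gt(got2, 1.3)

  # isolated pulse: floor-limited everywhere -> +Inf sentinel
  iso <- make_sequence(data.frame(time = 0.2, channel = 1L, magnitude = 0.5), map)
  expect_identical(decision_statistic(iso, 1, w), Inf)
  expect_error(decision_statistic(iso, 5, w), "out of range")
})

test_that("batch pruning matches the brute-force oracle on small sequences", {
  map <- fix_map1(rate = 1000)   # dt = 1 ms grid
  w <- ti_window(dt = 1e-3)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    times <- 0.1 + sort(sample(0:60, n)) * 1e-3
    mags <- round(runif(n, 0.05, 1), 3)
    s <- make_sequence(data.frame(time = times, channel = 1L, magnitude = mags),
                       map)
    for (crit in c(0.5, 1.3, 3)) {
      res <- apply_tips(s, w, decision_config(criterion_db = crit))
      keep_oracle <- oracle_prune(s$pulses$time, s$pulses$magnitude, crit,
                                  dt = 1e-3)
      expect_equal(res$sequence$pulses$time, s$pulses$time[keep_oracle],
                   info = sprintf("rep %d crit %.2f", rep, crit))
    }
  }
})

test_that("pruning is a pure subset operation with boundary criteria", {
  s <- fix_cis_sequence(duration = 0.5)
  res_all <- apply_tips(s, cfg = decision_config(criterion_db = -Inf))
  expect_equal(res_all$sequence$pulses, s$pulses)
  expect_equal(res_all$report$removal_fraction, 0)

  res_none <- apply_tips(s, cfg = decision_config(criterion_db = Inf))
  kept <- res_none$sequence$pulses
  # only isolated-pulse sentinels (and non-stimulating slots) survive
  expect_true(all(kept$magnitude == 0 |
                    vapply(which(kept$magnitude > 0), function(i)
                      is.infinite(decision_statistic(res_none$sequence, i)),
                      logical(1))))

  res_mid <- apply_tips(s, cfg = decision_config(criterion_db = 1))
  key <- function(p) paste(round(p$time * 1e9), p$channel)
  expect_true(all(key(res_mid$sequence$pulses) %in% key(s$pulses)))
  expect_equal(res_mid$sequence$pulses$magnitude,
               s$pulses$magnitude[match(key(res_mid$sequence$pulses),
                                        key(s$pulses))])
})

test_that("removal fraction is monotone in the criterion", {
  s <- fix_cis_sequence(duration = 0.5)
  crits <- c(-1, 0, 0.5, 1, 1.5, 3, 6)
  fr <- vapply(crits, function(cr)
    apply_tips(s, cfg = decision_config(criterion_db = cr))$report$removal_fraction,
    numeric(1))
  expect_true(all(diff(fr) >= 0))

  # sequential mode, empirically on small random sequences
  map <- fix_map1(rate = 1000)
  w <- ti_window(dt = 1e-3)
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    s2 <- make_sequence(data.frame(
      time = 0.1 + sort(sample(0:50, n)) * 1e-3, channel = 1L,
      magnitude = round(runif(n, 0.05, 1), 3)), map)
    fr2 <- vapply(c(0.5, 1.5, 3), function(cr)
      apply_tips(s2, w, decision_config(criterion_db = cr,
                                        scan_mode = "sequential"))$report$removal_fraction,
      numeric(1))
    expect_true(all(diff(fr2) >= -1e-12))
  }
})

test_that("batch decisions are order- and other-channel-independent", {
  map <- channel_map(c(1L, 2L), rate = 1000, phase_us = 20, ipg_us = 8,
                     cycle_overhead_us = 2)
  w <- ti_window(dt = 1e-3)
  set.seed(13)
  df <- data.frame(
    time = rep(0.1 + (0:29) * 1e-3, 2) + rep(c(0, 5e-4), each = 30),
    channel = rep(c(1L, 2L), each = 30),
    magnitude = round(runif(60, 0.05, 1), 3))
  s <- make_sequence(df, map, validate_interleaving = FALSE)
  cfg <- decision_config(criterion_db = 1.3)
  base <- apply_tips(s, w, cfg)

  # permutation invariance: shuffled input rows give the identical result
  s_shuf <- make_sequence(df[sample(nrow(df)), ], map,
                          validate_interleaving = FALSE)
  shuf <- apply_tips(s_shuf, w, cfg)
  expect_equal(shuf$sequence$pulses, base$sequence$pulses)

  # channel independence: rewriting channel 2 leaves channel 1 untouched
  df2 <- df
  df2$magnitude[df2$channel == 2L] <-
    round(runif(30, 0.05, 1), 3)
  alt <- apply_tips(make_sequence(df2, map, validate_interleaving = FALSE),
                    w, cfg)
  ch1 <- function(r) {
    p <- r$sequence$pulses[r$sequence$pulses$channel == 1L, ]
    rownames(p) <- NULL
    p
  }
  expect_equal(ch1(alt), ch1(base))
})

test_that("decisions are invariant to per-channel magnitude scaling", {
  map <- fix_map1(rate = 1000)
  w <- ti_window(dt = 1e-3)
  set.seed(5)
  times <- 0.1 + sort(sample(0:40, 8)) * 1e-3
  mags <- round(runif(8, 0.1, 0.9), 3)
  s1 <- make_sequence(data.frame(time = times, channel = 1L, magnitude = mags), map)
  s2 <- make_sequence(data.frame(time = times, channel = 1L, magnitude = mags / 2), map)
  st1 <- vapply(1:8, function(i) decision_statistic(s1, i, w), numeric(1))
  st2 <- vapply(1:8, function(i) decision_statistic(s2, i, w), numeric(1))
  expect_equal(st1, st2, tolerance = 1e-9)
})

test_that("criterion calibration achieves the target removal fraction", {
  s <- fix_cis_sequence(duration = 1)
  n <- pulse_counts(s)$total

  crit0 <- suppressWarnings(calibrate_criterion(s, 0))
  expect_equal(apply_tips(s, cfg = decision_config(criterion_db = crit0))$report$removal_fraction, 0)

  crit50 <- calibrate_criterion(s, 0.5)
  res <- apply_tips(s, cfg = decision_config(criterion_db = crit50))
  expect_lte(abs(res$report$removal_fraction - 0.5), 1 / n)
  # removed count equals half the baseline, within one pulse
  expect_lte(abs(pulse_counts(res$sequence)$total - n / 2), 1)

  crit33 <- calibrate_criterion(s, 1 / 3)
  expect_lte(crit33, crit50)

  # an all-isolated pattern cannot reach any positive removal target
  iso <- make_sequence(data.frame(time = seq(0, 1.8, by = 0.2), channel = 6L,
                                  magnitude = 0.5), fix_map8())
  expect_error(suppressWarnings(calibrate_criterion(iso, 0.5)),
               "target unreachable")
  expect_error(calibrate_criterion(s, 1.2), "target_fraction")
})

test_that("sequential calibration bisects to the target", {
  map <- fix_map1(rate = 1000)
  w <- ti_window(dt = 1e-3)
  set.seed(21)
  s <- make_sequence(data.frame(
    time = 0.1 + (0:199) * 1e-3, channel = 1L,
    magnitude = round(runif(200, 0.05, 1), 3)), map)
  cfg <- decision_config(scan_mode = "sequential")
  crit <- calibrate_criterion(s, 0.4, w, cfg)
  cfg$criterion_db <- crit
  achieved <- apply_tips(s, w, cfg)$report$removal_fraction
  expect_lte(abs(achieved - 0.4), 0.01)
})

test_that("removal reports are internally consistent and serializable", {
  s <- fix_cis_sequence(duration = 0.5)
  res <- apply_tips(s, cfg = decision_config(criterion_db = 1))
  rep <- res$report
  expect_equal(rep$n_kept + rep$n_removed, rep$n_stimulating)
  expect_equal(sum(rep$per_channel$kept), rep$n_kept)
  expect_equal(sum(rep$per_channel$removed), rep$n_removed)
  expect_gte(rep$removal_fraction, 0)
  expect_lte(rep$removal_fraction, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_removal_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_stimulating, rep$n_stimulating)
  expect_equal(length(parsed$per_channel), 8)
})
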