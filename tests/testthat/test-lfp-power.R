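test_that("bandpass passes the band, kills DC and out-of-band tones", {
  rate <- 5000
  t <- seq_len(2 * rate) / rate
  inband <- bandpass(lfp_trace(sin(2 * pi * 60 * t), rate))
  mid <- 2000:8000
  expect_gt(max(abs(inband$samples[mid])), 0.95)   # within 5% of unit input
  low <- bandpass(lfp_trace(sin(2 * pi * 5 * t), rate))
  expect_lt(max(abs(low$samples[mid])), 0.01)      # < 1% residual
  hi <- bandpass(lfp_trace(sin(2 * pi * 500 * t), rate))
  expect_lt(max(abs(hi$samples[mid])), 0.01)       # >= 40 dB attenuation
  dc <- bandpass(lfp_trace(rep(10, rate), rate))
  expect_lt(abs(mean(dc$samples)), 0.05)  # 10 uV offset -> < 0.5% residual
  expect_equal(length(inband$samples), length(t))  # same length
  expect_error(bandpass(lfp_trace(rnorm(100), 100), band = c(30, 95)),
               "Nyquist")
})

test_that("sliding_log_rms matches closed forms and the window count", {
  rate <- 5000
  s <- sliding_log_rms(lfp_trace(rep(2, rate), rate))
  expect_equal(unique(round(s$log_power, 12)), log10(2))
  # sine of amplitude A over whole cycles: RMS = A / sqrt(2)
  t <- seq_len(rate) / rate
  s2 <- sliding_log_rms(lfp_trace(3 * sin(2 * pi * 40 * t), rate))
  expect_equal(mean(10^s2$log_power), 3 / sqrt(2), tolerance = 1e-3)
  # frozen window count: floor((50000 - 1250) / 250) + 1 = 196
  s3 <- sliding_log_rms(lfp_trace(rnorm(50000), rate))
  expect_length(s3$times, 196L)
  expect_equal(unique(round(diff(s3$times), 10)), 0.05)
  expect_error(sliding_log_rms(lfp_trace(rnorm(100), rate)), "shorter")
  expect_error(sliding_log_rms(lfp_trace(rnorm(5000), rate),
                               window = 0.01, step = 0.05), "exceed")
})

test_that("trim fit: degenerate input, determinism, SD monotonicity", {
  expect_error(trim_gaussian_fit(rep(1, 100)), "zero variance")
  withr::local_seed(3)
  x <- c(rnorm(5000), rnorm(300, 8, 0.3))
  f1 <- trim_gaussian_fit(x)
  f2 <- trim_gaussian_fit(x)
  expect_identical(f1, f2)                      # no randomness
  expect_true(all(diff(f1$sd_trace) <= 1e-12))  # trim only shrinks SD
  expect_gt(f1$n_iterations, 0L)
  # robust variant also isolates the bulk
  fr <- trim_gaussian_fit(x, robust = TRUE)
  expect_lt(abs(fr$mean), 0.1)
})

test_that("fit_power_modes recovers a planted mixture and flags empty SM", {
  withr::local_seed(5)
  lp <- c(rnorm(9500), rnorm(500, 6, 0.5))   # 95% bulk + 5% high mode
  s <- as_band_power(lp)
  f <- fit_power_modes(s)
  # closed-form oracle: the SM is every original sample beyond the bulk's
  # mean + 2 SD, i.e. the whole planted mode plus the bulk's >2sigma tail
  # (mean excess dnorm(2)/pnorm(-2) = 2.373), not the planted mode alone
  tail_p <- pnorm(2, lower.tail = FALSE)
  excess <- dnorm(2) / tail_p
  delta_oracle <- (0.05 * 6 + 0.95 * tail_p * excess) /
    (0.05 + 0.95 * tail_p)                              # = 4.905
  n_sm_oracle <- 10000 * (0.05 + 0.95 * tail_p)         # = 716
  expect_lt(abs(f$delta_sm_mm - delta_oracle) / delta_oracle, 0.05)
  expect_lt(abs(f$n_sm - n_sm_oracle), 80)
  expect_false(f$sm_empty)
  expect_true(all(lp[f$sm_indices] > f$threshold))
  expect_gt(f$delta_sm_mm, 2 * f$mm_sd)                 # SM beyond threshold
  # identical input -> bit-identical metrics
  expect_identical(mode_metrics(fit_power_modes(s)), mode_metrics(f))
  # a sample with no tail: SM empty, delta reported 0 with flag
  # symmetric truncated-normal quantiles: max sample < mean + 2 sd
  lp0 <- qnorm(seq(0.1, 0.9, length.out = 201))
  f0 <- fit_power_modes(as_band_power(lp0))
  expect_true(f0$sm_empty)
  expect_equal(f0$delta_sm_mm, 0)
  expect_equal(mode_metrics(f0)$sm_count, 0L)
  expect_error(fit_power_modes(as_band_power(rnorm(10))), "at least 50")
})

test_that("null calibration: pure Gaussian series keep mm honest", {
  # small-n version of the acceptance check (criterion-scale run lives in
  # test-acceptance.R)
  withr::local_seed(17)
  fits <- replicate(30, {
    f <- fit_power_modes(as_band_power(rnorm(5000)))
    c(f$mm_mean, f$n_sm / 5000)
  })
  expect_lt(abs(mean(fits[1, ])), 0.05)
  expect_gt(mean(fits[2, ]), 0.01)
  expect_lt(mean(fits[2, ]), 0.04)
})

test_that("planted high bursts leave the MM and drive delta upward", {
  withr::local_seed(23)
  base <- rnorm(8000)
  f_base <- fit_power_modes(as_band_power(base))
  tail_p <- pnorm(2, lower.tail = FALSE)
  excess <- dnorm(2) / tail_p
  deltas <- c(3, 6, 10)
  got <- vapply(deltas, function(delta) {
    lp <- c(base, rnorm(160, delta, 0.2))
    f <- fit_power_modes(as_band_power(lp))
    # exact agreement with the independently coded naive procedure
    orc <- oracle_trim_modes(lp)
    expect_equal(f$delta_sm_mm, orc$delta, tolerance = 1e-10)
    expect_equal(f$mm_mean, orc$mm_mean, tolerance = 1e-10)
    expect_equal(f$n_sm, orc$n_sm)
    # bursts displace the Main Mode at most marginally (at moderate delta
    # the burst-inflated first threshold truncates the bulk and the trim
    # walks a little further; see the methods vignette)
    expect_lt(abs(f$mm_mean - f_base$mm_mean), 0.1)
    # coarse closed-form check: SM mixes bursts with the bulk tail
    closed <- (160 * delta + 8000 * tail_p * excess) /
      (160 + 8000 * tail_p)
    expect_lt(abs(f$delta_sm_mm - closed) / closed, 0.25)
    f$delta_sm_mm
  }, numeric(1))
  expect_true(all(diff(got) > 0))  # monotone in the planted excess
})

test_that("detect_events finds threshold upcrossings with separation", {
  lp <- rep(0, 400)
  lp[c(50:60, 70:75, 200:210)] <- 5
  s <- as_band_power(lp, times = seq_along(lp) * 0.05)
  fit <- structure(list(threshold = 2.5), class = "power_mode_fit")
  ev <- detect_events(fit, s, min_separation = 2)
  expect_equal(ev, c(50, 200) * 0.05)  # 70 suppressed by separation
  ev2 <- detect_events(fit, s, min_separation = 0.5)
  expect_length(ev2, 3L)
})
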