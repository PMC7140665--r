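test_that("gen_lfp is deterministic and self-calibrated", {
  g1 <- gen_lfp(duration = 30, burst_spec = list(n = 2, duration = 2,
                                                 delta = 1), seed = 9)
  g2 <- gen_lfp(duration = 30, burst_spec = list(n = 2, duration = 2,
                                                 delta = 1), seed = 9)
  expect_identical(g1$trace$samples, g2$trace$samples)
  expect_identical(g1$gt, g2$gt)
  g3 <- gen_lfp(duration = 30, burst_spec = list(n = 2, duration = 2,
                                                 delta = 1), seed = 10)
  expect_false(identical(g1$trace$samples, g3$trace$samples))
  # planted band-power excess within 5% of the request
  g <- gen_lfp(duration = 120, burst_spec = list(n = 4, duration = 5,
                                                 delta = 1), seed = 3)
  s <- sliding_log_rms(bandpass(g$trace))
  inb <- rep(FALSE, length(s$times))
  for (i in seq_along(g$gt$burst_onsets))
    inb <- inb | (s$times > g$gt$burst_onsets[i] + 0.3 &
                    s$times < g$gt$burst_onsets[i] +
                    g$gt$burst_durations[i] - 0.3)
  excess <- mean(s$log_power[inb]) - median(s$log_power[!inb])
  expect_lt(abs(excess - 1), 0.05)
  expect_error(gen_lfp(duration = 5), ">= 10")
  expect_error(gen_lfp(duration = 20,
                       burst_spec = list(n = 50, duration = 2)),
               "non-overlapping")
})

test_that("movement artifacts add no band power (WT-like null)", {
  g <- gen_lfp(duration = 120, burst_spec = list(n = 0),
               artifact_spec = list(n = 8, duration = 1.5, amplitude = 100),
               seed = 13)
  f <- fit_power_modes(sliding_log_rms(bandpass(g$trace)))
  # SM fraction stays at the pure-noise null (~2.3%), delta stays small
  expect_lt(f$n_sm / 2396, 0.04)
  expect_lt(f$delta_sm_mm, 0.35)
  expect_gt(max(abs(g$trace$samples)), 90)  # artifacts are in the raw trace
})

test_that("gen_movie plants retrievable structure", {
  lfp <- gen_lfp(duration = 80, burst_spec = list(n = 3, duration = 1,
                                                  delta = 1), seed = 15)
  m1 <- gen_movie(dims = c(48L, 48L), frames = 320L,
                  neuron_spec = list(n_ep = 6L, n_pre = 3L, n_silent = 3L),
                  lfp_gt = lfp$gt, seed = 16)
  m2 <- gen_movie(dims = c(48L, 48L), frames = 320L,
                  neuron_spec = list(n_ep = 6L, n_pre = 3L, n_silent = 3L),
                  lfp_gt = lfp$gt, seed = 16)
  expect_identical(m1$stack$pixels, m2$stack$pixels)
  expect_equal(nrow(m1$gt$centers), 12L)
  expect_equal(sum(m1$gt$classes == "pre_ep"), 3L)
  # pre-Ep neurons sit anterior (smaller y) to the Ep cohort
  expect_lt(max(m1$gt$centers$y[m1$gt$classes == "pre_ep"]),
            min(m1$gt$centers$y[m1$gt$classes == "ep"]))
  expect_error(gen_movie(dims = c(16L, 16L)), "32")
  expect_error(gen_movie(frames = 50L), "200")
  expect_error(gen_movie(dims = c(48L, 48L), frames = 300L, lfp_gt = lfp$gt,
                         dt_pre = 100), "inter-burst")
})

test_that("planted domains land in their region and classify there", {
  lfp <- gen_lfp(duration = 100, burst_spec = list(n = 4, duration = 1,
                                                   delta = 1.2), seed = 17)
  mov <- gen_movie(dims = c(64L, 64L), frames = 400L,
                   neuron_spec = list(n_ep = 0L, n_pre = 0L, n_silent = 0L),
                   domain_spec = list(n = 4, volume = c(350, 450),
                                      duration = c(8L, 10L), region = "Cb",
                                      at_bursts = TRUE, amplitude_snr = 5),
                   lfp_gt = lfp$gt, snr = 5, seed = 18)
  expect_gte(length(mov$gt$domains), 4L)
  for (d in mov$gt$domains) {
    labs <- mov$atlas$labels[cbind(((d$pixels_raw - 1) %% 64) + 1,
                                   ((d$pixels_raw - 1) %/% 64) + 1)]
    expect_true(all(labs == mov$atlas$names[["Cb"]]))
    expect_equal(d$volume, d$area_analysis * (d$t_end - d$t_start + 1))
  }
  # pipeline recovers and classifies them in the cerebellum
  dff <- compute_dff(preprocess(mov$stack, bin = 1))
  cl <- find_clusters(binarize(dff))
  tab <- classify_by_region(cl, mov$atlas, min_volume = 300)
  expect_gte(tab$count[tab$region == "Cb"], 4L)
  expect_equal(sum(tab$count[tab$region %in% c("OT", "MOb", "outside")]), 0L)
})

test_that("Ep-only movies leave the pre-Ep slot undefined", {
  lfp <- gen_lfp(duration = 150, burst_spec = list(n = 6, duration = 1,
                                                   delta = 1.2), seed = 19)
  mov <- gen_movie(dims = c(64L, 64L), frames = 600L,
                   neuron_spec = list(n_ep = 15L, n_pre = 0L,
                                      n_silent = 10L),
                   lfp_gt = lfp$gt, snr = 5, seed = 20)
  dff <- compute_dff(preprocess(mov$stack, bin = 1))
  power <- align_power(sliding_log_rms(bandpass(lfp$trace)),
                       frame_times_of(600))
  suppressMessages(rois <- extract_traces(dff, mov$gt$centers, radius = 3))
  pca <- run_pca(rois, n_pc = 10, power = power)
  cls <- select_components(pca, power)
  expect_false(cls$pre_ep_defined)
})

test_that("condition presets produce their stated contrasts", {
  ptz <- gen_condition_suite("PTZ", seed = 29)
  mo <- gen_condition_suite("MO", seed = 29)
  wt <- gen_condition_suite("WT", seed = 29)
  # ground truth: PTZ reaches the near-global event, MO never does
  ptz_max <- max(vapply(ptz$gt$domains, function(d) d$volume, numeric(1)))
  mo_max <- max(vapply(mo$gt$domains, function(d) d$volume, numeric(1)))
  expect_gt(length(ptz$gt$global_event$pixels) * 20, ptz_max)
  expect_gt(ptz_max + length(ptz$gt$global_event$pixels) * 20, mo_max)
  expect_null(mo$gt$global_event)
  # WT plants nothing above the 300-voxel classification cutoff
  expect_lt(max(vapply(wt$gt$domains, function(d) d$volume, numeric(1))),
            300)
  expect_length(wt$gt$burst_onsets, 0L)
  expect_gt(length(wt$gt$artifact_onsets), 0L)
  expect_s3_class(ptz$bundle, "recording_bundle")
  expect_error(gen_condition_suite("XX"), "arg")
})
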