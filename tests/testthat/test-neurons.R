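# small helper: an image with planted donut cells at given centers
plant_cells <- function(centers, dims = c(64, 64), radius = 3,
                        baseline = 100, contrast = 40) {
  img <- matrix(baseline, dims[1], dims[2])
  for (i in seq_len(nrow(centers))) {
    p <- epifish:::donut_profile(centers$y[i], centers$x[i], radius, dims)
    img[p$idx] <- img[p$idx] + contrast * p$w
  }
  img
}

test_that("donut templates are zero-sum with a bright ring and dim core", {
  for (sz in c(7, 10)) {
    w <- donut_template(sz)
    expect_equal(sum(w), 0, tolerance = 1e-12)
    c0 <- (sz + 1) / 2
    expect_lt(w[round(c0), round(c0)], 0)          # hole below the mean
    expect_gt(w[round(c0), round(c0 + 0.25 * sz)], 0)  # ring above
  }
})

test_that("detect_neurons finds planted cells and respects exclusion", {
  expect_equal(nrow(detect_neurons(matrix(100, 64, 64))), 0L)  # blank
  centers <- data.frame(y = c(15, 15, 40, 48), x = c(12, 40, 25, 50))
  det <- detect_neurons(plant_cells(centers), score_threshold = 0.3)
  expect_equal(nrow(det), 4L)
  d <- as.matrix(dist(rbind(as.matrix(centers[, c("y", "x")]),
                            as.matrix(det[, c("y", "x")]))))[1:4, 4 + 1:4]
  expect_lt(max(apply(d, 1, min)), 1.01)
  # two cells 2 px apart with min_distance 5 -> a single detection
  near <- data.frame(y = c(30, 30), x = c(30, 32))
  det2 <- detect_neurons(plant_cells(near), min_distance = 5)
  expect_equal(sum(det2$y > 25 & det2$y < 35), 1L)
})

test_that("detection at SNR 5 on a noisy stack stays precise", {
  withr::local_seed(97)
  centers <- data.frame(y = c(10, 10, 25, 25, 40, 52),
                        x = c(10, 40, 20, 50, 35, 12))
  img <- plant_cells(centers, contrast = 50)
  stack <- fluorescence_stack(
    array(rnorm(64 * 64 * 30, img, 10), c(64, 64, 30)), 4)
  det <- detect_neurons(stack)
  d <- as.matrix(dist(rbind(as.matrix(centers[, c("y", "x")]),
                            as.matrix(det[, c("y", "x")]))))[
                              seq_len(6), 6 + seq_len(nrow(det))]
  expect_gte(mean(apply(d, 1, min) <= 1.01), 5 / 6)   # recall
  expect_gte(mean(apply(d, 2, min) <= 1.01), 5 / 6)   # precision
})

test_that("extract_traces averages the discrete disk and drops edge ROIs", {
  nT <- 5
  a <- array(rep(seq_len(nT), each = 64), c(8, 8, nT)) * 0.1
  d <- as_dff(a)
  suppressMessages(
    rois <- extract_traces(d, data.frame(x = c(4, 1), y = c(4, 4)),
                           radius = 3))
  expect_equal(attr(rois, "dropped"), 2L)            # edge ROI reported
  expect_equal(dim(rois$traces), c(nT, 1L))
  expect_equal(rois$traces[, 1], seq_len(nT) * 0.1)  # uniform frame value
  expect_equal(nrow(epifish:::disk_offsets(3)), 29L) # 29-pixel disk
  expect_error(extract_traces(d, data.frame(x = numeric(0), y = numeric(0))),
               "empty")
})

test_that("run_pca normalizes, orders variance, reconstructs", {
  withr::local_seed(101)
  nT <- 400
  shared <- rnorm(nT)
  X <- sapply(1:12, function(i) shared * runif(1, 0.5, 2) + 0.01 * rnorm(nT))
  p <- run_pca(X, n_pc = 5)
  expect_gt(p$var_frac[1], 0.99)                      # rank-1 data
  expect_true(all(diff(p$var_frac) <= 1e-12))
  expect_lte(sum(p$var_frac), 1 + 1e-8)
  # two orthogonal equal-power cohorts -> two ~50% components
  s1 <- sin(2 * pi * seq_len(nT) / 40); s2 <- cos(2 * pi * seq_len(nT) / 40)
  X2 <- cbind(sapply(1:10, function(i) s1 + 0.01 * rnorm(nT)),
              sapply(1:10, function(i) s2 + 0.01 * rnorm(nT)))
  p2 <- run_pca(X2, n_pc = 5)
  expect_equal(p2$var_frac[1:2], c(0.5, 0.5), tolerance = 0.02)
  # full reconstruction from all components of standardized data
  Xs <- scale(X2)
  pr <- run_pca(X2, n_pc = ncol(X2))
  expect_equal(pr$scores %*% t(pr$loadings), unclass(Xs),
               ignore_attr = TRUE, tolerance = 1e-8)
  # sign fixing leaves variance fractions untouched
  pw <- as_aligned(s1)
  p3 <- run_pca(X2, n_pc = 5, power = pw)
  expect_equal(p3$var_frac, p2$var_frac)
  expect_error(run_pca(X[, 1:3], n_pc = 5), "fewer usable")
  X[, 1] <- 5
  expect_message(run_pca(X, n_pc = 5), "zero-variance")
})

test_that("select_components finds Ep and pre-Ep, flags degenerate cases", {
  withr::local_seed(103)
  nT <- 800
  events <- seq(60, nT - 60, by = 80)
  kern <- function(ev) {
    tr <- numeric(nT); tr[ev] <- 1
    as.numeric(stats::filter(tr, exp(-1 / 6), method = "recursive"))
  }
  power_v <- kern(events) + 0.05 * rnorm(nT)
  ep_sig <- kern(events)
  pre_sig <- kern(events - 8)
  X <- cbind(sapply(1:12, function(i) ep_sig + 0.2 * rnorm(nT)),
             sapply(1:6, function(i) pre_sig + 0.2 * rnorm(nT)),
             sapply(1:6, function(i) rnorm(nT)))
  pw <- as_aligned(power_v)
  pca <- run_pca(X, n_pc = 8, power = pw)
  cls <- select_components(pca, pw)
  expect_true(cls$pre_ep_defined)
  expect_false(cls$ep_pc == cls$pre_ep_pc)
  expect_lte(abs(cls$correlograms[[cls$ep_pc]]$lag[
    which.max(cls$correlograms[[cls$ep_pc]]$r)]), 1)
  expect_lte(abs(cls$pre_ep_peak_lag - (-8)), 2)
  # single-population data: pre-Ep undefined
  X1 <- cbind(sapply(1:12, function(i) ep_sig + 0.2 * rnorm(nT)),
              sapply(1:8, function(i) rnorm(nT)))
  cls1 <- select_components(run_pca(X1, n_pc = 8, power = pw), pw)
  expect_false(cls1$pre_ep_defined)
  expect_true(is.na(cls1$pre_ep_pc))
})

test_that("event_correlograms average per-event windows", {
  withr::local_seed(107)
  nT <- 1000
  events_f <- c(200, 400, 600, 800)
  kern <- function(ev) {
    tr <- numeric(nT); tr[ev[ev >= 1]] <- 1
    as.numeric(stats::filter(tr, exp(-1 / 6), method = "recursive"))
  }
  pw_v <- kern(events_f)
  pw <- as_aligned(pw_v)             # frame times at 4 Hz
  X <- cbind(sapply(1:8, function(i) kern(events_f) + 0.1 * rnorm(nT)),
             sapply(1:4, function(i) kern(events_f - 8) + 0.1 * rnorm(nT)))
  pca <- run_pca(X, n_pc = 6, power = pw)
  cls <- select_components(pca, pw)
  ev_times <- pw$frame_times[events_f]
  ec <- event_correlograms(cls, pca, pw, ev_times, window = 25)
  expect_equal(ec$n_events, 4L)
  expect_lte(abs(ec$lags[which.max(ec$ep)]), 1)
  expect_lte(abs(ec$lags[which.max(ec$pre_ep)] + 8), 2)
  # a window overrunning the recording is truncated and flagged
  ec2 <- event_correlograms(cls, pca, pw, pw$frame_times[c(30, 400)],
                            window = 25)
  expect_true(ec2$truncated)
  expect_error(event_correlograms(cls, pca, pw, numeric(0)), "no events")
})

test_that("loading_maps normalizes, prunes and profiles by axis", {
  loadings <- cbind(c(0.8, 0.4, -0.2, 0.1, 0.3),
                    c(0.1, 0.05, 0.5, 0.25, 0.29))
  pca <- structure(list(loadings = loadings, scores = NULL,
                        var_frac = c(0.5, 0.3), kept = 1:5, n_pc = 2L),
                   class = "pca_decomposition")
  cls <- structure(list(ep_pc = 1L, pre_ep_pc = 2L, pre_ep_defined = TRUE),
                   class = "ep_classification")
  centers <- data.frame(x = c(5, 6, 7, 8, 9), y = c(10, 20, 30, 40, 25))
  mp <- loading_maps(pca, cls, centers, both_threshold = 0.5, n_bins = 4,
                     dims = c(40, 12))
  expect_equal(max(mp$ep$normalized), 1)              # Eq.-style max = 1
  expect_false(3 %in% mp$ep$neuron)                   # negative removed
  # neuron 5: 0.3/0.8 = 0.375 and 0.29/0.5 = 0.58 -> not dual at 0.5+
  expect_true(5 %in% mp$ep$neuron && 5 %in% mp$pre_ep$neuron)
  # with a stricter dual threshold neuron 5 is removed from both
  mp2 <- loading_maps(pca, cls, centers, both_threshold = 0.37, n_bins = 4,
                      dims = c(40, 12))
  expect_equal(mp2$removed_both, 5L)
  expect_false(5 %in% mp2$ep$neuron || 5 %in% mp2$pre_ep$neuron)
  expect_equal(sum(mp$profile$ep), sum(mp$ep$normalized))
})

test_that("collective maps max-project and register translated fish", {
  mk_map <- function(cx, cy) {
    structure(list(
      ep = data.frame(x = cx, y = cy, normalized = 1, neuron = 1L),
      pre_ep = data.frame(x = numeric(0), y = numeric(0),
                          normalized = numeric(0), neuron = integer(0)),
      profile = NULL, removed_both = integer(0), axis = "y",
      dims = c(48L, 48L), empty = c(ep = FALSE, pre_ep = TRUE)),
      class = "loading_maps")
  }
  m1 <- mk_map(20, 20)
  # identity, single fish: collective equals the rasterized per-fish map
  cm <- collective_map(list(m1))
  expect_equal(cm$ep, epifish:::loading_map_image(m1$ep, c(48, 48), 3))
  # disjoint hotspots both survive the max projection
  cm2 <- collective_map(list(m1, mk_map(35, 35)))
  expect_equal(cm2$ep[20, 20], 1)
  expect_equal(cm2$ep[35, 35], 1)
  # translated copies realign under moment-based similarity registration
  ref_mask <- matrix(0, 48, 48); ref_mask[10:40, 8:30] <- 1
  sh_mask <- matrix(0, 48, 48); sh_mask[16:46, 16:38] <- 1   # +6, +8 shift
  m_ref <- mk_map(15, 20)
  m_sh <- mk_map(15 + 8, 20 + 6)
  cm3 <- collective_map(list(m_ref, m_sh), masks = list(ref_mask, sh_mask),
                        reference_mask = ref_mask,
                        registration = "similarity")
  hot <- which(cm3$ep == max(cm3$ep), arr.ind = TRUE)
  expect_lte(abs(mean(hot[, "row"]) - 20), 2)
  expect_lte(abs(mean(hot[, "col"]) - 15), 2)
  expect_lte(sum(cm3$ep > 0.5), 2 * sum(epifish:::loading_map_image(
    m_ref$ep, c(48, 48), 3) > 0.5))
  expect_error(collective_map(list(m1), reference_mask = matrix(1, 10, 10)),
               "grid mismatch")
})
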