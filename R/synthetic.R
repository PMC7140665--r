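# Synthetic paired LFP + calcium recordings with full ground truth.
# The generator emulates the statistical structure the analysis is built
# to detect: band-limited high-frequency discharges riding on 1/f-like
# background, movement artifacts without high-frequency content,
# contiguous calcium domains locked to the discharges, and two neuronal
# cohorts (one coincident with the bursts, one leading them).

#' Generate a synthetic LFP trace with planted discharges
#'
#' Background is 1/f-shaped Gaussian noise. Each burst is a 30-95 Hz
#' band-limited noise packet whose band RMS exceeds the background band
#' RMS by `delta` log10 units (so the windowed log-power during a burst
#' sits `delta` above the Main Mode). Optional movement-like artifacts are
#' smooth low-frequency half-sine transients carrying no added power in
#' the analysis band. Burst placements are rejection-sampled to be
#' non-overlapping; an over-constrained request fails with an error.
#'
#' @param duration recording length in seconds (>= 10).
#' @param rate sampling rate in Hz (default 5000).
#' @param burst_spec list: `n` bursts, `duration` (s) each, `delta`
#'   (log10 band-RMS excess), `band` (Hz).
#' @param artifact_spec optional list: `n`, `duration` (s), `amplitude`
#'   (microvolts).
#' @param noise_spec list: `sd` (microvolts), `one_over_f` (logical).
#' @param seed RNG seed (generation is fully reproducible).
#' @return list with `trace` ([lfp_trace]) and `gt` (ground truth:
#'   `burst_onsets`, `burst_durations` (s), `delta`, `artifact_onsets`,
#'   `band_sigma`, `seed`).
#' @export
gen_lfp <- function(duration = 300, rate = 5000,
                    burst_spec = list(n = 12L, duration = 5, delta = 1,
                                      band = c(30, 95)),
                    artifact_spec = NULL,
                    noise_spec = list(sd = 10, one_over_f = TRUE),
                    seed = 1L) {
  if (duration < 10) stop2("gen_lfp: duration must be >= 10 s")
  bs <- utils::modifyList(list(n = 12L, duration = 5, delta = 1,
                               band = c(30, 95)), as.list(burst_spec))
  ns <- utils::modifyList(list(sd = 10, one_over_f = TRUE),
                          as.list(noise_spec))
  with_seed(seed, {
    n <- round(duration * rate)
    x <- stats::rnorm(n)
    if (isTRUE(ns$one_over_f)) {
      nfft <- stats::nextn(n, 2L)
      X <- stats::fft(c(x, rep(0, nfft - n)))
      f <- pmin(0:(nfft - 1L), nfft - 0:(nfft - 1L)) * rate / nfft
      shape <- 1 / sqrt(pmax(f, 1))  # flat below 1 Hz, 1/f above
      x <- Re(stats::fft(X * shape, inverse = TRUE))[seq_len(n)] / nfft
    }
    x <- x / stats::sd(x) * ns$sd
    # band RMS of the background, measured exactly as the analysis will
    band_sigma <- sqrt(mean(bandpass(lfp_trace(x, rate),
                                     band = bs$band)$samples^2))
    place <- function(n_ev, dur, margin = 2) {
      onsets <- numeric(0)
      tries <- 0L
      while (length(onsets) < n_ev) {
        cand <- stats::runif(1, margin, duration - dur - margin)
        if (all(abs(cand - onsets) >= dur + 1)) onsets <- c(onsets, cand)
        tries <- tries + 1L
        if (tries > 10000L)
          stop2("gen_lfp: cannot place ", n_ev,
                " non-overlapping events (overlapping bursts rejected)")
      }
      sort(onsets)
    }
    burst_onsets <- if (bs$n > 0) place(bs$n, bs$duration) else numeric(0)
    for (t0 in burst_onsets) {
      i0 <- round(t0 * rate); nb <- round(bs$duration * rate)
      packet <- bandpass(lfp_trace(stats::rnorm(nb + 2000), rate),
                         band = bs$band)$samples[1001:(1000 + nb)]
      env <- rep(1, nb)
      ramp <- round(0.05 * nb)
      env[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
      env[(nb - ramp + 1):nb] <- seq(1, 0, length.out = ramp)
      packet <- packet * env
      target_rms <- band_sigma * sqrt(10^(2 * bs$delta) - 1)
      # calibrate against the packet's RMS after the *analysis* band-pass,
      # which the packet will traverse a second time
      refiltered <- bandpass(lfp_trace(packet, rate), band = bs$band)$samples
      packet <- packet * target_rms / sqrt(mean(refiltered^2))
      x[(i0 + 1):(i0 + nb)] <- x[(i0 + 1):(i0 + nb)] + packet
    }
    artifact_onsets <- numeric(0)
    if (!is.null(artifact_spec)) {
      as_ <- utils::modifyList(list(n = 5L, duration = 1.5, amplitude = 80),
                               as.list(artifact_spec))
      artifact_onsets <- place(as_$n, as_$duration)
      if (length(burst_onsets) > 0)
        artifact_onsets <- artifact_onsets[
          vapply(artifact_onsets, function(a)
            all(abs(a - burst_onsets) > bs$duration + as_$duration),
            logical(1))]
      for (t0 in artifact_onsets) {
        i0 <- round(t0 * rate); na <- round(as_$duration * rate)
        x[(i0 + 1):(i0 + na)] <- x[(i0 + 1):(i0 + na)] +
          as_$amplitude * sin(pi * seq_len(na) / na)
      }
    }
    list(trace = lfp_trace(x, rate),
         gt = list(burst_onsets = burst_onsets,
                   burst_durations = rep(bs$duration, length(burst_onsets)),
                   delta = bs$delta, band = bs$band,
                   artifact_onsets = artifact_onsets,
                   band_sigma = band_sigma, seed = seed))
  })
}

#' Three-band anatomical atlas on an elliptical brain mask
#'
#' Rostro-caudal (top-to-bottom) division of an elliptical "brain" into
#' optic tectum (OT), cerebellum (Cb) and medulla oblongata (MOb);
#' label 0 outside the brain.
#'
#' @param dims image dimensions (rows, cols).
#' @return list with `atlas` (a `region_atlas`) and `mask` (logical brain
#'   mask).
#' @export
make_atlas <- function(dims) {
  h <- dims[1]; w <- dims[2]
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  inside <- ((g$y - h / 2) / (0.45 * h))^2 +
    ((g$x - w / 2) / (0.42 * w))^2 <= 1
  lab <- integer(h * w)
  band <- cut(g$y, breaks = c(0, h * 0.4, h * 0.65, h + 1), labels = FALSE)
  lab[inside] <- band[inside]
  list(atlas = region_atlas(matrix(lab, h, w)),
       mask = matrix(inside, h, w))
}

# one donut intensity profile centered at (cy, cx); returns index/weight
donut_profile <- function(cy, cx, outer_r, dims) {
  offs <- disk_offsets(outer_r)
  ys <- cy + offs$dy; xs <- cx + offs$dx
  ok <- ys >= 1 & ys <= dims[1] & xs >= 1 & xs <= dims[2]
  r <- sqrt(offs$dy^2 + offs$dx^2)[ok]
  w <- ifelse(r > 0.4 * outer_r, 1, 0.35) * (1 - (r / outer_r)^2 * 0.3)
  list(idx = (xs[ok] - 1L) * dims[1] + ys[ok], w = w)
}

# impulse train -> instant-rise, exponential-decay transient trace
gcamp_trace <- function(frames, event_frames, amplitudes, tau_frames) {
  tr <- numeric(frames)
  ok <- event_frames >= 1 & event_frames <= frames
  tr[event_frames[ok]] <- tr[event_frames[ok]] + amplitudes[ok]
  as.numeric(stats::filter(tr, exp(-1 / tau_frames), method = "recursive"))
}

# grow a random 4-connected blob of `area` pixels within `allowed`
# (linear indices on an h x w grid), starting from a random seed pixel
grow_blob <- function(area, allowed, h, w) {
  seed_px <- sample(allowed, 1L)
  blob <- seed_px
  frontier <- seed_px
  allowed_set <- logical(h * w)
  allowed_set[allowed] <- TRUE
  in_blob <- logical(h * w)
  in_blob[seed_px] <- TRUE
  while (length(blob) < area && length(frontier) > 0) {
    fy <- ((frontier - 1L) %% h) + 1L
    fx <- ((frontier - 1L) %/% h) + 1L
    nb <- c(ifelse(fy > 1, frontier - 1L, NA),
            ifelse(fy < h, frontier + 1L, NA),
            ifelse(fx > 1, frontier - h, NA),
            ifelse(fx < w, frontier + h, NA))
    nb <- unique(nb[!is.na(nb)])
    nb <- nb[allowed_set[nb] & !in_blob[nb]]
    if (length(nb) == 0L) {
      if (length(frontier) == length(blob)) break  # fully jammed
      frontier <- blob  # retry from the whole boundary
      next
    }
    nb <- sample(nb)
    add <- nb[seq_len(min(length(nb), area - length(blob)))]
    blob <- c(blob, add)
    in_blob[add] <- TRUE
    frontier <- add
  }
  blob
}

#' Generate a synthetic calcium movie paired with an LFP ground truth
#'
#' Produces a raw-count fluorescence stack: an elliptical brain with
#' donut-shaped neurons on a baseline, plus contiguous activity domains.
#' Ep neurons emit GCaMP-like transients (instant rise, exponential decay
#' `tau` seconds) at each LFP burst onset; pre-Ep neurons lead the bursts
#' by `dt_pre` seconds; silent neurons fire sparse random transients.
#' Domain events are sustained plateaus occupying exactly their recorded
#' voxel set (a sustained population discharge), so their ground-truth
#' volume is well defined. Shot noise is approximated as Gaussian with
#' variance proportional to the mean; `snr` is the peak dff amplitude
#' over the per-pixel dff noise SD on this (raw) grid. Optional motion
#' events rigidly shift whole frames.
#'
#' When the movie is destined for a `bin x bin` analysis grid, set
#' `domain_spec$grid_bin`: domains are then unions of full bin blocks and
#' their ground-truth `volume` is counted in analysis-grid voxels.
#'
#' @param dims (rows, cols) of the generated grid (>= 32 each).
#' @param frames number of frames (>= 200).
#' @param frame_rate imaging rate in Hz (default 4).
#' @param neuron_spec list: `n_ep`, `n_pre`, `n_silent`, `radius` (px,
#'   default 3), `contrast` (donut brightness relative to baseline).
#' @param domain_spec NULL or list: `n` events, `volume` range (voxels on
#'   the analysis grid), `duration` range (frames), `region` name,
#'   `at_bursts` (lock onsets to LFP bursts), `at_motion` (lock onsets to
#'   motion events), `amplitude_snr`, `grid_bin`.
#' @param lfp_gt ground truth from [gen_lfp] (burst onsets drive events).
#' @param dt_pre pre-Ep lead time in seconds (must fit the inter-burst
#'   interval).
#' @param snr peak dff over raw-pixel dff noise SD.
#' @param tau GCaMP decay constant in seconds (default 1.5).
#' @param baseline baseline brain fluorescence in counts.
#' @param dark_level constant dark signal added to every pixel.
#' @param motion_spec NULL or list: `n` events, `displacement` c(dy, dx)
#'   px, `duration` frames.
#' @param seed RNG seed.
#' @return list with `stack` (`fluorescence_stack`), `atlas`
#'   (`region_atlas` on this grid), `mask` (brain mask), and `gt`
#'   (neuron centers/classes, burst frames, per-event domain records,
#'   motion frames, amplitudes, seed).
#' @export
gen_movie <- function(dims = c(64L, 64L), frames = 800L, frame_rate = 4,
                      neuron_spec = list(n_ep = 20L, n_pre = 8L,
                                         n_silent = 12L, radius = 3L,
                                         contrast = 0.4),
                      domain_spec = NULL, lfp_gt = NULL, dt_pre = 2,
                      snr = 5, tau = 1.5, baseline = 100, dark_level = 10,
                      motion_spec = NULL, seed = 1L) {
  if (any(dims < 32L)) stop2("gen_movie: dims must be >= 32 x 32")
  if (frames < 200L) stop2("gen_movie: need >= 200 frames")
  nspec <- utils::modifyList(list(n_ep = 20L, n_pre = 8L, n_silent = 12L,
                                  radius = 3L, contrast = 0.4),
                             as.list(neuron_spec))
  burst_frames <- integer(0)
  if (!is.null(lfp_gt) && length(lfp_gt$burst_onsets) > 0) {
    burst_frames <- pmax(1L, as.integer(round(lfp_gt$burst_onsets *
                                                frame_rate)))
    if (length(burst_frames) > 1 &&
        dt_pre >= min(diff(sort(lfp_gt$burst_onsets))))
      stop2("gen_movie: dt_pre exceeds the inter-burst interval")
  }
  with_seed(seed, {
    reg <- make_atlas(dims)
    npx <- dims[1] * dims[2]
    g <- expand.grid(y = seq_len(dims[1]), x = seq_len(dims[2]))
    # baseline image: bright brain with a gentle gradient, dim surround
    base <- ifelse(as.vector(reg$mask),
                   baseline * (1 + 0.1 * (g$x / dims[2] - 0.5)), 2)
    # --- neurons: pre-Ep cohort anterior (small y), Ep posterior ---------
    n_neur <- nspec$n_ep + nspec$n_pre + nspec$n_silent
    centers <- data.frame(y = integer(0), x = integer(0))
    classes <- character(0)
    if (n_neur > 0) {
      margin <- nspec$radius + 2L
      cand <- which(as.vector(reg$mask) &
                      g$y > margin & g$y < dims[1] - margin &
                      g$x > margin & g$x < dims[2] - margin)
      min_sep2 <- (2 * nspec$radius + 1)^2
      tries <- 0L
      while (nrow(centers) < n_neur && tries < 100000L) {
        i <- sample(cand, 1L)
        yy <- g$y[i]; xx <- g$x[i]
        if (nrow(centers) == 0L ||
            all((centers$y - yy)^2 + (centers$x - xx)^2 >= min_sep2))
          centers <- rbind(centers, data.frame(y = yy, x = xx))
        tries <- tries + 1L
      }
      if (nrow(centers) < n_neur)
        stop2("gen_movie: could not place ", n_neur, " neurons in ",
              dims[1], "x", dims[2])
      centers <- centers[order(centers$y, centers$x), , drop = FALSE]
      rownames(centers) <- NULL
      classes <- rep("silent", n_neur)
      if (nspec$n_pre > 0) classes[seq_len(nspec$n_pre)] <- "pre_ep"
      if (nspec$n_ep > 0)
        classes[nspec$n_pre + seq_len(nspec$n_ep)] <- "ep"
    }
    profs <- lapply(seq_len(n_neur), function(i)
      donut_profile(centers$y[i], centers$x[i], nspec$radius, dims))
    for (i in seq_len(n_neur))
      base[profs[[i]]$idx] <- base[profs[[i]]$idx] +
        baseline * nspec$contrast * profs[[i]]$w
    noise_scale <- 1
    sigma_dff <- noise_scale / sqrt(baseline)
    A <- snr * sigma_dff  # peak dff amplitude
    tau_frames <- tau * frame_rate
    dt_pre_frames <- as.integer(round(dt_pre * frame_rate))
    S <- matrix(0, npx, frames)  # dff-scale signal
    for (i in seq_len(n_neur)) {
      ev <- switch(classes[i],
                   ep = burst_frames,
                   pre_ep = burst_frames - dt_pre_frames,
                   silent = which(stats::runif(frames) < 0.01 / frame_rate))
      if (length(ev) == 0L) next
      amp <- A * stats::runif(length(ev), 0.8, 1.2)
      tr <- gcamp_trace(frames, ev, amp, tau_frames)
      S[profs[[i]]$idx, ] <- S[profs[[i]]$idx, ] +
        outer(profs[[i]]$w / max(profs[[i]]$w), tr)
    }
    # --- motion event times (domains may lock onto them) -----------------
    motion_starts <- integer(0)
    ms <- NULL
    if (!is.null(motion_spec)) {
      ms <- utils::modifyList(list(n = 4L, displacement = c(1, 1),
                                   duration = 2L), as.list(motion_spec))
      lockout <- unique(unlist(lapply(c(burst_frames), function(b)
        seq.int(max(1L, b - 20L), min(frames, b + 20L)))))
      pool <- setdiff(seq(20L, frames - 40L), lockout)
      motion_starts <- sort(sample(pool, ms$n))
    }
    # --- domains ---------------------------------------------------------
    domains <- list()
    if (!is.null(domain_spec)) {
      ds <- utils::modifyList(list(n = 6L, volume = c(300, 700),
                                   duration = c(8L, 14L), region = "Cb",
                                   at_bursts = FALSE, at_motion = FALSE,
                                   amplitude_snr = snr, grid_bin = 1L),
                              as.list(domain_spec))
      bin <- as.integer(ds$grid_bin)
      Ad <- ds$amplitude_snr * sigma_dff
      lab_target <- reg$atlas$names[[ds$region]]
      # blob support grid: raw, or the bin-block grid fully inside the region
      if (bin > 1L) {
        hc <- dims[1] %/% bin; wc <- dims[2] %/% bin
        lab_full <- reg$atlas$labels
        coarse_ok <- matrix(TRUE, hc, wc)
        for (by in seq_len(bin)) for (bx in seq_len(bin)) {
          sub <- lab_full[seq(by, hc * bin, bin), seq(bx, wc * bin, bin)]
          coarse_ok <- coarse_ok & (sub == lab_target)
        }
        allowed <- which(as.vector(coarse_ok))
        gh <- hc; gw <- wc
      } else {
        allowed <- which(as.vector(reg$atlas$labels) == lab_target)
        gh <- dims[1]; gw <- dims[2]
      }
      onsets <- integer(0)
      from_motion <- logical(0)
      if (isTRUE(ds$at_bursts) && length(burst_frames) > 0) {
        onsets <- rep_len(burst_frames, ds$n)
        from_motion <- rep(FALSE, length(onsets))
      } else if (isTRUE(ds$at_motion) && length(motion_starts) > 0) {
        onsets <- rep_len(motion_starts, ds$n)
        from_motion <- rep(TRUE, length(onsets))
      } else {
        onsets <- sort(sample(seq(20L, frames - 40L), ds$n))
        from_motion <- rep(FALSE, length(onsets))
      }
      for (k in seq_along(onsets)) {
        dur <- sample(seq(ds$duration[1], ds$duration[2]), 1L)
        vol <- stats::runif(1, ds$volume[1], ds$volume[2])
        area <- max(9L, round(vol / dur))  # analysis-grid pixels
        blob <- grow_blob(area, allowed, gh, gw)
        if (bin > 1L) {
          cy <- ((blob - 1L) %% gh) + 1L
          cx <- ((blob - 1L) %/% gh) + 1L
          px <- unlist(lapply(seq_along(blob), function(j) {
            ys <- (cy[j] - 1L) * bin + seq_len(bin)
            xs <- (cx[j] - 1L) * bin + seq_len(bin)
            as.vector(outer(ys, xs, function(a, b) (b - 1L) * dims[1] + a))
          }))
        } else {
          px <- blob
        }
        t0 <- onsets[k]
        t1 <- min(t0 + dur - 1L, frames)
        if (t0 < 1L || t0 > frames) next
        S[px, t0:t1] <- S[px, t0:t1] + Ad
        domains[[length(domains) + 1L]] <-
          list(pixels_raw = px, pixels_analysis = blob,
               t_start = t0, t_end = t1,
               area_analysis = length(blob),
               volume = length(blob) * (t1 - t0 + 1L),
               at_motion = from_motion[k])
      }
    }
    # --- assemble counts and apply motion --------------------------------
    Fm <- base * (1 + S)  # npx x frames (base recycled by column)
    motion_frames <- integer(0)
    if (!is.null(ms)) {
      for (t0 in motion_starts)
        motion_frames <- c(motion_frames,
                           seq.int(t0, min(t0 + ms$duration - 1L, frames)))
      motion_frames <- sort(unique(motion_frames))
      dy <- ms$displacement[1]; dx <- ms$displacement[2]
      for (k in motion_frames) {
        fr <- matrix(Fm[, k], dims[1], dims[2])
        sh <- matrix(2, dims[1], dims[2])  # background fill
        ys <- seq_len(dims[1] - abs(dy)); xs <- seq_len(dims[2] - abs(dx))
        sh[ys + max(dy, 0), xs + max(dx, 0)] <-
          fr[ys + max(-dy, 0), xs + max(-dx, 0)]
        Fm[, k] <- as.vector(sh)
      }
    }
    counts <- Fm + stats::rnorm(npx * frames,
                                0, noise_scale * sqrt(pmax(Fm, 0))) +
      dark_level
    stack <- fluorescence_stack(array(counts, c(dims, frames)),
                                frame_rate = frame_rate, pixel_size = 1.2,
                                dark_level = dark_level)
    list(stack = stack, atlas = reg$atlas, mask = reg$mask,
         gt = list(centers = centers, classes = classes,
                   neuron_radius = nspec$radius,
                   burst_frames = burst_frames,
                   dt_pre_frames = dt_pre_frames,
                   domains = domains,
                   motion_starts = motion_starts,
                   motion_frames = motion_frames,
                   snr = snr, amplitude_dff = A, sigma_dff = sigma_dff,
                   seed = seed))
  })
}

#' Preset paired recordings for the four experimental conditions
#'
#' Fixed generator presets emulating the four groups: `WT` (movement
#' artifacts in the LFP, tiny sparse calcium domains at tail flicks),
#' `PTZ` (strong discharges, frequent 300-700 voxel cerebellar domains
#' plus one near-global ictal event), `MO` (moderate discharges, patchy
#' cerebellar/hindbrain domains that never reach the generalized PTZ
#' size), `MO+VPA` (the MO preset with burst amplitude and rate strongly
#' reduced and only sub-threshold domains at motion events). All presets
#' pair a 120 s LFP at 5 kHz with a 480-frame movie at 4 Hz generated at
#' 64 x 64 (analysis grid 32 x 32 after 2 x 2 binning).
#'
#' @param condition one of `"WT"`, `"PTZ"`, `"MO"`, `"MO+VPA"`.
#' @param seed RNG seed.
#' @return list with `bundle` (a `recording_bundle`), `gt` (merged LFP +
#'   movie ground truth), `mask` (brain mask on the raw grid).
#' @export
gen_condition_suite <- function(condition = c("WT", "PTZ", "MO", "MO+VPA"),
                                seed = 1L) {
  condition <- match.arg(condition)
  duration <- 120; rate <- 5000; frame_rate <- 4
  frames <- as.integer(duration * frame_rate)
  dims <- c(64L, 64L)
  p <- switch(condition,
    WT = list(lfp = list(n = 0L),
              artifacts = list(n = 6L, duration = 1.5, amplitude = 80),
              domains = list(n = 5L, volume = c(20, 45),
                             duration = c(4L, 6L), region = "OT",
                             at_motion = TRUE, grid_bin = 2L),
              motion = list(n = 5L, displacement = c(1, 1), duration = 2L),
              snr = 6),
    PTZ = list(lfp = list(n = 10L, duration = 1.5, delta = 1.5),
               artifacts = NULL,
               domains = list(n = 9L, volume = c(300, 700),
                              duration = c(8L, 14L), region = "Cb",
                              at_bursts = TRUE, grid_bin = 2L),
               motion = list(n = 3L, displacement = c(1, 1), duration = 2L),
               snr = 6, global_event = TRUE),
    MO = list(lfp = list(n = 8L, duration = 2, delta = 1.2),
              artifacts = NULL,
              domains = list(n = 8L, volume = c(300, 650),
                             duration = c(8L, 14L), region = "Cb",
                             at_bursts = TRUE, grid_bin = 2L),
              motion = list(n = 3L, displacement = c(1, 1), duration = 2L),
              snr = 6),
    `MO+VPA` = list(lfp = list(n = 2L, duration = 2, delta = 0.5),
                    artifacts = NULL,
                    domains = list(n = 4L, volume = c(60, 140),
                                   duration = c(6L, 8L), region = "Cb",
                                   at_motion = TRUE, grid_bin = 2L),
                    motion = list(n = 4L, displacement = c(1, 1),
                                  duration = 2L),
                    snr = 6))
  lfp <- gen_lfp(duration = duration, rate = rate,
                 burst_spec = p$lfp, artifact_spec = p$artifacts,
                 seed = seed)
  mov <- gen_movie(dims = dims, frames = frames, frame_rate = frame_rate,
                   neuron_spec = list(n_ep = 10L, n_pre = 5L,
                                      n_silent = 8L, radius = 3L),
                   domain_spec = p$domains, lfp_gt = lfp$gt, dt_pre = 2,
                   snr = p$snr, motion_spec = p$motion,
                   seed = seed + 1000L)
  gt <- c(lfp$gt, mov$gt)
  if (isTRUE(p$global_event)) {
    # near-global ictal event: most of the brain active for 5 s
    brain_px <- which(as.vector(mov$mask))
    t0 <- as.integer(round(frames * 0.6)); t1 <- t0 + 19L
    a <- mov$stack$pixels
    d <- dim(a)
    add <- mov$gt$amplitude_dff
    m <- matrix(a, d[1] * d[2], d[3])
    m[brain_px, t0:t1] <- m[brain_px, t0:t1] * (1 + add)
    mov$stack$pixels <- array(m, d)
    gt$global_event <- list(pixels = brain_px, t_start = t0, t_end = t1)
  }
  # atlas on the analysis (binned) grid for downstream classification
  atlas_binned <- make_atlas(dims %/% 2L)$atlas
  bundle <- recording_bundle(lfp$trace, mov$stack, atlas = atlas_binned,
                             metadata = list(condition = condition,
                                             seed = seed))
  list(bundle = bundle, gt = gt, mask = mov$mask)
}
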