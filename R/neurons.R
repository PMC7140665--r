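#' Zero-mean donut template for cell-body matching
#'
#' A soft bright annulus peaking at the cytoplasmic ring with a dimmer
#' center, as a GCaMP-labeled soma (bright cytoplasm, dim nucleus)
#' appears in a median projection. The ring peaks at `inner_frac` of the
#' outer radius and rolls off smoothly to the support edge (hard-edged
#' annuli penalize the soft borders of real somata), and the template is
#' shifted to zero mean over its disk support so matching is insensitive
#' to the local baseline.
#'
#' @param size outer diameter in pixels.
#' @param inner_frac ring peak radius as a fraction of the outer radius
#'   (default 0.4; this is also where the central hole ends).
#' @return numeric matrix `size x size` (zero-sum over the disk support).
#' @export
donut_template <- function(size, inner_frac = 0.4) {
  c0 <- (size + 1) / 2
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  r <- sqrt((g$y - c0)^2 + (g$x - c0)^2)
  outer_r <- size / 2
  r0 <- inner_frac * outer_r          # ring peak radius
  sig <- 0.35 * (outer_r - r0)        # ring softness
  w <- matrix(0, size, size)
  disk <- r <= outer_r
  ring <- exp(-pmax(r[disk] - r0, 0)^2 / (2 * (2.2 * sig)^2))
  hole <- 0.55 * exp(-r[disk]^2 / (2 * (0.8 * r0)^2))
  w[disk] <- ring - hole
  w[disk] <- w[disk] - mean(w[disk])
  w
}

# normalized cross-correlation of an image with a zero-mean template,
# using the template's disk support for the local statistics
ncc_match <- function(image, template) {
  support <- (template != 0) + 0
  n1 <- sum(support)
  num <- xcorr2_fft(image, template)
  s1 <- xcorr2_fft(image, support)
  s2 <- xcorr2_fft(image^2, support)
  denom <- sqrt(pmax(s2 - s1^2 / n1, 0)) * sqrt(sum(template^2))
  score <- ifelse(denom > 1e-12, num / denom, 0)
  # exclude centers whose template would leave the image
  k <- nrow(template) %/% 2 + 1L
  h <- nrow(image); w <- ncol(image)
  score[c(seq_len(min(k, h)), seq.int(max(h - k + 1L, 1L), h)), ] <- 0
  score[, c(seq_len(min(k, w)), seq.int(max(w - k + 1L, 1L), w))] <- 0
  score
}

#' Detect neuron somata by donut-template matching
#'
#' The median projection of the stack is denoised with a 3x3 median
#' filter and cross-correlated (normalized) with zero-mean donut templates
#' of the given sizes; local maxima above `score_threshold` are accepted
#' greedily in descending score with a `min_distance` exclusion radius,
#' and detections from the different template sizes are merged by the same
#' distance rule.
#'
#' Normalized correlation is scale-free, so in featureless noise its local
#' maxima reach 0.3-0.5 whatever the noise amplitude. Candidates are
#' therefore also required to show a significant soma-over-surround
#' contrast: ring mean minus surround mean above `contrast_z` times its
#' standard error, with the pixel noise estimated robustly from the
#' median-filter residual.
#'
#' @param stack a `fluorescence_stack` (>= 10 frames for a stable median
#'   projection) or a single projection image (matrix).
#' @param template_sizes donut outer diameters in pixels (default 10 and 7).
#' @param min_distance exclusion radius between accepted centers (px).
#' @param score_threshold minimum normalized correlation score.
#' @param mask optional logical matrix restricting detection to the brain
#'   (the tissue boundary itself scores like a cell edge); centers whose
#'   template support leaves the mask are discarded.
#' @param contrast_z minimum z-score of the ring-over-surround contrast
#'   (default 4; 0 disables the amplitude test).
#' @return data.frame with `x`, `y` (1-based pixel coordinates), `score`,
#'   `template_size`; zero rows for a blank image.
#' @export
detect_neurons <- function(stack, template_sizes = c(10L, 7L),
                           min_distance = 5, score_threshold = 0.3,
                           mask = NULL, contrast_z = 4) {
  if (inherits(stack, "fluorescence_stack")) {
    if (dim(stack$pixels)[3] < 10L)
      stop2("detect_neurons: need >= 10 frames for a stable median projection")
    proj <- apply(stack$pixels, c(1, 2), stats::median)
  } else {
    proj <- as.matrix(stack)
  }
  raw_proj <- proj
  proj <- medfilt3(proj)
  sigma_px <- stats::mad(raw_proj - proj)  # robust pixel noise
  cand <- list()
  for (sz in template_sizes) {
    sc <- ncc_match(proj, donut_template(sz))
    if (!is.null(mask)) {
      # erode the mask by the template half-size
      r <- sz %/% 2
      er <- mask
      for (s in seq_len(r))
        er <- er & rbind(FALSE, er[-nrow(er), ]) & rbind(er[-1, ], FALSE) &
          cbind(FALSE, er[, -ncol(er)]) & cbind(er[, -1], FALSE)
      sc[!er] <- 0
    }
    # strict 8-neighbor local maxima above threshold
    h <- nrow(sc); w <- ncol(sc)
    is_max <- sc > score_threshold
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      sh <- matrix(-Inf, h, w)
      ys <- seq.int(max(1, 1 + dy), min(h, h + dy))
      xs <- seq.int(max(1, 1 + dx), min(w, w + dx))
      sh[ys, xs] <- sc[ys - dy, xs - dx]
      is_max <- is_max & (sc >= sh)
    }
    idx <- which(is_max)
    if (length(idx) > 0) {
      pos <- arrayInd(idx, dim(sc))
      cand[[length(cand) + 1L]] <-
        data.frame(x = pos[, 2], y = pos[, 1], score = sc[idx],
                   template_size = sz)
    }
  }
  if (length(cand) == 0L)
    return(data.frame(x = integer(0), y = integer(0), score = numeric(0),
                      template_size = integer(0)))
  cand <- do.call(rbind, cand)
  if (contrast_z > 0 && sigma_px > 0) {
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      sz <- cand$template_size[i]
      w <- donut_template(sz)
      half <- nrow(w) %/% 2
      g <- expand.grid(dy = -(half + 2):(half + 2), dx = -(half + 2):(half + 2))
      r <- sqrt(g$dy^2 + g$dx^2)
      ys <- cand$y[i] + g$dy; xs <- cand$x[i] + g$dx
      ok <- ys >= 1 & ys <= nrow(raw_proj) & xs >= 1 & xs <= ncol(raw_proj)
      vals <- raw_proj[cbind(ys[ok], xs[ok])]
      ring <- vals[r[ok] > 0.2 * sz / 2 & r[ok] <= sz / 2]
      surr <- vals[r[ok] > sz / 2 + 0.5]
      if (length(ring) < 4 || length(surr) < 4) return(FALSE)
      se <- sigma_px * sqrt(1 / length(ring) + 1 / length(surr))
      (mean(ring) - mean(surr)) / se >= contrast_z
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L)
      return(data.frame(x = integer(0), y = integer(0), score = numeric(0),
                        template_size = integer(0)))
  }
  cand <- cand[order(-cand$score), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt((cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2)
    if (all(dd >= min_distance)) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract per-neuron dff traces from circular ROIs
#'
#' Each trace is the mean fluctuation over the discrete disk of the given
#' radius (29 pixels at radius 3). Centers closer than `radius` to the
#' image border are dropped and reported via the `dropped` attribute.
#'
#' @param dff a `dff_stack`.
#' @param centers data.frame with `x`, `y` columns (e.g. from
#'   [detect_neurons]).
#' @param radius ROI radius in pixels (default 3).
#' @return a `neuron_rois`: `traces` (frames x neurons matrix), `centers`
#'   (retained rows), `radius`; attribute `dropped` = indices of discarded
#'   centers.
#' @export
extract_traces <- function(dff, centers, radius = 3) {
  stopifnot(inherits(dff, "dff_stack"))
  if (nrow(centers) == 0L) stop2("extract_traces: empty center list")
  d <- dim(dff$dff)
  offs <- disk_offsets(radius)
  inside <- centers$y - radius >= 1 & centers$y + radius <= d[1] &
    centers$x - radius >= 1 & centers$x + radius <= d[2]
  dropped <- which(!inside)
  if (length(dropped) > 0)
    message(sprintf("extract_traces: dropped %d ROI(s) at the image border",
                    length(dropped)))
  centers <- centers[inside, , drop = FALSE]
  if (nrow(centers) == 0L) stop2("extract_traces: no ROI fits the image")
  m <- matrix(dff$dff, d[1] * d[2], d[3])
  traces <- vapply(seq_len(nrow(centers)), function(i) {
    px <- (centers$x[i] + offs$dx - 1L) * d[1] + centers$y[i] + offs$dy
    colMeans(m[px, , drop = FALSE])
  }, numeric(d[3]))
  structure(list(traces = traces, centers = centers, radius = radius),
            class = "neuron_rois", dropped = dropped)
}

#' PCA of the single-neuron fluctuation traces
#'
#' Traces are normalized to unit standard deviation (each neuron is one
#' variable, time points are the samples) and decomposed by PCA; the first
#' `n_pc` components are retained. Component signs are fixed so that the
#' peak cross-correlation of each score with the log-RMS power is positive
#' (or, without a power series, so that each score is positively skewed).
#' Zero-variance neurons are dropped and reported.
#'
#' @param rois a `neuron_rois` (or a frames x neurons matrix).
#' @param n_pc number of retained components (default 10).
#' @param power optional `aligned_power` used for sign fixing.
#' @param max_lag lag range for the sign-fixing correlogram.
#' @return a `pca_decomposition`: `scores` (frames x n_pc), `loadings`
#'   (neurons x n_pc), `var_frac` (all components), `kept` (neuron
#'   indices), `n_pc`.
#' @export
run_pca <- function(rois, n_pc = 10L, power = NULL, max_lag = 20L) {
  X <- if (inherits(rois, "neuron_rois")) rois$traces else as.matrix(rois)
  sds <- apply(X, 2, stats::sd)
  kept <- which(sds > 0)
  if (length(kept) < ncol(X))
    message(sprintf("run_pca: dropped %d zero-variance neuron(s)",
                    ncol(X) - length(kept)))
  if (length(kept) < n_pc)
    stop2("run_pca: fewer usable neurons (", length(kept),
          ") than requested components (", n_pc, ")")
  Xs <- scale(X[, kept, drop = FALSE])
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, seq_len(n_pc), drop = FALSE]
  loadings <- pr$rotation[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {
    s <- if (!is.null(power)) {
      cg <- xcorr_trace(scores[, j], power, max_lag = max_lag)
      sign(cg$r[which.max(abs(cg$r))])
    } else {
      sign(mean(scores[, j]) - stats::median(scores[, j]))
    }
    if (is.na(s) || s == 0) s <- 1
    scores[, j] <- s * scores[, j]
    loadings[, j] <- s * loadings[, j]
  }
  structure(list(scores = scores, loadings = loadings, var_frac = var_frac,
                 kept = kept, n_pc = as.integer(n_pc)),
            class = "pca_decomposition")
}

#' @export
print.pca_decomposition <- function(x, ...) {
  cat(sprintf("<pca_decomposition> %d neurons, %d PCs (%.1f%% variance)\n",
              nrow(x$loadings), x$n_pc,
              100 * sum(x$var_frac[seq_len(x$n_pc)])))
  invisible(x)
}

#' Select the epileptiform and pre-epileptiform components
#'
#' Each retained PC score is cross-correlated with the interpolated
#' log-RMS power. The epileptiform (Ep) component is the PC with the
#' largest zero-lag correlation. The pre-epileptiform (pre-Ep) component
#' is chosen among the remaining PCs whose correlogram attains its global
#' maximum at a negative lag with a positive value above `min_peak_r`;
#' to keep weak event-residual components from shadowing a conspicuous
#' anticipating population, candidates below half of the strongest
#' candidate peak are dropped. Among the survivors the peak lag closest
#' to zero wins (ties: larger peak). With no qualifying candidate the
#' pre-Ep slot is flagged undefined.
#'
#' @param pca a `pca_decomposition`.
#' @param power an `aligned_power`.
#' @param max_lag correlogram half-width in frames.
#' @param min_peak_r floor on the peak correlation for a pre-Ep
#'   candidate; the effective floor is the larger of this and a
#'   Bonferroni-style significance bound on the maximum noise correlation
#'   over all lags and candidate PCs (alpha = 0.01).
#' @return an `ep_classification`: `ep_pc`, `pre_ep_pc` (NA when
#'   undefined), `pre_ep_defined`, `ep_zero_lag_r`, `pre_ep_peak_lag`,
#'   `correlograms` (list per PC).
#' @export
select_components <- function(pca, power, max_lag = 20L, min_peak_r = 0.1) {
  stopifnot(inherits(pca, "pca_decomposition"))
  cgs <- lapply(seq_len(pca$n_pc), function(j)
    xcorr_trace(pca$scores[, j], power, max_lag = max_lag))
  zero_lag <- vapply(cgs, function(cg) cg$r[cg$lag == 0], numeric(1))
  ep <- which.max(zero_lag)
  n_frames <- nrow(pca$scores)
  n_tests <- (2 * max_lag + 1) * (pca$n_pc - 1)
  r_crit <- stats::qnorm(1 - 0.01 / (2 * n_tests)) / sqrt(n_frames)
  # an anticipating *population* couples to the LFP on the same order as
  # the Ep population; event-locked residual components do not
  r_ep_peak <- max(vapply(cgs, function(cg) max(cg$r), numeric(1)))
  floor_r <- max(min_peak_r, r_crit, 0.3 * r_ep_peak)
  cand <- data.frame(pc = integer(0), lag = integer(0), r = numeric(0))
  for (j in setdiff(seq_len(pca$n_pc), ep)) {
    cg <- cgs[[j]]
    i <- which.max(cg$r)
    if (cg$r[i] > floor_r && cg$lag[i] < 0)
      cand <- rbind(cand, data.frame(pc = j, lag = cg$lag[i], r = cg$r[i]))
  }
  if (nrow(cand) == 0L) {
    pre <- NA_integer_; pre_lag <- NA_integer_
  } else {
    cand <- cand[cand$r >= 0.5 * max(cand$r), , drop = FALSE]
    cand <- cand[order(-cand$lag, -cand$r), , drop = FALSE]
    pre <- cand$pc[1]; pre_lag <- cand$lag[1]
  }
  structure(list(ep_pc = ep, pre_ep_pc = pre,
                 pre_ep_defined = !is.na(pre),
                 ep_zero_lag_r = zero_lag[ep],
                 pre_ep_peak_lag = pre_lag,
                 correlograms = cgs, max_lag = as.integer(max_lag)),
            class = "ep_classification")
}

#' @export
print.ep_classification <- function(x, ...) {
  cat(sprintf("<ep_classification> Ep = PC%d (r0 = %.3f); pre-Ep = %s\n",
              x$ep_pc, x$ep_zero_lag_r,
              if (x$pre_ep_defined)
                sprintf("PC%d (peak lag %d)", x$pre_ep_pc, x$pre_ep_peak_lag)
              else "undefined"))
  invisible(x)
}

#' Mean event-aligned correlograms of the selected components
#'
#' For each paroxysmal event, the correlogram of each selected PC score
#' with the aligned log-power is computed inside a window of `window`
#' seconds centered on the event, then averaged across events. Windows
#' clipped by the recording edges are truncated and flagged.
#'
#' @param classification an `ep_classification`.
#' @param pca the `pca_decomposition` the classification came from.
#' @param power an `aligned_power`.
#' @param events event times in seconds (see [detect_events]).
#' @param window window length in seconds (default 25).
#' @param max_lag correlogram half-width in frames.
#' @return list with `lags`, `ep` (mean r per lag), `pre_ep` (or NULL),
#'   `n_events`, `truncated`.
#' @export
event_correlograms <- function(classification, pca, power, events,
                               window = 25, max_lag = 20L) {
  stopifnot(inherits(classification, "ep_classification"),
            inherits(pca, "pca_decomposition"),
            inherits(power, "aligned_power"))
  if (length(events) == 0L) stop2("event_correlograms: no events")
  ft <- power$frame_times
  nT <- length(ft)
  half_s <- window / 2
  truncated <- FALSE
  per_event <- function(score) {
    acc <- NULL
    for (ev in events) {
      sel <- which(ft >= ev - half_s & ft <= ev + half_s)
      if (length(sel) < max_lag + 2L) { truncated <<- TRUE; next }
      if (ft[sel[1]] > ev - half_s + diff(range(ft)) / nT ||
          utils::tail(ft[sel], 1) < ev + half_s - diff(range(ft)) / nT)
        truncated <<- TRUE
      if (stats::sd(score[sel]) == 0 || stats::sd(power$values[sel]) == 0)
        next
      cg <- xcorr_trace(score[sel], power$values[sel], max_lag = max_lag)
      acc <- if (is.null(acc)) cg$r else acc + cg$r
    }
    acc
  }
  ep_acc <- per_event(pca$scores[, classification$ep_pc])
  n_used <- length(events)
  out <- list(lags = (-max_lag):max_lag,
              ep = if (is.null(ep_acc)) NULL else ep_acc / n_used,
              pre_ep = NULL, n_events = n_used, truncated = truncated)
  if (classification$pre_ep_defined) {
    pre_acc <- per_event(pca$scores[, classification$pre_ep_pc])
    out$pre_ep <- if (is.null(pre_acc)) NULL else pre_acc / n_used
  }
  out
}

#' Normalized-loading maps of the Ep and pre-Ep populations
#'
#' Per class, each neuron's loading is divided by the maximum loading of
#' that PC over all neurons, neurons with non-positive loading are
#' removed, and neurons whose normalized loading exceeds `both_threshold`
#' in *both* classes are removed from both (class-exclusive sets). A
#' rostro-caudal profile sums the normalized loadings in bins along the
#' declared axis.
#'
#' @param pca a `pca_decomposition`.
#' @param classification an `ep_classification` (pre-Ep must be defined
#'   for a pre-Ep map; otherwise only the Ep map is returned).
#' @param centers data.frame of the neuron centers the PCA was run on
#'   (rows matching `pca$kept`).
#' @param both_threshold dual-participation cutoff (default 0.5).
#' @param axis image axis of the rostro-caudal direction (`"y"` or `"x"`).
#' @param n_bins profile bins (default 16).
#' @param dims image dimensions (rows, cols) for the profile binning.
#' @return a `loading_maps`: per-class data.frames (`x`, `y`,
#'   `normalized`), `profile` data.frame, `removed_both` (neuron indices),
#'   `empty` flags.
#' @export
loading_maps <- function(pca, classification, centers, both_threshold = 0.5,
                         axis = c("y", "x"), n_bins = 16L, dims = NULL) {
  stopifnot(inherits(pca, "pca_decomposition"),
            inherits(classification, "ep_classification"))
  axis <- match.arg(axis)
  centers <- centers[pca$kept, , drop = FALSE]
  norm_load <- function(pc) {
    l <- pca$loadings[, pc]
    mx <- max(l)
    if (mx <= 0) return(rep(NA_real_, length(l)))
    l / mx
  }
  nl_ep <- norm_load(classification$ep_pc)
  nl_pre <- if (classification$pre_ep_defined)
    norm_load(classification$pre_ep_pc) else NULL
  removed_both <- integer(0)
  if (!is.null(nl_pre)) {
    removed_both <- which(nl_ep > both_threshold & nl_pre > both_threshold)
  }
  build <- function(nl) {
    keep <- which(nl > 0)
    keep <- setdiff(keep, removed_both)
    data.frame(x = centers$x[keep], y = centers$y[keep],
               normalized = nl[keep], neuron = keep)
  }
  ep_map <- build(nl_ep)
  pre_map <- if (!is.null(nl_pre)) build(nl_pre) else NULL
  if (is.null(dims))
    dims <- c(max(centers$y) + 1L, max(centers$x) + 1L)
  extent <- if (axis == "y") dims[1] else dims[2]
  edges <- seq(0.5, extent + 0.5, length.out = n_bins + 1L)
  prof_of <- function(mp) {
    if (is.null(mp) || nrow(mp) == 0L) return(rep(0, n_bins))
    pos <- if (axis == "y") mp$y else mp$x
    bin <- pmin(pmax(findInterval(pos, edges), 1L), n_bins)
    vapply(seq_len(n_bins), function(b) sum(mp$normalized[bin == b]),
           numeric(1))
  }
  profile <- data.frame(bin_center = (edges[-1] + edges[-length(edges)]) / 2,
                        ep = prof_of(ep_map), pre_ep = prof_of(pre_map))
  structure(list(ep = ep_map, pre_ep = pre_map, profile = profile,
                 removed_both = removed_both, axis = axis, dims = dims,
                 empty = c(ep = nrow(ep_map) == 0L,
                           pre_ep = !is.null(pre_map) && nrow(pre_map) == 0L)),
            class = "loading_maps")
}

# raster image of a loading map: disks of `radius` px at neuron centers,
# valued at the normalized loading (max where disks overlap)
loading_map_image <- function(mp, dims, radius = 3) {
  img <- matrix(0, dims[1], dims[2])
  if (is.null(mp) || nrow(mp) == 0L) return(img)
  offs <- disk_offsets(radius)
  for (i in seq_len(nrow(mp))) {
    ys <- mp$y[i] + offs$dy; xs <- mp$x[i] + offs$dx
    ok <- ys >= 1 & ys <= dims[1] & xs >= 1 & xs <= dims[2]
    idx <- cbind(ys[ok], xs[ok])
    img[idx] <- pmax(img[idx], mp$normalized[i])
  }
  img
}

# similarity transform (translation + rotation + isotropic scale) mapping
# reference-mask coordinates onto fish-mask coordinates, from mask moments
mask_similarity <- function(fish_mask, reference_mask) {
  moments <- function(m) {
    idx <- which(m > 0, arr.ind = TRUE)
    c0 <- colMeans(idx)
    cc <- sweep(idx, 2, c0)
    S <- crossprod(cc) / nrow(idx)
    e <- eigen(S, symmetric = TRUE)
    ang <- atan2(e$vectors[1, 1], e$vectors[2, 1])
    list(center = c0, angle = ang, area = nrow(idx))
  }
  mf <- moments(fish_mask); mr <- moments(reference_mask)
  dth <- mf$angle - mr$angle
  dth <- atan2(sin(dth), cos(dth))
  if (dth > pi / 2) dth <- dth - pi
  if (dth < -pi / 2) dth <- dth + pi
  list(scale = sqrt(mf$area / mr$area), angle = dth,
       fish_center = mf$center, ref_center = mr$center)
}

# resample a fish-frame image onto the reference grid (nearest neighbor)
warp_to_reference <- function(img, tf, ref_dims) {
  out <- matrix(0, ref_dims[1], ref_dims[2])
  g <- expand.grid(y = seq_len(ref_dims[1]), x = seq_len(ref_dims[2]))
  dy <- g$y - tf$ref_center[1]; dx <- g$x - tf$ref_center[2]
  cs <- cos(tf$angle); sn <- sin(tf$angle)
  fy <- round(tf$fish_center[1] + tf$scale * (cs * dy - sn * dx))
  fx <- round(tf$fish_center[2] + tf$scale * (sn * dy + cs * dx))
  ok <- fy >= 1 & fy <= nrow(img) & fx >= 1 & fx <= ncol(img)
  out[cbind(g$y[ok], g$x[ok])] <- img[cbind(fy[ok], fx[ok])]
  out
}

#' Collective (multi-fish) loading map
#'
#' Rasterizes each fish's per-class loading map, registers it onto a
#' reference mask, and takes the voxelwise maximum across fish. The
#' registration is a similarity transform estimated from mask moments
#' (translation + rotation + isotropic scale); externally computed
#' displacement fields can be supplied instead, and `"identity"` skips
#' registration (grids must then match).
#'
#' @param maps list of `loading_maps`, one per fish.
#' @param masks list of fish brain masks (binary matrices), needed for
#'   `"similarity"` registration.
#' @param reference_mask binary matrix defining the common grid.
#' @param registration `"identity"`, `"similarity"`, or `"fields"`.
#' @param fields for `"fields"`: list (per fish) of lists with `dy`, `dx`
#'   integer displacement matrices on the reference grid.
#' @param radius neuron disk radius for rasterization.
#' @return list with `ep` and `pre_ep` collective images on the reference
#'   grid.
#' @export
collective_map <- function(maps, masks = NULL, reference_mask = NULL,
                           registration = c("identity", "similarity",
                                            "fields"),
                           fields = NULL, radius = 3) {
  registration <- match.arg(registration)
  stopifnot(length(maps) >= 1L)
  ref_dims <- if (!is.null(reference_mask)) dim(reference_mask) else
    maps[[1]]$dims
  acc <- list(ep = matrix(0, ref_dims[1], ref_dims[2]),
              pre_ep = matrix(0, ref_dims[1], ref_dims[2]))
  for (i in seq_along(maps)) {
    for (cls in c("ep", "pre_ep")) {
      mp <- maps[[i]][[cls]]
      img <- loading_map_image(mp, maps[[i]]$dims, radius)
      img <- switch(registration,
        identity = {
          if (!all(dim(img) == ref_dims))
            stop2("collective_map: grid mismatch under identity registration")
          img
        },
        similarity = {
          if (is.null(masks) || is.null(reference_mask))
            stop2("collective_map: similarity registration needs masks ",
                  "and a reference mask")
          warp_to_reference(img, mask_similarity(masks[[i]], reference_mask),
                            ref_dims)
        },
        fields = {
          fl <- fields[[i]]
          g <- expand.grid(y = seq_len(ref_dims[1]), x = seq_len(ref_dims[2]))
          fy <- g$y + as.vector(fl$dy); fx <- g$x + as.vector(fl$dx)
          ok <- fy >= 1 & fy <= nrow(img) & fx >= 1 & fx <= ncol(img)
          out <- matrix(0, ref_dims[1], ref_dims[2])
          out[cbind(g$y[ok], g$x[ok])] <- img[cbind(fy[ok], fx[ok])]
          out
        })
      acc[[cls]] <- pmax(acc[[cls]], img)
    }
  }
  acc
}
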