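#' Dark subtraction and 2x2 binning of an imaging stack
#'
#' Subtracts the mean dark signal and block-averages the stack `bin x bin`
#' to reduce array size (a 512x512 acquisition becomes 256x256). Trailing
#' rows/columns that do not fill a block are dropped with a warning.
#'
#' @param stack a `fluorescence_stack`.
#' @param dark_level mean dark signal (scalar, or matrix on the raw grid);
#'   defaults to the stack's own `dark_level`.
#' @param bin spatial binning factor (default 2; 1 = no binning).
#' @return a preprocessed `fluorescence_stack` on the binned grid.
#' @export
preprocess <- function(stack, dark_level = NULL, bin = 2L) {
  stopifnot(inherits(stack, "fluorescence_stack"))
  if (is.null(dark_level)) dark_level <- stack$dark_level
  a <- stack$pixels
  pixel_means <- apply(a, c(1, 2), mean)
  if (max(if (is.matrix(dark_level)) dark_level else dark_level[1]) >
      min(pixel_means))
    stop2("preprocess: dark_level exceeds the dimmest pixel mean ",
          "(mis-set dark signal?)")
  a <- a - if (is.matrix(dark_level)) array(dark_level, dim(a)) else dark_level
  d <- dim(a)
  if (bin > 1L) {
    h2 <- d[1] %/% bin; w2 <- d[2] %/% bin
    if (h2 * bin != d[1] || w2 * bin != d[2])
      warning(sprintf("preprocess: dropping %d row(s), %d column(s) not filling a %dx%d block",
                      d[1] - h2 * bin, d[2] - w2 * bin, bin, bin), call. = FALSE)
    a <- a[seq_len(h2 * bin), seq_len(w2 * bin), , drop = FALSE]
    # block mean: average rows in groups of `bin`, then columns
    dim(a) <- c(bin, h2, w2 * bin * d[3])
    a <- colMeans(a)
    dim(a) <- c(h2, bin, w2, d[3])
    a <- colMeans(aperm(a, c(2, 1, 3, 4)))
    dim(a) <- c(h2, w2, d[3])
  }
  out <- fluorescence_stack(a, frame_rate = stack$frame_rate,
                            pixel_size = stack$pixel_size * bin,
                            dark_level = 0)
  attr(out, "preprocessed") <- TRUE
  out
}

#' Per-pixel fluorescence fluctuation about the global baseline
#'
#' For each pixel, dff(t) = (f(t) - <f>) / <f> with <f> the temporal mean
#' over the full recording (a global baseline; a movable-baseline variant
#' distorts responses during large transients and is deliberately not
#' offered). Pixels whose baseline is at or below `eps` are masked (NA).
#'
#' @param stack a preprocessed `fluorescence_stack`.
#' @param eps minimum admissible baseline (counts).
#' @return a `dff_stack`: list with `dff` array (rows, cols, frames), `mask`
#'   (logical matrix, TRUE = usable pixel), `frame_rate`, `pixel_size`.
#' @export
compute_dff <- function(stack, eps = 1e-6) {
  stopifnot(inherits(stack, "fluorescence_stack"))
  a <- stack$pixels
  if (all(a == 0)) stop2("compute_dff: all-zero stack")
  d <- dim(a)
  f0 <- apply(a, c(1, 2), mean)
  mask <- f0 > eps
  f0_safe <- ifelse(mask, f0, 1)
  dff <- sweep(sweep(a, c(1, 2), f0_safe, "-"), c(1, 2), f0_safe, "/")
  dff[array(!mask, d)] <- NA_real_
  structure(list(dff = dff, mask = mask, frame_rate = stack$frame_rate,
                 pixel_size = stack$pixel_size),
            class = "dff_stack")
}

#' @export
print.dff_stack <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf("<dff_stack> %dx%d px, %d frames (%d masked pixels)\n",
              d[1], d[2], d[3], sum(!x$mask)))
  invisible(x)
}

#' Pearson's second coefficient of skewness
#'
#' 3 (mean - median) / SD; zero for symmetric samples, positive when a
#' right tail (e.g. calcium transients) pulls the mean above the median.
#' Sample SD (denominator n - 1) is used.
#'
#' @param samples numeric vector, n >= 3.
#' @return scalar skewness.
#' @export
pearson_skewness <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 3L) stop2("pearson_skewness: need n >= 3")
  s <- stats::sd(samples)
  if (s == 0) stop2("pearson_skewness: zero SD")
  3 * (mean(samples) - stats::median(samples)) / s
}

#' Per-pixel skewness map of the fluorescence fluctuations
#'
#' @param dff a `dff_stack`.
#' @return a `skewness_map`: `map` (matrix, NA on masked pixels) and
#'   `pooled` (scalar skewness of all unmasked dff samples of the section).
#' @export
skewness_map <- function(dff) {
  stopifnot(inherits(dff, "dff_stack"))
  d <- dim(dff$dff)
  m <- matrix(dff$dff, d[1] * d[2], d[3])
  use <- as.vector(dff$mask)
  mu <- rowMeans(m)
  med <- apply(m, 1, stats::median)
  sdv <- sqrt(pmax(rowSums((m - mu)^2) / (d[3] - 1), 0))
  sk <- ifelse(use & sdv > 0, 3 * (mu - med) / sdv, NA_real_)
  pooled <- pearson_skewness(m[use, , drop = FALSE])
  structure(list(map = matrix(sk, d[1], d[2]), pooled = pooled),
            class = "skewness_map")
}

#' Temporal persistence filter of a binary stack
#'
#' Deletes positive runs shorter than `min_frames` in each pixel's time
#' series. Idempotent.
#'
#' @param b 0/1 array (rows, cols, frames).
#' @param min_frames minimum run length (default 3).
#' @return filtered 0/1 array.
#' @export
filter_persistence <- function(b, min_frames = 3L) {
  d <- dim(b)
  m <- matrix(b, d[1] * d[2], d[3])
  active <- which(rowSums(m) > 0)
  for (i in active) {
    r <- rle(m[i, ])
    r$values[r$values == 1 & r$lengths < min_frames] <- 0L
    m[i, ] <- inverse.rle(r)
  }
  array(m, d)
}

#' Spatial support filter of a binary stack
#'
#' Within each frame, keeps a positive pixel only if at least
#' `min_neighbors` of its 8 neighbors are positive; removal is iterated to
#' a fixed point so the filter is idempotent.
#'
#' @param b 0/1 array (rows, cols, frames).
#' @param min_neighbors minimum positive 8-neighbors (default 2).
#' @return filtered 0/1 array.
#' @export
filter_support <- function(b, min_neighbors = 2L) {
  d <- dim(b)
  for (k in seq_len(d[3])) {
    fr <- b[, , k]
    repeat {
      if (!any(fr == 1)) break
      keep <- fr == 1 & neighbor_count8(fr) >= min_neighbors
      changed <- sum(fr) - sum(keep)
      fr <- keep + 0L
      storage.mode(fr) <- storage.mode(b)
      if (changed == 0) break
    }
    b[, , k] <- fr
  }
  b
}

#' Statistical binarization of a dff stack
#'
#' Each pixel's baseline Gaussian is fitted with the same iterative-trim
#' procedure used for the LFP power ([trim_gaussian_fit]); samples more
#' than `k_sd` fitted SDs above the fitted mean are set to 1. The binary
#' stack is then cleaned by the temporal persistence filter (runs shorter
#' than `min_frames` deleted) followed by the spatial support filter
#' (positive pixels need `min_neighbors` positive 8-neighbors in their
#' frame). Zero-variance and masked pixels stay 0.
#'
#' @param dff a `dff_stack`.
#' @param k_sd threshold in fitted-SD units (default 2).
#' @param min_frames minimum temporal persistence in frames (default 3).
#' @param min_neighbors minimum in-frame positive 8-neighbors (default 2).
#' @param tol,max_iter passed to [trim_gaussian_fit].
#' @return a `binary_stack`: `voxels` 0/1 array plus the parameters used.
#' @export
binarize <- function(dff, k_sd = 2, min_frames = 3L, min_neighbors = 2L,
                     tol = 0.01, max_iter = 100L) {
  stopifnot(inherits(dff, "dff_stack"))
  d <- dim(dff$dff)
  m <- matrix(dff$dff, d[1] * d[2], d[3])
  b <- matrix(0L, d[1] * d[2], d[3])
  for (i in which(as.vector(dff$mask))) {
    v <- m[i, ]
    if (max(v) == min(v)) next  # zero-variance pixel: masked
    fit <- trim_gaussian_fit(v, k_sd = k_sd, tol = tol, max_iter = max_iter)
    b[i, ] <- as.integer(v > fit$threshold)
  }
  b <- array(b, d)
  b <- filter_persistence(b, min_frames)
  b <- filter_support(b, min_neighbors)
  structure(list(voxels = b, k_sd = k_sd, min_frames = min_frames,
                 min_neighbors = min_neighbors,
                 frame_rate = dff$frame_rate, pixel_size = dff$pixel_size),
            class = "binary_stack")
}

#' @export
print.binary_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_stack> %dx%dx%d, %d positive voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}
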