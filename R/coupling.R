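#' Interpolate the log-RMS power at the frame mean times
#'
#' Linear interpolation of the windowed log-power at each imaging frame's
#' mean exposure time. Frame times outside the power series' span are
#' extrapolated with the nearest value and counted in the
#' `n_extrapolated` attribute.
#'
#' @param series a `band_power`.
#' @param frame_times frame mean times in seconds.
#' @return an `aligned_power`: `values` (one per frame), `frame_times`,
#'   `series` (the source).
#' @export
align_power <- function(series, frame_times) {
  stopifnot(inherits(series, "band_power"))
  if (length(series$times) == 0L) stop2("align_power: empty power series")
  v <- stats::approx(series$times, series$log_power, xout = frame_times,
                     rule = 2)$y
  out <- structure(list(values = v, frame_times = frame_times,
                        series = series),
                   class = "aligned_power")
  attr(out, "n_extrapolated") <- sum(frame_times < min(series$times) |
                                       frame_times > max(series$times))
  out
}

#' @export
print.aligned_power <- function(x, ...) {
  cat(sprintf("<aligned_power> %d frames (%d extrapolated)\n",
              length(x$values), attr(x, "n_extrapolated")))
  invisible(x)
}

#' Lagged Pearson cross-correlogram of two equal-length traces
#'
#' `r(l)` is the Pearson correlation of `trace(t)` with `power(t - l)` over
#' their truncated overlap (no wrap-around). A negative lag therefore means
#' the first trace leads the second (e.g. calcium preceding LFP power).
#'
#' @param trace,power equal-length numeric vectors.
#' @param max_lag maximum |lag| in samples/frames.
#' @return a `correlogram` data.frame with columns `lag`, `r`.
#' @export
xcorr_trace <- function(trace, power, max_lag = 20L) {
  if (inherits(power, "aligned_power")) power <- power$values
  if (length(trace) != length(power))
    stop2("xcorr_trace: traces must have equal length")
  if (stats::sd(trace) == 0 || stats::sd(power) == 0)
    stop2("xcorr_trace: zero-variance trace")
  n <- length(trace)
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(trace[(1 + l):n], power[1:(n - l)])
    else stats::cor(trace[1:(n + l)], power[(1 - l):n])
  }, numeric(1))
  structure(data.frame(lag = lags, r = r), class = c("correlogram",
                                                     "data.frame"))
}

#' Pixelwise cross-correlation map of dff with the LFP log-RMS power
#'
#' For each pixel, the lag-l correlations (|l| <= L) between the z-scored
#' pixel fluctuation and the z-scored interpolated log-power are summed
#' and divided by the number of lag terms, so the map value is a bounded
#' correlation-like quantity in [-1, 1]. Each lag is normalized by its own
#' truncated-overlap length. The raw (unnormalized, scale-dependent) sum
#' is available with `mode = "raw"`.
#'
#' @param dff a `dff_stack`.
#' @param power an `aligned_power` with one value per frame.
#' @param L lag half-width in frames (see [estimate_L]).
#' @param window optional frame window, length-2 (start, end) 1-based
#'   inclusive; default = the full recording.
#' @param mode `"bounded"` (z-scored, per-term normalized) or `"raw"`.
#' @param normalize divide the map by its maximum value (map max = 1).
#' @return an `xcorr_map`: `C` matrix (NA on masked pixels), `L`, `mode`,
#'   `window`, `normalized`.
#' @export
xcorr_map <- function(dff, power, L = 3L, window = NULL,
                      mode = c("bounded", "raw"), normalize = FALSE) {
  stopifnot(inherits(dff, "dff_stack"))
  mode <- match.arg(mode)
  p <- if (inherits(power, "aligned_power")) power$values else power
  d <- dim(dff$dff)
  if (length(p) != d[3])
    stop2("xcorr_map: power and stack frame counts differ")
  if (L < 0L) stop2("xcorr_map: L must be >= 0")
  if (is.null(window)) window <- c(1L, d[3])
  fr <- seq.int(window[1], window[2])
  if (length(fr) < 2L * L + 1L)
    stop2("xcorr_map: window shorter than 2L+1 frames")
  m <- matrix(dff$dff, d[1] * d[2], d[3])[, fr, drop = FALSE]
  pv <- p[fr]
  Tn <- length(fr)
  use <- as.vector(dff$mask)
  if (mode == "bounded") {
    mu <- rowMeans(m)
    sdv <- sqrt(rowMeans((m - mu)^2))
    sdv[sdv == 0 | !use] <- NA
    Z <- (m - mu) / sdv
    zp <- zscore_pop(pv)
  } else {
    Z <- m
    zp <- pv
  }
  acc <- numeric(d[1] * d[2])
  for (l in (-L):L) {
    if (l >= 0) {
      ov <- Tn - l
      s <- Z[, (1 + l):Tn, drop = FALSE] %*% zp[1:ov]
    } else {
      ov <- Tn + l
      s <- Z[, 1:ov, drop = FALSE] %*% zp[(1 - l):Tn]
    }
    acc <- acc + if (mode == "bounded") as.vector(s) / ov else as.vector(s)
  }
  C <- acc / if (mode == "bounded") (2 * L + 1) else 1
  C[!use] <- NA
  C <- matrix(C, d[1], d[2])
  if (normalize) {
    mx <- max(C, na.rm = TRUE)
    if (mx > 0) C <- C / mx
  }
  structure(list(C = C, L = L, mode = mode, window = window,
                 normalized = normalize),
            class = "xcorr_map")
}

#' @export
print.xcorr_map <- function(x, ...) {
  cat(sprintf("<xcorr_map> %dx%d, L = %d, mode %s, frames %d..%d\n",
              nrow(x$C), ncol(x$C), x$L, x$mode, x$window[1], x$window[2]))
  invisible(x)
}

#' Estimate the lag half-width L of the coupling peak
#'
#' L is the half-width at half maximum of the central peak of the
#' correlogram between the whole-field mean fluctuation and the aligned
#' log-power, floored at 1 frame. When the correlogram has no positive
#' central peak, the configured default is returned with attribute
#' `flagged = TRUE`.
#'
#' @param dff a `dff_stack`.
#' @param power an `aligned_power`.
#' @param max_lag correlogram half-width to scan (frames).
#' @param default_L fallback when no positive peak exists.
#' @return integer L (frames), attribute `flagged` when defaulted.
#' @export
estimate_L <- function(dff, power, max_lag = 20L, default_L = 3L) {
  stopifnot(inherits(dff, "dff_stack"))
  d <- dim(dff$dff)
  m <- matrix(dff$dff, d[1] * d[2], d[3])
  tr <- colMeans(m[as.vector(dff$mask), , drop = FALSE])
  cg <- xcorr_trace(tr, power, max_lag = max_lag)
  i0 <- which.max(cg$r)
  pk <- cg$r[i0]
  if (!is.finite(pk) || pk <= 0) {
    out <- as.integer(default_L)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  half <- pk / 2
  # walk out from the peak to the half-max crossings, interpolating
  cross <- function(dir) {
    i <- i0
    while (i + dir >= 1 && i + dir <= nrow(cg) && cg$r[i + dir] >= half)
      i <- i + dir
    if (i + dir < 1 || i + dir > nrow(cg)) return(abs(i - i0))
    frac <- (cg$r[i] - half) / (cg$r[i] - cg$r[i + dir])
    abs(i - i0) + frac
  }
  width <- cross(-1L) + cross(1L)
  out <- max(1L, as.integer(round(width / 2)))
  attr(out, "flagged") <- FALSE
  out
}

#' Cross-correlation maps restricted to activity windows
#'
#' One self-normalized map per frame interval, e.g. interictal vs ictal
#' periods.
#'
#' @param dff a `dff_stack`.
#' @param power an `aligned_power`.
#' @param intervals list of length-2 frame ranges (1-based inclusive).
#' @param L lag half-width in frames.
#' @return list of `xcorr_map`, one per interval (empty list for no
#'   intervals).
#' @export
windowed_maps <- function(dff, power, intervals, L = 3L) {
  lapply(intervals, function(iv)
    xcorr_map(dff, power, L = L, window = iv, normalize = TRUE))
}
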