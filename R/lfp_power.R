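#' LFP trace container
#'
#' @param samples numeric vector of voltage samples (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @return an `lfp_trace` object (list with `samples`, `sampling_rate`,
#'   optional `band` when band-pass filtered).
#' @export
lfp_trace <- function(samples, sampling_rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop2("lfp_trace: sampling_rate must be a positive scalar (Hz)")
  if (length(samples) == 0L) stop2("lfp_trace: zero-length trace")
  if (any(!is.finite(samples))) stop2("lfp_trace: samples must be finite")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 band = NULL),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              if (is.null(x$band)) "" else
                sprintf(", band %g-%g Hz", x$band[1], x$band[2])))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Applies the magnitude-squared response of a 4th-order Butterworth
#' band-pass (the response a forward-backward IIR pass would apply) in the
#' frequency domain, giving an exactly zero-phase, same-length trace. DC is
#' fully removed and out-of-band tones are strongly attenuated.
#'
#' @param trace an [lfp_trace].
#' @param band length-2 numeric, (low, high) corner frequencies in Hz.
#' @param order analog prototype order (default 4).
#' @return filtered [lfp_trace] with the band recorded in `$band`.
#' @export
bandpass <- function(trace, band = c(30, 95), order = 4L) {
  stopifnot(inherits(trace, "lfp_trace"))
  rate <- trace$sampling_rate
  low <- band[1]; high <- band[2]
  if (!(low > 0 && high > low && high < rate / 2))
    stop2("bandpass: need 0 < low < high < Nyquist (", rate / 2, " Hz)")
  x <- trace$samples
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  k <- 0:(nfft - 1L)
  f <- pmin(k, nfft - k) * rate / nfft
  # |H|^2 of Butterworth low-pass at `high` times high-pass at `low`
  H2 <- 1 / (1 + (f / high)^(2 * order))
  fr <- pmax(f, .Machine$double.eps)
  H2 <- H2 / (1 + (low / fr)^(2 * order))
  H2[f == 0] <- 0
  y <- Re(stats::fft(X * H2, inverse = TRUE))[seq_len(n)] / nfft
  out <- lfp_trace(y, rate)
  out$band <- c(low, high)
  out
}

#' Sliding-window log10 RMS power
#'
#' RMS amplitude in a window of `window` seconds translated along the trace
#' in steps of `step` seconds; the base-10 logarithm is reported per window
#' together with the window center times.
#'
#' @param trace an [lfp_trace] (typically band-passed).
#' @param window window length in seconds (default 0.25).
#' @param step window translation in seconds (default 0.05).
#' @return a `band_power` object: list with `times` (s, window centers),
#'   `log_power` (log10 microvolt RMS), `band`, `window`, `step`.
#' @export
sliding_log_rms <- function(trace, window = 0.25, step = 0.05) {
  stopifnot(inherits(trace, "lfp_trace"))
  rate <- trace$sampling_rate
  ws <- round(window * rate)
  ss <- round(step * rate)
  if (ws < 2L) stop2("sliding_log_rms: window must span >= 2 samples")
  if (ss > ws) stop2("sliding_log_rms: step must not exceed window")
  x <- trace$samples
  n <- length(x)
  if (n < ws) stop2("sliding_log_rms: trace shorter than one window")
  n_win <- (n - ws) %/% ss + 1L
  cs2 <- c(0, cumsum(x^2))
  starts <- (seq_len(n_win) - 1L) * ss
  rms <- sqrt((cs2[starts + ws + 1L] - cs2[starts + 1L]) / ws)
  structure(list(times = (starts + ws / 2) / rate,
                 log_power = log10(rms),
                 band = trace$band, window = window, step = step),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> %d windows (%.3g s window, %.3g s step)\n",
              length(x$times), x$window, x$step))
  invisible(x)
}

#' Main Mode / Secondary Mode decomposition of log-RMS power
#'
#' Decomposes the distribution of the windowed log-power into a Gaussian
#' Main Mode (MM), fitted by [trim_gaussian_fit], and a Secondary Mode
#' (SM): all samples of the *original* population farther than
#' `k_sd` fitted SDs above the MM mean. The difference between the SM and
#' MM means (delta SM-MM) measures the extent of high-power events.
#'
#' @param series a `band_power` object from [sliding_log_rms].
#' @param k_sd tail cutoff in SD units (default 2).
#' @param tol,max_iter,robust passed to [trim_gaussian_fit].
#' @return a `power_mode_fit` object: `mm_mean`, `mm_sd`, `threshold`,
#'   `sm_indices`, `sm_mean`, `delta_sm_mm`, `n_sm`, `sm_empty`,
#'   `n_iterations`, `converged`.
#' @export
fit_power_modes <- function(series, k_sd = 2, tol = 0.01, max_iter = 100L,
                            robust = FALSE) {
  stopifnot(inherits(series, "band_power"))
  lp <- series$log_power
  if (length(lp) < 50L)
    stop2("fit_power_modes: need at least 50 windows, got ", length(lp))
  if (any(!is.finite(lp)))
    stop2("fit_power_modes: non-finite log-power (silent window?)")
  fit <- trim_gaussian_fit(lp, k_sd = k_sd, tol = tol, max_iter = max_iter,
                           robust = robust)
  sm_idx <- which(lp > fit$threshold)
  sm_empty <- length(sm_idx) == 0L
  sm_mean <- if (sm_empty) NA_real_ else mean(lp[sm_idx])
  structure(list(mm_mean = fit$mean, mm_sd = fit$sd,
                 threshold = fit$threshold,
                 sm_indices = sm_idx,
                 sm_mean = sm_mean,
                 delta_sm_mm = if (sm_empty) 0 else sm_mean - fit$mean,
                 n_sm = length(sm_idx), sm_empty = sm_empty,
                 n_iterations = fit$n_iterations,
                 converged = fit$converged, k_sd = k_sd,
                 sd_trace = fit$sd_trace),
            class = "power_mode_fit")
}

#' @export
print.power_mode_fit <- function(x, ...) {
  cat(sprintf(
    "<power_mode_fit> MM mean %.4f (sd %.4f), SM n=%d, delta SM-MM %.4f%s\n",
    x$mm_mean, x$mm_sd, x$n_sm, x$delta_sm_mm,
    if (x$sm_empty) " [SM empty]" else ""))
  invisible(x)
}

#' Scalar metrics of a power-mode fit
#'
#' @param fit a `power_mode_fit`.
#' @return list with `mm_mean`, `delta_sm_mm`, `sm_count`, `sm_empty`.
#' @export
mode_metrics <- function(fit) {
  stopifnot(inherits(fit, "power_mode_fit"))
  list(mm_mean = fit$mm_mean, delta_sm_mm = fit$delta_sm_mm,
       sm_count = fit$n_sm, sm_empty = fit$sm_empty)
}

#' Paroxysmal event times from a power-mode fit
#'
#' Upward crossings of the Secondary-Mode threshold, thinned so that
#' consecutive events are at least `min_separation` seconds apart.
#'
#' @param fit a `power_mode_fit`.
#' @param series the `band_power` the fit was computed from.
#' @param min_separation minimum event separation in seconds.
#' @return numeric vector of event times (s).
#' @export
detect_events <- function(fit, series, min_separation = 12.5) {
  stopifnot(inherits(fit, "power_mode_fit"), inherits(series, "band_power"))
  lp <- series$log_power
  above <- lp > fit$threshold
  up <- which(above & !c(FALSE, above[-length(above)]))
  times <- series$times[up]
  keep <- numeric(0)
  for (t in times) {
    if (length(keep) == 0L || t - keep[length(keep)] >= min_separation)
      keep <- c(keep, t)
  }
  keep
}
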