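#' @keywords internal
"_PACKAGE"

# Run code with a private RNG state so generators are deterministic under
# `seed` without clobbering the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# population z-score (sd with denominator n); constant vectors -> all zeros
zscore_pop <- function(v) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) return(rep(0, length(v)))
  (v - m) / s
}

# 2-D cross-correlation of image with kernel via FFT, "same" size output.
# Kernel center is at floor(dim/2)+1. Zero padding outside the image.
xcorr2_fft <- function(image, kernel) {
  di <- dim(image); dk <- dim(kernel)
  n1 <- stats::nextn(di[1] + dk[1], 2L)
  n2 <- stats::nextn(di[2] + dk[2], 2L)
  A <- matrix(0, n1, n2); A[seq_len(di[1]), seq_len(di[2])] <- image
  B <- matrix(0, n1, n2); B[seq_len(dk[1]), seq_len(dk[2])] <- kernel
  C <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) / (n1 * n2)
  # correlation with kernel anchored at its center:
  # score(y, x) = sum over (i, j) of image[y - cy + i, x - cx + j] * kernel[i, j]
  cy <- (dk[1] %/% 2); cx <- (dk[2] %/% 2)
  idx1 <- ((seq_len(di[1]) - cy - 1L) %% n1) + 1L
  idx2 <- ((seq_len(di[2]) - cx - 1L) %% n2) + 1L
  C[idx1, idx2, drop = FALSE]
}

# 3x3 median filter with edge replication
medfilt3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[h, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, w, drop = FALSE])
  stacked <- vapply(1:3, function(i) {
    vapply(1:3, function(j) as.vector(pad[i:(i + h - 1), j:(j + w - 1)]),
           numeric(h * w))
  }, matrix(0, h * w, 3))
  dim(stacked) <- c(h * w, 9L)
  matrix(apply(stacked, 1, stats::median), h, w)
}

# Sum of the 8 neighbors of every pixel in a binary (0/1) matrix
neighbor_count8 <- function(b) {
  h <- nrow(b); w <- ncol(b)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- b
  out <- matrix(0, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out + p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  }
  out
}

# Otsu's automatic threshold on a numeric vector
otsu_threshold <- function(x, n_breaks = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = n_breaks + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# lattice-point disk offsets for a circular ROI of the given pixel radius
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

stop2 <- function(...) stop(..., call. = FALSE)
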