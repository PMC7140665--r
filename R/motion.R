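#' Frame-wise larva motion metric
#'
#' Per frame, the larva's position is the centroid of the supra-threshold
#' silhouette; the displacement is its Euclidean distance (pixels) from
#' the median centroid over the entire sequence. The silhouette threshold
#' defaults to an Otsu split of the pixel intensities. An alternative
#' reading of the position ("area") uses the absolute difference between
#' the frame's silhouette area and the median area, in pixels.
#'
#' @param stack a `fluorescence_stack`.
#' @param silhouette_threshold intensity threshold separating fish from
#'   background; `NULL` (default) = Otsu on the whole stack.
#' @param position `"centroid"` (default) or `"area"`.
#' @return a `motion_series`: data.frame with `frame`, `displacement`
#'   (px, NA where a frame has an empty silhouette), plus attributes
#'   `threshold` and `median_position`.
#' @export
motion_metric <- function(stack, silhouette_threshold = NULL,
                          position = c("centroid", "area")) {
  stopifnot(inherits(stack, "fluorescence_stack"))
  position <- match.arg(position)
  a <- stack$pixels
  d <- dim(a)
  thr <- if (is.null(silhouette_threshold)) otsu_threshold(as.vector(a))
         else silhouette_threshold
  cy <- numeric(d[3]); cx <- numeric(d[3]); area <- numeric(d[3])
  for (k in seq_len(d[3])) {
    sil <- a[, , k] > thr
    n <- sum(sil)
    area[k] <- n
    if (n == 0L) { cy[k] <- NA; cx[k] <- NA; next }
    idx <- which(sil, arr.ind = TRUE)
    cy[k] <- mean(idx[, 1]); cx[k] <- mean(idx[, 2])
  }
  empty <- area == 0L
  if (any(empty))
    warning(sprintf("motion_metric: %d frame(s) with empty silhouette",
                    sum(empty)), call. = FALSE)
  if (position == "centroid") {
    ref <- c(stats::median(cy, na.rm = TRUE), stats::median(cx, na.rm = TRUE))
    disp <- sqrt((cy - ref[1])^2 + (cx - ref[2])^2)
  } else {
    ref <- stats::median(area)
    disp <- abs(area - ref)
    disp[empty] <- NA
  }
  out <- data.frame(frame = seq_len(d[3]), displacement = disp)
  attr(out, "threshold") <- thr
  attr(out, "median_position") <- ref
  class(out) <- c("motion_series", "data.frame")
  out
}
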