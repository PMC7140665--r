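# Small in-code fixtures shared across test files.

# wrap a plain array as a dff_stack without running the full pipeline
as_dff <- function(a, frame_rate = 4, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, dim(a)[1], dim(a)[2])
  structure(list(dff = a, mask = mask, frame_rate = frame_rate,
                 pixel_size = 1),
            class = "dff_stack")
}

# constant-rate frame times for n frames
frame_times_of <- function(n, frame_rate = 4) (seq_len(n) - 0.5) / frame_rate

# a band_power series carrying arbitrary values (for coupling tests)
as_band_power <- function(values, times = seq_along(values)) {
  structure(list(times = times, log_power = values, band = c(30, 95),
                 window = 0.25, step = diff(times[1:2])),
            class = "band_power")
}

# aligned power directly from a vector
as_aligned <- function(values, frame_rate = 4) {
  structure(list(values = values,
                 frame_times = frame_times_of(length(values), frame_rate),
                 series = NULL),
            class = "aligned_power")
}

# tiny fluorescence stack with given constant value
const_stack <- function(value, dims = c(8, 8), frames = 4, frame_rate = 4) {
  fluorescence_stack(array(value, c(dims, frames)), frame_rate = frame_rate)
}
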