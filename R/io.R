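#' Read an LFP trace from delimited text or raw binary
#'
#' Text format: one voltage value (microvolts) per line, optional header
#' lines that fail numeric parsing are skipped, non-finite rows are dropped
#' with a warning reporting the count. Binary format: raw little-endian
#' values of a declared dtype.
#'
#' @param path input file.
#' @param sampling_rate sampling rate in Hz (must be positive).
#' @param format `"text"` or `"binary"`.
#' @param dtype for binary input: `"float32"`, `"float64"`, `"int16"` or
#'   `"int32"`. Must be declared explicitly.
#' @return an [lfp_trace].
#' @export
read_lfp <- function(path, sampling_rate, format = c("text", "binary"),
                     dtype = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("read_lfp: no such file: ", path)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop2("read_lfp: sampling_rate must be positive")
  if (format == "text") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    vals <- suppressWarnings(as.numeric(lines))
    # a leading non-numeric header is tolerated; interior NAs are rejected rows
    if (length(vals) > 0 && is.na(vals[1]) && !nzchar(gsub("[^0-9eE.+-]", "", lines[1])))
      vals <- vals[-1]
  } else {
    if (is.null(dtype))
      stop2("read_lfp: binary input requires a declared dtype")
    spec <- switch(dtype,
                   float32 = list(what = "double", size = 4),
                   float64 = list(what = "double", size = 8),
                   int16 = list(what = "integer", size = 2),
                   int32 = list(what = "integer", size = 4),
                   stop2("read_lfp: undeclared or unknown binary dtype: ", dtype))
    n <- file.size(path) %/% spec$size
    vals <- readBin(path, spec$what, n = n, size = spec$size,
                    endian = "little")
  }
  bad <- sum(!is.finite(vals))
  if (bad > 0) {
    warning(sprintf("read_lfp: dropped %d non-finite sample(s)", bad),
            call. = FALSE)
    vals <- vals[is.finite(vals)]
  }
  if (length(vals) == 0L) stop2("read_lfp: zero-length trace")
  lfp_trace(vals, sampling_rate)
}

#' Write an LFP trace as one value per line
#' @param trace an [lfp_trace].
#' @param path output file.
#' @export
write_lfp <- function(trace, path) {
  stopifnot(inherits(trace, "lfp_trace"))
  writeLines(format(trace$samples, digits = 17, scientific = TRUE,
                    trim = TRUE), path)
  invisible(path)
}

#' Fluorescence stack container
#'
#' @param pixels numeric array (rows, columns, frames), photon counts.
#' @param frame_rate frame rate in Hz.
#' @param pixel_size pixel size in micrometers.
#' @param dark_level mean dark signal in counts (scalar or matrix).
#' @return a `fluorescence_stack` object.
#' @export
fluorescence_stack <- function(pixels, frame_rate, pixel_size = 1,
                               dark_level = 0) {
  stopifnot(length(dim(pixels)) == 3L)
  if (dim(pixels)[3] < 2L) stop2("fluorescence_stack: need >= 2 frames")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop2("fluorescence_stack: frame_rate must be positive")
  structure(list(pixels = pixels, frame_rate = frame_rate,
                 pixel_size = pixel_size, dark_level = dark_level),
            class = "fluorescence_stack")
}

#' @export
print.fluorescence_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fluorescence_stack> %dx%d px, %d frames @ %g Hz\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

#' Read a time-lapse imaging stack from a multi-page TIFF
#'
#' @param path TIFF file.
#' @param frame_rate frame rate in Hz (from the acquisition config; TIFF
#'   tags are not trusted for timing).
#' @param pixel_size pixel size in micrometers.
#' @param dark_level mean dark signal in counts.
#' @return a `fluorescence_stack`.
#' @export
read_stack <- function(path, frame_rate, pixel_size = 1, dark_level = 0) {
  a <- read_tiff_stack(path)
  fluorescence_stack(a, frame_rate = frame_rate, pixel_size = pixel_size,
                     dark_level = dark_level)
}

#' Region atlas: anatomical labels on the analysis grid
#'
#' @param labels integer matrix; 0 = outside the brain.
#' @param names named integer vector mapping region name -> label. Must
#'   cover every nonzero label present; the canonical macro-areas are
#'   `OT` (optic tectum), `Cb` (cerebellum) and `MOb` (medulla oblongata).
#' @return a `region_atlas` object.
#' @export
region_atlas <- function(labels,
                         names = c(OT = 1L, Cb = 2L, MOb = 3L)) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!all(present %in% names))
    stop2("region_atlas: unnamed label(s): ",
          paste(setdiff(present, names), collapse = ", "))
  structure(list(labels = labels, names = names), class = "region_atlas")
}

#' Recording bundle: one paired LFP + imaging session
#'
#' Frame times default to the mean exposure time of each frame,
#' `(i - 0.5) / frame_rate` for frame i = 1..T. Frame times outside the
#' LFP time span are flagged (attribute `frames_out_of_span`), never
#' silently clipped.
#'
#' @param lfp an [lfp_trace].
#' @param stack a `fluorescence_stack`.
#' @param frame_times optional vector of frame mean times (s), strictly
#'   increasing, one per frame.
#' @param atlas optional `region_atlas` on the analysis grid.
#' @param metadata free-form named list (fish id, condition, ...).
#' @return a `recording_bundle`.
#' @export
recording_bundle <- function(lfp, stack, frame_times = NULL, atlas = NULL,
                             metadata = list()) {
  stopifnot(inherits(lfp, "lfp_trace"), inherits(stack, "fluorescence_stack"))
  nt <- dim(stack$pixels)[3]
  if (is.null(frame_times))
    frame_times <- (seq_len(nt) - 0.5) / stack$frame_rate
  if (length(frame_times) != nt)
    stop2("recording_bundle: frame_times length != frame count")
  if (any(diff(frame_times) <= 0))
    stop2("recording_bundle: frame_times must be strictly increasing")
  span <- length(lfp$samples) / lfp$sampling_rate
  out <- structure(list(lfp = lfp, stack = stack, frame_times = frame_times,
                        atlas = atlas, metadata = metadata),
                   class = "recording_bundle")
  attr(out, "frames_out_of_span") <-
    sum(frame_times < 0 | frame_times > span)
  out
}

#' Write analysis products to a results directory
#'
#' Float maps go out as TIFF, tables as tab-separated text, and structured
#' objects (cluster voxel lists, PCA arrays, fits) into an R serialization
#' container (`results.rds`); a JSON manifest records what was written.
#' Reading the directory back reproduces arrays bit-exactly for integer
#' data and to full double precision otherwise.
#'
#' @param products named list. Matrices/arrays are written as TIFF
#'   (`float64`), data frames as TSV, everything else into the container.
#' @param path output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_results <- function(products, path) {
  stopifnot(is.list(products), !is.null(names(products)))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop2("write_results: cannot create ", path)
  manifest <- list()
  container <- list()
  for (nm in names(products)) {
    x <- products[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(path, paste0(nm, ".tsv"))
      utils::write.table(format(x, digits = 17, trim = TRUE), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest[[nm]] <- list(kind = "table", file = basename(f))
    } else if (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L)) {
      f <- file.path(path, paste0(nm, ".tif"))
      fmt <- if (is.integer(x)) "int32" else "float64"
      write_tiff_stack(x, f, format = fmt)
      manifest[[nm]] <- list(kind = "image", file = basename(f), format = fmt,
                             dim = dim(x))
    } else {
      container[[nm]] <- x
      manifest[[nm]] <- list(kind = "object", file = "results.rds")
    }
  }
  if (length(container) > 0)
    saveRDS(container, file.path(path, "results.rds"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a results directory written by [write_results]
#' @param path results directory.
#' @return named list of products.
#' @export
read_results <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  container <- NULL
  out <- list()
  for (nm in names(mf)) {
    entry <- mf[[nm]]
    if (entry$kind == "table") {
      out[[nm]] <- utils::read.table(file.path(path, entry$file),
                                     header = TRUE, sep = "\t")
    } else if (entry$kind == "image") {
      a <- read_tiff_stack(file.path(path, entry$file))
      if (length(entry$dim) == 2L) a <- a[, , 1]
      if (identical(entry$format, "int32")) storage.mode(a) <- "integer"
      out[[nm]] <- a
    } else {
      if (is.null(container))
        container <- readRDS(file.path(path, "results.rds"))
      out[[nm]] <- container[[nm]]
    }
  }
  out
}

#' Read a key/value configuration file
#'
#' Plain-text `key: value` lines (`#` comments allowed). Values are parsed
#' as numeric vectors where possible (comma-separated), otherwise kept as
#' strings. Unknown keys are rejected against [pipeline_config].
#'
#' @param path config file.
#' @param validate reject keys not in the default pipeline configuration.
#' @return named list.
#' @export
read_config <- function(path, validate = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop2("read_config: malformed line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    out[[key]] <- if (!any(is.na(num))) num else val
  }
  if (validate) out <- do.call(pipeline_config, out)
  out
}

#' Write a configuration as `key: value` text
#' @param config named list.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, ": ", paste(format(v, digits = 15, trim = TRUE),
                          collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
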