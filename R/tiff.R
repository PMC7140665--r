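# Minimal classic-TIFF codec for single-channel multi-page stacks.
# No TIFF package ships with the analysis environment, so the package
# carries its own reader/writer restricted to what the pipeline needs:
# uncompressed, strip-based, one sample per pixel, integer (8/16/32 bit,
# signed or unsigned) or IEEE float (32/64 bit) data. The reader accepts
# both byte orders; the writer emits little-endian.

TIFF_FORMATS <- list(
  uint8   = list(bits = 8L,  fmt = 1L), uint16 = list(bits = 16L, fmt = 1L),
  uint32  = list(bits = 32L, fmt = 1L), int16  = list(bits = 16L, fmt = 2L),
  int32   = list(bits = 32L, fmt = 2L), float32 = list(bits = 32L, fmt = 3L),
  float64 = list(bits = 64L, fmt = 3L))

#' Write a numeric array as a multi-page grayscale TIFF
#'
#' @param a numeric matrix or 3-D array (rows, columns, frames).
#' @param path output file.
#' @param format storage format, one of `"uint8"`, `"uint16"`, `"uint32"`,
#'   `"int16"`, `"int32"`, `"float32"`, `"float64"`.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(a, path, format = "float32") {
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  stopifnot(length(dim(a)) == 3L)
  spec <- TIFF_FORMATS[[format]]
  if (is.null(spec)) stop2("write_tiff_stack: unknown format ", format)
  h <- dim(a)[1]; w <- dim(a)[2]; np <- dim(a)[3]
  bytes <- spec$bits %/% 8L
  strip_len <- h * w * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(c(42L), con, size = 2, endian = "little")
  first_ifd <- 8L + np * strip_len
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  put_page <- function(v) {
    if (spec$fmt == 3L) {
      writeBin(as.numeric(v), con, size = bytes, endian = "little")
    } else {
      v <- round(v)
      if (format == "uint8") v <- ifelse(v > 127, v - 256, v)
      if (format == "uint16") v <- ifelse(v > 32767, v - 65536, v)
      writeBin(as.integer(v), con, size = bytes, endian = "little")
    }
  }
  for (k in seq_len(np)) put_page(as.vector(t(a[, , k])))  # row-major
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(c(tag, type)), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT inline
      writeBin(as.integer(c(value, 0L)), con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  ifd_size <- 2L + 10L * 12L + 4L
  for (k in seq_len(np)) {
    writeBin(10L, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)                     # ImageWidth
    entry(257L, 4L, 1L, h)                     # ImageLength
    entry(258L, 3L, 1L, spec$bits)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)                    # Compression: none
    entry(262L, 3L, 1L, 1L)                    # Photometric: BlackIsZero
    entry(273L, 4L, 1L, 8L + (k - 1L) * strip_len)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                    # SamplesPerPixel
    entry(278L, 4L, 1L, h)                     # RowsPerStrip
    entry(279L, 4L, 1L, strip_len)             # StripByteCounts
    entry(339L, 3L, 1L, spec$fmt)              # SampleFormat
    nxt <- if (k < np) first_ifd + k * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a single-channel multi-page TIFF into an array
#'
#' Supports uncompressed strip-based grayscale TIFFs (the format written by
#' [write_tiff_stack] and by common scientific writers when compression is
#' off), in either byte order.
#'
#' @param path TIFF file.
#' @return numeric array (rows, columns, frames).
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop2("read_tiff_stack: no such file: ", path)
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 8L) stop2("read_tiff_stack: not a TIFF (too short)")
  bom <- rawToChar(raw_all[1:2])
  endian <- switch(bom, II = "little", MM = "big",
                   stop2("read_tiff_stack: not a TIFF (bad byte order mark)"))
  ru <- function(off, size, n = 1L) {
    v <- readBin(raw_all[(off + 1L):(off + size * n)], "integer",
                 n = n, size = size, signed = size >= 4L, endian = endian)
    if (size < 4L) v[v < 0] <- v[v < 0] + 2^(8 * size)  # unsigned small ints
    else v[v < 0] <- v[v < 0] + 2^32
    v
  }
  magic <- ru(2L, 2L)
  if (magic != 42L) stop2("read_tiff_stack: not a classic TIFF")
  ifd_off <- ru(4L, 4L)
  pages <- list()
  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  while (ifd_off != 0L) {
    n_ent <- ru(ifd_off, 2L)
    tags <- list()
    for (i in seq_len(n_ent)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- ru(e, 2L); type <- ru(e + 2L, 2L); count <- ru(e + 4L, 4L)
      if (type == 5L || type == 2L) next  # RATIONAL/ASCII tags unused
      tsz <- if (type <= 5L) type_size[type] else 1L
      if (tsz * count <= 4L) {
        val <- ru(e + 8L, tsz, count)
      } else {
        val <- ru(ru(e + 8L, 4L), tsz, count)
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stop2("read_tiff_stack: IFD without size")
    if (g(259, 1L)[1] != 1L) stop2("read_tiff_stack: compressed TIFF unsupported")
    if (g(277, 1L)[1] != 1L) stop2("read_tiff_stack: multi-sample TIFF unsupported")
    bits <- g(258, 1L)[1]; fmt <- g(339, 1L)[1]
    bytes <- bits %/% 8L
    offs <- g(273); lens <- g(279, h * w * bytes)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      npx <- lens[s] %/% bytes
      seg <- raw_all[(offs[s] + 1L):(offs[s] + lens[s])]
      v <- if (fmt == 3L) {
        readBin(seg, "double", n = npx, size = bytes, endian = endian)
      } else {
        x <- readBin(seg, "integer", n = npx, size = bytes,
                     signed = !(fmt == 1L && bytes < 4L), endian = endian)
        if (fmt == 1L && bytes == 4L) x[x < 0] <- x[x < 0] + 2^32
        x
      }
      vals <- c(vals, v)
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd_off <- ru(ifd_off + 2L + n_ent * 12L, 4L)
  }
  if (length(pages) == 0L) stop2("read_tiff_stack: zero frames")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop2("read_tiff_stack: ragged pages (mixed shapes)")
  array(unlist(pages), c(dims[1, 1], dims[2, 1], length(pages)))
}
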