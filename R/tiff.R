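# Minimal baseline multi-page TIFF I/O (little-endian, uncompressed,
# grayscale, strip-based; 8/16-bit unsigned or 32-bit float). Implemented
# here because no TIFF package is available in the target library; the
# writer records the voxel size in an ImageDescription JSON tag that the
# reader (and ImageJ-style tooling) can parse.

.tiff_tag <- function(id, type, count, value_or_offset) {
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_or_offset)
}

.le4 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")
.le2pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little"), as.raw(c(0, 0)))

#' Write a voxel stack as a multi-page TIFF
#'
#' One grayscale 32-bit float page per z-plane, uncompressed little-endian,
#' with the physical voxel size stored as JSON in the ImageDescription tag.
#'
#' @param stack a [voxel_stack()].
#' @param path output file.
#' @export
write_tiff <- function(stack, path) {
  a <- stack$intensities
  d <- dim(a)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  desc <- sprintf('{"voxel_size_nm":[%g,%g,%g]}', stack$voxel_size_nm[1],
                  stack$voxel_size_nm[2], stack$voxel_size_nm[3])
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  # layout: header(8) | desc | pages of [pixel data | IFD]
  desc_off <- 8L
  strip_bytes <- nx * ny * 4L
  n_tags <- 9L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  page_bytes <- strip_bytes + ifd_bytes
  first_ifd <- desc_off + length(desc_raw) + strip_bytes
  writeBin(.le4(first_ifd), con)
  writeBin(desc_raw, con)
  for (k in seq_len(nz)) {
    page_start <- desc_off + length(desc_raw) + (k - 1L) * page_bytes
    strip_off <- page_start
    ifd_off <- page_start + strip_bytes
    # the next page's IFD sits after that page's pixel data
    next_ifd <- if (k < nz) ifd_off + ifd_bytes + strip_bytes else 0L
    # pixel data row-major: x runs fastest within each image row (y), which
    # is exactly R's column-major order for the [x, y] slice
    writeBin(as.numeric(a[, , k]), con, size = 4, endian = "little")
    writeBin(as.integer(n_tags), con, size = 2, endian = "little")
    writeBin(.tiff_tag(256, 3, 1, .le2pad(nx)), con)          # ImageWidth
    writeBin(.tiff_tag(257, 3, 1, .le2pad(ny)), con)          # ImageLength
    writeBin(.tiff_tag(258, 3, 1, .le2pad(32)), con)          # BitsPerSample
    writeBin(.tiff_tag(259, 3, 1, .le2pad(1)), con)           # Compression
    writeBin(.tiff_tag(262, 3, 1, .le2pad(1)), con)           # BlackIsZero
    writeBin(.tiff_tag(270, 2, length(desc_raw), .le4(desc_off)), con)
    writeBin(.tiff_tag(273, 4, 1, .le4(strip_off)), con)      # StripOffsets
    writeBin(.tiff_tag(279, 4, 1, .le4(strip_bytes)), con)    # StripByteCnt
    writeBin(.tiff_tag(339, 3, 1, .le2pad(3)), con)           # float
    writeBin(.le4(next_ifd), con)
  }
  invisible(path)
}

.read_le <- function(raw, off, size, n = 1L, what = "integer",
                     signed = TRUE) {
  if (size == 4L) signed <- TRUE  # readBin limitation; offsets stay < 2^31
  readBin(raw[(off + 1):(off + size * n)], what = what, n = n, size = size,
          endian = "little", signed = signed)
}

#' Read a multi-page TIFF into a voxel stack
#'
#' Supports baseline uncompressed little-endian grayscale TIFFs with 8- or
#' 16-bit unsigned or 32-bit float samples (including the files written by
#' [write_tiff()]). If no voxel-size metadata is found, `default_voxel_nm`
#' is used with a warning.
#'
#' @param path TIFF file.
#' @param default_voxel_nm fallback voxel size, default `c(110, 110, 300)`.
#' @return a [voxel_stack()].
#' @export
read_tiff <- function(path, default_voxel_nm = c(110, 110, 300)) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 8)
    .stop_erythro(sprintf("'%s' is not a TIFF file (too short)", path),
                  "format_error")
  if (rawToChar(raw[1:2]) != "II")
    .stop_erythro("only little-endian ('II') TIFFs are supported",
                  "format_error")
  if (.read_le(raw, 2, 2) != 42L)
    .stop_erythro(sprintf("'%s' is not a TIFF file", path), "format_error")
  ifd_off <- .read_le(raw, 4, 4)
  planes <- list()
  desc <- NULL
  shape <- NULL
  while (ifd_off != 0) {
    n_tags <- .read_le(raw, ifd_off, 2)
    tags <- list()
    for (t in seq_len(n_tags)) {
      base <- ifd_off + 2 + (t - 1) * 12
      id <- .read_le(raw, base, 2, signed = FALSE)
      type <- .read_le(raw, base + 2, 2)
      count <- .read_le(raw, base + 4, 4)
      tags[[as.character(id)]] <- list(type = type, count = count,
                                       base = base)
    }
    tagval <- function(id, n = 1L) {
      tg <- tags[[as.character(id)]]
      if (is.null(tg)) return(NULL)
      sz <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)[as.character(tg$type)]
      total <- sz * tg$count
      off <- if (total <= 4) tg$base + 8 else .read_le(raw, tg$base + 8, 4)
      if (tg$type == 2) return(rawToChar(raw[(off + 1):(off + tg$count - 1)]))
      .read_le(raw, off, sz, tg$count, signed = FALSE)
    }
    w <- tagval(256); h <- tagval(257)
    bits <- tagval(258) %||% 1L
    comp <- tagval(259) %||% 1L
    fmt <- tagval(339) %||% 1L
    if (comp != 1L)
      .stop_erythro("compressed TIFFs are not supported", "format_error")
    if (is.null(w) || is.null(h))
      .stop_erythro("TIFF page missing dimensions", "format_error")
    if (!is.null(shape) && any(shape != c(w, h)))
      .stop_erythro("inconsistent plane shapes across TIFF pages",
                    "format_error")
    shape <- c(w, h)
    d <- tagval(270)
    if (!is.null(d)) desc <- d
    offs <- tagval(273, n = NULL)
    cnts <- tagval(279, n = NULL)
    rows_strip <- tagval(278) %||% h
    px <- numeric(0)
    for (s in seq_along(offs)) {
      nbytes <- cnts[s]
      chunk <- raw[(offs[s] + 1):(offs[s] + nbytes)]
      px <- c(px, switch(as.character(bits),
        `8` = as.numeric(readBin(chunk, "integer", n = nbytes, size = 1,
                                 signed = FALSE)),
        `16` = as.numeric(readBin(chunk, "integer", n = nbytes / 2, size = 2,
                                  endian = "little", signed = FALSE)),
        `32` = {
          if (fmt != 3L)
            .stop_erythro("32-bit integer TIFFs are not supported",
                          "format_error")
          readBin(chunk, "numeric", n = nbytes / 4, size = 4,
                  endian = "little")
        },
        .stop_erythro(sprintf("unsupported bit depth %d", bits),
                      "format_error")))
    }
    planes[[length(planes) + 1L]] <- matrix(px, nrow = w)
    ifd_off <- .read_le(raw, ifd_off + 2 + n_tags * 12, 4)
  }
  if (!length(planes))
    .stop_erythro(sprintf("'%s' contains no image pages", path),
                  "format_error")
  nx <- shape[1]; ny <- shape[2]; nz <- length(planes)
  arr <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) arr[, , k] <- planes[[k]]
  vs <- NULL
  if (!is.null(desc) && grepl("voxel_size_nm", desc, fixed = TRUE)) {
    vs <- tryCatch(jsonlite::fromJSON(desc)$voxel_size_nm,
                   error = function(e) NULL)
  }
  if (is.null(vs)) {
    warning("no voxel-size metadata found; using defaults (",
            paste(default_voxel_nm, collapse = ", "), " nm)")
    vs <- default_voxel_nm
  }
  voxel_stack(arr, vs)
}
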