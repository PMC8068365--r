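# Minimal baseline TIFF codec.
#
# No TIFF package ships with this toolchain, so the package carries its own
# reader/writer for the subset it needs: uncompressed baseline TIFF,
# grayscale 8/16-bit (multi-page) and interleaved 8-bit RGB, plus an OME-XML
# ImageDescription on the first page for multichannel / multidimensional
# metadata. The writer always emits little-endian files; the reader accepts
# both byte orders. Tiled TIFF, compression, and palette images are out of
# scope and surface as structured read errors upstream.

# ---- byte helpers -----------------------------------------------------------

.u16le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

.u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256,
           (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# Read n unsigned little/big-endian integers of `size` bytes from raw buffer
# at 1-based offset. Returns doubles (offsets may exceed .Machine$integer.max).
.read_uint <- function(buf, offset, size, n, little) {
  idx <- offset + seq_len(size * n) - 1
  if (max(idx) > length(buf)) stop("TIFF: truncated file", call. = FALSE)
  bytes <- as.numeric(buf[idx])
  m <- matrix(bytes, nrow = size)
  weights <- if (little) 256^(seq_len(size) - 1) else 256^(rev(seq_len(size)) - 1)
  as.numeric(weights %*% m)
}

# ---- writer -----------------------------------------------------------------

.plane_bytes <- function(plane) {
  v <- as.vector(t(plane$pixels))  # row-major strip order
  if (plane$bit_depth == 8L) {
    as.raw(v)
  } else {
    out <- raw(2L * length(v))
    out[c(TRUE, FALSE)] <- as.raw(v %% 256L)
    out[c(FALSE, TRUE)] <- as.raw(v %/% 256L)
    out
  }
}

.ifd_entry <- function(tag, type, count, value_raw4) {
  c(.u16le(tag), .u16le(type), .u32le(count), value_raw4)
}

# OME-XML description declaring channel/slice/frame counts. Extra <Image>
# elements stand in for additional series/positions.
.ome_description <- function(size_x, size_y, size_c, size_z, size_t,
                             bit_depth, n_series) {
  pixels <- sprintf(
    paste0('<Pixels ID="Pixels:%d" DimensionOrder="XYCZT" Type="uint%d" ',
           'SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="%d" SizeT="%d"/>'),
    seq_len(n_series) - 1L, bit_depth, size_x, size_y, size_c, size_z, size_t
  )
  images <- sprintf('<Image ID="Image:%d">%s</Image>',
                    seq_len(n_series) - 1L, pixels)
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    paste(images, collapse = ""),
    "</OME>"
  )
}

#' Write a grayscale multi-page TIFF
#'
#' Pages are written in the order given, one uncompressed strip per page.
#' With `ome = TRUE` an OME-XML `ImageDescription` is attached to the first
#' page declaring the channel/slice/frame structure of the page sequence
#' (page order: channels fastest, then z, then t, matching `DimensionOrder
#' XYCZT`).
#'
#' @param planes list of [channel_plane()] objects sharing size and depth;
#'   `length(planes)` must equal `size_c * size_z * size_t`.
#' @param path output file path.
#' @param ome attach OME-XML metadata to the first page.
#' @param size_c,size_z,size_t declared channel / z-slice / time-frame counts.
#' @param n_series number of `<Image>` series declared in the OME metadata
#'   (>1 emulates multipoint files; pixel data is written for the first
#'   series only).
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(planes, path, ome = FALSE,
                            size_c = length(planes), size_z = 1L,
                            size_t = 1L, n_series = 1L) {
  stopifnot(length(planes) >= 1L)
  check_planes_conformable(planes)
  if (length(planes) != size_c * size_z * size_t) {
    stop("page count must equal size_c * size_z * size_t", call. = FALSE)
  }
  w <- planes[[1L]]$width
  h <- planes[[1L]]$height
  bits <- planes[[1L]]$bit_depth

  desc_raw <- NULL
  if (ome) {
    desc <- .ome_description(w, h, size_c, size_z, size_t, bits, n_series)
    desc_raw <- c(charToRaw(desc), as.raw(0L))  # NUL-terminated ASCII
  }

  n_pages <- length(planes)
  strip_bytes <- lapply(planes, .plane_bytes)
  strip_len <- vapply(strip_bytes, length, integer(1))

  # Layout: header | strips | (description) | IFDs
  offset <- 8
  strip_offsets <- numeric(n_pages)
  for (i in seq_len(n_pages)) {
    strip_offsets[i] <- offset
    offset <- offset + strip_len[i]
    if (offset %% 2 == 1) offset <- offset + 1  # word-align
  }
  desc_offset <- 0
  if (!is.null(desc_raw)) {
    desc_offset <- offset
    offset <- offset + length(desc_raw)
    if (offset %% 2 == 1) offset <- offset + 1
  }

  ifd_offsets <- numeric(n_pages)
  n_entries <- integer(n_pages)
  for (i in seq_len(n_pages)) {
    n_entries[i] <- 9L + (i == 1L && !is.null(desc_raw))
    ifd_offsets[i] <- offset
    offset <- offset + 2 + 12 * n_entries[i] + 4
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16le(42), .u32le(ifd_offsets[1L])), con)
  pos <- 8
  for (i in seq_len(n_pages)) {
    writeBin(strip_bytes[[i]], con)
    pos <- pos + strip_len[i]
    if (pos %% 2 == 1) { writeBin(as.raw(0L), con); pos <- pos + 1 }
  }
  if (!is.null(desc_raw)) {
    writeBin(desc_raw, con)
    pos <- pos + length(desc_raw)
    if (pos %% 2 == 1) { writeBin(as.raw(0L), con); pos <- pos + 1 }
  }
  for (i in seq_len(n_pages)) {
    entries <- list(
      .ifd_entry(256, 4, 1, .u32le(w)),
      .ifd_entry(257, 4, 1, .u32le(h)),
      .ifd_entry(258, 3, 1, c(.u16le(bits), .u16le(0))),
      .ifd_entry(259, 3, 1, c(.u16le(1), .u16le(0))),
      .ifd_entry(262, 3, 1, c(.u16le(1), .u16le(0)))
    )
    if (i == 1L && !is.null(desc_raw)) {
      entries <- c(entries, list(
        .ifd_entry(270, 2, length(desc_raw), .u32le(desc_offset))
      ))
    }
    entries <- c(entries, list(
      .ifd_entry(273, 4, 1, .u32le(strip_offsets[i])),
      .ifd_entry(277, 3, 1, c(.u16le(1), .u16le(0))),
      .ifd_entry(278, 4, 1, .u32le(h)),
      .ifd_entry(279, 4, 1, .u32le(strip_len[i]))
    ))
    next_ifd <- if (i < n_pages) ifd_offsets[i + 1L] else 0
    writeBin(.u16le(length(entries)), con)
    for (e in entries) writeBin(e, con)
    writeBin(.u32le(next_ifd), con)
  }
  invisible(path)
}

#' Write an 8-bit interleaved RGB TIFF
#'
#' @param rgb integer array `height x width x 3` with values in 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_rgb <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  # interleave to RGBRGB... in row-major order
  px <- aperm(rgb, c(3L, 2L, 1L))
  strip <- as.raw(as.vector(px))
  strip_offset <- 8
  bps_offset <- strip_offset + length(strip)
  if (bps_offset %% 2 == 1) bps_offset <- bps_offset + 1
  ifd_offset <- bps_offset + 6

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16le(42), .u32le(ifd_offset)), con)
  writeBin(strip, con)
  if ((8 + length(strip)) %% 2 == 1) writeBin(as.raw(0L), con)
  writeBin(c(.u16le(8), .u16le(8), .u16le(8)), con)  # BitsPerSample array
  entries <- list(
    .ifd_entry(256, 4, 1, .u32le(w)),
    .ifd_entry(257, 4, 1, .u32le(h)),
    .ifd_entry(258, 3, 3, .u32le(bps_offset)),
    .ifd_entry(259, 3, 1, c(.u16le(1), .u16le(0))),
    .ifd_entry(262, 3, 1, c(.u16le(2), .u16le(0))),
    .ifd_entry(273, 4, 1, .u32le(strip_offset)),
    .ifd_entry(277, 3, 1, c(.u16le(3), .u16le(0))),
    .ifd_entry(278, 4, 1, .u32le(h)),
    .ifd_entry(279, 4, 1, .u32le(length(strip))),
    .ifd_entry(284, 3, 1, c(.u16le(1), .u16le(0)))
  )
  writeBin(.u16le(length(entries)), con)
  for (e in entries) writeBin(e, con)
  writeBin(.u32le(0), con)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

.tiff_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8)

.read_ifd_values <- function(buf, type, count, value_field_offset, little) {
  size <- .tiff_type_size[as.character(type)]
  if (is.na(size)) return(NULL)  # unsupported field type: ignore tag
  total <- size * count
  off <- if (total <= 4) value_field_offset else {
    .read_uint(buf, value_field_offset, 4, 1, little)[1] + 1
  }
  if (type == 2) {  # ASCII
    bytes <- buf[off + seq_len(count) - 1]
    return(rawToChar(bytes[bytes != as.raw(0L)]))
  }
  if (type == 5) {  # RATIONAL: numerator/denominator pairs
    v <- .read_uint(buf, off, 4, 2 * count, little)
    return(v[c(TRUE, FALSE)] / pmax(v[c(FALSE, TRUE)], 1))
  }
  .read_uint(buf, off, size, count, little)
}

#' Read a baseline TIFF file
#'
#' Supports uncompressed grayscale (8/16-bit) and interleaved 8-bit RGB
#' pages, multi-strip or single-strip. Interleaved RGB pages are split into
#' three channel planes.
#'
#' @param path TIFF file path.
#' @return list with `pages` (one entry per IFD: a list of [channel_plane()]
#'   objects, length 1 for grayscale and 3 for RGB) and `description` (the
#'   first `ImageDescription` string, or `NULL`).
#' @export
read_tiff <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 8) stop("TIFF: file too short", call. = FALSE)
  order_tag <- rawToChar(buf[1:2])
  little <- switch(order_tag, II = TRUE, MM = FALSE,
                   stop("TIFF: bad byte-order mark", call. = FALSE))
  if (.read_uint(buf, 3, 2, 1, little) != 42) {
    stop("TIFF: bad magic number", call. = FALSE)
  }
  ifd_offset <- .read_uint(buf, 5, 4, 1, little) + 1

  pages <- list()
  description <- NULL
  while (ifd_offset > 1) {
    n_entries <- .read_uint(buf, ifd_offset, 2, 1, little)
    tags <- list()
    for (k in seq_len(n_entries)) {
      ent <- ifd_offset + 2 + 12 * (k - 1)
      tag <- .read_uint(buf, ent, 2, 1, little)
      type <- .read_uint(buf, ent + 2, 2, 1, little)
      count <- .read_uint(buf, ent + 4, 4, 1, little)
      vals <- .read_ifd_values(buf, type, count, ent + 8, little)
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    tg <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- tg(256); h <- tg(257)
    if (is.null(w) || is.null(h)) stop("TIFF: IFD missing dimensions", call. = FALSE)
    compression <- tg(259, 1)
    if (compression != 1) {
      stop(sprintf("TIFF: unsupported compression scheme (%d)", compression),
           call. = FALSE)
    }
    spp <- tg(277, 1)
    bits <- unique(tg(258, 8))
    if (length(bits) != 1L || !bits %in% c(8, 16)) {
      stop("TIFF: only 8- and 16-bit samples are supported", call. = FALSE)
    }
    if (!tg(284, 1) %in% 1) {
      stop("TIFF: planar (non-interleaved) configuration is unsupported",
           call. = FALSE)
    }
    if (is.null(tg(273))) stop("TIFF: missing strip offsets", call. = FALSE)
    strip_off <- tg(273)
    strip_cnt <- tg(279, (w * h * spp * bits / 8) / length(strip_off))
    raw_strip <- do.call(c, lapply(seq_along(strip_off), function(i) {
      buf[strip_off[i] + seq_len(strip_cnt[i])]
    }))
    n_px <- w * h * spp
    vals <- if (bits == 8) {
      as.integer(raw_strip[seq_len(n_px)])
    } else {
      .read_uint(raw_strip, 1, 2, n_px, little)
    }
    if (is.null(description)) description <- tg(270)

    if (spp == 1) {
      m <- matrix(as.integer(vals), nrow = h, ncol = w, byrow = TRUE)
      pages[[length(pages) + 1L]] <- list(channel_plane(m, as.integer(bits)))
    } else if (spp == 3) {
      planes <- lapply(1:3, function(s) {
        m <- matrix(as.integer(vals[seq(s, n_px, by = 3)]),
                    nrow = h, ncol = w, byrow = TRUE)
        channel_plane(m, as.integer(bits))
      })
      pages[[length(pages) + 1L]] <- planes
    } else {
      stop(sprintf("TIFF: unsupported samples per pixel (%d)", spp),
           call. = FALSE)
    }
    ifd_offset <- .read_uint(buf, ifd_offset + 2 + 12 * n_entries, 4, 1,
                             little) + 1
  }
  list(pages = pages, description = description)
}
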