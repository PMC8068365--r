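# Image input/output: multichannel TIFF/OME-TIFF reading into channel
# planes with dimension metadata, and RGB montage export (PNG/JPEG/TIFF).

.parse_ome_attr <- function(xml, attr) {
  m <- regmatches(xml, gregexpr(sprintf('%s="([0-9]+)"', attr), xml))[[1L]]
  if (!length(m)) return(integer(0))
  as.integer(sub(sprintf('%s="([0-9]+)"', attr), "\\1", m))
}

# Dimension metadata for one image file: channel / z / t / series counts
# plus pixel geometry. For plain TIFF without OME metadata, pages are taken
# as channels (the caller decides whether that matches the declared channel
# count); interleaved RGB counts as 3 channels.
dimension_info <- function(n_channels, n_z, n_t, n_series, bit_depth,
                           width, height) {
  structure(
    list(n_channels = as.integer(n_channels), n_z = as.integer(n_z),
         n_t = as.integer(n_t), n_series = as.integer(n_series),
         bit_depth = as.integer(bit_depth), width = as.integer(width),
         height = as.integer(height)),
    class = "dimension_info"
  )
}

#' Read a multichannel image file
#'
#' Reads a plain TIFF or OME-TIFF into a list of channel planes plus
#' dimension metadata. The reader itself does not reject files with extra
#' z-slices, time frames or series: it reports them in the metadata, and
#' dataset discovery decides what to skip. For plain multi-page TIFF without
#' OME metadata every page is reported as a channel; a single interleaved
#' RGB page is reported as 3 channels. For OME-TIFF the declared
#' `SizeC`/`SizeZ`/`SizeT` and the number of `<Image>` series are used, and
#' the returned planes are the channels of the first z/t/series position.
#'
#' @param path image file path.
#' @param reader optional plugin hook for proprietary formats: a function
#'   `function(path)` returning `list(planes = <list of channel_plane>,
#'   info = <dimension_info>)`. When supplied it replaces the native TIFF
#'   reader.
#' @return list with `planes` (list of [channel_plane()]) and `info`
#'   (dimension metadata: `n_channels`, `n_z`, `n_t`, `n_series`,
#'   `bit_depth`, `width`, `height`).
#' @export
read_image <- function(path, reader = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  if (!is.null(reader)) {
    out <- reader(path)
    if (!is.list(out) || is.null(out$planes) || is.null(out$info)) {
      stop("plugin reader must return list(planes=, info=)", call. = FALSE)
    }
    return(out)
  }
  tif <- read_tiff(path)
  n_pages <- length(tif$pages)
  first <- tif$pages[[1L]]
  bit_depth <- first[[1L]]$bit_depth
  width <- first[[1L]]$width
  height <- first[[1L]]$height

  is_ome <- !is.null(tif$description) && grepl("<OME", tif$description,
                                               fixed = TRUE)
  if (is_ome) {
    size_c <- .parse_ome_attr(tif$description, "SizeC")
    size_z <- .parse_ome_attr(tif$description, "SizeZ")
    size_t <- .parse_ome_attr(tif$description, "SizeT")
    n_series <- length(regmatches(tif$description,
                                  gregexpr("<Image[ >]", tif$description))[[1L]])
    if (n_series < 1L) n_series <- 1L
    nc <- if (length(size_c)) size_c[1L] else n_pages
    nz <- if (length(size_z)) size_z[1L] else 1L
    nt <- if (length(size_t)) size_t[1L] else 1L
    info <- dimension_info(nc, nz, nt, n_series, bit_depth, width, height)
    # DimensionOrder XYCZT: first `nc` pages are the channels of z=1, t=1.
    n_take <- min(nc, n_pages)
    planes <- lapply(tif$pages[seq_len(n_take)], `[[`, 1L)
  } else {
    spp <- length(first)
    if (n_pages == 1L && spp == 3L) {
      info <- dimension_info(3L, 1L, 1L, 1L, bit_depth, width, height)
      planes <- first
    } else {
      info <- dimension_info(n_pages, 1L, 1L, 1L, bit_depth, width, height)
      planes <- lapply(tif$pages, `[[`, 1L)
    }
  }
  list(planes = planes, info = info)
}

#' Write an RGB montage image
#'
#' PNG and TIFF are lossless (pixel-exact round trip); JPEG is written at
#' quality 90 and is lossy.
#'
#' @param tile an `rgb_tile` (see [colorize()]) or an integer array
#'   `height x width x 3` in 0..255.
#' @param path output path (extension not enforced).
#' @param format `"png"`, `"jpeg"` or `"tiff"`.
#' @param quality JPEG quality in 1..100 (default 90); ignored otherwise.
#' @return `path`, invisibly.
#' @export
write_montage <- function(tile, path, format = c("png", "jpeg", "tiff"),
                          quality = 90) {
  format <- match.arg(format)
  rgb <- if (inherits(tile, "rgb_tile")) tile$pixels else tile
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  arr <- rgb / 255
  switch(format,
    png = png::writePNG(arr, target = path),
    jpeg = jpeg::writeJPEG(arr, target = path, quality = quality / 100),
    tiff = write_tiff_rgb(rgb, path)
  )
  invisible(path)
}

# Extension for an export format.
montage_extension <- function(format) {
  switch(format, png = "png", jpeg = "jpg", tiff = "tif",
         stop("unknown export format", call. = FALSE))
}
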