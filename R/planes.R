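#' Single-channel intensity plane
#'
#' The elementary pixel container of the package: one grayscale channel of a
#' field of view, stored as an integer matrix (rows = image rows, columns =
#' image columns) together with its bit depth. Valid intensities are
#' `0 .. 2^bit_depth - 1` (255 for 8-bit, 65535 for 16-bit).
#'
#' @param pixels integer matrix of non-negative intensities; `nrow` is the
#'   image height, `ncol` the width.
#' @param bit_depth 8 or 16.
#' @return An object of class `channel_plane` with fields `pixels`,
#'   `bit_depth`, `width`, `height`.
#' @export
channel_plane <- function(pixels, bit_depth) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  mx <- bit_depth_max(bit_depth)
  rng <- range(pixels)
  if (anyNA(pixels) || rng[1L] < 0L || rng[2L] > mx) {
    stop(sprintf("pixel intensities must lie in [0, %d]", mx), call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      bit_depth = as.integer(bit_depth),
      width = ncol(pixels),
      height = nrow(pixels)
    ),
    class = "channel_plane"
  )
}

#' @export
print.channel_plane <- function(x, ...) {
  cat(sprintf(
    "<channel_plane> %dx%d px, %d-bit, intensity range [%d, %d]\n",
    x$width, x$height, x$bit_depth, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

# Largest representable intensity for a bit depth (255 / 65535; real pixel
# values never reach 2^bit_depth).
bit_depth_max <- function(bit_depth) {
  as.integer(2^as.integer(bit_depth) - 1)
}

is_channel_plane <- function(x) inherits(x, "channel_plane")

# All planes of one record must agree in size and depth.
check_planes_conformable <- function(planes) {
  stopifnot(length(planes) >= 1L)
  w <- vapply(planes, function(p) p$width, integer(1))
  h <- vapply(planes, function(p) p$height, integer(1))
  b <- vapply(planes, function(p) p$bit_depth, integer(1))
  if (length(unique(w)) > 1L || length(unique(h)) > 1L) {
    stop("channel planes differ in pixel dimensions", call. = FALSE)
  }
  if (length(unique(b)) > 1L) {
    stop("channel planes differ in bit depth", call. = FALSE)
  }
  invisible(TRUE)
}
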