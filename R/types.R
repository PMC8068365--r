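#' Describe an image dataset on disk
#'
#' A dataset is a parent directory with one subfolder per experimental
#' condition. Each subfolder holds the fields of view of that condition,
#' either as one multichannel file per field of view (`structure =
#' "single_file"`) or as one single-channel file per channel whose names
#' differ only by a channel identifier substring (`structure =
#' "separated_channels"`).
#'
#' @param parent_path path to the parent (experiment) directory.
#' @param structure `"single_file"` or `"separated_channels"`.
#' @param extension image file extension without the dot (matched
#'   case-insensitively), e.g. `"tif"`.
#' @param n_channels number of acquired channels per field of view.
#' @param channel_identifiers character vector of length `n_channels`;
#'   required iff `structure = "separated_channels"`. Identifiers must be
#'   non-empty, pairwise distinct, and none may be a substring of another
#'   (otherwise grouping files into fields of view is ambiguous).
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(parent_path,
                         structure = c("single_file", "separated_channels"),
                         extension = "tif",
                         n_channels = 1L,
                         channel_identifiers = NULL) {
  structure_mode <- match.arg(structure)
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) {
    stop("`n_channels` must be a positive integer", call. = FALSE)
  }
  extension <- sub("^\\.", "", as.character(extension))
  if (!nzchar(extension)) stop("`extension` must be non-empty", call. = FALSE)

  if (structure_mode == "separated_channels") {
    ids <- as.character(channel_identifiers)
    if (length(ids) != n_channels) {
      stop(sprintf(
        "`channel_identifiers` must have length n_channels (%d), got %d",
        n_channels, length(ids)
      ), call. = FALSE)
    }
    if (any(!nzchar(ids))) {
      stop("channel identifiers must be non-empty", call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      stop("channel identifiers must be pairwise distinct", call. = FALSE)
    }
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i != j && grepl(ids[i], ids[j], fixed = TRUE)) {
          stop(sprintf(
            "channel identifier \"%s\" is a substring of \"%s\"; grouping would be ambiguous",
            ids[i], ids[j]
          ), call. = FALSE)
        }
      }
    }
  } else {
    ids <- NULL
  }

  base::structure(
    list(
      parent_path = parent_path,
      structure = structure_mode,
      extension = extension,
      n_channels = n_channels,
      channel_identifiers = ids
    ),
    class = "dataset_spec"
  )
}

#' Contrast-enhancement policy for a run
#'
#' Three modes are supported. `"none"` leaves pixel data untouched.
#' `"autoscale"` min-max stretches every channel of every image independently
#' to the full bit depth (no saturation). `"user_defined"` gives per-channel
#' control: whether to enhance at all, what fraction of pixels may saturate,
#' and whether stretch bounds are computed jointly over all images of a
#' montage (preserving between-image intensity comparisons) or per image
#' (maximizing each image's contrast, invalidating comparisons).
#'
#' @param mode `"none"`, `"autoscale"` or `"user_defined"`.
#' @param channels for `"user_defined"` only: a list with one entry per
#'   channel, each built by [channel_contrast()].
#' @return An object of class `contrast_policy`.
#' @seealso [channel_contrast()]
#' @export
contrast_policy <- function(mode = c("none", "autoscale", "user_defined"),
                            channels = NULL) {
  mode <- match.arg(mode)
  if (mode == "user_defined") {
    if (is.null(channels) || length(channels) < 1L) {
      stop("user_defined mode requires per-channel settings", call. = FALSE)
    }
    ok <- vapply(channels, function(x) inherits(x, "channel_contrast"), logical(1))
    if (!all(ok)) {
      stop("each per-channel entry must be built by channel_contrast()", call. = FALSE)
    }
  } else {
    channels <- NULL
  }
  base::structure(list(mode = mode, channels = channels),
                  class = "contrast_policy")
}

# Canonical saturation menu (fractions): 0%, 0.01%, 0.1%, 0.4%, 1%.
.canonical_saturations <- c(0, 0.0001, 0.001, 0.004, 0.01)

#' Per-channel contrast settings
#'
#' @param enhance logical; `FALSE` leaves this channel untouched.
#' @param saturation_fraction fraction of pixels allowed to clip to black or
#'   white during stretching, in `[0, 0.01]`. The canonical menu is 0,
#'   0.0001, 0.001, 0.004, 0.01 (i.e. 0%, 0.01%, 0.1%, 0.4%, 1%); other
#'   values in range are accepted but flagged in the run log.
#' @param scope `"joint"` (one bounds pair pooled over all images of the
#'   montage) or `"individual"` (bounds per image).
#' @return An object of class `channel_contrast`.
#' @export
channel_contrast <- function(enhance = TRUE,
                             saturation_fraction = 0,
                             scope = c("joint", "individual")) {
  scope <- match.arg(scope)
  saturation_fraction <- as.numeric(saturation_fraction)
  if (is.na(saturation_fraction) ||
      saturation_fraction < 0 || saturation_fraction > 0.01) {
    stop("`saturation_fraction` must lie in [0, 0.01]", call. = FALSE)
  }
  noncanonical <- !isTRUE(any(abs(saturation_fraction - .canonical_saturations) < 1e-12))
  base::structure(
    list(
      enhance = isTRUE(enhance),
      saturation_fraction = saturation_fraction,
      scope = scope,
      noncanonical = noncanonical
    ),
    class = "channel_contrast"
  )
}

.palette_colors <- list(
  red     = c(1, 0, 0),
  green   = c(0, 1, 0),
  blue    = c(0, 0, 1),
  gray    = c(1, 1, 1),
  cyan    = c(0, 1, 1),
  magenta = c(1, 0, 1),
  yellow  = c(1, 1, 0)
)

# Default palette by channel position; wraps around past 7 channels.
.default_palette_order <- c("blue", "green", "red", "gray", "cyan",
                            "magenta", "yellow")

#' Montage rendering options
#'
#' @param palette character vector of length `n_channels` assigning each
#'   channel a merge color from red, green, blue, gray, cyan, magenta,
#'   yellow. `NULL` uses the default order blue, green, red, gray, cyan,
#'   magenta, yellow.
#' @param n_channels number of channels (used to expand the default palette).
#' @param label_tiles draw "C<k> <folder> <file>" / "merge <folder> <file>"
#'   on each tile.
#' @param orientation `"horizontal"` (rows = images, columns = channels +
#'   merge) or `"vertical"` (the transpose).
#' @param export_format `"png"`, `"jpeg"` or `"tiff"`.
#' @param omit_from_singles channel indices not shown as single-channel
#'   grayscale tiles.
#' @param omit_from_merge channel indices left out of the merged composite;
#'   at least one channel must remain.
#' @return An object of class `render_options`.
#' @export
render_options <- function(palette = NULL,
                           n_channels = NULL,
                           label_tiles = TRUE,
                           orientation = c("horizontal", "vertical"),
                           export_format = c("png", "jpeg", "tiff"),
                           omit_from_singles = integer(0),
                           omit_from_merge = integer(0)) {
  orientation <- match.arg(orientation)
  export_format <- match.arg(export_format)
  if (is.null(palette)) {
    if (is.null(n_channels)) {
      stop("supply `palette` or `n_channels`", call. = FALSE)
    }
    palette <- rep_len(.default_palette_order, n_channels)
  }
  palette <- as.character(palette)
  unknown <- setdiff(palette, names(.palette_colors))
  if (length(unknown)) {
    stop(sprintf(
      "unknown palette color(s): %s (available: %s)",
      paste(unknown, collapse = ", "),
      paste(names(.palette_colors), collapse = ", ")
    ), call. = FALSE)
  }
  n <- length(palette)
  omit_from_singles <- sort(unique(as.integer(omit_from_singles)))
  omit_from_merge <- sort(unique(as.integer(omit_from_merge)))
  for (idx in c(omit_from_singles, omit_from_merge)) {
    if (is.na(idx) || idx < 1L || idx > n) {
      stop("omitted channel indices must lie in 1..n_channels", call. = FALSE)
    }
  }
  if (length(omit_from_merge) >= n) {
    stop("`omit_from_merge` must leave at least one channel in the merge",
         call. = FALSE)
  }
  base::structure(
    list(
      palette = palette,
      label_tiles = isTRUE(label_tiles),
      orientation = orientation,
      export_format = export_format,
      omit_from_singles = omit_from_singles,
      omit_from_merge = omit_from_merge
    ),
    class = "render_options"
  )
}
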