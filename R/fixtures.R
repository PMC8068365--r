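# Synthetic dataset generation.
#
# Fixture images are flat-field scenes with axis-aligned squares of known
# mean intensity over a uniform background, with optional clipped Gaussian
# noise. That is enough structure to exercise discovery, contrast
# enhancement and rendering with exact, analytically known expectations;
# no attempt is made to imitate cell morphology or optics.

# Run `expr`-style code under a fixed seed without disturbing the caller's
# RNG stream.
.with_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  fun()
}

# Render one plane: uniform background plus non-overlapping squares, each a
# data.frame row (x, y, side, mean) with 1-based top-left corners. Gaussian
# noise of sd `noise_sd` is added and the result clipped to the bit depth.
.render_square_plane <- function(width, height, bit_depth, background,
                                 squares, noise_sd) {
  mx <- bit_depth_max(bit_depth)
  field <- matrix(background, nrow = height, ncol = width)
  if (!is.null(squares) && nrow(squares)) {
    for (i in seq_len(nrow(squares))) {
      sq <- squares[i, ]
      ys <- sq$y + seq_len(sq$side) - 1L
      xs <- sq$x + seq_len(sq$side) - 1L
      if (max(ys) > height || max(xs) > width || sq$x < 1L || sq$y < 1L) {
        stop("square extends beyond the image", call. = FALSE)
      }
      if (any(field[ys, xs] != background)) {
        stop("squares must not overlap", call. = FALSE)
      }
      if (sq$mean < 0 || sq$mean > mx) {
        stop("square mean outside the bit-depth intensity range",
             call. = FALSE)
      }
      field[ys, xs] <- sq$mean
    }
  }
  if (noise_sd > 0) {
    field <- field + stats::rnorm(length(field), sd = noise_sd)
  }
  m <- matrix(as.integer(pmin(pmax(floor(field + 0.5), 0), mx)),
              nrow = height, ncol = width)
  channel_plane(m, bit_depth)
}

# Deterministic per-image scene: two squares whose means depend on the
# channel (dimmer low channels, brighter high channels) and alternate with
# the image index, so joint-vs-individual contrast scoping is observable.
.default_scene <- function(img_idx, ch, n_channels, width, height,
                           bit_depth) {
  mx <- bit_depth_max(bit_depth)
  lvl <- (0.2 + 0.6 * ch / n_channels) * (0.6 + 0.4 * (img_idx %% 2L))
  side_a <- max(4L, height %/% 4L)
  side_b <- max(4L, height %/% 5L)
  data.frame(
    x = c(max(1L, width %/% 8L), max(1L, (5L * width) %/% 8L)),
    y = c(max(1L, height %/% 8L), max(1L, (5L * height) %/% 8L)),
    side = c(side_a, side_b),
    mean = round(c(lvl, lvl / 2) * mx)
  )
}

#' Generate a synthetic experiment directory
#'
#' Writes a parent directory with one subfolder per condition, each holding
#' multichannel fields of view in the requested layout: one multichannel
#' (OME-)TIFF per field of view, or one single-channel TIFF per channel with
#' identifier-suffixed names. Images are square-on-background scenes with
#' clipped Gaussian noise; the same arguments and seed always reproduce
#' byte-identical files.
#'
#' @param path parent directory to create (must not already contain a
#'   clashing tree; created recursively).
#' @param n_subfolders,images_per_subfolder dataset shape.
#' @param n_channels channels per field of view.
#' @param bit_depth 8 or 16.
#' @param width,height plane size in pixels.
#' @param structure `"single_file"` or `"separated_channels"`.
#' @param extension file extension to write (default `"tif"`).
#' @param noise_sd Gaussian noise standard deviation in intensity units;
#'   `NULL` defaults to 1% of full scale.
#' @param seed RNG seed; fixes the dataset bytes.
#' @param subfolder_names optional condition names (default `cond01`, ...).
#' @param channel_identifiers identifiers for separated mode (default
#'   `C1`..`Cn`).
#' @return the matching [dataset_spec()], invisibly usable directly with
#'   [run_preview()] / [run_summary()].
#' @export
generate_dataset <- function(path,
                             n_subfolders = 2L,
                             images_per_subfolder = 3L,
                             n_channels = 3L,
                             bit_depth = 16L,
                             width = 64L,
                             height = 64L,
                             structure = c("single_file",
                                           "separated_channels"),
                             extension = "tif",
                             noise_sd = NULL,
                             seed = 1L,
                             subfolder_names = NULL,
                             channel_identifiers = NULL) {
  structure_mode <- match.arg(structure)
  if (is.null(noise_sd)) noise_sd <- 0.01 * bit_depth_max(bit_depth)
  if (is.null(subfolder_names)) {
    subfolder_names <- sprintf("cond%02d", seq_len(n_subfolders))
  }
  stopifnot(length(subfolder_names) == n_subfolders)
  if (is.null(channel_identifiers)) {
    channel_identifiers <- paste0("C", seq_len(n_channels))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    stop(sprintf("cannot create dataset directory: %s", path), call. = FALSE)
  }

  .with_seed(seed, function() {
    for (si in seq_len(n_subfolders)) {
      sub_path <- file.path(path, subfolder_names[si])
      dir.create(sub_path, showWarnings = FALSE)
      for (ii in seq_len(images_per_subfolder)) {
        planes <- lapply(seq_len(n_channels), function(ch) {
          .render_square_plane(
            width, height, bit_depth,
            background = round(0.05 * bit_depth_max(bit_depth)),
            squares = .default_scene(ii, ch, n_channels, width, height,
                                     bit_depth),
            noise_sd = noise_sd
          )
        })
        stem <- sprintf("img%02d", ii)
        if (structure_mode == "single_file") {
          write_tiff_gray(
            planes,
            file.path(sub_path, paste0(stem, ".", extension)),
            ome = n_channels > 1L
          )
        } else {
          for (ch in seq_len(n_channels)) {
            write_tiff_gray(
              planes[ch],
              file.path(sub_path, paste0(stem, "_", channel_identifiers[ch],
                                         ".", extension))
            )
          }
        }
      }
    }
  })

  invisible(dataset_spec(
    parent_path = path,
    structure = structure_mode,
    extension = extension,
    n_channels = n_channels,
    channel_identifiers = if (structure_mode == "separated_channels") {
      channel_identifiers
    } else NULL
  ))
}

#' Default contrast-pitfall scene
#'
#' Four single-channel pictures of squares on a zero background that make
#' the classic contrast-enhancement pitfall measurable: the large square 1
#' has the same mean in pictures 1 and 4 and a 3-fold lower mean in
#' pictures 2 and 3, and in picture 3 the small square 4 is brighter than
#' every other square of that picture. Joint (pooled) stretching with a
#' pooled minimum of 0 preserves the 3-fold ratio; per-picture stretching
#' destroys it.
#'
#' @param bit_depth 8 or 16.
#' @param noise_sd Gaussian noise sd (default 0 for exact assertions).
#' @param seed RNG seed (only relevant with noise).
#' @return a scene list consumable by [generate_pitfall_set()].
#' @export
pitfall_scene <- function(bit_depth = 16L, noise_sd = 0, seed = 1L) {
  base <- if (bit_depth == 16L) 1 else 1 / 256
  sq <- function(x, y, side, mean) {
    data.frame(x = x, y = y, side = side, mean = round(mean * base))
  }
  common <- function(m1, m2, m3) {
    rbind(sq(9L, 9L, 48L, m1), sq(73L, 17L, 24L, m2), sq(17L, 73L, 24L, m3))
  }
  pictures <- list(
    common(9000, 6000, 1500),
    common(3000, 2000, 500),
    rbind(common(3000, 2000, 500), sq(85L, 85L, 12L, 12000)),
    common(9000, 6000, 1500)
  )
  list(
    width = 128L, height = 128L, bit_depth = as.integer(bit_depth),
    background = 0, noise_sd = noise_sd, seed = seed,
    pictures = pictures
  )
}

#' Generate the contrast-pitfall picture set
#'
#' Renders the four planes of a scene (see [pitfall_scene()]) along with
#' per-square logical masks so region means can be measured directly. With
#' `noise_sd = 0` region means equal the specified means exactly.
#'
#' @param scene a scene list: `width`, `height`, `bit_depth`, `background`,
#'   `noise_sd`, `seed`, and `pictures` (a list of square data.frames with
#'   columns `x`, `y`, `side`, `mean`).
#' @return list with `planes` (list of [channel_plane()]) and `masks`
#'   (per picture, a list of logical matrices, one per square).
#' @export
generate_pitfall_set <- function(scene = pitfall_scene()) {
  planes <- .with_seed(scene$seed, function() {
    lapply(scene$pictures, function(squares) {
      .render_square_plane(scene$width, scene$height, scene$bit_depth,
                           scene$background, squares, scene$noise_sd)
    })
  })
  masks <- lapply(scene$pictures, function(squares) {
    lapply(seq_len(nrow(squares)), function(i) {
      m <- matrix(FALSE, nrow = scene$height, ncol = scene$width)
      sq <- squares[i, ]
      m[sq$y + seq_len(sq$side) - 1L, sq$x + seq_len(sq$side) - 1L] <- TRUE
      m
    })
  })
  list(planes = planes, masks = masks)
}

#' Mean intensity over a region mask
#'
#' @param plane a [channel_plane()].
#' @param mask logical matrix of the plane's dimensions.
#' @return mean intensity of the masked pixels.
#' @export
region_mean <- function(plane, mask) {
  stopifnot(is_channel_plane(plane), identical(dim(mask), dim(plane$pixels)))
  mean(plane$pixels[mask])
}
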