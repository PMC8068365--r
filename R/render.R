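# Tile rendering: channel colorization, additive merging, label drawing,
# and montage grid assembly.
#
# Labels are rasterized with a built-in 5x7 bitmap font (scaled by integer
# nearest-neighbour), so output is byte-identical across platforms and
# needs no system font stack. Lowercase letters map onto the uppercase
# glyphs; characters without a glyph render as a filled box.

#' RGB tile
#'
#' @param pixels integer array `height x width x 3` with components in
#'   0..255.
#' @param label optional label string already drawn on the tile.
#' @return An object of class `rgb_tile`.
#' @export
rgb_tile <- function(pixels, label = NULL) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L)
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 0L || max(pixels) > 255L) {
    stop("RGB components must lie in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, label = label), class = "rgb_tile")
}

#' Colorize a channel plane
#'
#' Scales intensities to the 8-bit display range
#' (`round(value * 255 / (2^bit_depth - 1))`) and multiplies them into the
#' unit RGB vector of the chosen color: red (1,0,0), green (0,1,0), blue
#' (0,0,1), gray (1,1,1), cyan (0,1,1), magenta (1,0,1), yellow (1,1,0).
#'
#' @param plane a [channel_plane()].
#' @param color one of the seven palette color names.
#' @return an [rgb_tile()].
#' @export
colorize <- function(plane, color) {
  stopifnot(is_channel_plane(plane))
  unit <- .palette_colors[[color]]
  if (is.null(unit)) {
    stop(sprintf("unknown color \"%s\" (available: %s)", color,
                 paste(names(.palette_colors), collapse = ", ")),
         call. = FALSE)
  }
  v8 <- floor(plane$pixels * (255 / bit_depth_max(plane$bit_depth)) + 0.5)
  px <- array(0L, dim = c(plane$height, plane$width, 3L))
  for (s in 1:3) px[, , s] <- as.integer(v8 * unit[s])
  rgb_tile(px)
}

#' Merge channels into one composite tile
#'
#' Component-wise sum of the colorized included channels, clamped to 255
#' per component (saturating additive blending, the usual fluorescence
#' composite convention). Channels listed in `omit_from_merge` are left
#' out; at least one channel must remain.
#'
#' @param planes list of [channel_plane()]s (all channels, in order).
#' @param options a [render_options()] supplying the palette and
#'   `omit_from_merge`.
#' @return an [rgb_tile()].
#' @export
merge_channels <- function(planes, options) {
  check_planes_conformable(planes)
  keep <- setdiff(seq_along(planes), options$omit_from_merge)
  if (!length(keep)) {
    stop("all channels omitted from the merge", call. = FALSE)
  }
  acc <- array(0, dim = c(planes[[1L]]$height, planes[[1L]]$width, 3L))
  for (ch in keep) {
    acc <- acc + colorize(planes[[ch]], options$palette[ch])$pixels
  }
  rgb_tile(array(as.integer(pmin(acc, 255)), dim = dim(acc)))
}

# ---- bitmap font ------------------------------------------------------------

# 5x7 glyphs, one integer per row, bit 4 (value 16) = leftmost column.
.font5x7 <- list(
  "A" = c(14,17,17,31,17,17,17), "B" = c(30,17,17,30,17,17,30),
  "C" = c(14,17,16,16,16,17,14), "D" = c(30,17,17,17,17,17,30),
  "E" = c(31,16,16,30,16,16,31), "F" = c(31,16,16,30,16,16,16),
  "G" = c(14,17,16,23,17,17,14), "H" = c(17,17,17,31,17,17,17),
  "I" = c(14,4,4,4,4,4,14),      "J" = c(7,2,2,2,2,18,12),
  "K" = c(17,18,20,24,20,18,17), "L" = c(16,16,16,16,16,16,31),
  "M" = c(17,27,21,21,17,17,17), "N" = c(17,25,21,19,17,17,17),
  "O" = c(14,17,17,17,17,17,14), "P" = c(30,17,17,30,16,16,16),
  "Q" = c(14,17,17,17,21,18,13), "R" = c(30,17,17,30,20,18,17),
  "S" = c(15,16,16,14,1,1,30),   "T" = c(31,4,4,4,4,4,4),
  "U" = c(17,17,17,17,17,17,14), "V" = c(17,17,17,17,17,10,4),
  "W" = c(17,17,17,21,21,21,10), "X" = c(17,17,10,4,10,17,17),
  "Y" = c(17,17,10,4,4,4,4),     "Z" = c(31,1,2,4,8,16,31),
  "0" = c(14,17,19,21,25,17,14), "1" = c(4,12,4,4,4,4,14),
  "2" = c(14,17,1,2,4,8,31),     "3" = c(31,2,4,2,1,17,14),
  "4" = c(2,6,10,18,31,2,2),     "5" = c(31,16,30,1,1,17,14),
  "6" = c(6,8,16,30,17,17,14),   "7" = c(31,1,2,4,8,8,8),
  "8" = c(14,17,17,14,17,17,14), "9" = c(14,17,17,15,1,2,12),
  " " = c(0,0,0,0,0,0,0),        "." = c(0,0,0,0,0,12,12),
  "_" = c(0,0,0,0,0,0,31),       "-" = c(0,0,0,31,0,0,0),
  "(" = c(2,4,8,8,8,4,2),        ")" = c(8,4,2,2,2,4,8),
  "/" = c(1,1,2,4,8,16,16),      ":" = c(0,12,12,0,12,12,0),
  "," = c(0,0,0,0,12,4,8),       "+" = c(0,4,4,31,4,4,0),
  "=" = c(0,0,31,0,31,0,0)
)
.font_fallback <- c(31,17,17,17,17,17,31)

.glyph_rows <- function(ch) {
  g <- .font5x7[[ch]]
  if (is.null(g)) g <- .font5x7[[toupper(ch)]]
  if (is.null(g)) g <- .font_fallback
  g
}

# Logical mask (7 x 5) for one character.
.glyph_mask <- function(ch) {
  rows <- .glyph_rows(ch)
  t(vapply(rows, function(r) {
    as.logical(bitwAnd(r, c(16L, 8L, 4L, 2L, 1L)))
  }, logical(5)))
}

#' Label font height for a tile
#'
#' The deterministic sizing rule: `max(8, floor(tile_height / 24))` pixels.
#' Glyphs render at the largest multiple of 8 px not exceeding this target
#' (integer nearest-neighbour scaling of an 8-px line cell).
#'
#' @param tile_height tile height in pixels.
#' @return target font height in pixels.
#' @export
label_font_height <- function(tile_height) {
  max(8L, as.integer(floor(tile_height / 24)))
}

# Rasterize `text` as a logical matrix at integer scale s (cell: 6s wide,
# 8s tall per character).
.rasterize_text <- function(text, s) {
  chars <- strsplit(text, "")[[1L]]
  if (!length(chars)) return(matrix(FALSE, nrow = 8L * s, ncol = 0L))
  out <- matrix(FALSE, nrow = 8L * s, ncol = 6L * s * length(chars))
  for (i in seq_along(chars)) {
    mask <- .glyph_mask(chars[i])
    big <- mask[rep(seq_len(7), each = s), rep(seq_len(5), each = s),
                drop = FALSE]
    out[seq_len(7L * s), (i - 1L) * 6L * s + seq_len(5L * s)] <- big
  }
  out
}

#' Draw a label on a tile
#'
#' Writes `"<channel_token> <folder> <file>"` (channel token `"C1"`..`"Cn"`
#' or `"merge"`) in white at the tile's top-left corner. Font height follows
#' [label_font_height()]; text wider than the tile is truncated with a
#' trailing ellipsis (`...`).
#'
#' @param tile an [rgb_tile()].
#' @param channel_token `"C<k>"` or `"merge"`.
#' @param folder condition subfolder name.
#' @param file field-of-view base name.
#' @return the labeled [rgb_tile()].
#' @export
label_tile <- function(tile, channel_token, folder, file) {
  text <- paste(channel_token, folder, file)
  h <- dim(tile$pixels)[1L]
  w <- dim(tile$pixels)[2L]
  s <- max(1L, label_font_height(h) %/% 8L)
  max_chars <- w %/% (6L * s)
  if (nchar(text) > max_chars) {
    text <- paste0(substr(text, 1L, max(0L, max_chars - 3L)), "...")
    text <- substr(text, 1L, max_chars)
  }
  mask <- .rasterize_text(text, s)
  mh <- min(nrow(mask), h)
  mw <- min(ncol(mask), w)
  if (mh > 0L && mw > 0L) {
    px <- tile$pixels
    sub <- mask[seq_len(mh), seq_len(mw), drop = FALSE]
    for (sch in 1:3) {
      slab <- px[seq_len(mh), seq_len(mw), sch]
      slab[sub] <- 255L
      px[seq_len(mh), seq_len(mw), sch] <- slab
    }
    tile <- rgb_tile(px, label = text)
  }
  tile
}

#' Assemble tiles into a montage
#'
#' Takes the logical tile grid — one row per field of view, columns = shown
#' single channels then the merge — and lays it out on a canvas.
#' `"horizontal"` orientation keeps that grid; `"vertical"` transposes it.
#' Tiles are abutted with a 2-px black separator and never rescaled; all
#' tiles must share dimensions.
#'
#' @param tile_grid list of rows, each a list of [rgb_tile()]s (rectangular).
#' @param options a [render_options()] (orientation).
#' @return an [rgb_tile()] holding the full montage.
#' @export
assemble_montage <- function(tile_grid, options) {
  stopifnot(length(tile_grid) >= 1L)
  n_cols <- unique(lengths(tile_grid))
  if (length(n_cols) != 1L || n_cols < 1L) {
    stop("tile grid must be rectangular", call. = FALSE)
  }
  if (options$orientation == "vertical") {
    tile_grid <- lapply(seq_len(n_cols), function(j) {
      lapply(tile_grid, `[[`, j)
    })
    n_cols <- length(tile_grid[[1L]])
  }
  dims <- lapply(tile_grid, function(row) {
    lapply(row, function(t) dim(t$pixels)[1:2])
  })
  th <- dims[[1L]][[1L]][1L]
  tw <- dims[[1L]][[1L]][2L]
  for (i in seq_along(dims)) {
    for (j in seq_along(dims[[i]])) {
      if (!identical(dims[[i]][[j]], c(th, tw))) {
        stop(sprintf(
          "inconsistent tile size at row %d, column %d: %dx%d vs %dx%d",
          i, j, dims[[i]][[j]][2L], dims[[i]][[j]][1L], tw, th
        ), call. = FALSE)
      }
    }
  }
  sep <- 2L
  n_rows <- length(tile_grid)
  H <- n_rows * th + (n_rows - 1L) * sep
  W <- n_cols * tw + (n_cols - 1L) * sep
  canvas <- array(0L, dim = c(H, W, 3L))
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      y0 <- (i - 1L) * (th + sep)
      x0 <- (j - 1L) * (tw + sep)
      canvas[y0 + seq_len(th), x0 + seq_len(tw), ] <-
        tile_grid[[i]][[j]]$pixels
    }
  }
  rgb_tile(canvas)
}
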