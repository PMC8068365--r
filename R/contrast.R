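# Contrast enhancement by histogram stretching.
#
# The engine works entirely on integer histograms (one bin per representable
# intensity), so joint scaling over many images pools histograms by simple
# summation instead of holding all pixel data at once. Stretch bounds are
# percentile clip points: with saturation fraction f over N pooled pixels,
# k = floor(N * f / 2) pixels may clip at each tail. All arithmetic stays at
# the input bit depth; stretched values are rounded half-up.

#' Intensity histogram of a plane
#'
#' @param plane a [channel_plane()].
#' @return integer vector of length `2^bit_depth`; element `b + 1` counts
#'   the pixels with intensity `b`. Sums to `width * height`.
#' @export
compute_histogram <- function(plane) {
  stopifnot(is_channel_plane(plane))
  n_bins <- bit_depth_max(plane$bit_depth) + 1L
  tabulate(as.vector(plane$pixels) + 1L, nbins = n_bins)
}

#' Percentile clip bounds from (pooled) histograms
#'
#' With saturation fraction f and N pooled pixels, up to `floor(N * f / 2)`
#' pixels may clip at each tail: `low` is the smallest intensity whose
#' cumulative count strictly exceeds that budget, `high` the largest
#' intensity whose cumulative count from above strictly exceeds it. With
#' f = 0 this reduces to the pooled minimum and maximum (no saturation).
#' A constant input yields `low == high`; the stretch step then passes
#' pixels through unchanged.
#'
#' @param histograms a single histogram vector or a list of histograms
#'   (pooled by summation; all must share length).
#' @param saturation_fraction fraction in `[0, 0.01]`.
#' @return list with integer `low` and `high`.
#' @export
compute_clip_bounds <- function(histograms, saturation_fraction = 0) {
  h <- if (is.list(histograms)) {
    stopifnot(length(unique(lengths(histograms))) == 1L)
    Reduce(`+`, histograms)
  } else {
    histograms
  }
  n <- sum(as.numeric(h))
  if (n <= 0) stop("empty histogram: no pixels to compute bounds from",
                   call. = FALSE)
  k <- floor(n * saturation_fraction / 2)
  cum_lo <- cumsum(as.numeric(h))
  cum_hi <- rev(cumsum(rev(as.numeric(h))))
  low <- which(cum_lo > k)[1L] - 1L
  high <- max(which(cum_hi > k)) - 1L
  if (high < low) {  # degenerate saturation budget; fall back to extremes
    low <- which(h > 0)[1L] - 1L
    high <- max(which(h > 0)) - 1L
  }
  list(low = as.integer(low), high = as.integer(high))
}

#' Linear histogram stretch of one plane
#'
#' Maps `low` to 0 and `high` to the full scale `M = 2^bit_depth - 1`,
#' clamping values outside the bounds:
#' `p -> round((clamp(p, low, high) - low) * M / (high - low))`
#' (rounding half-up). Equal bounds (constant input) return the plane
#' unchanged. Output bit depth equals input bit depth.
#'
#' @param plane a [channel_plane()].
#' @param bounds list with `low`, `high` as from [compute_clip_bounds()].
#' @return a stretched [channel_plane()].
#' @export
apply_linear_stretch <- function(plane, bounds) {
  stopifnot(is_channel_plane(plane))
  low <- bounds$low
  high <- bounds$high
  mx <- bit_depth_max(plane$bit_depth)
  if (low < 0 || high > mx || low > high) {
    stop("clip bounds invalid for this bit depth", call. = FALSE)
  }
  if (low == high) return(plane)
  p <- pmin(pmax(plane$pixels, low), high)
  out <- floor((p - low) * (mx / (high - low)) + 0.5)
  m <- matrix(as.integer(out), nrow = plane$height, ncol = plane$width)
  channel_plane(m, plane$bit_depth)
}

# Resolve the per-record, per-channel clip bounds for one montage group
# under a contrast policy. Returns NULL for channels left untouched.
.plan_bounds <- function(records, policy, n_channels) {
  n_rec <- length(records)
  plan <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    plan[[ch]] <- vector("list", n_rec)
  }
  if (policy$mode == "none") return(plan)

  if (policy$mode == "autoscale") {
    for (ch in seq_len(n_channels)) {
      for (r in seq_len(n_rec)) {
        h <- compute_histogram(records[[r]]$planes[[ch]])
        plan[[ch]][[r]] <- compute_clip_bounds(h, 0)
      }
    }
    return(plan)
  }

  # user_defined
  if (length(policy$channels) != n_channels) {
    stop(sprintf(
      "user_defined contrast needs settings for all %d channels, got %d",
      n_channels, length(policy$channels)
    ), call. = FALSE)
  }
  for (ch in seq_len(n_channels)) {
    cs <- policy$channels[[ch]]
    if (!cs$enhance) next
    if (cs$scope == "individual") {
      for (r in seq_len(n_rec)) {
        h <- compute_histogram(records[[r]]$planes[[ch]])
        plan[[ch]][[r]] <- compute_clip_bounds(h, cs$saturation_fraction)
      }
    } else {
      hists <- lapply(records, function(rec) {
        compute_histogram(rec$planes[[ch]])
      })
      joint <- compute_clip_bounds(hists, cs$saturation_fraction)
      for (r in seq_len(n_rec)) plan[[ch]][[r]] <- joint
    }
  }
  plan
}

#' Enhance all records of one montage group
#'
#' Applies the contrast policy to the records that share one montage file.
#' `none` is the identity. `autoscale` min-max stretches every channel of
#' every record on its own histogram (saturation 0). `user_defined` follows
#' the per-channel settings: untouched channels pass through; `individual`
#' scope computes bounds per record; `joint` scope pools the channel's
#' histograms across all records of the group and applies one bounds pair
#' to every record, so between-image intensity ratios stay comparable.
#'
#' @param records list of image records (fields `base_name`, `planes`, ...).
#' @param policy a [contrast_policy()].
#' @param n_channels channel count of the dataset.
#' @return list with `records` (enhanced copies) and `bounds_report`: per
#'   channel, either the joint bounds or the per-record bounds (named by
#'   record base name); `NULL` entries mark untouched channels.
#' @export
enhance_dataset <- function(records, policy, n_channels) {
  if (!length(records)) return(list(records = records, bounds_report = list()))
  depths <- unlist(lapply(records, function(r) {
    vapply(r$planes, function(p) p$bit_depth, integer(1))
  }))
  if (length(unique(depths)) > 1L) {
    stop("mixed bit depths within one montage group", call. = FALSE)
  }
  plan <- .plan_bounds(records, policy, n_channels)

  out <- records
  for (r in seq_along(records)) {
    for (ch in seq_len(n_channels)) {
      b <- plan[[ch]][[r]]
      if (!is.null(b)) {
        out[[r]]$planes[[ch]] <-
          apply_linear_stretch(records[[r]]$planes[[ch]], b)
      }
    }
  }

  report <- vector("list", n_channels)
  names(report) <- paste0("C", seq_len(n_channels))
  rec_names <- vapply(records, `[[`, character(1), "base_name")
  for (ch in seq_len(n_channels)) {
    per_rec <- plan[[ch]]
    if (all(vapply(per_rec, is.null, logical(1)))) next
    joint <- policy$mode == "user_defined" &&
      policy$channels[[ch]]$enhance && policy$channels[[ch]]$scope == "joint"
    if (joint) {
      report[[ch]] <- list(scope = "joint", bounds = per_rec[[1L]])
    } else {
      names(per_rec) <- rec_names
      report[[ch]] <- list(scope = "individual", bounds = per_rec)
    }
  }
  list(records = out, bounds_report = report)
}
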