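# The run log: a plain-text execution record with four numbered sections,
# written next to the montages and tagged with the same timestamp token.

.fmt_bounds <- function(b) sprintf("(%d, %d)", b$low, b$high)

.log_contrast_lines <- function(contrast) {
  lines <- c(sprintf("contrast mode: %s", contrast$mode))
  if (contrast$mode == "user_defined") {
    for (i in seq_along(contrast$channels)) {
      cs <- contrast$channels[[i]]
      lines <- c(lines, sprintf(
        "channel %d: enhance=%s saturation_fraction=%g (%g%%) scope=%s%s",
        i, cs$enhance, cs$saturation_fraction,
        100 * cs$saturation_fraction, cs$scope,
        if (cs$noncanonical) " [non-canonical saturation value]" else ""
      ))
    }
  }
  c(lines, paste("saturation convention: the saturation fraction is split",
                 "equally between the low and high tails"))
}

.log_render_lines <- function(render) {
  c(
    sprintf("palette: %s",
            paste(sprintf("C%d=%s", seq_along(render$palette),
                          render$palette), collapse = ", ")),
    sprintf("label_tiles: %s", render$label_tiles),
    sprintf("orientation: %s", render$orientation),
    sprintf("export_format: %s", render$export_format),
    sprintf("omit_from_singles: %s",
            if (length(render$omit_from_singles)) {
              paste(render$omit_from_singles, collapse = ", ")
            } else "none"),
    sprintf("omit_from_merge: %s",
            if (length(render$omit_from_merge)) {
              paste(render$omit_from_merge, collapse = ", ")
            } else "none"),
    "merge blending: saturating additive (component-wise sum clamped to 255)"
  )
}

.log_bounds_lines <- function(bounds_reports) {
  lines <- character(0)
  for (group in names(bounds_reports)) {
    rep <- bounds_reports[[group]]
    for (ch in names(rep)) {
      entry <- rep[[ch]]
      if (is.null(entry)) next
      if (entry$scope == "joint") {
        lines <- c(lines, sprintf("%s %s: joint bounds %s", group, ch,
                                  .fmt_bounds(entry$bounds)))
      } else {
        for (rec in names(entry$bounds)) {
          lines <- c(lines, sprintf("%s %s: %s bounds %s", group, ch, rec,
                                    .fmt_bounds(entry$bounds[[rec]])))
        }
      }
    }
  }
  if (!length(lines)) lines <- "no contrast bounds applied"
  lines
}

#' Write the run log
#'
#' Produces the four-section plain-text execution record: (1) an
#' introductory message naming the tool, mode and execution date, (2) every
#' user input and resolved parameter (including any contrast bounds
#' applied), (3) the content of the parent directory, and (4) per
#' subdirectory, the selected image files and every skip diagnostic. The
#' final line reads `"Macro finished on <YYYYMMDD-HHMMSS> (YYYYMMDD-HHMMSS)
#' and lasted <seconds> s"` with the duration to 3 decimals.
#'
#' @param config the [run_config()] of the run.
#' @param discovery named per-subfolder results of [collect_images()].
#' @param bounds_reports named list of bounds reports from
#'   [enhance_dataset()] (per montage group).
#' @param selections summary mode: named list subfolder -> selected base
#'   name; `NULL` in preview mode.
#' @param token the shared timestamp token.
#' @param start_time POSIXct run start.
#' @param duration run duration in seconds.
#' @return the log file path, invisibly.
#' @export
write_log <- function(config, discovery, bounds_reports, selections,
                      token, start_time, duration) {
  spec <- config$spec
  path <- file.path(spec$parent_path, sprintf("log_%s.txt", token))
  finish <- .timestamp_token(Sys.time())

  lines <- c(
    sprintf("(1) picmontage %s run, started on %s (YYYYMMDD-HHMMSS)",
            config$mode, token),
    "",
    "(2) User inputs and parameters",
    sprintf("parent_path: %s", spec$parent_path),
    sprintf("structure: %s", spec$structure),
    sprintf("extension: %s", spec$extension),
    sprintf("n_channels: %d", spec$n_channels),
    sprintf("channel_identifiers: %s",
            if (is.null(spec$channel_identifiers)) "not applicable" else
              paste(spec$channel_identifiers, collapse = ", ")),
    .log_contrast_lines(config$contrast),
    .log_render_lines(config$render),
    if (config$mode == "summary") {
      paste("summary contrast pooling: joint scope pools across all",
            "selected records of the montage")
    },
    "applied contrast bounds (channel -> (low, high)):",
    paste0("  ", .log_bounds_lines(bounds_reports)),
    "",
    "(3) Parent directory content",
    paste0("  ", list.files(spec$parent_path, recursive = FALSE)),
    "",
    "(4) Selected image files per subdirectory"
  )

  for (sub in names(discovery)) {
    d <- discovery[[sub]]
    lines <- c(lines, sprintf("  %s:", sub))
    if (!length(d$records)) {
      lines <- c(lines,
                 "    no compliant images; subfolder omitted from montages")
    } else if (!is.null(selections)) {
      sel <- selections[[sub]]
      if (is.null(sel)) {
        lines <- c(lines, "    no representative selected")
      } else {
        lines <- c(lines, sprintf("    representative: %s", sel))
      }
    } else {
      for (r in d$records) {
        lines <- c(lines, sprintf("    selected: %s (%s)", r$base_name,
                                  paste(basename(r$source_paths),
                                        collapse = ", ")))
      }
    }
    for (dg in d$diagnostics) {
      lines <- c(lines, sprintf("    skipped: %s (%s%s)", dg$file,
                                dg$reason,
                                if (nzchar(dg$detail)) {
                                  paste0("; ", dg$detail)
                                } else ""))
    }
    for (wn in d$warnings) {
      lines <- c(lines, sprintf("    warning: %s", wn))
    }
  }

  lines <- c(lines, "", sprintf(
    "Macro finished on %s (YYYYMMDD-HHMMSS) and lasted %.3f s",
    finish, duration
  ))
  writeLines(unlist(lines), path)
  invisible(path)
}
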