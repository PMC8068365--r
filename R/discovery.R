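# Dataset discovery: enumerate condition subfolders, resolve compliant
# image files into logical multichannel records, and report everything that
# was skipped and why.
#
# Ordering is deterministic everywhere: byte-wise lexicographic (radix)
# sort by subfolder name, then by file/base name, independent of locale and
# filesystem enumeration order.

.lex_sort <- function(x) sort(x, method = "radix")

# Path length past which the run log records a provenance warning
# ("subfolder/file.ext" combinations longer than this are known to break
# some toolchains; they are processed normally here).
.path_length_warn <- 61L

skip_diag <- function(file, reason, detail = "") {
  list(file = file, reason = reason, detail = detail)
}

#' List condition subfolders of a dataset
#'
#' Immediate child directories of the parent path, sorted lexicographically.
#' Files directly inside the parent are never dataset images: images must
#' live one level down, in one subfolder per condition.
#'
#' @param spec a [dataset_spec()].
#' @return character vector of subfolder names.
#' @export
discover_subfolders <- function(spec) {
  parent <- spec$parent_path
  if (!dir.exists(parent)) {
    stop(sprintf("parent directory not found or unreadable: %s", parent),
         call. = FALSE)
  }
  subs <- list.dirs(parent, full.names = FALSE, recursive = FALSE)
  if (!length(subs)) {
    stop(sprintf(
      paste0("no subfolders found in %s: images must be grouped in one ",
             "subfolder per condition; remember to select the parent ",
             "directory, not the directory directly containing the pictures"),
      parent
    ), call. = FALSE)
  }
  .lex_sort(subs)
}

# Files in a subfolder carrying the declared extension (case-insensitive),
# lexicographically sorted.
.candidate_files <- function(subfolder_path, extension) {
  all_files <- list.files(subfolder_path, full.names = FALSE,
                          recursive = FALSE)
  all_files <- all_files[!dir.exists(file.path(subfolder_path, all_files))]
  ext <- tolower(tools::file_ext(all_files))
  .lex_sort(all_files[ext == tolower(extension)])
}

#' Group separated-channel files into fields of view
#'
#' When each channel is saved as its own file, the files of one field of
#' view differ only by the channel identifier substring. The first
#' identifier acts as the pivot: every file containing it exactly once
#' proposes a group whose sibling names are formed by substituting the
#' other identifiers; the group is kept only if all siblings exist. Files
#' containing the pivot more than once ("ambiguous identifier") and files
#' left without a complete group ("incomplete group") are reported as
#' diagnostics, never silently dropped.
#'
#' @param file_names character vector of candidate file names.
#' @param identifiers ordered channel identifiers (pivot first).
#' @return list with `groups` (each: `base_name`, `files` in channel order)
#'   sorted by base name, and `diagnostics` (skip records).
#' @export
group_separated_channels <- function(file_names, identifiers) {
  stopifnot(length(identifiers) >= 1L)
  pivot <- identifiers[1L]
  diagnostics <- list()
  groups <- list()
  used <- character(0)

  pivot_count <- vapply(file_names, function(f) {
    length(gregexpr(pivot, f, fixed = TRUE)[[1L]][
      gregexpr(pivot, f, fixed = TRUE)[[1L]] > 0])
  }, integer(1))

  for (f in file_names[pivot_count > 1L]) {
    diagnostics[[length(diagnostics) + 1L]] <- skip_diag(
      f, "ambiguous identifier",
      sprintf("channel identifier \"%s\" occurs more than once in the name",
              pivot)
    )
  }

  for (f in .lex_sort(file_names[pivot_count == 1L])) {
    siblings <- vapply(identifiers, function(id) {
      sub(pivot, id, f, fixed = TRUE)
    }, character(1))
    if (all(siblings %in% file_names)) {
      base <- sub(pivot, "", f, fixed = TRUE)
      base <- tools::file_path_sans_ext(base)
      groups[[length(groups) + 1L]] <- list(base_name = base,
                                            files = unname(siblings))
      used <- c(used, unname(siblings))
    } else {
      missing <- siblings[!siblings %in% file_names]
      diagnostics[[length(diagnostics) + 1L]] <- skip_diag(
        f, "incomplete group",
        sprintf("missing sibling file(s): %s", paste(missing, collapse = ", "))
      )
      used <- c(used, f)  # accounted for by the diagnostic
    }
  }

  # Every candidate file must land in exactly one of {groups, diagnostics}:
  # orphans that never contained the pivot get their own diagnostic.
  accounted <- c(used, file_names[pivot_count > 1L])
  for (f in .lex_sort(setdiff(file_names, accounted))) {
    diagnostics[[length(diagnostics) + 1L]] <- skip_diag(
      f, "incomplete group",
      sprintf("no matching \"%s\" (channel 1) file for this name", pivot)
    )
  }

  if (length(groups)) {
    ord <- order(vapply(groups, `[[`, character(1), "base_name"),
                 method = "radix")
    groups <- groups[ord]
  }
  list(groups = groups, diagnostics = diagnostics)
}

.dim_skip_reason <- function(info, n_channels) {
  if (info$n_z > 1L) {
    return(sprintf("multi-slice (z-stack with %d slices)", info$n_z))
  }
  if (info$n_t > 1L) {
    return(sprintf("multi-frame (time-lapse with %d frames)", info$n_t))
  }
  if (info$n_series > 1L) {
    return(sprintf("multi-series (multipoint file with %d series)",
                    info$n_series))
  }
  if (info$n_channels != n_channels) {
    return(sprintf("channel count mismatch (%d found, %d declared)",
                    info$n_channels, n_channels))
  }
  NULL
}

#' Collect the image records of one condition subfolder
#'
#' Applies the compliance rules: only files with the declared extension are
#' considered; files whose channel count differs from the declared one, or
#' that carry more than one z-slice, time frame or series/position, are
#' skipped with a diagnostic (not an error), as are unreadable files. In
#' separated-channels mode, files are first grouped into fields of view via
#' [group_separated_channels()].
#'
#' @param subfolder subfolder name (relative to the parent path).
#' @param spec a [dataset_spec()].
#' @param reader optional plugin reader passed to [read_image()].
#' @return list with `records` (each: `subfolder_name`, `base_name`,
#'   `source_paths`, `planes`), `diagnostics`, and `warnings` (provenance
#'   notes such as over-long path names).
#' @export
collect_images <- function(subfolder, spec, reader = NULL) {
  sub_path <- file.path(spec$parent_path, subfolder)
  if (!dir.exists(sub_path)) {
    stop(sprintf("subfolder not found: %s", sub_path), call. = FALSE)
  }
  files <- .candidate_files(sub_path, spec$extension)
  records <- list()
  diagnostics <- list()
  warnings <- character(0)

  for (f in files) {
    rel <- paste0(subfolder, "/", f)
    if (nchar(rel) > .path_length_warn) {
      warnings <- c(warnings, sprintf(
        "path \"%s\" exceeds %d characters; processed anyway", rel,
        .path_length_warn))
    }
  }

  if (spec$structure == "single_file") {
    for (f in files) {
      path <- file.path(sub_path, f)
      res <- tryCatch(read_image(path, reader = reader), error = identity)
      if (inherits(res, "error")) {
        diagnostics[[length(diagnostics) + 1L]] <-
          skip_diag(f, "unreadable file", conditionMessage(res))
        next
      }
      reason <- .dim_skip_reason(res$info, spec$n_channels)
      if (!is.null(reason)) {
        diagnostics[[length(diagnostics) + 1L]] <- skip_diag(f, reason)
        next
      }
      records[[length(records) + 1L]] <- list(
        subfolder_name = subfolder,
        base_name = tools::file_path_sans_ext(f),
        source_paths = path,
        planes = res$planes
      )
    }
  } else {
    grouped <- group_separated_channels(files, spec$channel_identifiers)
    diagnostics <- grouped$diagnostics
    for (g in grouped$groups) {
      paths <- file.path(sub_path, g$files)
      planes <- vector("list", length(paths))
      failed <- NULL
      for (i in seq_along(paths)) {
        res <- tryCatch(read_image(paths[i], reader = reader),
                        error = identity)
        if (inherits(res, "error")) {
          failed <- skip_diag(g$files[i], "unreadable file",
                              conditionMessage(res))
          break
        }
        reason <- .dim_skip_reason(res$info, 1L)
        if (!is.null(reason)) {
          failed <- skip_diag(g$files[i], reason)
          break
        }
        planes[[i]] <- res$planes[[1L]]
      }
      if (!is.null(failed)) {
        diagnostics[[length(diagnostics) + 1L]] <- failed
        next
      }
      conform <- tryCatch(check_planes_conformable(planes), error = identity)
      if (inherits(conform, "error")) {
        diagnostics[[length(diagnostics) + 1L]] <- skip_diag(
          g$files[1L], "inconsistent channel files", conditionMessage(conform))
        next
      }
      records[[length(records) + 1L]] <- list(
        subfolder_name = subfolder,
        base_name = g$base_name,
        source_paths = paths,
        planes = planes
      )
    }
  }

  if (length(records)) {
    ord <- order(vapply(records, `[[`, character(1), "base_name"),
                 method = "radix")
    records <- records[ord]
  }
  list(records = records, diagnostics = diagnostics, warnings = warnings)
}
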