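# Run orchestration: the two montage modes and the timestamp-paired run log.
#
# preview: one montage per condition subfolder, gathering all of its fields
#   of view; contrast pooling never crosses subfolders.
# summary: one montage for the whole experiment with one representative
#   field of view per condition; contrast pooling spans exactly the
#   selected records (they share one montage file).
#
# All outputs (montages + one log) land in the parent directory, tagged
# with a shared YYYYMMDD-HHMMSS token so they can be unequivocally paired;
# existing outputs are never overwritten (same-second reruns get a
# disambiguating suffix).

#' Assemble a run configuration
#'
#' @param spec a [dataset_spec()].
#' @param mode `"preview"` or `"summary"`.
#' @param contrast a [contrast_policy()] (default: no enhancement).
#' @param render a [render_options()] (default: standard palette, labels
#'   on, horizontal, PNG).
#' @param representatives summary mode only: named character or integer
#'   vector / list mapping subfolder names to a record base name or 1-based
#'   index; subfolders not listed default to their first record in
#'   lexicographic order.
#' @param reader optional plugin reader passed through to [read_image()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec,
                       mode = c("preview", "summary"),
                       contrast = contrast_policy("none"),
                       render = NULL,
                       representatives = NULL,
                       reader = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "dataset_spec"))
  stopifnot(inherits(contrast, "contrast_policy"))
  if (is.null(render)) render <- render_options(n_channels = spec$n_channels)
  stopifnot(inherits(render, "render_options"))
  if (length(render$palette) != spec$n_channels) {
    stop("render palette length must equal the channel count", call. = FALSE)
  }
  if (contrast$mode == "user_defined" &&
      length(contrast$channels) != spec$n_channels) {
    stop("user_defined contrast needs one settings entry per channel",
         call. = FALSE)
  }
  structure(
    list(mode = mode, spec = spec, contrast = contrast, render = render,
         representatives = representatives, reader = reader),
    class = "run_config"
  )
}

.timestamp_token <- function(time = Sys.time()) {
  format(time, "%Y%m%d-%H%M%S")
}

# Pick an output token that collides with no planned path; same-second
# reruns get "-2", "-3", ... appended.
.resolve_token <- function(parent, base_token, planned_stems, ext) {
  token <- base_token
  k <- 1L
  repeat {
    paths <- c(file.path(parent, sprintf("log_%s.txt", token)),
               file.path(parent, sprintf("%s_%s.%s", planned_stems, token,
                                         ext)))
    if (!any(file.exists(paths))) return(token)
    k <- k + 1L
    token <- sprintf("%s-%d", base_token, k)
  }
}

# Build the tile grid for one group of (already enhanced) records.
.render_record_rows <- function(records, render, n_channels) {
  shown <- setdiff(seq_len(n_channels), render$omit_from_singles)
  lapply(records, function(rec) {
    row <- lapply(shown, function(ch) {
      tile <- colorize(rec$planes[[ch]], "gray")
      if (render$label_tiles) {
        tile <- label_tile(tile, paste0("C", ch), rec$subfolder_name,
                           rec$base_name)
      }
      tile
    })
    merged <- merge_channels(rec$planes, render)
    if (render$label_tiles) {
      merged <- label_tile(merged, "merge", rec$subfolder_name,
                           rec$base_name)
    }
    c(row, list(merged))
  })
}

.check_parent_writable <- function(parent) {
  if (!dir.exists(parent)) {
    stop(sprintf("parent directory not found: %s", parent), call. = FALSE)
  }
  if (file.access(parent, 2L) != 0L) {
    stop(sprintf("parent directory is not writable: %s", parent),
         call. = FALSE)
  }
}

#' Run preview mode: one all-images montage per condition
#'
#' For each subfolder with at least one compliant record, applies the
#' contrast policy scoped within that subfolder's montage group and writes
#' one montage `"<subfolder>_preview_<timestamp>.<ext>"` to the parent
#' directory. Exactly one log file is written per run. Subfolders with zero
#' compliant records produce no montage, only a log notice; zero records
#' across the whole dataset is a fatal error (after writing a diagnostic
#' log).
#'
#' @param config a [run_config()] with `mode = "preview"`.
#' @return list with `montage_paths`, `log_path`, `timestamp` (the shared
#'   token), `duration_seconds`.
#' @export
run_preview <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "preview") stop("config mode is not \"preview\"",
                                     call. = FALSE)
  t0 <- Sys.time()
  spec <- config$spec
  .check_parent_writable(spec$parent_path)
  subs <- discover_subfolders(spec)
  discovery <- lapply(subs, collect_images, spec = spec,
                      reader = config$reader)
  names(discovery) <- subs

  n_rec <- vapply(discovery, function(d) length(d$records), integer(1))
  ext <- montage_extension(config$render$export_format)
  active <- subs[n_rec > 0L]
  token <- .resolve_token(spec$parent_path, .timestamp_token(t0),
                          planned_stems = paste0(active, "_preview"),
                          ext = ext)

  if (!any(n_rec > 0L)) {
    log_path <- write_log(config, discovery, bounds_reports = list(),
                          selections = NULL, token = token,
                          start_time = t0,
                          duration = as.numeric(Sys.time() - t0, units = "secs"))
    stop(sprintf(
      "no compliant image records in any subfolder of %s (see log %s)",
      spec$parent_path, log_path
    ), call. = FALSE)
  }

  montage_paths <- character(0)
  bounds_reports <- list()
  for (sub in active) {
    d <- discovery[[sub]]
    enh <- enhance_dataset(d$records, config$contrast, spec$n_channels)
    bounds_reports[[sub]] <- enh$bounds_report
    grid <- .render_record_rows(enh$records, config$render, spec$n_channels)
    montage <- assemble_montage(grid, config$render)
    out <- file.path(spec$parent_path,
                     sprintf("%s_preview_%s.%s", sub, token, ext))
    write_montage(montage, out, config$render$export_format)
    montage_paths <- c(montage_paths, out)
  }

  duration <- as.numeric(Sys.time() - t0, units = "secs")
  log_path <- write_log(config, discovery, bounds_reports,
                        selections = NULL, token = token, start_time = t0,
                        duration = duration)
  list(montage_paths = montage_paths, log_path = log_path,
       timestamp = token, duration_seconds = duration)
}

# Resolve the representative record index for one subfolder.
.resolve_representative <- function(sub, records, representatives) {
  base_names <- vapply(records, `[[`, character(1), "base_name")
  ref <- NULL
  if (!is.null(representatives) && sub %in% names(representatives)) {
    ref <- representatives[[sub]]
  }
  if (is.null(ref)) return(1L)
  if (is.numeric(ref)) {
    idx <- as.integer(ref)
    if (idx < 1L || idx > length(records)) {
      stop(sprintf(
        "representative index %d out of range for subfolder %s (1..%d)",
        idx, sub, length(records)
      ), call. = FALSE)
    }
    return(idx)
  }
  idx <- match(as.character(ref), base_names)
  if (is.na(idx)) {
    stop(sprintf(
      "representative \"%s\" not found in subfolder %s; available: %s",
      ref, sub, paste(base_names, collapse = ", ")
    ), call. = FALSE)
  }
  idx
}

#' Run summary mode: one experiment-wide montage of representatives
#'
#' Selects one record per condition (from `representatives`, defaulting to
#' the first record in lexicographic order), pools joint-scope contrast
#' across all selected records (they share the one montage file), and
#' writes `"summary_<timestamp>.<ext>"` plus the run log to the parent
#' directory. Montage rows are the conditions.
#'
#' @param config a [run_config()] with `mode = "summary"`.
#' @return list with `montage_paths`, `log_path`, `timestamp`,
#'   `duration_seconds`.
#' @export
run_summary <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "summary") stop("config mode is not \"summary\"",
                                     call. = FALSE)
  t0 <- Sys.time()
  spec <- config$spec
  .check_parent_writable(spec$parent_path)
  subs <- discover_subfolders(spec)
  discovery <- lapply(subs, collect_images, spec = spec,
                      reader = config$reader)
  names(discovery) <- subs
  n_rec <- vapply(discovery, function(d) length(d$records), integer(1))
  ext <- montage_extension(config$render$export_format)
  token <- .resolve_token(spec$parent_path, .timestamp_token(t0),
                          planned_stems = "summary", ext = ext)

  if (!any(n_rec > 0L)) {
    log_path <- write_log(config, discovery, bounds_reports = list(),
                          selections = NULL, token = token,
                          start_time = t0,
                          duration = as.numeric(Sys.time() - t0, units = "secs"))
    stop(sprintf(
      "no compliant image records in any subfolder of %s (see log %s)",
      spec$parent_path, log_path
    ), call. = FALSE)
  }

  active <- subs[n_rec > 0L]
  selections <- list()
  selected <- list()
  for (sub in active) {
    recs <- discovery[[sub]]$records
    idx <- .resolve_representative(sub, recs, config$representatives)
    selections[[sub]] <- recs[[idx]]$base_name
    selected[[length(selected) + 1L]] <- recs[[idx]]
  }

  enh <- enhance_dataset(selected, config$contrast, spec$n_channels)
  grid <- .render_record_rows(enh$records, config$render, spec$n_channels)
  montage <- assemble_montage(grid, config$render)
  out <- file.path(spec$parent_path, sprintf("summary_%s.%s", token, ext))
  write_montage(montage, out, config$render$export_format)

  duration <- as.numeric(Sys.time() - t0, units = "secs")
  log_path <- write_log(config, discovery,
                        bounds_reports = list(summary = enh$bounds_report),
                        selections = selections, token = token,
                        start_time = t0, duration = duration)
  list(montage_paths = out, log_path = log_path, timestamp = token,
       duration_seconds = duration)
}
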