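# Dataset discovery: subfolder enumeration, compliance filtering, and
# separated-channel grouping.

test_that("discover_subfolders returns sorted child directories only", {
  d <- tmp_dir()
  dir.create(file.path(d, "WT"))
  dir.create(file.path(d, "Mutant"))
  writeLines("x", file.path(d, "readme.txt"))
  spec <- dataset_spec(d, n_channels = 3)
  expect_identical(discover_subfolders(spec), c("Mutant", "WT"))

  empty <- tmp_dir()
  expect_error(discover_subfolders(dataset_spec(empty, n_channels = 1)),
               "parent directory")
  expect_error(
    discover_subfolders(dataset_spec(file.path(d, "nope"), n_channels = 1)),
    "not found")
})

test_that("dataset_spec rejects ambiguous channel identifiers", {
  expect_error(dataset_spec(".", "separated_channels", n_channels = 2,
                            channel_identifiers = c("C1", "C1")),
               "distinct")
  expect_error(dataset_spec(".", "separated_channels", n_channels = 2,
                            channel_identifiers = c("GFP", "GFP2")),
               "substring")
  expect_error(dataset_spec(".", "separated_channels", n_channels = 2,
                            channel_identifiers = c("", "GFP")),
               "non-empty")
  expect_error(dataset_spec(".", "separated_channels", n_channels = 3,
                            channel_identifiers = c("a", "b")),
               "length")
})

test_that("collect_images partitions files into records and diagnostics", {
  d <- tmp_dir()
  sub <- file.path(d, "WT")
  dir.create(sub)
  set.seed(21)
  for (i in 1:3) {
    write_tiff_gray(lapply(1:3, function(c) rand_plane(8, 8, 16L)),
                    file.path(sub, sprintf("WT%d.tif", i)),
                    ome = TRUE, size_c = 3L)
  }
  # non-compliant companions
  write_tiff_gray(lapply(1:4, function(c) rand_plane(8, 8, 16L)),
                  file.path(sub, "four_channel.tif"), ome = TRUE,
                  size_c = 4L)
  write_tiff_gray(lapply(1:15, function(c) rand_plane(8, 8, 16L)),
                  file.path(sub, "zstack.tif"), ome = TRUE,
                  size_c = 3L, size_z = 5L)
  write_tiff_gray(lapply(1:3, function(c) rand_plane(8, 8, 16L)),
                  file.path(sub, "multipoint.tif"), ome = TRUE,
                  size_c = 3L, n_series = 3L)
  writeBin(as.raw(1:32), file.path(sub, "corrupt.tif"))
  writeLines("x", file.path(sub, "notes.csv"))  # other extension: invisible

  spec <- dataset_spec(d, "single_file", extension = "tif", n_channels = 3)
  res <- collect_images("WT", spec)
  expect_length(res$records, 3L)
  expect_identical(vapply(res$records, `[[`, character(1), "base_name"),
                   c("WT1", "WT2", "WT3"))
  reasons <- vapply(res$diagnostics, `[[`, character(1), "reason")
  skipped <- vapply(res$diagnostics, `[[`, character(1), "file")
  expect_setequal(skipped, c("four_channel.tif", "zstack.tif",
                             "multipoint.tif", "corrupt.tif"))
  expect_match(reasons[skipped == "four_channel.tif"], "channel count")
  expect_match(reasons[skipped == "zstack.tif"], "multi-slice")
  expect_match(reasons[skipped == "multipoint.tif"], "multi-series")
  expect_match(reasons[skipped == "corrupt.tif"], "unreadable")

  # partition: every .tif accounted for exactly once
  tifs <- list.files(sub, pattern = "\\.tif$")
  loaded <- basename(unlist(lapply(res$records, `[[`, "source_paths")))
  expect_setequal(c(loaded, skipped), tifs)
  expect_identical(anyDuplicated(c(loaded, skipped)), 0L)

  # determinism: a second scan yields the identical structure
  expect_identical(collect_images("WT", spec), res)
})

test_that("extension matching is case-insensitive", {
  d <- tmp_dir()
  sub <- file.path(d, "A")
  dir.create(sub)
  write_tiff_gray(list(make_plane(0:63, 8, 8)), file.path(sub, "up.TIF"))
  spec <- dataset_spec(d, extension = "tif", n_channels = 1)
  expect_length(collect_images("A", spec)$records, 1L)
})

test_that("group_separated_channels applies the pivot/sibling rule", {
  ids <- c("DAPI", "GFP")
  res <- group_separated_channels(
    c("img01_DAPI.tif", "img01_GFP.tif", "img02_DAPI.tif", "img02_GFP.tif"),
    ids)
  expect_length(res$groups, 2L)
  expect_identical(vapply(res$groups, `[[`, character(1), "base_name"),
                   c("img01_", "img02_"))
  expect_identical(res$groups[[1L]]$files,
                   c("img01_DAPI.tif", "img01_GFP.tif"))
  expect_length(res$diagnostics, 0L)

  res <- group_separated_channels(
    c("img01_DAPI.tif", "img01_GFP.tif", "img03_GFP.tif"), ids)
  expect_length(res$groups, 1L)
  expect_length(res$diagnostics, 1L)
  expect_match(res$diagnostics[[1L]]$reason, "incomplete group")
  expect_identical(res$diagnostics[[1L]]$file, "img03_GFP.tif")

  # pivot occurring twice: ambiguous
  res <- group_separated_channels(
    c("DAPI_img_DAPI.tif", "DAPI_img_GFP.tif"), ids)
  expect_length(res$groups, 0L)
  reasons <- vapply(res$diagnostics, `[[`, character(1), "reason")
  expect_true("ambiguous identifier" %in% reasons)
})

test_that("grouping equals the brute-force stem oracle on random deletions", {
  ids <- c("DAPI", "GFP", "RFP")
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    stems <- sprintf("fov%02d_", 1:20)
    files <- as.vector(outer(stems, ids, function(s, i) {
      paste0(s, i, ".tif")
    }))
    files <- setdiff(files, sample(files, 5))
    res <- group_separated_channels(sample(files), ids)
    expected <- brute_force_groups(stems, ids, files)
    expect_identical(vapply(res$groups, `[[`, character(1), "base_name"),
                     expected)
    # partition invariant
    diag_files <- vapply(res$diagnostics, `[[`, character(1), "file")
    grouped <- unlist(lapply(res$groups, `[[`, "files"))
    expect_setequal(c(grouped, diag_files), files)
  }
})

test_that("separated-channels datasets load into conformable records", {
  d <- tmp_dir()
  spec <- generate_dataset(d, n_subfolders = 1, images_per_subfolder = 3,
                           n_channels = 3, structure = "separated_channels",
                           seed = 5)
  # remove one channel file: that field of view must drop out, diagnosed
  file.remove(file.path(d, "cond01", "img02_C2.tif"))
  res <- collect_images("cond01", spec)
  expect_length(res$records, 2L)
  expect_identical(vapply(res$records, `[[`, character(1), "base_name"),
                   c("img01_", "img03_"))
  expect_length(res$records[[1L]]$planes, 3L)
  files_diag <- vapply(res$diagnostics, `[[`, character(1), "file")
  expect_true("img02_C1.tif" %in% files_diag)
})

test_that("over-long subfolder/file paths are warned about but processed", {
  d <- tmp_dir()
  sub <- file.path(d, "condition_with_a_rather_long_name")
  dir.create(sub)
  long_name <- "field_of_view_with_an_extremely_long_file_name_0001.tif"
  write_tiff_gray(list(make_plane(0:63, 8, 8)), file.path(sub, long_name))
  spec <- dataset_spec(d, n_channels = 1)
  res <- collect_images("condition_with_a_rather_long_name", spec)
  expect_length(res$records, 1L)
  expect_match(res$warnings, "61 characters", all = FALSE)
})
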