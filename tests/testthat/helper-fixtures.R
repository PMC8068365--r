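# Shared helpers: tiny in-code fixtures and independent oracles.

# Plane from a vector of intensities, filled row-wise.
make_plane <- function(values, width, height, bit_depth = 8L) {
  channel_plane(matrix(as.integer(values), nrow = height, ncol = width,
                       byrow = TRUE), bit_depth)
}

rand_plane <- function(width, height, bit_depth = 8L) {
  make_plane(sample(0:bit_depth_max_(bit_depth), width * height,
                    replace = TRUE), width, height, bit_depth)
}

bit_depth_max_ <- function(b) as.integer(2^b - 1)

make_record <- function(planes, base_name = "rec", subfolder = "sub") {
  list(subfolder_name = subfolder, base_name = base_name,
       source_paths = character(0), planes = planes)
}

# Independent sort-based percentile oracle for clip bounds: sort the raw
# pixels, discard floor(N*f/2) per tail, take the remaining extremes.
sort_bounds_oracle <- function(pixels, f) {
  s <- sort(as.vector(pixels))
  n <- length(s)
  k <- floor(n * f / 2)
  list(low = s[k + 1L], high = s[n - k])
}

# Brute-force grouping oracle over constructed names stem+id+ext: the
# stems whose complete identifier set of files exists.
brute_force_groups <- function(stems, identifiers, file_names,
                               ext = ".tif") {
  keep <- vapply(stems, function(st) {
    all(paste0(st, identifiers, ext) %in% file_names)
  }, logical(1))
  sort(stems[keep], method = "radix")
}

# Run a short python snippet, returning stdout lines (tifffile / Pillow act
# as independent decoders for files this package wrote).
run_python <- function(code, args = character(0)) {
  system2("python", args = c("-c", shQuote(code), args), stdout = TRUE,
          stderr = TRUE)
}

tmp_dir <- function(envir = parent.frame()) {
  d <- file.path(tempdir(), paste0("pm", paste(sample(letters, 8), collapse = "")))
  dir.create(d, recursive = TRUE)
  withr::defer(unlink(d, recursive = TRUE), envir = envir)
  d
}
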