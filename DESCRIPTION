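Package: picmontage
Title: Batch Montage Assembly for Multichannel Fluorescence Microscopy Datasets
Version: 0.1.0
Authors@R: person("picmontage", "developers", role = c("aut", "cre"),
    email = "picmontage@example.org")
Description: Headless batch assembly of annotated montages from directories of
    multichannel fluorescence microscopy images. From a parent directory with
    one subfolder per experimental condition, builds one all-images montage
    per condition (preview mode) and one experiment-wide montage of
    representative images (summary mode). Supports histogram-stretch contrast
    enhancement with configurable saturation percentiles and joint or
    per-image scaling, channel colorization and additive merging, tile
    labeling, and timestamp-paired run logs. Reads plain and OME TIFF natively
    and writes PNG, JPEG or TIFF montages. Includes a synthetic dataset
    generator for reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    png,
    optparse,
    yaml,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
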