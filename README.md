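# picmontage

Batch montage assembly for multichannel fluorescence microscopy datasets,
as a headless R library and command-line tool.

## The problem

A routine fluorescence microscopy experiment produces many multichannel
fields of view per condition — far more than anyone inspects comfortably by
hand. `picmontage` turns a directory of per-condition subfolders of images
into annotated overview figures in one call:

* **preview mode** — for every condition subfolder, one montage gathering
  *all* of its fields of view (rows = fields of view, columns = the
  single-channel grayscale tiles followed by a merged RGB composite);
* **summary mode** — one experiment-wide montage with a single
  *representative* field of view per condition (rows = conditions).

Every run also writes a plain-text log — user parameters, directory
content, selected and skipped files, applied contrast bounds — tagged with
the same `YYYYMMDD-HHMMSS` timestamp as the montages so outputs and
provenance pair unambiguously.

## The processing model

**Discovery.** The parent directory is scanned one level deep; each
immediate subdirectory is a condition. Two dataset layouts are supported:
one multichannel (OME-)TIFF per field of view, or one single-channel file
per channel whose names differ only by a channel identifier substring
(e.g. `img01_DAPI.tif` / `img01_GFP.tif`). Files with the wrong extension
or channel count, or with more than one z-slice, time frame or
series/position, are skipped with a logged diagnostic, never silently.

**Contrast enhancement** is linear histogram stretching. For a channel
with pixel intensities in `0..2^b - 1`, clip bounds `(low, high)` are the
percentile points leaving at most `floor(N f / 2)` pixels per tail at
saturation fraction `f` (menu: 0, 0.01, 0.1, 0.4, 1 %), and each pixel
maps as

```
p  ->  round( (clamp(p, low, high) - low) * (2^b - 1) / (high - low) )
```

Bounds can be computed **jointly** (one pair pooled over all images of a
montage and channel — between-image intensity ratios remain comparable) or
**individually** per image (maximal contrast, but any quantitative
comparison between images becomes invalid). `autoscale` is the
per-image/per-channel min–max special case; `none` keeps raw data.

**Rendering.** Single-channel tiles are grayscale; the merge is a
saturating additive composite of the channels colorized with a 7-color
palette (red, green, blue, gray, cyan, magenta, yellow). Tiles are
optionally labeled `"C<k> <folder> <file>"` with a built-in bitmap font,
and abutted on a 2-px black grid, horizontally or vertically. Montages
export as PNG or TIFF (lossless) or JPEG (quality 90, lossy).

## Worked example

```r
library(picmontage)

# a synthetic 2-condition experiment (3 fields of view x 3 channels each)
d <- file.path(tempdir(), "Experiment001")
spec <- generate_dataset(d, n_subfolders = 2, images_per_subfolder = 3,
                         n_channels = 3, subfolder_names = c("WT", "Mutant"),
                         seed = 1)

res <- run_preview(run_config(spec, "preview",
                              contrast = contrast_policy("autoscale")))
basename(res$montage_paths)
#> [1] "Mutant_preview_20260911-091432.png" "WT_preview_20260911-091432.png"
dim(png::readPNG(res$montage_paths[1]))[1:2]
#> [1] 196 262      # 3 rows x 4 columns of 64-px tiles + 2-px separators

res2 <- run_summary(run_config(spec, "summary",
                               representatives = list(WT = "img03")))
basename(res2$montage_paths)
#> [1] "summary_20260911-091432-2.png"
```

Each preview montage is a 3 × 4 tile grid: three fields of view
(rows) × three grayscale channel tiles plus the RGB merge (columns). The
summary montage has one row per condition, with `img03` standing for `WT`
and the lexicographic first record (`img01`) for `Mutant` by default. The
log ends with the run duration, e.g.

```
Macro finished on 20260911-091432 (YYYYMMDD-HHMMSS) and lasted 0.035 s
```

Note the `-2` suffix on the summary outputs: both runs fell in the same
second, and outputs are never overwritten.

## Command line

The installed script `exec/picmontage` mirrors the R API:

```sh
picmontage preview /data/Experiment001 --channels 3 --contrast autoscale
picmontage summary /data/Experiment001 --channels 3 \
    --representatives WT=WT3,Mutant=Mutant1 --format jpeg
picmontage preview /data/Exp2 --structure separated --channels 2 \
    --identifiers DAPI,GFP --contrast custom \
    --saturation c1=0.4,c2=0 --scope c1=individual,c2=joint
```

Every flag can also live in a YAML file (`--config run.yaml`); explicit
flags override the file, and all resolved values are echoed to log
section (2).

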