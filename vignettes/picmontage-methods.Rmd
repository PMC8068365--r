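---
title: "picmontage: processing model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{picmontage: processing model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`picmontage` assembles overview montages from an experiment directory laid
out one level deep: a parent folder, one subfolder per condition, image
files inside the subfolders. A *record* is one logical multichannel field
of view; it either comes from a single multichannel (OME-)TIFF or from a
group of single-channel files whose names differ only by a channel
identifier substring. All outputs — montages plus one log per run — are
written to the parent folder, never into the condition subfolders, and all
share one `YYYYMMDD-HHMMSS` token.

Native input is uncompressed baseline TIFF and OME-TIFF, 8- or 16-bit.
The toolchain this package targets ships no R TIFF package, so it carries
a small codec of its own (`read_tiff()`, `write_tiff_gray()`,
`write_tiff_rgb()`); the test suite cross-checks it in both directions
against an independent Python decoder (`tifffile`). Proprietary microscope
formats are deliberately not parsed: `read_image()` accepts a plugin
`reader` callable so such formats can be bolted on without touching the
pipeline.

### Compliance filtering

Dimension metadata is *reported* by `read_image()` and *judged* by
`collect_images()`: a file is skipped — with a diagnostic that ends up in
log section (4) — when its channel count differs from the declared one, or
when it has more than one z-slice, time frame, or series/position. For a
plain multi-page TIFF without OME metadata the pages are taken to be
channels, and the declared channel count decides whether that reading was
right; this is the safest interpretation of an ambiguous container. An
interleaved RGB page counts as 3 channels.

Two deliberate deviations from the behaviour of the historical tooling
this package replaces:

* **File ordering** is byte-wise lexicographic everywhere (subfolders,
  then file/base names). Enumeration order of the original environment is
  undocumented; determinism was judged more valuable than parity.
* **Long paths work.** The original had a practical ~61-character limit on
  `subfolder/file.ext`; here longer names are processed normally and only
  noted in the log for provenance.

Extension matching is case-insensitive (`TIF` = `tif`), since mixed-case
extensions are common on instrument PCs.

### Separated-channel grouping

The first identifier is the pivot. Every file containing the pivot
*exactly once* proposes a group; sibling names are formed by substituting
the pivot with each other identifier, and the group survives only if all
siblings exist. Everything else is diagnosed: pivot twice in one name
("ambiguous identifier"), missing siblings ("incomplete group"), orphan
non-pivot files. Identifiers must be pairwise distinct, non-empty, and no
identifier may be a substring of another — that invariant is enforced at
`dataset_spec()` construction because grouping would otherwise be
ill-defined. The property suite checks the whole mechanism against a
brute-force "stems whose complete file set exists" oracle on randomized
name sets with deletions.

## Contrast enhancement

Enhancement is linear histogram stretching at the original bit depth.
The engine works on integer histograms (one bin per representable
intensity), so pooling across images is histogram summation and never
needs all pixel data at once.

Given pooled pixel count $N$ and saturation fraction $f \in [0, 0.01]$,
the per-tail budget is $k = \lfloor N f / 2 \rfloor$; `low` is the
smallest intensity whose cumulative count strictly exceeds $k$, `high`
the largest with cumulative count from above strictly exceeding $k$.
Pixels map as
$p \mapsto \mathrm{round}\!\left((\mathrm{clamp}(p) - \mathrm{low}) \cdot
\frac{2^b - 1}{\mathrm{high} - \mathrm{low}}\right)$,
rounding half-up.

Numerical choices worth stating:

* **Full scale is $2^b - 1$** (255 / 65535). Informal descriptions of bit
  depth ranges as "0–256" / "0–65,536" are off-by-one colloquialisms; real
  pixels cannot reach $2^b$.
* **The saturation fraction splits equally between tails.** Only a total
  percentage is specified by convention; the symmetric split is the common
  histogram-stretch behaviour and is recorded in every log.
* **Ties at the bounds all clip together**: every pixel equal to `low`
  maps to 0 and every pixel equal to `high` to full scale. Bin granularity
  makes exact pixel-count saturation impossible; the property suite bounds
  the excess by the tie counts.
* **Constant planes pass through unchanged** (`low == high`). Blank
  control images must not kill a run.
* **Rounding is half-up** (`floor(x + 0.5)`), not banker's rounding, so
  the map is exactly reproducible across platforms. Under this formula a
  pixel of 105 under bounds (10, 200) at 8 bit maps to
  `round(95 * 255/190) = round(127.5) = 128`.
* `autoscale` is per-image, per-channel stretching at saturation 0 — pure
  min–max.

**Joint vs. individual scope** is the scientifically loaded switch. Joint
scope computes one bounds pair from the pooled histograms of a channel
across all records of one montage file, so the brightest pixel anywhere in
the group sets the reference and between-image mean-intensity ratios are
preserved (exactly so, up to rounding, when the pooled minimum is 0 — the
property suite asserts this). Individual scope makes each image's own
maximum the reference, which equalizes genuinely different images; the
bundled `pitfall_scene()` reproduces this failure mode with four
square-pattern pictures in which the large square has a 3-fold
between-picture intensity ratio that joint scaling preserves and
individual scaling destroys.

In summary mode, joint scope pools across *all selected records*: they
share one montage file, and the pooling boundary follows the montage file.
Whether pooling should instead stay per condition is genuinely open; the
montage-file reading was chosen and is flagged in the log so users can see
what was compared to what. In preview mode pooling never crosses
subfolders, because each subfolder is its own montage file.

## Rendering

Single-channel tiles are drawn grayscale; the merge is the component-wise
sum of the colorized included channels, clamped to 255. Clamped addition
(rather than per-component maximum) matches the common fluorescence
composite convention; saturated overlaps are therefore possible and the
convention is stated in the log. Display scaling from 16-bit to 8-bit
happens after contrast enhancement, by full-range linear scaling.

Labels read `"C<k> <folder> <file>"` (or `"merge ..."`), white, top-left.
Only the content and ordering of the label are externally fixed; the
styling rule chosen here is deterministic: target font height
`max(8 px, floor(tile_height / 24))`, rendered with a built-in 5×7 bitmap
font at an integer scale (so the realized height is the largest multiple
of 8 px not exceeding the target), text truncated with `...` at the tile
width. A bitmap font avoids any dependence on platform font stacks —
montage bytes are reproducible everywhere.

Tiles are abutted with a 2-px black separator (a fixed choice; only the
visual separation itself is conventional). Mixed tile sizes within one
montage are a fatal error naming the offending grid cell — silently
padding or rescaling images of different sizes would corrupt exactly the
visual comparisons montages exist for.

## Synthetic data

`generate_dataset()` writes complete experiment trees in both layouts:
flat-background scenes with two non-overlapping squares per channel whose
mean intensities vary deterministically with channel and image index, plus
clipped Gaussian noise. Defaults: 64×64 px, 16-bit, background 5 % of full
scale, noise sd 1 % of full scale — values in the range of a dim,
well-exposed widefield acquisition, chosen once so that autoscale,
joint/individual scoping and merge rendering all have visible work to do.
The same arguments and seed reproduce byte-identical files (the generator
runs on a private RNG stream and restores the caller's).

What the generator does *not* emulate: cell morphology, PSF blur, uneven
illumination, hot pixels, or compressed/tiled TIFF variants. A green test
therefore establishes the pipeline's bookkeeping and arithmetic — file
grouping, exclusion rules, bounds, composition, export — not robustness to
every real-world TIFF flavor.

`pitfall_scene()` is exact by construction with `noise_sd = 0`: region
means over the square masks equal the specified means, which is what makes
the joint-vs-individual assertions sharp rather than statistical. The
exact pixel values of the original demonstration images are not published;
only their stated relations (equal square-1 means in pictures 1 and 4,
3-fold lower in 2 and 3, square 4 brightest within picture 3) are
reproduced, with means 9000/3000/12000 at 16 bit chosen to sit well inside
the dynamic range.

## Logs, timestamps, CLI

The log has exactly four numbered sections — (1) tool/mode and start
timestamp, (2) every resolved parameter including applied contrast bounds,
(3) parent directory content, (4) per-subfolder selected files, skip
diagnostics and warnings — and a final
`Macro finished on <ts> (YYYYMMDD-HHMMSS) and lasted <s.sss> s` line with
the duration at 3 decimals. Montage stems are
`<subfolder>_preview_<token>` and `summary_<token>`; the stem format is a
package choice made for sortability, the timestamp pairing is contract.
Two runs in the same second get `-2`, `-3`, … suffixes; existing outputs
are never overwritten. Because montages land in the parent directory and
dataset images live one level down, outputs can never be re-ingested as
inputs on a rerun; a same-extension collision is additionally prevented by
the stem prefix.

The CLI is non-interactive by design (no dialog flow): representatives
are passed as `--representatives WT=WT3,...` or by 1-based index, with
"first record, lexicographically" as the default — the same default used
for the benchmark composition runs. YAML config mirrors every flag; CLI
overrides config; log section (2) records the resolved result, so the log
is always sufficient to reproduce a run.

## Known limitations

* TIFF support is the uncompressed baseline subset (plus OME-XML
  metadata); LZW/deflate/tiled files surface as "unreadable" skip
  diagnostics rather than being decoded.
* No multi-level directory recursion; the one-level layout is the data
  model, not a tunable.
* JPEG export is lossy by nature; PNG or TIFF should be used whenever
  montages might be measured rather than viewed.
* Wall-clock performance claims are explicitly not part of the contract;
  the implementation holds one montage group in memory at a time, which
  is ample for overview-sized images but not tuned for gigapixel inputs.
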