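---
title: "Block-pyramid storage for large volumes: format, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-pyramid storage for large volumes: format, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brickvol)
```

This vignette is the package's account of how and why its machinery works:
the on-disk model, the algorithms, the numerical conventions, and the design
decisions that were genuinely open. The companion README shows the user-facing
workflow; here we explain the internals a maintainer or reviewer needs.

## The problem and the storage model

A modern whole-brain light-microscopy acquisition is a stack of 10^4–10^5
2D grayscale TIFF slices: a single 3D volume of 10^12–10^15 voxels. Two
access patterns dominate downstream work — arbitrary 3D regions of interest
(for tracing, inspection, annotation) and coarse overviews (for navigation)
— and slice-oriented storage serves both badly: a 512³ ROI touches tens of
thousands of slice files, and any overview requires reading everything.

`brickvol` stores the volume as a pyramid of cubic **blocks**:

* **Level 1** is the original sampling. Level *n+1* halves every axis of
  level *n* with ceiling. Subsampling stops at the first level where all
  three axes are smaller than the block edge *B*, which guarantees the top
  level fits in a single block (so a whole-dataset thumbnail is one file
  read). A volume already smaller than *B* everywhere has exactly one level.
* Each level is tiled by `ceil(dims / B)` blocks per axis. Boundary blocks
  are zero-padded to exactly *B*³ — every block file has identical shape and
  size, which makes addressing pure arithmetic.
* Coordinates are 0-based, axis order (x = width, y = height, z = slice),
  half-open extents. Block `(bx, by, bz)` covers voxels
  `[bx·B, (bx+1)·B) × …` of its level.
* Blocks live in a four-level directory tree,
  `level_<L>/z<bz>/y<by>/<bx>_<by>_<bz>.tif`, so the file name alone encodes
  the block's position and directory fan-out stays bounded even for
  petabyte-scale grids (a 19012³ volume at *B* = 512 has a 38×38×38 grid:
  38 `z` directories of 38 `y` directories of 38 files). The path grammar is
  a stated convention of this package, and `parse_block_path()` inverts it
  exactly; the invariant suite checks the bijection and that block extents
  tile each level exactly once.
* The block container is an uncompressed multi-page grayscale TIFF (*B*
  pages of *B*×*B*), chosen because it round-trips 8- and 16-bit samples
  bit-exactly and every imaging tool can open it. Compression codecs and
  alternative containers (HDF5/N5/zarr-style) are out of scope.
* A JSON descriptor (suffix `.bvol.json`) carries the seven mandatory
  fields: dims, resolution (µm/voxel), bit depth, block size, level count,
  container format and storage root. Reading validates each field and names
  the offending key on error; unknown keys warn and are ignored so the
  format can grow.

*B* defaults to 512 — at 8 bit that is a 128 MiB block, a good unit for both
disk and network — but is configurable down to 8. The whole test suite runs
at *B* = 16/32 so that multi-level, multi-block geometry is exercised on
volumes of 32–128 voxels per side; the production-geometry numbers (block
counts, buffer sizes at *B* = 512) are pure arithmetic and are asserted
directly.

## The reformatter and its memory bound

Conversion from a slice sequence proceeds level by level; each level's
slices are read exactly twice (once to cut blocks, once to build the next
level):

1. **Subsampling.** Slice pairs are merged and pooled 2×2 in plane: each
   output voxel is the arithmetic mean of its ≤2×2×2 source window (partial
   windows at odd edges), rounded half-up. Only two full slices are ever in
   memory. The mean was chosen over decimation because it preserves
   photometry — a uniform region keeps its intensity at every level, which
   the pooling-sanity test asserts — and over a Gaussian because it is
   exactly invertible arithmetic to test against. Rounding is half-up
   (`floor(x + 0.5)`), not banker's, so the 0/255 checkerboard mean 127.5
   lands deterministically on 128.
2. **Cuboid reading.** For each (y-stripe, z-slab) pair the reformatter
   fills one **cuboid** buffer of `width × B × B` voxels, zero-padding
   beyond the y/z extent. The cuboid is the entire per-worker working set:
   `width × B × B × bytes-per-voxel`, independent of volume height and
   depth — 4.64 GiB for an 8-bit volume 19 012 voxels wide at *B* = 512.
3. **Block splitting.** The cuboid is cut into `ceil(width / B)` blocks
   along x (last block zero-padded) and written. Reassembling the split
   blocks reproduces the cuboid voxel-for-voxel (tested).

Parallelism is an executor count, not a prescribed mechanism: units of work
are one cuboid (level pass), one output slice (subsampling) and one block
(writes), all independent, so output block files are byte-identical for any
worker count (asserted by checksum). Worker errors propagate.

**Memory accounting convention.** R cannot address 1-byte array elements, so
buffers are accounted in *payload bytes* — voxel count × stored sample width
— the same metric as the `width × B × B × bpp` bound itself. The reformatter
instruments the actual cuboid buffers it allocates and reports the per-worker
peak in the `"stats"` attribute; the test suite asserts it never exceeds the
bound. The R TIFF reader decodes whole slices (it has no partial-strip API),
so one decoded slice is a transient overhead on top of the bound; voxel
*ingestion* (copies into cuboids) is counted separately and equals each
level's voxel count exactly once.

## Reading back: sequential, ROI, cache

**Sequential reads** visit every block of a level once (z, then y, then x
with one worker; same multiset with more), bypassing the cache — a pass that
touches everything once would only pollute it.

**ROI reads** use read-crop: compute the overlapped blocks at the serving
level, fetch each cache-first, assemble by position, crop. ROI coordinates
are always level-1 voxels — callers address physical space once — and map to
level L by `floor(origin / 2^(L-1))` and `ceil(size / 2^(L-1))`.

**Level selection.** The serving level is either forced by the caller or
chosen automatically as the *finest* level whose scaled ROI voxel count fits
a budget (default *B*³ voxels ≈ one block). A voxel budget was chosen over a
display-size rule because it is device-independent and gives the natural
monotonicity (bigger ROIs never map to finer levels, tested). The budget is
exposed as a parameter.

**Cache.** Decoded blocks are cached under LRU eviction (default capacity
512 blocks; at the desk-scale *B* = 32 that is ~16 MiB, at *B* = 512 it
would be sized in blocks to the machine). The cache is an IO optimisation
only: results with capacity 0 and capacity ∞ are identical (tested), storage
reads never increase with capacity (tested), and the eviction order is
replayed against a brute-force recency simulation over 1000 random
operations.

**Out-of-bounds policy.** ROIs beyond the padded level-1 extent raise a
range error rather than zero-filling — silent zeros hide caller bugs —
while padding voxels *inside* boundary blocks legitimately read as 0.

## Block-wise rigid transformation

A rigid registration matrix (rotation + translation, estimated by external
tools on a coarse level) is applied to a dataset that cannot be loaded:

1. The eight corners of `[0, dims)` are transformed; the axis-aligned
   bounding box, rounded to nearest (ties up), is the target extent, and
   the shift taking the box minimum to the origin is folded into the
   transform. Round-to-nearest is deliberate: a 512-cube rotated 45° has
   extent 512·√2 ≈ 724.08 → 724 (ceiling would give 725), and a 1000-cube
   gives 1414.21 → 1414.
2. Each target block's corners are inverse-mapped into the source; the
   bounding source region plus a 1-voxel interpolation margin is fetched via
   the cached ROI reader. Neighbouring target blocks request overlapping
   source regions, so the cache converts the naive 8× re-read into one
   storage read per source block — the instrumented single-block worked
   example (one 45°-rotated block → four target blocks) shows exactly 1
   storage read and 3 cache hits.
3. Each target voxel is sampled at its inverse-mapped source coordinate,
   trilinear by default (nearest available). Samples outside the source are
   0, consistent with the format's padding semantics. Values are rounded
   half-up and clamped to the sample range; target-padding voxels are forced
   to 0 to keep the format invariant.

**Sampling convention.** Coordinates are voxel *centers*: index p sits at
continuous position p + ½. Under this convention the identity transform is
a bit-exact copy and a 90° rotation is an exact index permutation (both
tested); with corner-anchored coordinates a 90° rotation would shift the
lattice by one voxel and manufacture a zero edge. Level L maps to continuous
level-1 coordinates by `u = (p + 0.5)·2^(L-1)`.

**Coarse output levels** are, by default, produced by transforming the
matching source level with the level-scaled transform (rotation unchanged,
translation divided by `2^(L-1)`); when the target pyramid is deeper than
the source's, the deepest source level serves the remainder. The
alternative — re-subsampling the transformed level 1 — is available as
`levels_mode = "subsample"` and is property-tested to agree with the default
within ±3 intensity units on a smooth ramp volume away from the source
border (at the border the two constructions blend different amounts of
background, so exact agreement is not expected and not claimed).

**Correctness claim.** The core property is block-wise/whole-volume
equivalence: for identity (exact), 90° under nearest (exact permutation) and
45° under trilinear (≤ 1 intensity unit), the assembled block-wise output
equals an independent dense resampler that maps the entire volume in memory
with the same sampling convention. Composition of transforms at the dataset
level is asserted exactly for 90° rotations (where no interpolation blur
intervenes); for general angles the dense-equivalence oracle is the
operative guarantee, since two interpolation passes never reproduce one
pass bit-for-bit.

Interpolation choice: trilinear is the field's default for intensity
volumes (smooth, cheap, monotone); nearest is kept for label-like data and
for exactness arguments. Higher-order splines were left out deliberately —
they widen the support (larger fetch margins) for little benefit at the
noise levels of this data.

Anisotropic voxels: matrices given in µm are converted to voxel space by
pre/post scaling with the metadata resolution; the worked geometry examples
all use isotropic voxel space.

## Re-slicing

Orthogonal planes are named anatomically: horizontal ⊥ z, coronal ⊥ y,
sagittal ⊥ x. Positions and slab thicknesses are micrometres, converted by
the per-axis resolution; MIP mode takes the voxelwise maximum over the slab
(clipped at the volume end). The pixel payload is written as a plain TIFF
with a JSON sidecar carrying pixel size and slab parameters, because the R
TIFF writer exposes no resolution tags.

## The chessboard phantom

The synthetic benchmark volume is an n³ chessboard: in-plane tiles of
`tile` px (default 256), whole pattern inverting every `phase_period`
slices (default 256), so all three axes carry structure at a known scale.
Voxel (x, y, z) is white iff `⌊x/tile⌋ + ⌊y/tile⌋ + ⌊z/phase_period⌋` is
even; white = dtype max, black = 0. Noise is additive zero-mean Gaussian
with σ = `noise_fraction` × dynamic range (default 5 %), clipped to the
sample range — the σ-based reading of "5 % noise" was chosen and is recorded
in the manifest, since an amplitude-based reading is equally defensible.
Generation is streamed slice by slice (O(n²) memory), seeded, and the
manifest records parameters plus per-slice MD5 checksums; a fixed seed gives
bit-identical volumes, different seeds give different noise but the same
thresholded pattern.

What the phantom emulates: sharp structure at every scale, both phases of
contrast, boundary effects at tile edges, realistic entropy under noise.
What it does not: anisotropic resolution, vignetting and stitching seams,
depth-dependent attenuation, sparse bright structures over dark background
(the regime of neurite imaging). Tests passing on the phantom therefore
certify the *storage and resampling machinery* — bit-exact pyramids, crops,
cache transparency, transform equivalence — not photometric fidelity on any
particular modality.

## Problem sizes and numerical choices

The suite and the acceptance checks run, by choice, at desk scale: phantoms
of 32–128 voxels per side, B = 16/32, 200 random ROIs, 1000-operation cache
replays; the whole suite completes in well under a minute on one core.
These sizes were picked so every code path (multi-level pyramids, boundary
padding, multi-block ROIs, cache eviction, block-wise transforms of >100
blocks) is exercised with whole-volume oracles held in memory; nothing in
the implementation depends on them. Tie-break and degeneracy conventions,
collected:

* all rounding of intensities and extents is half-up (`floor(x + 0.5)`);
* rigid validation: orthonormality within 1e-4, last row exactly
  (0, 0, 0, 1) within 1e-8, inverse residual within 1e-6 (the inverse is
  computed by `solve()`, not the transpose, so near-orthonormal inputs from
  text files still invert to machine precision);
* degenerate inputs: a single small slice reformats to one padded block and
  a one-level pyramid; a transform mapping a block entirely outside the
  source yields a zero block; empty ROIs are rejected (`size ≥ 1`).

## Known limitations

* One grayscale channel per dataset; multi-channel data means parallel
  datasets.
* No resumable/incremental reformatting: a crashed run is restarted with
  `force = TRUE`.
* The in-process parallel executor is fork-based (`parallel::mclapply`),
  so `workers > 1` falls back to serial execution on platforms without
  fork; output is identical either way by construction.
* The LRU cache is per-handle and in-process; forked transform workers do
  not share it, so the read-once-then-cache IO pattern is a single-worker
  guarantee.
* Estimating the registration matrix is out of scope; the package applies a
  matrix obtained elsewhere (an example matrix from a whole-brain
  registration ships in `inst/extdata/`).
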