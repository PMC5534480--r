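# brickvol

Block-pyramid storage and out-of-core processing for very large 3D
grayscale microscopy volumes, in R.

Whole-brain light microscopy (light-sheet, MOST and friends) produces a 3D
volume as tens of thousands of 2D TIFF slices — terabytes of data that no
workstation can hold in memory, and that slice-oriented storage makes
painfully slow to access in 3D. `brickvol` re-stores such a volume as a
**multi-resolution pyramid of fixed-size cubic blocks** ("bricks") on disk
and provides the operations that make the format useful without ever loading
the volume:

- **Reformatter** — converts a slice sequence into the brick pyramid with a
  provable per-worker memory bound. The working buffer is one *cuboid* of
  `width × B × B` voxels (`B` = block edge, default 512): for an 8-bit
  volume 19 012 voxels wide that is 19 012 × 512 × 512 bytes ≈ **4.64 GiB**,
  independent of the volume's height and depth.
- **Accessor** — random region-of-interest reads via the *read-crop*
  strategy (find overlapping blocks → fetch cache-first → assemble → crop),
  with automatic pyramid-level selection under a voxel budget and an LRU
  block cache; plus block-sequential whole-level iteration.
- **Rigid transformer** — applies a 4×4 rigid registration matrix to an
  entire dataset one output block at a time: each target block is
  inverse-mapped into the source, the bounding source region is fetched
  through the cache, and every voxel is sampled (trilinear or nearest).
- **Reslicer** — orthogonal single planes or maximum-intensity projections
  of configurable thickness in micrometres.
- **Phantom generator** — a seeded 3D chessboard benchmark volume (256-px
  tiles, phase flip every 256 slices, 5 % Gaussian noise) at any size.

The pyramid geometry: level 1 is full resolution; every further level
halves all three axes (ceiling) until all are smaller than `B`, so the top
level always fits in one block. Level dims `d` are tiled by
`ceil(d / B)` blocks per axis, boundary blocks zero-padded; block
`bx_by_bz` of a level starts at voxel `(bx·B, by·B, bz·B)` and lives at
`level_<L>/z<bz>/y<by>/<bx>_<by>_<bz>.tif` (an uncompressed multi-page
TIFF). A JSON descriptor (`*.bvol.json`) records dims, resolution, bit
depth, block size, level count, container format and storage root.

Everything is parameterised, so the full machinery runs at desk scale with
`B = 16` or `32` in the tests, while the arithmetic of the production
geometry (`B = 512`) is exercised directly.

## Worked example

```r
library(brickvol)

src <- file.path(tempdir(), "phantom"); dst <- file.path(tempdir(), "bricks")
generate_phantom(src, n = 64, tile = 16, phase_period = 16, seed = 1)
meta <- reformat(src, dst, resolution = c(1, 1, 1), block_size = 32)
ds <- open_dataset(dst)
print(ds)
#> brick-pyramid dataset metadata
#>   dims (x,y,z):   64 x 64 x 64 voxels
#>   resolution:     1 x 1 x 1 um/voxel
#>   bit depth:      8
#>   block size:     32
#>   levels:         3
#>   storage root:   .
#>   level 1: 64x64x64 voxels, 2x2x2 blocks (8 files)
#>   level 2: 32x32x32 voxels, 1x1x1 blocks (1 files)
#>   level 3: 16x16x16 voxels, 1x1x1 blocks (1 files)
#>   io: 0 storage reads, 0 cache hits

roi <- read_roi(ds, origin = c(16, 16, 16), size = c(32, 32, 32))
print(roi)
#> ROI read at level 1: 32x32x32 voxels at 1x1x1 um/voxel, origin (16,16,16)

tf <- rotation_about("z", 45)
rotated_bounds(c(512, 512, 512), tf)$dims
#> [1] 724 724 512

out <- file.path(tempdir(), "rotated")
transform_dataset(ds, tf, out)              # block-wise rigid re-sampling
mip <- reslice(open_dataset(out), "horizontal", position_um = 20,
               thickness_um = 16, mode = "mip")
dim(mip)
#> [1] 91 91
```

The ROI came back at level 1 because 32³ voxels fit the default budget; a
whole-volume request on a large dataset would be served from a coarser
level instead. The rotated bounding box of a 512-voxel cube is
724 × 724 × 512 — four blocks at `B = 512` where the source needed one.
The MIP is the voxelwise maximum over a 16 µm slab of the rotated phantom
(91 = round(64·√2)).

A command-line wrapper with the same operations is installed at
`inst/cli/brickvol` (subcommands `make-phantom`, `reformat`, `info`,
`read-roi`, `transform`, `reslice`).

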