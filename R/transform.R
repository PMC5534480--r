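#' Rigid transforms
#'
#' A rigid transform is a 4x4 homogeneous matrix, rotation plus translation,
#' applied to column vectors \code{(x, y, z, 1)^T} in level-1 voxel
#' coordinates. Construction validates the rigid invariants: the upper-left
#' 3x3 must be orthonormal within 1e-4, the last row must be (0, 0, 0, 1),
#' and the numeric inverse must satisfy \code{inv \%*\% m = I} within 1e-6.
#' Registration tools typically estimate such a matrix on a coarse pyramid
#' level; this package then applies it to the full-resolution dataset block
#' by block.
#'
#' @param m a 4x4 numeric matrix (row-major rotation + translation), or an
#'   existing \code{rigid_transform}.
#' @return An object of class \code{rigid_transform} with elements
#'   \code{matrix} and \code{inverse}.
#' @examples
#' tf <- rotation_about("z", 45)
#' tf$matrix %*% c(1, 0, 0, 1)
#' @export
rigid_transform <- function(m) {
  if (inherits(m, "rigid_transform")) return(m)
  m <- as.matrix(m)
  if (!identical(dim(m), c(4L, 4L)) || !all(is.finite(m)))
    stop_bv("bv_transform_error", "transform must be a finite 4x4 matrix")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop_bv("bv_transform_error", "last row of a rigid transform must be (0,0,0,1)")
  R <- m[1:3, 1:3]
  if (abs(det(R)) < 1e-6)
    stop_bv("bv_transform_error", "singular transform (det = %g)", det(R))
  if (max(abs(crossprod(R) - diag(3))) > 1e-4)
    stop_bv("bv_transform_error",
            "rotation part is not orthonormal (max deviation %g > 1e-4)",
            max(abs(crossprod(R) - diag(3))))
  inv <- solve(m)
  if (max(abs(inv %*% m - diag(4))) > 1e-6)
    stop_bv("bv_transform_error", "inverse check failed")
  structure(list(matrix = m, inverse = inv), class = "rigid_transform")
}

#' Convert a physical-space (micrometre) transform to voxel space
#'
#' Registration matrices are usually estimated in physical units. With
#' per-axis voxel size r (um/voxel) the voxel-space map is
#' \code{S^-1 M S}, \code{S = diag(r)}. For isotropic voxels the result is
#' rigid and validated as such; for anisotropic voxels the conjugated matrix
#' is a general invertible affine (class \code{affine_transform}), which the
#' resampling machinery accepts but the strict rigid validator would not.
#'
#' @param m a 4x4 matrix or [rigid_transform()] in micrometre coordinates.
#' @param resolution um per voxel, length 3 (e.g. from [brick_meta()]).
#' @return A \code{rigid_transform} or \code{affine_transform}.
#' @export
um_to_voxel_transform <- function(m, resolution) {
  if (inherits(m, "rigid_transform")) m <- m$matrix
  if (length(resolution) != 3L || any(resolution <= 0))
    stop_bv("bv_transform_error", "resolution must be three positive values")
  S <- diag(c(resolution, 1))
  mv <- solve(S) %*% m %*% S
  ok <- try(rigid_transform(mv), silent = TRUE)
  if (!inherits(ok, "try-error")) return(ok)
  if (abs(det(mv[1:3, 1:3])) < 1e-9)
    stop_bv("bv_transform_error", "singular transform after unit conversion")
  structure(list(matrix = mv, inverse = solve(mv)), class = "affine_transform")
}

# accept a validated transform object, or strictly validate a raw matrix
as_volume_transform <- function(m) {
  if (inherits(m, c("rigid_transform", "affine_transform"))) m
  else rigid_transform(m)
}

#' @rdname rigid_transform
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param degrees rotation angle, right-handed about the axis.
#' @param translation optional translation (length 3, voxels).
#' @export
rotation_about <- function(axis = c("z", "y", "x"), degrees,
                           translation = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- degrees * pi / 180
  cs <- cos(a); sn <- sin(a)
  R <- switch(axis,
    z = matrix(c(cs, -sn, 0, sn, cs, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    y = matrix(c(cs, 0, sn, 0, 1, 0, -sn, 0, cs), 3, 3, byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, cs, -sn, 0, sn, cs), 3, 3, byrow = TRUE))
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- translation
  rigid_transform(m)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform (4x4, row-major):\n")
  print(unname(x$matrix))
  invisible(x)
}

#' Read and write a transform matrix file
#'
#' The on-disk form is JSON: either \code{{"matrix": [[...], ...]}} with four
#' rows of four, or a flat array of 16 numbers in row-major order. A plain
#' text file of 16 whitespace-separated numbers is also accepted on read.
#'
#' @param path file path.
#' @param tf a [rigid_transform()] (or 4x4 matrix) to write.
#' @return \code{read_transform}: a [rigid_transform()].
#' @export
read_transform <- function(path) {
  if (!file.exists(path))
    stop_bv("bv_io_error", "transform file not found: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_bv("bv_transform_error", "unparsable transform file %s", path))
    if (is.list(j) && !is.null(j$matrix)) j$matrix else j
  } else {
    scan(path, quiet = TRUE)
  }
  m <- if (is.matrix(vals)) vals else matrix(as.numeric(unlist(vals)), 4, 4, byrow = TRUE)
  rigid_transform(m)
}

#' @rdname read_transform
#' @export
write_transform <- function(tf, path) {
  tf <- rigid_transform(tf)
  jsonlite::write_json(list(matrix = apply(tf$matrix, 1, c, simplify = FALSE)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bounding box of a volume under a rigid transform
#'
#' Transforms the eight corners of the axis-aligned box \code{[0, dims)},
#' takes the axis-aligned bounding box of the images, and rounds each extent
#' to the nearest integer (ties up). The returned offset is the translation
#' that maps the box minimum to the new origin, i.e. the transformed dataset
#' lives at \code{R x + t + offset}.
#'
#' @param dims source voxel counts (length 3).
#' @param transform a [rigid_transform()] or 4x4 matrix.
#' @return List with \code{dims} (transformed voxel counts) and \code{offset}.
#' @examples
#' rotated_bounds(c(512, 512, 512), rotation_about("z", 45))$dims  # 724 724 512
#' @export
rotated_bounds <- function(dims, transform) {
  dims <- check_dims(dims)
  tf <- as_volume_transform(transform)
  corners <- t(as.matrix(expand.grid(x = c(0, dims[1]), y = c(0, dims[2]),
                                     z = c(0, dims[3]))))
  p <- tf$matrix[1:3, 1:3] %*% corners + tf$matrix[1:3, 4]
  mn <- apply(p, 1, min)
  mx <- apply(p, 1, max)
  list(dims = pmax(1, round_half_up(mx - mn)), offset = -mn)
}

# zero-outside lookup of source voxels inside a fetched region.
# idx: 3 x N integer source coords (level coords); returns numeric values
lookup_region <- function(region, region_origin, src_dims, idx) {
  inside <- idx[1, ] >= 0 & idx[1, ] < src_dims[1] &
            idx[2, ] >= 0 & idx[2, ] < src_dims[2] &
            idx[3, ] >= 0 & idx[3, ] < src_dims[3]
  li <- idx - region_origin
  rd <- dim(region)
  lin <- 1 + li[1, ] + rd[1] * (li[2, ] + rd[2] * li[3, ])
  lin[!inside] <- 1L   # placeholder; masked below
  vals <- as.numeric(region[lin])
  vals[!inside] <- 0
  vals
}

# resample one target block at target_level by inverse mapping through tf.
# coordinates are voxel centers: index p has continuous (level-1) position
# (p + 0.5) * 2^(L-1), so a 90-degree rotation permutes the lattice exactly.
# target voxel p (target level-L coords) samples source level Ls at
#   s = Rinv ((p + 0.5) * 2^(L-1) - t_total) / 2^(Ls-1) - 0.5
resample_block_region <- function(ds, tf_total, target_level, b, target_ldims,
                                  interpolation) {
  meta <- ds$meta
  B <- meta$block_size
  src_level <- min(target_level, meta$n_levels)
  tsc <- 2^(target_level - 1)
  ssc <- 2^(src_level - 1)
  src_dims <- ds$levels[[src_level]]$dims
  Rinv <- tf_total$inverse[1:3, 1:3]
  tinv <- tf_total$inverse[1:3, 4]
  o <- b * B
  g <- expand.grid(x = o[1] + 0:(B - 1), y = o[2] + 0:(B - 1),
                   z = o[3] + 0:(B - 1))
  P <- (t(as.matrix(g)) + 0.5) * tsc
  S <- (Rinv %*% P + tinv) / ssc - 0.5
  # source AABB with a 1-voxel interpolation margin, clipped to the source
  lo <- pmax(floor(apply(S, 1, min)) - 1, 0)
  hi <- pmin(ceiling(apply(S, 1, max)) + 2, src_dims)
  vals <- if (all(hi > lo)) {
    region <- read_region(ds, src_level, lo, hi - lo)
    if (interpolation == "nearest") {
      lookup_region(region, lo, src_dims, floor(S + 0.5))
    } else {
      f <- floor(S)
      w <- S - f
      acc <- numeric(ncol(S))
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        wt <- (if (cx) w[1, ] else 1 - w[1, ]) *
              (if (cy) w[2, ] else 1 - w[2, ]) *
              (if (cz) w[3, ] else 1 - w[3, ])
        acc <- acc + wt * lookup_region(region, lo, src_dims, f + c(cx, cy, cz))
      }
      acc
    }
  } else numeric(nrow(g))   # block maps entirely outside the source
  vals <- clamp(round_half_up(vals), 0, max_intensity(meta$bit_depth))
  # format invariant: padding voxels of boundary blocks are 0
  pad <- g$x >= target_ldims[1] | g$y >= target_ldims[2] | g$z >= target_ldims[3]
  vals[pad] <- 0
  arr <- array(as.integer(vals), dim = c(B, B, B))
  arr
}

#' Compute one block of the rigidly transformed dataset
#'
#' The unit step of [transform_dataset()]: the corners of the target block
#' are inverse-mapped into the source, the bounding source region (plus a one
#' voxel interpolation margin) is fetched through the cached ROI reader, and
#' every target voxel is sampled at its inverse-mapped source coordinate.
#' Samples falling outside the source volume are 0.
#'
#' @param ds source [open_dataset()] handle.
#' @param transform a [rigid_transform()]; source level-1 voxel coordinates
#'   map to target coordinates as \code{R x + t + offset}.
#' @param offset origin shift of the target volume, from [rotated_bounds()].
#' @param b 0-based target block coordinates (length 3).
#' @param level target pyramid level.
#' @param target_dims target voxel counts at level 1 (from
#'   [rotated_bounds()]).
#' @param interpolation \code{"trilinear"} or \code{"nearest"}.
#' @return A B^3 integer array.
#' @export
transform_block <- function(ds, transform, offset, b, level = 1L,
                            target_dims = NULL,
                            interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  tf <- as_volume_transform(transform)
  if (is.null(target_dims))
    target_dims <- rotated_bounds(ds$meta$dims, tf)$dims
  total <- tf$matrix
  total[1:3, 4] <- total[1:3, 4] + offset
  tf_total <- list(matrix = total, inverse = solve(total))
  tlev <- pyramid_levels(target_dims, ds$meta$block_size)
  if (level < 1L || level > length(tlev))
    stop_bv("bv_range_error", "target level %d out of range [1, %d]",
            level, length(tlev))
  grid <- tlev[[level]]$grid
  if (any(b < 0) || any(b >= grid))
    stop_bv("bv_range_error", "target block (%s) outside grid (%s)",
            paste(b, collapse = ","), paste(grid, collapse = ","))
  resample_block_region(ds, tf_total, level, b, tlev[[level]]$dims,
                        interpolation)
}

#' Rigidly transform a whole dataset, block by block
#'
#' Applies a rigid transform to a brick-pyramid dataset without ever holding
#' the volume in memory: the target extent is computed with
#' [rotated_bounds()], and every target block of every level is produced
#' independently by [transform_block()], reading only the source region it
#' needs through the block cache. Lower-resolution target levels are, by
#' default, computed by applying the level-scaled transform (rotation
#' unchanged, translation divided by \code{2^(L-1)}) to the matching source
#' level; \code{levels_mode = "subsample"} instead rebuilds them by mean
#' pooling the transformed level 1. Output is deterministic for any worker
#' count.
#'
#' @param ds source [open_dataset()] handle.
#' @param transform a [rigid_transform()] or 4x4 matrix.
#' @param out_root output dataset directory.
#' @param workers parallel workers (unit of work: one target block).
#' @param interpolation \code{"trilinear"} (default) or \code{"nearest"}.
#' @param levels_mode \code{"transform"} or \code{"subsample"}, see above.
#' @param force overwrite an existing non-empty \code{out_root}.
#' @return The target dataset's [brick_meta()], invisibly.
#' @export
transform_dataset <- function(ds, transform, out_root, workers = 1L,
                              interpolation = c("trilinear", "nearest"),
                              levels_mode = c("transform", "subsample"),
                              force = FALSE) {
  interpolation <- match.arg(interpolation)
  levels_mode <- match.arg(levels_mode)
  tf <- as_volume_transform(transform)
  meta <- ds$meta
  rb <- rotated_bounds(meta$dims, tf)
  out_meta <- brick_meta(rb$dims, meta$resolution, meta$bit_depth,
                         meta$block_size, storage_root = ".")
  check_output_dir(out_root, force)
  tlev <- pyramid_levels(rb$dims, meta$block_size)
  do_level <- function(L) {
    grid <- tlev[[L]]$grid
    idx <- expand.grid(x = 0:(grid[1] - 1), y = 0:(grid[2] - 1),
                       z = 0:(grid[3] - 1))
    one <- function(i) {
      b <- c(idx$x[i], idx$y[i], idx$z[i])
      arr <- transform_block(ds, tf, rb$offset, b, level = L,
                             target_dims = rb$dims,
                             interpolation = interpolation)
      write_block_tiff(arr, file.path(out_root, block_path(out_meta, L, b)),
                       meta$bit_depth)
      NULL
    }
    run_parallel(seq_len(nrow(idx)), one, workers)
    invisible(NULL)
  }
  if (levels_mode == "transform") {
    for (L in seq_along(tlev)) do_level(L)
  } else {
    do_level(1L)
    write_metadata(out_meta, file.path(out_root, paste0("dataset", META_SUFFIX)))
    subsample_levels_from_level1(out_root, out_meta, tlev, workers)
  }
  write_metadata(out_meta, file.path(out_root, paste0("dataset", META_SUFFIX)))
  invisible(out_meta)
}

# rebuild levels >= 2 by extracting level 1 as a temporary slice sequence and
# re-running the subsample + cuboid chain on it
subsample_levels_from_level1 <- function(out_root, out_meta, tlev, workers) {
  if (length(tlev) < 2L) return(invisible(NULL))
  ds1 <- open_dataset(out_root, cache_blocks = 2L * tlev[[1]]$grid[1] * tlev[[1]]$grid[2])
  dims <- tlev[[1]]$dims
  tmp <- tempfile("bv_l1_slices_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  files <- character(dims[3])
  for (z in seq_len(dims[3]) - 1L) {
    sl <- read_region(ds1, 1L, c(0, 0, z), c(dims[1], dims[2], 1))
    files[z + 1L] <- file.path(tmp, sprintf("slice_%06d.tif", z))
    write_slice_tiff(sl[, , 1], files[z + 1L], out_meta$bit_depth)
  }
  for (L in 2:length(tlev)) {
    sub <- tempfile(sprintf("bv_sub%d_", L))
    files <- subsample_slices(files, sub, out_meta$bit_depth, workers)
    process_level(files, tlev[[L]]$dims, L, out_meta, out_root, workers)
  }
  invisible(NULL)
}
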