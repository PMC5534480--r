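# The reformatter: turns a 2D slice sequence into the brick pyramid with a
# provable per-worker memory bound. Three stages per level:
#   1. subsampling   - level n slices -> level n+1 slices (two slices in
#                      memory at a time)
#   2. cuboid pass   - read one WIDTH x B x B stripe/slab buffer at a time
#   3. block split   - cut the cuboid into B^3 bricks along x and write them
# The cuboid is the whole working set: WIDTH x B x B voxels of the stored
# sample width, which for production B = 512 on a 19012-voxel-wide 8-bit
# volume is 4.64 GiB -- independent of volume height and depth.

# pairwise sum along rows (x): row i of output = rows 2i-1 (+ 2i if present)
pairsum_rows <- function(m) {
  X <- nrow(m)
  out <- m[seq(1, X, 2), , drop = FALSE]
  if (X > 1) {
    idx <- seq(2, X, 2)
    out[seq_along(idx), ] <- out[seq_along(idx), ] + m[idx, , drop = FALSE]
  }
  out
}

# in-plane 2x2 sum pooling (ceiling at odd edges)
pool2_sum <- function(m) t(pairsum_rows(t(pairsum_rows(m))))

#' Subsample a slice sequence by a factor of two per axis
#'
#' Merges slice pairs and pools 2x2 in plane: every output voxel is the
#' arithmetic mean of its (up to) 2 x 2 x 2 source voxels -- fewer at odd
#' edges, where the window is partial -- rounded half-up to the integer
#' sample type. Output dimensions are \code{ceiling(input / 2)} per axis.
#' Only two full slices are held in memory at a time per worker.
#'
#' @param files slice file paths at level n, in order.
#' @param out_dir directory for the level n+1 slice sequence.
#' @param bit_depth sample depth of the sequence.
#' @param workers parallel workers (unit of work: one output slice).
#' @return Character vector of output slice paths, in order.
#' @export
subsample_slices <- function(files, out_dir, bit_depth, workers = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nz_out <- ceiling(length(files) / 2)
  dims_xy <- dim(read_slice_tiff(files[1]))
  one <- function(zo) {
    i1 <- 2L * zo - 1L
    m1 <- read_slice_tiff(files[i1])
    if (!identical(dim(m1), dims_xy))
      stop_bv("bv_io_error", "slice shape mismatch at %s: got %s, expected %s",
              files[i1], paste(dim(m1), collapse = "x"),
              paste(dims_xy, collapse = "x"))
    s <- pool2_sum(m1 * 1.0)
    cnt <- pool2_sum(matrix(1.0, dims_xy[1], dims_xy[2]))
    if (i1 + 1L <= length(files)) {
      m2 <- read_slice_tiff(files[i1 + 1L])
      if (!identical(dim(m2), dims_xy))
        stop_bv("bv_io_error", "slice shape mismatch at %s", files[i1 + 1L])
      s <- s + pool2_sum(m2 * 1.0)
      cnt <- cnt * 2
    }
    out <- round_half_up(s / cnt)
    storage.mode(out) <- "integer"
    p <- file.path(out_dir, sprintf("slice_%06d.tif", zo - 1L))
    write_slice_tiff(out, p, bit_depth)
    p
  }
  unlist(run_parallel(seq_len(nz_out), one, workers))
}

#' Working-buffer size of the cuboid pass
#'
#' Payload bytes of one cuboid buffer: \code{width * B * B * bit_depth / 8}.
#' This is the reformatter's per-worker memory bound -- it depends only on
#' the volume width, never on height or depth.
#'
#' @param width level width in voxels (x axis).
#' @param block_size block edge B.
#' @param bit_depth 8 or 16.
#' @return Bytes (numeric).
#' @examples
#' cuboid_bytes(19012, 512, 8) / 2^30  # 4.64 GiB
#' @export
cuboid_bytes <- function(width, block_size = 512L, bit_depth = 8L) {
  as.numeric(width) * as.numeric(block_size)^2 * bytes_per_voxel(bit_depth)
}

#' Read one cuboid of a slice sequence
#'
#' A cuboid is the reformatter's working buffer: the full volume width, one
#' block-height stripe of y (\code{stripe_y}) and one block-depth slab of z
#' (\code{slab_z}). Voxels beyond the volume's y or z extent are zero-padded
#' so the buffer always has shape \code{width x B x B}.
#'
#' @param files slice file paths of the level, in order.
#' @param dims level voxel counts (x, y, z).
#' @param bit_depth sample depth.
#' @param stripe_y 0-based stripe index along y.
#' @param slab_z 0-based slab index along z.
#' @param block_size block edge B.
#' @return An object of class \code{brick_cuboid}: \code{stripe_y},
#'   \code{slab_z} and the \code{voxels} buffer.
#' @export
read_cuboid <- function(files, dims, bit_depth, stripe_y, slab_z,
                        block_size = 512L) {
  dims <- check_dims(dims)
  B <- check_block_size(block_size)
  grid <- ceiling(dims / B)
  if (stripe_y < 0 || stripe_y >= grid[2] || slab_z < 0 || slab_z >= grid[3])
    stop_bv("bv_range_error", "stripe_y/slab_z (%d,%d) outside grid (%d,%d)",
            stripe_y, slab_z, grid[2], grid[3])
  buf <- array(0L, dim = c(dims[1], B, B))
  ys <- (stripe_y * B):(min((stripe_y + 1) * B, dims[2]) - 1)
  for (dz in 0:(B - 1L)) {
    gz <- slab_z * B + dz
    if (gz >= dims[3]) break
    m <- read_slice_tiff(files[gz + 1L])
    if (!identical(as.numeric(dim(m)), dims[1:2]))
      stop_bv("bv_io_error",
              "slice %d (%s) has shape %s, expected %s", gz, files[gz + 1L],
              paste(dim(m), collapse = "x"), paste(dims[1:2], collapse = "x"))
    buf[, seq_along(ys), dz + 1L] <- m[, ys + 1L]
  }
  structure(list(stripe_y = as.integer(stripe_y), slab_z = as.integer(slab_z),
                 bit_depth = as.integer(bit_depth), voxels = buf),
            class = "brick_cuboid")
}

#' Split a cuboid into blocks along x
#'
#' Cuts the \code{width x B x B} buffer into \code{ceiling(width / B)} cubic
#' blocks; the last block is zero-padded where the width is not a multiple of
#' B. Concatenating the unpadded parts reproduces the cuboid exactly and no
#' voxel lands in two blocks.
#'
#' @param cuboid a [read_cuboid()] result.
#' @param block_size block edge B.
#' @return List of blocks, each with \code{index} (0-based bx, by, bz) and
#'   \code{voxels} (a B^3 array).
#' @export
split_cuboid <- function(cuboid, block_size = 512L) {
  B <- check_block_size(block_size)
  width <- dim(cuboid$voxels)[1]
  stopifnot(identical(dim(cuboid$voxels)[2:3], c(B, B)))
  lapply(seq_len(ceiling(width / B)) - 1L, function(bx) {
    xs <- (bx * B):(min((bx + 1) * B, width) - 1)
    vox <- array(0L, dim = c(B, B, B))
    vox[seq_along(xs), , ] <- cuboid$voxels[xs + 1L, , ]
    list(index = c(bx, cuboid$stripe_y, cuboid$slab_z), voxels = vox)
  })
}

run_parallel <- function(items, fn, workers) {
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(items, fn, mc.cores = workers)
  } else {
    lapply(items, fn)
  }
  bad <- vapply(res, inherits, logical(1), "try-error")
  if (any(bad))
    stop_bv("bv_io_error", "worker failed: %s",
            conditionMessage(attr(res[[which(bad)[1]]], "condition")))
  res
}

# cuboid pass for one level: every (stripe, slab) pair is one unit of work;
# each source voxel of the level is copied into exactly one cuboid
process_level <- function(files, ldims, level, meta, out_root, workers) {
  B <- meta$block_size
  grid <- ceiling(ldims / B)
  tasks <- expand.grid(y = 0:(grid[2] - 1), z = 0:(grid[3] - 1))
  one <- function(i) {
    cub <- read_cuboid(files, ldims, meta$bit_depth, tasks$y[i], tasks$z[i], B)
    for (blk in split_cuboid(cub, B)) {
      write_block_tiff(blk$voxels,
                       file.path(out_root, block_path(meta, level, blk$index)),
                       meta$bit_depth)
    }
    ylen <- min((tasks$y[i] + 1) * B, ldims[2]) - tasks$y[i] * B
    zlen <- min((tasks$z[i] + 1) * B, ldims[3]) - tasks$z[i] * B
    c(buffer_bytes = prod(dim(cub$voxels)) * bytes_per_voxel(meta$bit_depth),
      ingested = ldims[1] * ylen * zlen)
  }
  res <- run_parallel(seq_len(nrow(tasks)), one, workers)
  list(peak_buffer_bytes = max(vapply(res, `[[`, 0, "buffer_bytes")),
       voxels_ingested = sum(vapply(res, `[[`, 0, "ingested")),
       n_blocks = prod(grid))
}

#' Reformat a slice sequence into a brick-pyramid dataset
#'
#' Runs the full conversion: the slice sequence is recursively subsampled to
#' build the pyramid levels (see [subsample_slices()]), and every level is
#' then read cuboid by cuboid and cut into blocks (see [read_cuboid()],
#' [split_cuboid()]). Each level's slices are read twice: once by the cuboid
#' pass and once by the subsampler that produces the next level. PNG input
#' slices are converted to TIFF first. Output block files are byte-identical
#' for any worker count.
#'
#' @param input slice sequence: a directory, glob pattern, or file vector
#'   (see [list_slices()]).
#' @param out_root output dataset directory.
#' @param resolution micrometres per voxel at level 1 (length 3).
#' @param block_size block edge B (production default 512).
#' @param workers parallel workers; the memory bound scales with this.
#' @param force overwrite an existing non-empty \code{out_root}.
#' @return The dataset [brick_meta()], invisibly, with attribute
#'   \code{"stats"}: per-level peak cuboid buffer payload bytes, voxels
#'   ingested, and block counts.
#' @examples
#' \donttest{
#' src <- file.path(tempdir(), "phantom_src")
#' generate_phantom(src, n = 16, tile = 8, phase_period = 8, seed = 1,
#'                  force = TRUE)
#' ds <- reformat(src, file.path(tempdir(), "phantom_ds"), block_size = 8,
#'                force = TRUE)
#' }
#' @export
reformat <- function(input, out_root, resolution = c(1, 1, 1),
                     block_size = 512L, workers = 1L, force = FALSE) {
  files <- list_slices(input)
  files <- files[!grepl("manifest\\.json$", files)]
  if (any(grepl("\\.png$", files, ignore.case = TRUE))) {
    depth_guess <- if (any(grepl("\\.tiff?$", files, ignore.case = TRUE)))
      slice_bit_depth(grep("\\.tiff?$", files, ignore.case = TRUE, value = TRUE)[1])
    else 8L
    files <- convert_slices_to_tiff(files, tempfile("bv_png2tif_"), depth_guess)
  }
  bit_depth <- slice_bit_depth(files[1])
  dims_xy <- dim(read_slice_tiff(files[1]))
  dims <- c(dims_xy, length(files))
  meta <- brick_meta(dims, resolution, bit_depth, block_size,
                     storage_root = ".")
  check_output_dir(out_root, force)
  levels <- pyramid_levels(dims, meta$block_size)
  stats <- list(levels = list(), peak_buffer_bytes = 0)
  tmp_dirs <- character(0)
  on.exit(unlink(tmp_dirs, recursive = TRUE), add = TRUE)
  for (L in seq_along(levels)) {
    st <- process_level(files, levels[[L]]$dims, L, meta, out_root, workers)
    stats$levels[[L]] <- st
    stats$peak_buffer_bytes <- max(stats$peak_buffer_bytes, st$peak_buffer_bytes)
    if (L < length(levels)) {
      tmp <- tempfile(sprintf("bv_level%d_", L + 1L))
      tmp_dirs <- c(tmp_dirs, tmp)
      files <- subsample_slices(files, tmp, bit_depth, workers)
    }
  }
  stats$total_blocks <- sum(vapply(stats$levels, `[[`, 0, "n_blocks"))
  write_metadata(meta, file.path(out_root, paste0("dataset", META_SUFFIX)))
  attr(meta, "stats") <- stats
  invisible(meta)
}
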