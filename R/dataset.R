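#' Open a brick-pyramid dataset for reading
#'
#' Locates and validates the dataset descriptor under \code{root} and returns
#' a handle that carries the block cache and IO counters used by all read
#' operations. The cache (see [block_cache()]) makes repeated and overlapping
#' ROI reads cheap without changing any result.
#'
#' @param root dataset directory (the one containing the \code{.bvol.json}
#'   descriptor).
#' @param cache_blocks cache capacity in blocks; 0 disables caching.
#' @return An object of class \code{brick_dataset}.
#' @export
open_dataset <- function(root, cache_blocks = 512L) {
  meta <- read_metadata(find_metadata(root))
  ds <- new.env(parent = emptyenv())
  ds$root <- root
  ds$meta <- meta
  ds$levels <- pyramid_levels(meta$dims, meta$block_size)
  ds$cache <- block_cache(cache_blocks)
  ds$storage_reads <- 0L
  ds$cache_hits <- 0L
  class(ds) <- "brick_dataset"
  ds
}

#' @export
print.brick_dataset <- function(x, ...) {
  print(x$meta)
  for (lg in x$levels)
    cat(sprintf("  level %d: %s voxels, %s blocks (%d files)\n", lg$level,
                paste(lg$dims, collapse = "x"), paste(lg$grid, collapse = "x"),
                prod(lg$grid)))
  cat(sprintf("  io: %d storage reads, %d cache hits\n",
              x$storage_reads, x$cache_hits))
  invisible(x)
}

#' IO counters of a dataset handle
#'
#' Every block fetched from storage and every block served from the cache is
#' counted on the handle; tests and benchmarks use these to assert access
#' patterns (e.g. that a repeated ROI read performs zero storage reads).
#'
#' @param ds a [open_dataset()] handle.
#' @return \code{io_counters}: list with \code{storage_reads} and
#'   \code{cache_hits}.
#' @export
io_counters <- function(ds) {
  list(storage_reads = ds$storage_reads, cache_hits = ds$cache_hits)
}

#' @rdname io_counters
#' @export
reset_io_counters <- function(ds) {
  ds$storage_reads <- 0L
  ds$cache_hits <- 0L
  invisible(ds)
}

block_key <- function(level, b) sprintf("%d_%d_%d_%d", level, b[1], b[2], b[3])

# cache-first block fetch; the single place storage reads happen
fetch_block <- function(ds, level, b) {
  key <- block_key(level, b)
  hit <- cache_get(ds$cache, key)
  if (!is.null(hit)) {
    ds$cache_hits <- ds$cache_hits + 1L
    return(hit)
  }
  vox <- read_block_tiff(file.path(ds$root, block_path(ds$meta, level, b)))
  ds$storage_reads <- ds$storage_reads + 1L
  cache_put(ds$cache, key, vox)
  vox
}

#' Visit every block of a level sequentially
#'
#' Calls \code{visitor(voxels, index)} exactly once per block of the level.
#' With \code{workers = 1} blocks are visited in deterministic z-, then y-,
#' then x-major order; with more workers the order is unspecified but the
#' visited set is identical. Sequential reads bypass the cache (each block is
#' touched exactly once, so caching would only evict useful entries).
#'
#' @param ds a [open_dataset()] handle.
#' @param level pyramid level to iterate.
#' @param visitor \code{function(voxels, index)}; \code{index} is a list with
#'   \code{level} and 0-based \code{b}.
#' @param workers parallel workers.
#' @return The visit count (the level's block count), with the visitors'
#'   return values in attribute \code{"results"}.
#' @export
sequential_read <- function(ds, level, visitor, workers = 1L) {
  if (level < 1L || level > length(ds$levels))
    stop_bv("bv_range_error", "level %d out of range [1, %d]",
            level, length(ds$levels))
  grid <- ds$levels[[level]]$grid
  idx <- expand.grid(x = 0:(grid[1] - 1), y = 0:(grid[2] - 1),
                     z = 0:(grid[3] - 1))   # x fastest => z,y,x loop order
  one <- function(i) {
    b <- c(idx$x[i], idx$y[i], idx$z[i])
    vox <- read_block_tiff(file.path(ds$root, block_path(ds$meta, level, b)))
    visitor(vox, list(level = level, b = b))
  }
  results <- run_parallel(seq_len(nrow(idx)), one, workers)
  structure(nrow(idx), results = results)
}

#' Automatic pyramid-level selection for an ROI
#'
#' Returns the finest level whose scaled ROI stays within a voxel budget: at
#' level L every axis shrinks by \code{2^(L-1)}, so the voxel count shrinks
#' by \code{8^(L-1)}. Larger ROIs therefore map to coarser levels; an ROI
#' already under budget is served at full resolution. The default budget is
#' one block's worth of voxels (\code{B^3}).
#'
#' @param meta a [brick_meta()].
#' @param roi_size ROI voxel counts at level 1 (length 3).
#' @param budget maximum number of output voxels.
#' @return The selected level (clamped to the available levels).
#' @export
select_level <- function(meta, roi_size, budget = NULL) {
  budget <- budget %||% as.numeric(meta$block_size)^3
  if (budget < 1) stop_bv("bv_usage_error", "budget must be >= 1")
  for (L in seq_len(meta$n_levels)) {
    if (prod(ceiling(roi_size / 2^(L - 1))) <= budget) return(L)
  }
  meta$n_levels
}

# read an axis-aligned region given in *level-L* voxel coordinates, assembling
# the overlapped blocks (cache-first) and cropping: the read-crop strategy
read_region <- function(ds, level, origin, size) {
  B <- ds$meta$block_size
  padded <- ds$levels[[level]]$grid * B
  if (any(origin < 0) || any(size < 1) || any(origin + size > padded))
    stop_bv("bv_range_error",
            "region origin (%s) + size (%s) outside padded level-%d extent (%s)",
            paste(origin, collapse = ","), paste(size, collapse = ","),
            level, paste(padded, collapse = ","))
  out <- array(0L, dim = size)
  b0 <- floor(origin / B)
  b1 <- floor((origin + size - 1) / B)
  for (bz in b0[3]:b1[3]) for (by in b0[2]:b1[2]) for (bx in b0[1]:b1[1]) {
    b <- c(bx, by, bz)
    vox <- fetch_block(ds, level, b)
    g0 <- pmax(origin, b * B)              # overlap in level coords
    g1 <- pmin(origin + size, (b + 1) * B)
    li <- (g0[1]:(g1[1] - 1)) - bx * B + 1L
    lj <- (g0[2]:(g1[2] - 1)) - by * B + 1L
    lk <- (g0[3]:(g1[3] - 1)) - bz * B + 1L
    out[(g0[1]:(g1[1] - 1)) - origin[1] + 1L,
        (g0[2]:(g1[2] - 1)) - origin[2] + 1L,
        (g0[3]:(g1[3] - 1)) - origin[3] + 1L] <- vox[li, lj, lk]
  }
  out
}

#' Read a region of interest
#'
#' The random-access read path: the ROI is given in level-1 voxel
#' coordinates; the serving level is chosen automatically (see
#' [select_level()]) or forced with \code{level}; the blocks overlapping the
#' scaled ROI are fetched cache-first, assembled by position, and cropped.
#' ROI coordinates map to level L with \code{floor(origin / 2^(L-1))} and
#' \code{ceiling(size / 2^(L-1))}. Requests beyond the padded level-1 extent
#' error rather than zero-fill; padding voxels inside boundary blocks read
#' as 0.
#'
#' @param ds a [open_dataset()] handle.
#' @param origin ROI origin, level-1 voxel coordinates (0-based, length 3).
#' @param size ROI voxel counts at level 1 (length 3).
#' @param level serving level, or \code{"auto"}.
#' @param budget voxel budget for automatic level selection.
#' @return Object of class \code{brick_roi}: \code{voxels} (a 3D integer
#'   array at the realized level), \code{level}, \code{origin} (level-L
#'   coords) and \code{resolution} (um per voxel at that level).
#' @export
read_roi <- function(ds, origin, size, level = "auto", budget = NULL) {
  meta <- ds$meta
  origin <- as.numeric(origin); size <- as.numeric(size)
  if (length(origin) != 3L || length(size) != 3L || any(size < 1))
    stop_bv("bv_usage_error", "origin and size must be length-3, size >= 1")
  padded1 <- ds$levels[[1]]$grid * meta$block_size
  if (any(origin < 0) || any(origin + size > padded1))
    stop_bv("bv_range_error",
            "ROI origin (%s) + size (%s) outside padded extent (%s)",
            paste(origin, collapse = ","), paste(size, collapse = ","),
            paste(padded1, collapse = ","))
  L <- if (identical(level, "auto")) select_level(meta, size, budget)
       else {
         level <- as.integer(level)
         if (is.na(level) || level < 1L || level > meta$n_levels)
           stop_bv("bv_range_error", "level %s out of range [1, %d]",
                   as.character(level), meta$n_levels)
         level
       }
  sc <- 2^(L - 1)
  o_L <- floor(origin / sc)
  s_L <- ceiling(size / sc)
  structure(list(voxels = read_region(ds, L, o_L, s_L),
                 level = L, origin = o_L, resolution = meta$resolution * sc),
            class = "brick_roi")
}

#' @export
print.brick_roi <- function(x, ...) {
  cat(sprintf("ROI read at level %d: %s voxels at %s um/voxel, origin (%s)\n",
              x$level, paste(dim(x$voxels), collapse = "x"),
              paste(x$resolution, collapse = "x"),
              paste(x$origin, collapse = ",")))
  invisible(x)
}
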