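#' Dataset metadata for a brick-pyramid volume
#'
#' A brick-pyramid dataset stores a single 3D grayscale volume as a
#' multi-resolution pyramid of fixed-size cubic blocks ("bricks"). Level 1 is
#' full resolution; every further level halves all three axes (ceiling) until
#' all axes are smaller than the block edge. The metadata descriptor records
#' everything needed to address and interpret the blocks: the level-1 voxel
#' counts, the physical voxel size, the sample bit depth, the block edge, the
#' number of pyramid levels, the block container format and the storage root.
#'
#' @param dims integer vector of length 3: level-1 voxel counts (x = width,
#'   y = height, z = number of slices).
#' @param resolution numeric vector of length 3: micrometres per voxel at
#'   level 1, per axis.
#' @param bit_depth 8 or 16 (grayscale sample depth).
#' @param block_size block edge length in voxels; a power of two >= 8.
#'   The production default is 512; tests use small values such as 32.
#' @param file_format block container name; only \code{"tiff"} is supported.
#' @param storage_root dataset directory the block tree lives under (stored
#'   verbatim; [open_dataset()] always uses the actual location on disk).
#' @return An object of class \code{brick_meta}.
#' @examples
#' m <- brick_meta(c(1000, 1000, 1000), c(0.5, 0.5, 0.5), bit_depth = 8)
#' m$n_levels
#' @export
brick_meta <- function(dims, resolution, bit_depth, block_size = 512L,
                       file_format = "tiff", storage_root = ".") {
  dims <- check_dims(dims)
  if (length(resolution) != 3L || anyNA(resolution) || any(resolution <= 0))
    stop_bv("bv_metadata_error", "resolution must be three positive values (um/voxel)")
  if (!bit_depth %in% c(8L, 16L))
    stop_bv("bv_metadata_error", "bit_depth must be 8 or 16, got %s",
            as.character(bit_depth))
  block_size <- check_block_size(block_size)
  if (!identical(file_format, "tiff"))
    stop_bv("bv_metadata_error", "file_format must be \"tiff\", got %s", file_format)
  levels <- pyramid_levels(dims, block_size)
  structure(list(
    dims = dims,
    resolution = as.numeric(resolution),
    bit_depth = as.integer(bit_depth),
    block_size = block_size,
    n_levels = length(levels),
    file_format = file_format,
    storage_root = storage_root
  ), class = "brick_meta")
}

#' @export
print.brick_meta <- function(x, ...) {
  cat("brick-pyramid dataset metadata\n")
  cat(sprintf("  dims (x,y,z):   %s voxels\n", paste(x$dims, collapse = " x ")))
  cat(sprintf("  resolution:     %s um/voxel\n", paste(x$resolution, collapse = " x ")))
  cat(sprintf("  bit depth:      %d\n", x$bit_depth))
  cat(sprintf("  block size:     %d\n", x$block_size))
  cat(sprintf("  levels:         %d\n", x$n_levels))
  cat(sprintf("  storage root:   %s\n", x$storage_root))
  invisible(x)
}

#' Compute the pyramid level geometries for a volume
#'
#' Level 1 has the input dimensions; each further level halves every axis with
#' ceiling (so no voxel is ever dropped). Subsampling stops once all three
#' axes are strictly smaller than the block edge, which guarantees the top
#' level fits in a single block. A volume already smaller than the block edge
#' on all axes has exactly one level.
#'
#' @param dims level-1 voxel counts (length 3).
#' @param block_size block edge length.
#' @return A list of level geometries, each a list with elements
#'   \code{level}, \code{dims} and \code{grid} (block counts per axis).
#' @examples
#' length(pyramid_levels(c(19012, 19012, 19012), 512))  # 7 levels
#' @export
pyramid_levels <- function(dims, block_size = 512L) {
  dims <- check_dims(dims)
  block_size <- check_block_size(block_size)
  out <- list()
  d <- dims
  repeat {
    out[[length(out) + 1L]] <- list(
      level = length(out) + 1L,
      dims = d,
      grid = ceiling(d / block_size)
    )
    if (all(d < block_size)) break
    d <- ceiling(d / 2)
  }
  out
}

#' Block grid of a level
#'
#' Number of blocks per axis needed to tile a level: \code{ceiling(dims / B)}.
#' The product is the number of block files of that level.
#'
#' @param dims voxel counts of the level.
#' @param block_size block edge length.
#' @return Integer vector of length 3 (blocks along x, y, z).
#' @examples
#' block_grid(c(1000, 1000, 1000), 512)  # 2 2 2 -> 8 blocks
#' block_grid(c(1414, 1414, 1000), 512)  # 3 3 2 -> 18 blocks
#' @export
block_grid <- function(dims, block_size = 512L) {
  dims <- check_dims(dims)
  as.integer(ceiling(dims / check_block_size(block_size)))
}

level_dims <- function(meta, level) {
  levels <- pyramid_levels(meta$dims, meta$block_size)
  if (level < 1L || level > length(levels))
    stop_bv("bv_range_error", "level %d out of range [1, %d]", level, length(levels))
  levels[[level]]$dims
}

#' On-disk path of a block
#'
#' Blocks are laid out in a four-level directory hierarchy below the storage
#' root, \code{level_<L>/z<bz>/y<by>/<bx>_<by>_<bz>.tif}, so that directory
#' fan-out stays bounded for very large grids while the file name alone
#' encodes the block position: block \code{2_3_4} starts at voxel
#' \code{(2 B, 3 B, 4 B)} of its level. [parse_block_path()] inverts the
#' mapping exactly.
#'
#' @param meta a [brick_meta()] object (used for range checking).
#' @param level pyramid level (1-based).
#' @param b integer vector of length 3: 0-based block coordinates (bx, by, bz).
#' @return Relative path string.
#' @examples
#' m <- brick_meta(c(4000, 4000, 4000), c(1, 1, 1), 8)
#' block_path(m, 1, c(2, 3, 4))  # "level_1/z4/y3/2_3_4.tif"
#' @export
block_path <- function(meta, level, b) {
  levels <- pyramid_levels(meta$dims, meta$block_size)
  if (level < 1L || level > length(levels))
    stop_bv("bv_range_error", "level %d out of range [1, %d]", level, length(levels))
  grid <- levels[[level]]$grid
  if (length(b) != 3L || any(b < 0) || any(b >= grid) || any(b != floor(b)))
    stop_bv("bv_range_error",
            "block index (%s) outside grid (%s) at level %d",
            paste(b, collapse = ","), paste(grid, collapse = ","), level)
  sprintf("level_%d/z%d/y%d/%d_%d_%d.tif", level, b[3], b[2], b[1], b[2], b[3])
}

#' @rdname block_path
#' @param path a relative block path produced by [block_path()].
#' @return For \code{parse_block_path}: a list with \code{level} and \code{b}.
#' @export
parse_block_path <- function(path) {
  m <- regmatches(path, regexec(
    "^level_([0-9]+)/z([0-9]+)/y([0-9]+)/([0-9]+)_([0-9]+)_([0-9]+)\\.tif$", path))[[1]]
  if (length(m) != 7L)
    stop_bv("bv_io_error", "not a block path: %s", path)
  v <- as.integer(m[-1])
  if (v[2] != v[6] || v[3] != v[5])
    stop_bv("bv_io_error", "inconsistent block path (folder/name mismatch): %s", path)
  list(level = v[1], b = c(v[4], v[5], v[6]))
}

# --- metadata serialization -------------------------------------------------

META_SUFFIX <- ".bvol.json"

# the mandatory descriptor fields: volume size, physical resolution, container
# format, sample depth, pyramid depth, block edge, storage location
META_FIELDS <- c("dims", "resolution", "bit_depth", "block_size",
                 "n_levels", "file_format", "storage_root")

#' Read and write the dataset descriptor
#'
#' The descriptor is a small JSON file (suffix \code{.bvol.json}) holding the
#' mandatory fields of [brick_meta()]. Reading validates every field and
#' errors with the name of the offending key; unknown keys are ignored with a
#' warning, so future descriptors remain readable.
#'
#' @param meta a [brick_meta()] object.
#' @param path file path to write to / read from.
#' @return \code{read_metadata} returns a [brick_meta()]; \code{write_metadata}
#'   returns \code{path} invisibly.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "brick_meta"))
  payload <- unclass(meta)
  payload$format_name <- "brickvol"
  payload$format_version <- 1L
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    stop_bv("bv_io_error", "metadata file not found: %s", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_bv("bv_metadata_error", "unparsable metadata file %s: %s",
                            path, conditionMessage(e)))
  known <- c(META_FIELDS, "format_name", "format_version")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning(sprintf("ignoring unknown metadata keys: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  for (f in META_FIELDS)
    if (is.null(raw[[f]]))
      stop_bv("bv_metadata_error", "metadata file %s is missing mandatory field: %s",
              path, f)
  meta <- brick_meta(dims = raw$dims, resolution = raw$resolution,
                     bit_depth = raw$bit_depth, block_size = raw$block_size,
                     file_format = raw$file_format, storage_root = raw$storage_root)
  if (!identical(meta$n_levels, as.integer(raw$n_levels)))
    stop_bv("bv_metadata_error",
            "metadata file %s: stored n_levels (%s) inconsistent with dims/block_size (expect %d)",
            path, as.character(raw$n_levels), meta$n_levels)
  meta
}

find_metadata <- function(root) {
  hits <- list.files(root, pattern = paste0("\\Q", META_SUFFIX, "\\E$"),
                     full.names = TRUE)
  if (length(hits) == 0L)
    stop_bv("bv_io_error", "no %s descriptor found in %s", META_SUFFIX, root)
  if (length(hits) > 1L)
    stop_bv("bv_io_error", "multiple descriptors found in %s", root)
  hits
}
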