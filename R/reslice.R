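#' Re-slice a dataset along an orthogonal plane
#'
#' Extracts a single plane, or a maximum-intensity projection (MIP) over a
#' slab of given thickness, orthogonal to one of the three anatomical axes.
#' The convention used here: \code{"horizontal"} planes are orthogonal to z
#' (the slice axis), \code{"coronal"} planes orthogonal to y, and
#' \code{"sagittal"} planes orthogonal to x. Position and thickness are given
#' in micrometres and converted with the dataset's per-axis resolution.
#'
#' @param ds a [open_dataset()] handle.
#' @param plane \code{"horizontal"}, \code{"coronal"} or \code{"sagittal"}.
#' @param position_um slab start position along the plane's axis, um.
#' @param thickness_um slab thickness, um; at most one voxel is used in
#'   \code{"single"} mode.
#' @param mode \code{"single"} (one plane) or \code{"mip"} (voxelwise
#'   maximum over the slab).
#' @param level pyramid level to read from (default 1, full resolution).
#' @return A 2D integer matrix with attributes \code{plane},
#'   \code{position_um}, \code{thickness_um}, \code{pixel_size_um} (the two
#'   in-plane voxel sizes at the realized level) and \code{level}.
#' @export
reslice <- function(ds, plane = c("horizontal", "coronal", "sagittal"),
                    position_um, thickness_um = 0,
                    mode = c("single", "mip"), level = 1L) {
  plane <- match.arg(plane)
  mode <- match.arg(mode)
  if (thickness_um < 0)
    stop_bv("bv_usage_error", "thickness_um must be >= 0")
  meta <- ds$meta
  axis <- switch(plane, sagittal = 1L, coronal = 2L, horizontal = 3L)
  res_axis <- meta$resolution[axis]
  pos_vox <- floor(position_um / res_axis)
  if (pos_vox < 0 || pos_vox >= meta$dims[axis])
    stop_bv("bv_range_error",
            "position %g um (voxel %d) outside axis extent [0, %d)",
            position_um, pos_vox, meta$dims[axis])
  t_vox <- if (mode == "single") 1
           else max(1, round_half_up(thickness_um / res_axis))
  t_vox <- min(t_vox, meta$dims[axis] - pos_vox)
  origin <- c(0, 0, 0)
  size <- meta$dims
  origin[axis] <- pos_vox
  size[axis] <- t_vox
  roi <- read_roi(ds, origin, size, level = level)
  img <- apply(roi$voxels, setdiff(1:3, axis), max)
  storage.mode(img) <- "integer"
  structure(img,
            plane = plane, position_um = position_um,
            thickness_um = thickness_um,
            pixel_size_um = roi$resolution[setdiff(1:3, axis)],
            level = roi$level)
}

#' Write a re-slice to a single-page TIFF
#'
#' The pixel payload goes into an uncompressed grayscale TIFF; the physical
#' pixel size and slab parameters are recorded in a JSON sidecar next to it
#' (\code{<name>.json}).
#'
#' @param img a [reslice()] result.
#' @param path output TIFF path.
#' @param bit_depth sample depth to write (default: smallest that fits).
#' @return \code{path}, invisibly.
#' @export
write_reslice <- function(img, path, bit_depth = NULL) {
  bit_depth <- bit_depth %||% (if (max(img) > 255) 16L else 8L)
  write_slice_tiff(img, path, bit_depth)
  side <- list(pixel_size_um = attr(img, "pixel_size_um"),
               plane = attr(img, "plane"),
               position_um = attr(img, "position_um"),
               thickness_um = attr(img, "thickness_um"),
               level = attr(img, "level"))
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
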