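# TIFF container IO. All in-memory arrays use axis order (x, y, z) with x
# fastest; TIFF pages are stored row-major (y rows, x columns), so every
# read/write transposes. Samples are kept as R integers; files store
# unsigned 8- or 16-bit grayscale, uncompressed, so block IO is bit-exact.

write_slice_tiff <- function(mat_xy, path, bit_depth) {
  maxv <- max_intensity(bit_depth)
  ok <- try(tiff::writeTIFF(t(mat_xy) / maxv, path,
                            bits.per.sample = as.integer(bit_depth),
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_bv("bv_io_error", "failed to write TIFF %s", path)
  invisible(path)
}

read_slice_tiff <- function(path) {
  if (!file.exists(path))
    stop_bv("bv_io_error", "slice file not found: %s", path)
  img <- try(suppressWarnings(tiff::readTIFF(path, as.is = TRUE)), silent = TRUE)
  if (inherits(img, "try-error"))
    stop_bv("bv_io_error", "failed to read TIFF %s", path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # tolerate stray extra channels
  storage.mode(img) <- "integer"
  t(img)
}

slice_bit_depth <- function(path) {
  info <- try(suppressWarnings(tiff::readTIFF(path, payload = FALSE)), silent = TRUE)
  if (inherits(info, "try-error") || is.null(info[["bits.per.sample"]]))
    stop_bv("bv_io_error", "cannot determine bit depth of %s", path)
  as.integer(info[["bits.per.sample"]][1])
}

# block container: one multi-page TIFF, B pages (z) of B x B (y rows, x cols)
write_block_tiff <- function(arr_xyz, path, bit_depth) {
  maxv <- max_intensity(bit_depth)
  pages <- lapply(seq_len(dim(arr_xyz)[3]), function(z) t(arr_xyz[, , z]) / maxv)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bit_depth),
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_bv("bv_io_error", "failed to write block %s", path)
  invisible(path)
}

read_block_tiff <- function(path) {
  if (!file.exists(path))
    stop_bv("bv_integrity_error", "missing block file: %s", path)
  pages <- try(suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE)),
               silent = TRUE)
  if (inherits(pages, "try-error"))
    stop_bv("bv_integrity_error", "unreadable block file: %s", path)
  b <- ncol(pages[[1]])
  arr <- array(0L, dim = c(b, nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    storage.mode(p) <- "integer"
    arr[, , z] <- t(p)
  }
  arr
}

# natural sort: order by the last run of digits in the file name, then
# lexicographically, so slice_2 < slice_10 regardless of zero padding
natural_sort <- function(paths) {
  base <- basename(paths)
  num <- suppressWarnings(as.numeric(sub(".*?([0-9]+)[^0-9]*$", "\\1", base)))
  num[is.na(num)] <- Inf
  paths[order(num, base)]
}

#' List the slice files of a 2D image sequence
#'
#' Accepts a directory (all \code{.tif/.tiff/.png} files in it) or a glob
#' pattern, and returns the files in natural sort order (numeric suffixes
#' compare as numbers).
#'
#' @param input directory path or glob pattern.
#' @return Character vector of file paths.
#' @export
list_slices <- function(input) {
  if (length(input) > 1L) return(natural_sort(input))
  if (dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
  } else if (grepl("[*?]", input)) {
    files <- Sys.glob(input)
  } else if (file.exists(input)) {
    files <- input
  } else {
    stop_bv("bv_io_error", "input not found: %s", input)
  }
  if (length(files) == 0L)
    stop_bv("bv_io_error", "no slice files found under %s", input)
  natural_sort(files)
}

# non-TIFF slices (PNG) are converted to a temporary TIFF sequence before
# reformatting so the cuboid pass only ever deals with one container
convert_slices_to_tiff <- function(files, tmp_dir, bit_depth) {
  dir.create(tmp_dir, recursive = TRUE, showWarnings = FALSE)
  maxv <- max_intensity(bit_depth)
  out <- character(length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop_bv("bv_io_error", "png package required to convert %s", f)
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      mat <- t(round_half_up(img * maxv))
      storage.mode(mat) <- "integer"
      out[i] <- file.path(tmp_dir, sprintf("slice_%06d.tif", i - 1L))
      write_slice_tiff(mat, out[i], bit_depth)
    } else {
      out[i] <- f
    }
  }
  out
}
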