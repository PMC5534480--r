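#' Generate a 3D chessboard phantom slice sequence
#'
#' The standard benchmark input for this package: an \code{n x n x n} voxel
#' volume written as \code{n} numbered grayscale TIFF slices. Each slice is a
#' black/white chessboard of \code{tile x tile} pixel squares, and the whole
#' pattern inverts every \code{phase_period} slices, so every axis carries
#' structure. White squares are at the dtype maximum, black at 0; zero-mean
#' Gaussian noise with standard deviation \code{noise_fraction} of the
#' dynamic range is added and clipped to the dtype range (this emulates
#' camera noise and keeps the slices from compressing unrealistically well).
#' Slices are generated streaming, so memory use is O(n^2) whatever n is.
#'
#' Voxel (x, y, z) is white iff
#' \code{floor(x/tile) + floor(y/tile) + floor(z/phase_period)} is even.
#'
#' @param out_dir output directory for the slice sequence (created).
#' @param n edge length in voxels.
#' @param tile in-plane tile edge in pixels (default 256).
#' @param phase_period slices per phase flip (default 256).
#' @param noise_fraction Gaussian noise sigma as a fraction of the dynamic
#'   range, in [0, 1) (default 0.05).
#' @param bit_depth 8 or 16.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @param force overwrite an existing non-empty \code{out_dir}.
#' @return Invisibly, the manifest (also written as \code{manifest.json}):
#'   the generation parameters, the noise convention, and an MD5 checksum per
#'   slice.
#' @examples
#' d <- file.path(tempdir(), "phantom_example")
#' man <- generate_phantom(d, n = 16, tile = 8, phase_period = 8, seed = 1)
#' length(man$slices)
#' @export
generate_phantom <- function(out_dir, n, tile = 256L, phase_period = 256L,
                             noise_fraction = 0.05, bit_depth = 8L, seed = 1L,
                             force = FALSE) {
  if (n < 1 || tile < 1 || phase_period < 1)
    stop_bv("bv_geometry_error", "n, tile and phase_period must be >= 1")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop_bv("bv_usage_error", "noise_fraction must be in [0, 1)")
  if (!bit_depth %in% c(8L, 16L))
    stop_bv("bv_usage_error", "bit_depth must be 8 or 16")
  check_output_dir(out_dir, force)
  required <- edge_to_size(n, bit_depth)
  refuse_if_disk_short(out_dir, required)

  maxv <- max_intensity(bit_depth)
  xpar <- floor((seq_len(n) - 1) / tile)
  plane_parity <- outer(xpar, xpar, `+`)  # in-plane tile parity, n x n
  set.seed(as.integer(seed))
  files <- character(n)
  sums <- 0
  for (z in seq_len(n) - 1L) {
    parity <- (plane_parity + floor(z / phase_period)) %% 2
    base <- ifelse(parity == 0, maxv, 0)
    if (noise_fraction > 0) {
      vals <- base + matrix(stats::rnorm(n * n, 0, noise_fraction * maxv), n, n)
      vals <- clamp(round_half_up(vals), 0, maxv)
    } else {
      vals <- base
    }
    storage.mode(vals) <- "integer"
    files[z + 1L] <- file.path(out_dir, sprintf("slice_%06d.tif", z))
    write_slice_tiff(vals, files[z + 1L], bit_depth)
    sums <- sums + sum(as.numeric(vals))
  }
  checksums <- as.character(tools::md5sum(files))
  manifest <- list(
    generator = "3D chessboard phantom",
    n = as.integer(n), tile = as.integer(tile),
    phase_period = as.integer(phase_period),
    noise_fraction = noise_fraction, bit_depth = as.integer(bit_depth),
    seed = as.integer(seed),
    noise_convention = "additive zero-mean Gaussian, sigma = noise_fraction * dtype max, clipped to [0, max]",
    white = maxv, black = 0L,
    mean_intensity = sums / n^3,
    slices = stats::setNames(checksums, basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Convert between phantom edge length and total raw size
#'
#' \code{edge_to_size} gives the raw payload in bytes of an \code{n^3} volume
#' at the given bit depth; \code{size_to_edge} inverts it, rounding the cube
#' root to the nearest integer edge. Useful for sizing benchmark volumes by
#' their storage footprint (e.g. a 6400 GiB 8-bit volume has edge 19012).
#'
#' @param n edge length in voxels.
#' @param total_bytes raw volume size in bytes.
#' @param bit_depth 8 or 16.
#' @return \code{edge_to_size}: bytes (numeric); \code{size_to_edge}: integer
#'   edge length.
#' @examples
#' edge_to_size(1024, 8) / 2^30   # exactly 1 GiB
#' size_to_edge(6400 * 2^30, 8)   # 19012
#' @export
edge_to_size <- function(n, bit_depth = 8L) {
  as.numeric(n)^3 * bytes_per_voxel(bit_depth)
}

#' @rdname edge_to_size
#' @export
size_to_edge <- function(total_bytes, bit_depth = 8L) {
  if (total_bytes <= 0)
    stop_bv("bv_usage_error", "total_bytes must be positive")
  as.integer(round_half_up((total_bytes / bytes_per_voxel(bit_depth))^(1 / 3)))
}

check_output_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L) {
    if (!force)
      stop_bv("bv_io_error",
              "output directory %s exists and is not empty (use force = TRUE)",
              out_dir)
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
}

# best-effort free-space check; silently passes where df is unavailable
refuse_if_disk_short <- function(dir, required_bytes) {
  avail <- tryCatch({
    df <- system2("df", c("-kP", shQuote(dir)), stdout = TRUE, stderr = FALSE)
    as.numeric(strsplit(trimws(df[2]), "[[:space:]]+")[[1]][4]) * 1024
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  if (!is.na(avail) && required_bytes > avail)
    stop_bv("bv_io_error",
            "insufficient disk space: need %.0f bytes, %.0f available",
            required_bytes, avail)
  invisible(NULL)
}
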