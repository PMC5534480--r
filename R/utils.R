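# Internal helpers: rounding, validation, condition constructors.

# round-to-nearest with ties away from zero-towards +Inf (half-up); base round()
# uses banker's rounding, which is wrong for image arithmetic here.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_power_of_two <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L

# All package errors carry a subclass so the CLI can map them to exit codes:
#   bv_usage_error      -> 1
#   bv_io_error / bv_integrity_error / bv_metadata_error / bv_range_error -> 2
#   bv_geometry_error / bv_transform_error -> 3
stop_bv <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "brickvol_error")))
}

check_dims <- function(dims, what = "dims") {
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1) || any(dims != floor(dims)))
    stop_bv("bv_geometry_error", "%s must be three positive integers, got: %s",
            what, paste(dims, collapse = ","))
  as.numeric(dims)
}

check_block_size <- function(block_size) {
  if (length(block_size) != 1L || is.na(block_size) || block_size < 8 ||
      !is_power_of_two(block_size))
    stop_bv("bv_geometry_error", "block_size must be a power of two >= 8, got %s",
            as.character(block_size))
  as.integer(block_size)
}

max_intensity <- function(bit_depth) 2^bit_depth - 1

# payload bytes of one stored voxel (the on-disk sample width, not R's
# in-memory width)
bytes_per_voxel <- function(bit_depth) bit_depth / 8

`%||%` <- function(a, b) if (is.null(a)) b else a
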