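#' Least-recently-used block cache
#'
#' ROI reads touch the same blocks over and over (neighbouring queries share
#' bricks), so decoded blocks are kept in an in-memory cache with LRU
#' eviction. The cache is purely an IO optimisation: results of every read
#' are identical with capacity 0 (caching disabled) and unbounded capacity.
#'
#' @param capacity maximum number of resident blocks; 0 disables caching.
#' @return An object of class \code{block_cache}.
#' @examples
#' bc <- block_cache(2)
#' cache_put(bc, "a", 1); cache_put(bc, "b", 2)
#' cache_get(bc, "a")      # refreshes recency of "a"
#' cache_put(bc, "c", 3)   # evicts "b", the least recently used
#' cache_keys(bc)
#' @export
block_cache <- function(capacity = 512L) {
  if (length(capacity) != 1L || is.na(capacity) || capacity < 0)
    stop_bv("bv_usage_error", "cache capacity must be a non-negative integer")
  e <- new.env(parent = emptyenv())
  e$entries <- list()
  e$recency <- character(0)   # least recently used first
  e$capacity <- as.integer(capacity)
  class(e) <- "block_cache"
  e
}

#' @rdname block_cache
#' @param cache a [block_cache()].
#' @param key character key (one block address).
#' @return \code{cache_get}: the stored value, or \code{NULL} on a miss.
#' @export
cache_get <- function(cache, key) {
  v <- cache$entries[[key]]
  if (!is.null(v))
    cache$recency <- c(setdiff(cache$recency, key), key)
  v
}

#' @rdname block_cache
#' @param value value to store under \code{key}.
#' @export
cache_put <- function(cache, key, value) {
  if (cache$capacity == 0L) return(invisible(NULL))
  if (is.null(cache$entries[[key]]) &&
      length(cache$entries) >= cache$capacity) {
    victim <- cache$recency[1L]
    cache$entries[[victim]] <- NULL
    cache$recency <- cache$recency[-1L]
  }
  cache$entries[[key]] <- value
  cache$recency <- c(setdiff(cache$recency, key), key)
  invisible(NULL)
}

#' @rdname block_cache
#' @return \code{cache_keys}: resident keys ordered least- to most-recently
#'   used.
#' @export
cache_keys <- function(cache) cache$recency

#' @export
print.block_cache <- function(x, ...) {
  cat(sprintf("block cache: %d / %d resident\n", length(x$entries), x$capacity))
  invisible(x)
}
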