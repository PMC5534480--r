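# Independent oracles and fixture builders for the test suite. Everything
# here avoids the package's own code paths where it matters: slice files are
# decoded directly with the tiff package, downsampling/cropping/resampling
# are recomputed from whole in-memory arrays, and the LRU reference is a
# plain vector simulation.

# assemble a written slice sequence into an in-memory (x, y, z) array
oracle_read_slices <- function(dir) {
  files <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  files <- files[order(as.integer(sub(".*_(\\d+)\\.tif$", "\\1", files)))]
  pages <- lapply(files, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    storage.mode(m) <- "integer"
    t(m)
  })
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

# naive factor-2 mean-pooling downsample: per output voxel, the mean of its
# (up to) 2x2x2 source window, rounded half-up
oracle_downsample <- function(v) {
  d <- dim(v)
  nd <- ceiling(d / 2)
  out <- array(0L, nd)
  for (k in seq_len(nd[3])) for (j in seq_len(nd[2])) for (i in seq_len(nd[1])) {
    win <- v[(2 * i - 1):min(2 * i, d[1]),
             (2 * j - 1):min(2 * j, d[2]),
             (2 * k - 1):min(2 * k, d[3])]
    out[i, j, k] <- as.integer(floor(mean(win) + 0.5))
  }
  out
}

# full pyramid: level 1 is the input; halve until all axes < block_size
oracle_pyramid <- function(v, block_size) {
  levels <- list(v)
  while (any(dim(levels[[length(levels)]]) >= block_size))
    levels[[length(levels) + 1L]] <- oracle_downsample(levels[[length(levels)]])
  levels
}

# zero-pad an array to the padded block-grid extent
oracle_pad <- function(v, block_size) {
  pd <- ceiling(dim(v) / block_size) * block_size
  out <- array(0L, pd)
  out[seq_len(dim(v)[1]), seq_len(dim(v)[2]), seq_len(dim(v)[3])] <- v
  out
}

# read one level of a written dataset back block-by-block with tiff alone,
# assembling via the path convention (kept in lockstep with the format docs)
oracle_read_level <- function(root, level, dims, block_size) {
  grid <- ceiling(dims / block_size)
  out <- array(0L, grid * block_size)
  for (bz in seq_len(grid[3]) - 1) for (by in seq_len(grid[2]) - 1)
    for (bx in seq_len(grid[1]) - 1) {
      p <- file.path(root, sprintf("level_%d/z%d/y%d/%d_%d_%d.tif",
                                   level, bz, by, bx, by, bz))
      pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
      for (z in seq_along(pages)) {
        pg <- pages[[z]]
        storage.mode(pg) <- "integer"
        out[bx * block_size + seq_len(block_size),
            by * block_size + seq_len(block_size),
            bz * block_size + z] <- t(pg)
      }
    }
  out[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
}

# chessboard phantom base pattern (no noise), by direct definition
oracle_phantom <- function(n, tile, period, maxv = 255L) {
  xpar <- floor((seq_len(n) - 1) / tile)
  v <- array(0L, c(n, n, n))
  plane <- outer(xpar, xpar, `+`)
  for (z in seq_len(n) - 1)
    v[, , z + 1] <- ifelse((plane + floor(z / period)) %% 2 == 0, maxv, 0L)
  v
}

# dense whole-volume rigid resample with voxel-center coordinates, matching
# the documented sampling convention but computed on full arrays (no blocks,
# no region fetches). M maps source level-1 coords to target: u_t = R u_s + t.
oracle_resample <- function(src, M, offset, out_dims, interpolation, maxv) {
  Minv <- solve(M)
  Rinv <- Minv[1:3, 1:3]
  tinv <- Minv[1:3, 4]
  tinv <- tinv - Rinv %*% offset
  d <- dim(src)
  out <- array(0L, out_dims)
  val_at <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    lin <- 1 + ix + d[1] * (iy + d[2] * iz)
    lin[!ok] <- 1
    v <- as.numeric(src[lin])
    v[!ok] <- 0
    v
  }
  for (z in seq_len(out_dims[3]) - 1) {
    g <- expand.grid(x = seq_len(out_dims[1]) - 1, y = seq_len(out_dims[2]) - 1)
    P <- rbind(g$x, g$y, rep(z, nrow(g))) + 0.5
    S <- Rinv %*% P + as.numeric(tinv) - 0.5
    if (interpolation == "nearest") {
      vals <- val_at(floor(S[1, ] + 0.5), floor(S[2, ] + 0.5), floor(S[3, ] + 0.5))
    } else {
      f <- floor(S)
      w <- S - f
      vals <- 0
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        wt <- (if (cx) w[1, ] else 1 - w[1, ]) *
              (if (cy) w[2, ] else 1 - w[2, ]) *
              (if (cz) w[3, ] else 1 - w[3, ])
        vals <- vals + wt * val_at(f[1, ] + cx, f[2, ] + cy, f[3, ] + cz)
      }
    }
    out[, , z + 1] <- matrix(as.integer(pmin(pmax(floor(vals + 0.5), 0), maxv)),
                             out_dims[1], out_dims[2])
  }
  out
}

# reference LRU: a recency vector (LRU first) over keys, capacity-bounded
oracle_lru_run <- function(capacity, ops) {
  recency <- character(0)
  lapply(ops, function(op) {
    if (op$kind == "put") {
      if (capacity > 0) {
        if (!(op$key %in% recency) && length(recency) >= capacity)
          recency <<- recency[-1]
        recency <<- c(setdiff(recency, op$key), op$key)
      }
    } else if (op$key %in% recency) {
      recency <<- c(setdiff(recency, op$key), op$key)
    }
    recency
  })
}

# write an arbitrary (x, y, z) integer array as a slice sequence
write_volume_slices <- function(v, dir, bit_depth = 8L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxv <- 2^bit_depth - 1
  for (z in seq_len(dim(v)[3])) {
    tiff::writeTIFF(t(v[, , z]) / maxv,
                    file.path(dir, sprintf("slice_%06d.tif", z - 1L)),
                    bits.per.sample = bit_depth, compression = "none")
  }
  invisible(dir)
}

# build a reformatted phantom dataset once per test file run
make_phantom_dataset <- function(n, block_size, tile = n / 4, period = n / 4,
                                 noise = 0.05, seed = 7, workers = 1L) {
  src <- file.path(tempdir(), sprintf("ph_src_%d_%d_%d", n, block_size, seed))
  dst <- file.path(tempdir(), sprintf("ph_ds_%d_%d_%d", n, block_size, seed))
  if (!dir.exists(dst)) {
    generate_phantom(src, n = n, tile = tile, phase_period = period,
                     noise_fraction = noise, seed = seed, force = TRUE)
    reformat(src, dst, block_size = block_size, workers = workers, force = TRUE)
  }
  list(src = src, root = dst)
}

md5_tree <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE,
                           pattern = "\\.tif$"))
  unname(tools::md5sum(file.path(root, files)))
}

# concatenate 3D arrays along x
abind_x <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(0L, c(sum(vapply(arrs, function(a) dim(a)[1], 0)), d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
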