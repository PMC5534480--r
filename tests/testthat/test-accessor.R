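test_that("sequential reads visit every block of a level exactly once", {
  fix <- make_phantom_dataset(64, 32)
  ds <- open_dataset(fix$root)
  seen <- character(0)
  n <- sequential_read(ds, 1, function(vox, idx) {
    seen <<- c(seen, paste(idx$b, collapse = "_"))
    sum(as.numeric(vox))
  })
  expect_equal(as.integer(n), 8L)           # grid 2x2x2 at level 1
  expect_equal(length(unique(seen)), 8L)
  # summing unpadded voxels through the visitor equals the whole-volume sum
  v <- oracle_read_slices(fix$src)
  expect_equal(sum(unlist(attr(n, "results"))), sum(as.numeric(v)))

  # a grid (3,3,2) level visits 18 blocks
  m <- brick_meta(c(1414, 1410, 1000), c(1, 1, 1), 8)
  expect_equal(prod(block_grid(c(1414, 1410, 1000), 512)), 18)

  # multi-worker visits the same multiset of blocks
  n2 <- sequential_read(ds, 2, function(vox, idx) paste(idx$b, collapse = "_"),
                        workers = 2)
  expect_equal(as.integer(n2), 1L)
  expect_error(sequential_read(ds, 9, function(...) NULL), class = "bv_range_error")
})

test_that("a missing block file raises an integrity error naming its path", {
  fix <- make_phantom_dataset(64, 32)
  broken <- tempfile("broken_ds_")
  fs <- list.files(fix$root, recursive = TRUE)
  dir.create(broken)
  for (f in fs) {
    dir.create(file.path(broken, dirname(f)), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(fix$root, f), file.path(broken, f))
  }
  unlink(file.path(broken, "level_1/z1/y0/1_0_1.tif"))
  ds <- open_dataset(broken)
  expect_error(sequential_read(ds, 1, function(...) NULL),
               "1_0_1", class = "bv_integrity_error")
  expect_error(read_roi(ds, c(32, 0, 32), c(8, 8, 8), level = 1),
               class = "bv_integrity_error")
})

test_that("automatic level selection serves the finest level within budget", {
  m <- brick_meta(c(8000, 8000, 8000), c(1, 1, 1), 8, 512)
  expect_equal(select_level(m, c(100, 100, 100), 512^3), 1L)
  # 2000^3 / 8 > 512^3 but 2000^3 / 64 <= 512^3 -> level 3
  expect_equal(select_level(m, c(2000, 2000, 2000), 512^3), 3L)
  # monotone: larger ROIs never map to finer levels
  sizes <- c(64, 256, 700, 1500, 3000, 8000)
  lv <- vapply(sizes, function(s) select_level(m, rep(s, 3), 512^3), 0L)
  expect_true(all(diff(lv) >= 0))
  # clamped to the available levels
  expect_equal(select_level(m, c(8000, 8000, 8000), 8), m$n_levels)
})

test_that("ROI reads equal oracle crops at every level, bit-exactly", {
  fix <- make_phantom_dataset(64, 32)
  ds <- open_dataset(fix$root)
  v <- oracle_read_slices(fix$src)
  pyr <- lapply(oracle_pyramid(v, 32), oracle_pad, block_size = 32)

  # aligned exactly on one block: that block verbatim
  roi <- read_roi(ds, c(32, 0, 32), c(32, 32, 32), level = 1)
  expect_equal(roi$voxels, v[33:64, 1:32, 33:64])

  # straddling all 8 level-1 blocks
  roi <- read_roi(ds, c(16, 16, 16), c(32, 32, 32), level = 1)
  expect_equal(roi$voxels, v[17:48, 17:48, 17:48])

  # 60 random ROIs per level, including ones reaching into block padding
  set.seed(99)
  padded <- dim(pyr[[1]])   # padded level-1 extent; ROIs are level-1 coords
  for (L in 1:3) {
    for (i in 1:60) {
      o <- vapply(padded, function(d) sample(0:(d - 1), 1), 0)
      s <- vapply(padded - o, function(d) sample(1:d, 1), 0)
      roi <- read_roi(ds, o, s, level = L)
      oL <- floor(o / 2^(L - 1)); sL <- ceiling(s / 2^(L - 1))
      expect_equal(dim(roi$voxels), sL)
      expect_identical(roi$voxels,
                       pyr[[L]][oL[1] + seq_len(sL[1]), oL[2] + seq_len(sL[2]),
                                oL[3] + seq_len(sL[3]), drop = FALSE])
    }
  }
  # realized resolution doubles per level
  expect_equal(read_roi(ds, c(0, 0, 0), c(8, 8, 8), level = 3)$resolution,
               rep(4, 3))
})

test_that("ROIs beyond the padded extent error instead of zero-filling", {
  fix <- make_phantom_dataset(64, 32)
  ds <- open_dataset(fix$root)
  expect_error(read_roi(ds, c(60, 0, 0), c(8, 8, 8), level = 1),
               class = "bv_range_error")
  expect_error(read_roi(ds, c(-1, 0, 0), c(4, 4, 4)), class = "bv_range_error")
  expect_error(read_roi(ds, c(0, 0, 0), c(4, 4, 4), level = 7),
               class = "bv_range_error")
})

test_that("the cache changes IO counts but never results", {
  fix <- make_phantom_dataset(64, 32)
  set.seed(15)
  rois <- replicate(25, {
    o <- sample(0:56, 3, replace = TRUE)
    list(o = o, s = pmin(sample(1:32, 3, replace = TRUE), 64 - o))
  }, simplify = FALSE)

  ds_on <- open_dataset(fix$root, cache_blocks = 64)
  ds_off <- open_dataset(fix$root, cache_blocks = 0)
  for (r in rois) {
    a <- read_roi(ds_on, r$o, r$s, level = 1)
    b <- read_roi(ds_off, r$o, r$s, level = 1)
    expect_identical(a$voxels, b$voxels)
  }
  expect_lt(io_counters(ds_on)$storage_reads, io_counters(ds_off)$storage_reads)
  expect_equal(io_counters(ds_off)$cache_hits, 0L)

  # a repeated ROI with sufficient capacity performs zero storage reads
  ds_on <- open_dataset(fix$root, cache_blocks = 64)  # fresh, empty cache
  read_roi(ds_on, c(10, 10, 10), c(40, 40, 40), level = 1)
  first <- io_counters(ds_on)$storage_reads
  read_roi(ds_on, c(10, 10, 10), c(40, 40, 40), level = 1)
  expect_equal(io_counters(ds_on)$storage_reads, first)
  expect_gt(first, 0L)
})

test_that("enlarging cache capacity never increases storage reads", {
  fix <- make_phantom_dataset(64, 32)
  set.seed(23)
  seq_access <- replicate(40, {
    o <- sample(0:60, 3, replace = TRUE)
    list(o = o, s = pmin(sample(1:16, 3, replace = TRUE), 64 - o))
  }, simplify = FALSE)
  reads <- vapply(c(0, 1, 2, 4, 8, 64), function(cap) {
    ds <- open_dataset(fix$root, cache_blocks = cap)
    for (r in seq_access) read_roi(ds, r$o, r$s, level = 1)
    io_counters(ds)$storage_reads
  }, 0L)
  expect_true(all(diff(reads) <= 0))
})
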