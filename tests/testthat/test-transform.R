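test_that("rigid transform validation enforces the rotation invariants", {
  tf <- rotation_about("z", 45)
  expect_s3_class(tf, "rigid_transform")
  expect_lt(max(abs(tf$inverse %*% tf$matrix - diag(4))), 1e-12)

  bad <- diag(4); bad[1, 1] <- 2           # scaling is not rigid
  expect_error(rigid_transform(bad), class = "bv_transform_error")
  bad <- diag(4); bad[4, ] <- c(0, 0, 0, 2)
  expect_error(rigid_transform(bad), class = "bv_transform_error")
  shear <- diag(4); shear[1, 2] <- 0.3
  expect_error(rigid_transform(shear), class = "bv_transform_error")
  expect_error(rigid_transform(matrix(0, 4, 4)), class = "bv_transform_error")
})

test_that("the bundled whole-brain registration matrix is a valid rotation", {
  path <- system.file("extdata", "example_registration_matrix.json",
                      package = "brickvol")
  tf <- read_transform(path)
  R <- tf$matrix[1:3, 1:3]
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-4)
  expect_equal(tf$matrix[4, ], c(0, 0, 0, 1))
  expect_equal(tf$matrix[1, 1], 0.868588)
})

test_that("transform files roundtrip through JSON and plain text", {
  tf <- rotation_about("y", 30, translation = c(5, -2, 1))
  p <- tempfile(fileext = ".json")
  write_transform(tf, p)
  expect_equal(read_transform(p)$matrix, tf$matrix)
  p2 <- tempfile(fileext = ".txt")
  writeLines(paste(t(tf$matrix), collapse = " "), p2)
  expect_equal(read_transform(p2)$matrix, tf$matrix)
})

test_that("rotated bounding boxes match the worked geometry examples", {
  tf45 <- rotation_about("z", 45)
  rb <- rotated_bounds(c(512, 512, 512), tf45)
  expect_equal(rb$dims, c(724, 724, 512))
  expect_equal(prod(block_grid(rb$dims, 512)), 4)

  rb2 <- rotated_bounds(c(1000, 1000, 1000), tf45)
  expect_equal(rb2$dims[1], 1414)
  expect_equal(prod(block_grid(rb2$dims, 512)), 18)

  rb3 <- rotated_bounds(c(100, 200, 300), diag(4))
  expect_equal(rb3$dims, c(100, 200, 300))
  expect_equal(rb3$offset, c(0, 0, 0))
  # offset maps the transformed box minimum to the origin
  expect_equal(rb$offset, c(512 * sin(pi / 4), 0, 0), tolerance = 1e-12)
})

test_that("identity transform reproduces the source dataset byte-for-byte", {
  fix <- make_phantom_dataset(64, 32)
  ds <- open_dataset(fix$root)
  out <- tempfile("tf_ident_")
  transform_dataset(ds, diag(4), out, interpolation = "trilinear")
  expect_equal(md5_tree(out), md5_tree(fix$root))
})

test_that("90-degree rotation is an exact index permutation", {
  fix <- make_phantom_dataset(48, 16)
  ds <- open_dataset(fix$root)
  v <- oracle_read_slices(fix$src)
  out <- tempfile("tf_90_")
  transform_dataset(ds, rotation_about("z", 90), out, interpolation = "nearest")
  got <- oracle_read_level(out, 1, c(48, 48, 48), 16)
  # Rz(90): (x, y, z) -> (-y, x, z); after shifting into [0, dims) the target
  # voxel (i, j, k) holds source voxel (j, dims_y - 1 - i, k)
  perm <- aperm(v[, 48:1, , drop = FALSE], c(2, 1, 3))
  expect_identical(got, perm)
})

test_that("block-wise transform equals the dense whole-volume resample", {
  fix <- make_phantom_dataset(64, 32)
  ds <- open_dataset(fix$root)
  v <- oracle_read_slices(fix$src)
  tf <- rotation_about("z", 45)
  rb <- rotated_bounds(dim(v), tf)

  for (interp in c("nearest", "trilinear")) {
    out <- tempfile(paste0("tf_45_", interp, "_"))
    transform_dataset(ds, tf, out, interpolation = interp)
    got <- oracle_read_level(out, 1, rb$dims, 32)
    want <- oracle_resample(v, tf$matrix, rb$offset, rb$dims, interp, 255L)
    expect_true(max(abs(got - want)) <= 1, info = interp)
  }
})

test_that("composed 90-degree transforms equal the single composed transform", {
  fix <- make_phantom_dataset(48, 16)
  ds <- open_dataset(fix$root)
  t1 <- rotation_about("z", 90)
  t2 <- rotation_about("x", 90)
  out1 <- tempfile("tf_c1_"); out12 <- tempfile("tf_c12_"); outc <- tempfile("tf_cc_")
  transform_dataset(ds, t1, out1, interpolation = "nearest")
  transform_dataset(open_dataset(out1), t2, out12, interpolation = "nearest")
  transform_dataset(ds, rigid_transform(t2$matrix %*% t1$matrix), outc,
                    interpolation = "nearest")
  expect_equal(md5_tree(out12), md5_tree(outc))
})

test_that("foreground volume is conserved under rotation of a binary ball", {
  n <- 48
  ctr <- (n - 1) / 2
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  ball <- array(ifelse((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 18^2,
                       255L, 0L), c(n, n, n))
  src <- write_volume_slices(ball, tempfile("ball_"))
  dsr <- tempfile("ball_ds_"); out <- tempfile("ball_rot_")
  reformat(src, dsr, block_size = 16)
  tf <- rotation_about("z", 45)
  transform_dataset(open_dataset(dsr), tf, out, interpolation = "nearest")
  rb <- rotated_bounds(c(n, n, n), tf)
  got <- oracle_read_level(out, 1, rb$dims, 16)
  n_fg_src <- sum(ball > 0)
  n_fg_rot <- sum(got > 0)
  expect_lt(abs(n_fg_rot - n_fg_src) / n_fg_src, 0.01)
})

test_that("single-source-block rotation reads storage once, then hits the cache", {
  # a source volume of exactly one block, rotated 45 degrees, needs a 2x2x1
  # grid of target blocks, each fetching the same single source block
  fix <- make_phantom_dataset(32, 32, tile = 8, period = 8)
  ds <- open_dataset(fix$root, cache_blocks = 16)
  tf <- rotation_about("z", 45)
  rb <- rotated_bounds(c(32, 32, 32), tf)
  expect_equal(block_grid(rb$dims, 32), c(2L, 2L, 1L))
  reset_io_counters(ds)
  for (bz in 0) for (by in 0:1) for (bx in 0:1)
    transform_block(ds, tf, rb$offset, c(bx, by, bz), level = 1,
                    target_dims = rb$dims)
  expect_equal(io_counters(ds)$storage_reads, 1L)
  expect_equal(io_counters(ds)$cache_hits, 3L)
})

test_that("scaled-transform and re-subsampling level modes nearly agree on a smooth volume", {
  # a linear ramp is reproduced exactly by trilinear interpolation and by
  # mean pooling, so the two ways of building coarse levels should agree to
  # a couple of intensity units except where border voxels sample outside
  n <- 48
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  ramp <- array(as.integer(round((g$x + g$y + g$z) / (3 * (n - 1)) * 255)),
                c(n, n, n))
  src <- write_volume_slices(ramp, tempfile("ramp_"))
  dsr <- tempfile("ramp_ds_")
  reformat(src, dsr, block_size = 16)
  ds <- open_dataset(dsr)
  tf <- rotation_about("z", 20)
  rb <- rotated_bounds(c(n, n, n), tf)
  o1 <- tempfile("ramp_t_"); o2 <- tempfile("ramp_s_")
  transform_dataset(ds, tf, o1, levels_mode = "transform")
  transform_dataset(ds, tf, o2, levels_mode = "subsample")
  lv <- pyramid_levels(rb$dims, 16)
  src_lv <- pyramid_levels(c(n, n, n), 16)
  for (L in 2:min(length(lv), length(src_lv))) {
    a <- oracle_read_level(o1, L, lv[[L]]$dims, 16)
    b <- oracle_read_level(o2, L, lv[[L]]$dims, 16)
    # compare only voxels that inverse-map well inside the source at this
    # level; near the source border the two constructions legitimately blend
    # different amounts of background
    sc <- 2^(L - 1)
    ld <- lv[[L]]$dims; sd_ <- src_lv[[L]]$dims
    g <- expand.grid(x = 0:(ld[1] - 1), y = 0:(ld[2] - 1), z = 0:(ld[3] - 1))
    M <- tf$matrix; M[1:3, 4] <- M[1:3, 4] + rb$offset
    Minv <- solve(M)
    S <- (Minv[1:3, 1:3] %*% ((t(as.matrix(g)) + 0.5) * sc) +
            Minv[1:3, 4]) / sc - 0.5
    interior <- array(S[1, ] >= 2 & S[1, ] <= sd_[1] - 3 &
                      S[2, ] >= 2 & S[2, ] <= sd_[2] - 3 &
                      S[3, ] >= 2 & S[3, ] <= sd_[3] - 3, ld)
    expect_gt(mean(interior), 0.1)
    expect_lte(max(abs(a[interior] - b[interior])), 3)
    expect_lt(mean(abs(a[interior] - b[interior])), 1)
  }
})

test_that("micrometre transforms convert to voxel space and resample correctly", {
  # isotropic voxels: conjugation is a no-op and stays rigid
  tf <- rotation_about("z", 30)
  v1 <- um_to_voxel_transform(tf, c(0.5, 0.5, 0.5))
  expect_s3_class(v1, "rigid_transform")
  expect_equal(v1$matrix, tf$matrix)

  # anisotropic voxels: the voxel-space map is a general affine
  res <- c(1, 1, 2)
  va <- um_to_voxel_transform(rotation_about("x", 30), res)
  expect_s3_class(va, "affine_transform")
  S <- diag(c(res, 1))
  p <- c(3, 4, 5, 1)
  expect_equal(as.numeric(va$matrix %*% p),
               as.numeric(solve(S) %*% rotation_about("x", 30)$matrix %*% S %*% p))
  # a raw non-orthonormal matrix is still rejected by the strict path
  expect_error(rotated_bounds(c(10, 10, 10), va$matrix), class = "bv_transform_error")

  # the block-wise machinery accepts the affine and matches the dense oracle
  set.seed(64)
  v <- array(sample(0:255, 32^3, replace = TRUE), c(32, 32, 32))
  src <- write_volume_slices(v, tempfile("um_src_"))
  root <- tempfile("um_ds_")
  reformat(src, root, resolution = res, block_size = 16)
  ds <- open_dataset(root)
  rb <- rotated_bounds(c(32, 32, 32), va)
  out <- tempfile("um_out_")
  transform_dataset(ds, va, out)
  got <- oracle_read_level(out, 1, rb$dims, 16)
  want <- oracle_resample(v, va$matrix, rb$offset, rb$dims, "trilinear", 255L)
  expect_lte(max(abs(got - want)), 1)
})
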