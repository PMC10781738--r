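test_that("MRC write/read round-trips values, voxel size and origin", {
  m <- fx_toy(3)
  gt <- make_ground_truth_map(m, toy_spec(n_residues = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_density_map(gt$map, path)
  r <- read_density_map(path)
  expect_equal(dim(r$values), dim(gt$map$values))
  ## float32 storage: relative error bounded by single precision
  expect_lt(max(abs(r$values - gt$map$values)),
            1e-6 * max(abs(gt$map$values)) + 1e-12)
  expect_equal(r$voxel_size, gt$map$voxel_size, tolerance = 1e-6)
  expect_equal(r$origin, gt$map$origin, tolerance = 1e-5)
})

test_that("a 4x4x4 zero map round-trips and satisfies the invariants", {
  z <- density_map(array(0, c(4, 4, 4)), voxel_size = 1.3,
                   origin = c(-1, 2, 0.5))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_density_map(z, path)
  r <- read_density_map(path)
  expect_true(all(r$values == 0))
  expect_true(all(is.finite(r$values)))
  expect_equal(r$voxel_size, rep(1.3, 3), tolerance = 1e-6)
})

test_that("anisotropic voxels produce cell lengths = shape * voxel_size", {
  v <- density_map(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                   voxel_size = c(1.0, 1.2, 1.5))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_density_map(v, path)
  hdr <- oracle_read_mrc(path)
  expect_equal(hdr$cella, c(4, 5, 6) * c(1.0, 1.2, 1.5), tolerance = 1e-6)
  r <- read_density_map(path)
  expect_equal(r$voxel_size, c(1.0, 1.2, 1.5), tolerance = 1e-6)
})

test_that("header statistics match an independent reader's recomputation", {
  set.seed(4)
  v <- density_map(array(rnorm(6^3), c(6, 6, 6)))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_density_map(v, path)
  hdr <- oracle_read_mrc(path)
  expect_equal(hdr$mode, 2L)
  expect_equal(hdr$dmin, min(v$values), tolerance = 1e-6)
  expect_equal(hdr$dmax, max(v$values), tolerance = 1e-6)
  expect_equal(hdr$dmean, mean(v$values), tolerance = 1e-6)
})

test_that("permuted-axis files read back equal to their unpermuted twin", {
  set.seed(9)
  vals <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  voxel <- c(1, 1, 1)
  origin <- c(2, -1, 0)
  p1 <- withr::local_tempfile(fileext = ".mrc")
  p2 <- withr::local_tempfile(fileext = ".mrc")
  oracle_write_mrc(vals, voxel, origin, p1, mapcrs = c(1, 2, 3))
  oracle_write_mrc(vals, voxel, origin, p2, mapcrs = c(2, 1, 3))
  r1 <- read_density_map(p1)
  r2 <- read_density_map(p2)
  expect_equal(r2$values, r1$values, tolerance = 1e-6)
  ## a third, fully rotated permutation
  p3 <- withr::local_tempfile(fileext = ".mrc")
  oracle_write_mrc(vals, voxel, origin, p3, mapcrs = c(3, 1, 2))
  expect_equal(read_density_map(p3)$values, r1$values, tolerance = 1e-6)
})

test_that("origin falls back to nstart * voxel_size when the record is zero", {
  set.seed(2)
  vals <- array(rnorm(24), c(2, 3, 4))
  path <- withr::local_tempfile(fileext = ".mrc")
  con <- file(path, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(2, 3, 4)); wi(2L); wi(c(5L, -2L, 1L)); wi(c(2, 3, 4))
  wf(c(2, 3, 4) * 1.5); wf(c(90, 90, 90)); wi(1:3)
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1L); wi(0L); wi(integer(25)); wf(c(0, 0, 0))
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0); wi(0L); writeBin(raw(800), con); wf(as.vector(vals))
  close(con)
  r <- read_density_map(path)
  expect_equal(r$origin, c(5, -2, 1) * 1.5, tolerance = 1e-6)
})

test_that("malformed headers are rejected with a message naming the field", {
  path <- withr::local_tempfile(fileext = ".mrc")
  v <- density_map(array(0, c(2, 2, 2)))
  write_density_map(v, path)
  ## corrupt the mode word
  con <- file(path, "r+b")
  seek(con, 12, rw = "write")
  writeBin(77L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_density_map(path), "mode")
  ## corrupt mapc/mapr/maps
  write_density_map(v, path)
  con <- file(path, "r+b")
  seek(con, 64, rw = "write")
  writeBin(c(1L, 1L, 3L), con, size = 4, endian = "little")
  close(con)
  expect_error(read_density_map(path), "mapc")
  expect_error(read_density_map(withr::local_tempfile(fileext = ".mrc")),
               "no such file")
})

test_that("trilinear interpolation is exact at voxel centres and for affine fields", {
  n <- c(5, 6, 4)
  idx <- as.matrix(expand.grid(0:(n[1] - 1), 0:(n[2] - 1), 0:(n[3] - 1)))
  vox <- c(0.8, 1.0, 1.2)
  org <- c(-1, 0.5, 2)
  coords <- sweep(sweep(idx, 2, vox, "*"), 2, org, "+")
  aff <- 0.7 + 0.3 * coords[, 1] - 0.2 * coords[, 2] + 0.05 * coords[, 3]
  mp <- density_map(array(aff, n), vox, org)
  ## lattice points reproduce voxel values
  expect_equal(trilinear_value(mp, coords), aff, tolerance = 1e-12)
  ## interior off-lattice points reproduce the affine field exactly
  set.seed(7)
  pts <- cbind(runif(50, org[1], org[1] + (n[1] - 1) * vox[1]),
               runif(50, org[2], org[2] + (n[2] - 1) * vox[2]),
               runif(50, org[3], org[3] + (n[3] - 1) * vox[3]))
  expect_equal(trilinear_value(mp, pts),
               0.7 + 0.3 * pts[, 1] - 0.2 * pts[, 2] + 0.05 * pts[, 3],
               tolerance = 1e-10)
  ## constant map is constant anywhere inside
  cm <- density_map(array(3.5, c(4, 4, 4)))
  expect_equal(trilinear_value(cm, cbind(0.37, 1.91, 2.05)), 3.5,
               tolerance = 1e-12)
})

test_that("trilinear midpoint between voxel centres averages the two values", {
  v <- array(0, c(5, 5, 5))
  v[3, 3, 3] <- 2
  mp <- density_map(v)
  expect_equal(trilinear_value(mp, c(2.5, 2, 2)), 1.0)
  expect_equal(trilinear_value(mp, c(2, 2, 2)), 2.0)
})

test_that("points outside the grid clamp by default and can error on request", {
  mp <- density_map(array(1:8, c(2, 2, 2)))
  expect_equal(trilinear_value(mp, c(-5, 0, 0)), trilinear_value(mp, c(0, 0, 0)))
  expect_error(trilinear_value(mp, c(-5, 0, 0), outside = "error"),
               "outside")
})

test_that("trilinear gradient matches finite differences of the interpolant", {
  set.seed(11)
  mp <- density_map(array(rnorm(6^3), c(6, 6, 6)), voxel_size = 0.9)
  pts <- cbind(runif(10, 0.5, 4), runif(10, 0.5, 4), runif(10, 0.5, 4))
  g <- trilinear_gradient(mp, pts)
  for (k in seq_len(nrow(pts))) {
    fd <- fd_gradient(function(x) trilinear_value(mp, x[1, , drop = FALSE]),
                      pts[k, , drop = FALSE], h = 1e-6)
    expect_equal(g[k, ], fd[1, ], tolerance = 1e-5)
  }
})

test_that("resampling onto the same grid is the identity", {
  m <- fx_toy(3)
  gt <- make_ground_truth_map(m, toy_spec(n_residues = 3, seed = 2))
  r <- resample_map(gt$map, gt$map)
  expect_equal(r$values, gt$map$values, tolerance = 1e-10)
})
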