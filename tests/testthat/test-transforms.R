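test_that("inverting trivial fields is exact", {
  d <- c(12L, 12L, 12L)
  zero <- array(0, c(d, 3L))
  inv <- invertTransform(zero, spacing = rep(0.6, 3))
  expect_equal(max(abs(inv)), 0)
  expect_equal(max(attr(inv, "residual")), 0)
  ## uniform translation: inverse is exactly the negated translation
  tr <- array(0, c(d, 3L))
  tr[, , , 1] <- 1.3; tr[, , , 2] <- -0.4
  inv <- invertTransform(tr, spacing = rep(0.6, 3))
  expect_equal(inv[, , , 1], array(-1.3, d), tolerance = 1e-12)
  expect_equal(inv[, , , 2], array(0.4, d), tolerance = 1e-12)
  expect_equal(max(abs(inv[, , , 3])), 0)
})

test_that("phantom displacement fields invert below a tenth of a voxel", {
  ph <- smallPhantom("CMV")
  ts <- ph$truth@transforms
  nPeak <- which.max(ph$truth@modulation)
  inv <- invertTransform(ts, phase = nPeak, mask = ph$truth@refMask)
  expect_lt(max(attr(inv, "residual")), 0.1)
})

test_that("pullback composition reduces to the identity for equal phases", {
  ph <- smallPhantom("HFOV")
  ts <- ph$truth@transforms
  d <- dim(ts@disp)[1:3]
  pb <- composePullback(ts, 3, 3)
  grid <- vapply(1:3, function(ax)
    strain4d:::.axisGrid(d, ts@spacing, ax), array(0, d))
  expect_equal(pb@map, array(grid, c(d, 3L)), tolerance = 1e-15)
  ## two distinct phases with identical fields: identity within
  ## interpolation tolerance
  nPeak <- which.max(ph$truth@modulation)
  dup <- array(ts@disp[, , , , c(nPeak, nPeak)], c(d, 3L, 2L))
  ts2 <- new("TransformSet", disp = dup, spacing = ts@spacing, f0 = ts@f0)
  pb2 <- composePullback(ts2, 1, 2)
  err <- abs(pb2@map - array(grid, c(d, 3L))) / 0.6
  expect_lt(max(err[is.finite(err)]), 0.05)
})

test_that("pullback to the minimum-inflation phase matches the analytic map", {
  ph <- smallPhantom("CMV")
  ts <- ph$truth@transforms
  d <- dim(ts@disp)[1:3]
  nPeak <- which.max(ph$truth@modulation)
  pb <- composePullback(ts, nPeak, 1)   # phi_1 is the identity
  grid <- array(vapply(1:3, function(ax)
    strain4d:::.axisGrid(d, ts@spacing, ax), array(0, d)), c(d, 3L))
  closed <- grid + displacement(ts, nPeak)
  expect_equal(pb@map, closed, tolerance = 1e-12)
})

test_that("general pullback matches the analytic composition to < 0.05 voxel", {
  ph <- smallPhantom("CMV")
  cfg <- phantomConfig(gridShape = c(24L, 24L, 24L), N = 6, f0 = 0.4,
                       modality = "CMV", noiseSdHu = 0, seed = 7L)
  geom <- strain4d:::.phantomGeom(cfg)
  ts <- ph$truth@transforms
  g <- ph$truth@modulation
  n <- which.max(g); m <- 2L
  pb <- composePullback(ts, n, m)
  d <- dim(ts@disp)[1:3]
  gx <- strain4d:::.axisGrid(d, ts@spacing, 1L)
  gy <- strain4d:::.axisGrid(d, ts@spacing, 2L)
  gz <- strain4d:::.axisGrid(d, ts@spacing, 3L)
  ## oracle: analytic fixed-point inverse of phi_m, then analytic phi_n
  X <- strain4d:::.phantomInverse(geom, as.vector(gx), as.vector(gy),
                                  as.vector(gz), g[m], tol = 1e-10,
                                  maxIter = 200L)
  u <- strain4d:::.phantomDisp(geom, X$x, X$y, X$z, g[n])
  oracle <- array(c(X$x + u$ux, X$y + u$uy, X$z + u$uz), c(d, 3L))
  err <- abs(pb@map - oracle) / 0.6
  expect_lt(max(err[array(rep(ph$truth@refMask, 3), c(d, 3L))]), 0.05)
})

test_that("warping through trivial maps reproduces the image", {
  d <- c(10L, 10L, 10L)
  sp <- rep(0.6, 3)
  img <- array(stats::rnorm(prod(d)), d)
  grid <- array(vapply(1:3, function(ax)
    strain4d:::.axisGrid(d, sp, ax), array(0, d)), c(d, 3L))
  expect_equal(warpImage(img, grid, spacing = sp), img, tolerance = 1e-12)
  ## shift by exactly one voxel along x: interior equals the shifted image
  shift <- grid; shift[, , , 1] <- shift[, , , 1] + 0.6
  w <- warpImage(img, shift, spacing = sp)
  expect_equal(w[1:9, , ], img[2:10, , ], tolerance = 1e-12)
  expect_true(all(is.na(w[10, , ])))
  expect_error(warpImage(img[1:5, , ], grid, spacing = sp), "mismatch")
})

test_that("warping a phase to the reference aligns the lung masks", {
  ph <- smallPhantom("CMV")
  ts <- ph$truth@transforms
  nPeak <- which.max(ph$truth@modulation)
  pb <- composePullback(ts, nPeak, 1)
  warped <- warpImage(maskArray(ph$sequence, nPeak) * 1.0, pb)
  a <- warped >= 0.5 & !is.na(warped)
  b <- maskArray(ph$sequence, 1)
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gt(dice, 0.99)
})

test_that("Jacobian determinants are exact for affine maps", {
  d <- c(12L, 12L, 12L)
  sp <- rep(0.5, 3)
  grid <- array(vapply(1:3, function(ax)
    strain4d:::.axisGrid(d, sp, ax), array(0, d)), c(d, 3L))
  expect_equal(jacobianField(grid, spacing = sp)@det, array(1, d),
               tolerance = 1e-14)
  ## uniform scaling about the origin: det = s^3 everywhere (affine maps are
  ## differentiated exactly by every stencil, boundaries included)
  expect_equal(jacobianField(grid * 1.1, spacing = sp)@det,
               array(1.1^3, d), tolerance = 1e-12)
  ## composition of commuting scalings multiplies determinants
  s1 <- 1.05; s2 <- 0.95
  dAB <- jacobianField(grid * (s1 * s2), spacing = sp)@det
  dA <- jacobianField(grid * s1, spacing = sp)@det
  dB <- jacobianField(grid * s2, spacing = sp)@det
  expect_equal(dAB, dA * dB, tolerance = 1e-12)
})

test_that("numeric determinants recover the analytic phantom Jacobian", {
  ph <- bigPhantom("HFOV")
  vm <- bigMetrics("HFOV")
  tr <- ph$truth
  d <- dim(tr@detJ)
  num <- vm@volume / prod(voxelSpacing(vm))
  err <- abs(num - tr@detJ)
  interior <- maskArray(vm) & tr@rho <= 0.8
  expect_lt(max(err[array(rep(interior, d[4]), d)]), 1e-3)
  ## sign convention: inflation relative to minimum-volume reference
  nPeak <- which.max(tr@modulation)
  core <- maskArray(vm) & tr@rho <= 0.5
  expect_true(all(num[, , , nPeak][core] > 1))
})

test_that("full Jacobian matrices are returned in (i, j) = dT_i/dx_j order", {
  d <- c(8L, 8L, 8L)
  sp <- rep(1, 3)
  grid <- array(vapply(1:3, function(ax)
    strain4d:::.axisGrid(d, sp, ax), array(0, d)), c(d, 3L))
  ## shear: T_x = x + 0.2 y
  sheared <- grid; sheared[, , , 1] <- grid[, , , 1] + 0.2 * grid[, , , 2]
  J <- jacobianField(sheared, spacing = sp, keepJ = TRUE)@J
  expect_equal(J[4, 4, 4, 1, 2], 0.2, tolerance = 1e-12)
  expect_equal(J[4, 4, 4, 2, 1], 0, tolerance = 1e-12)
  expect_equal(J[4, 4, 4, 1, 1], 1, tolerance = 1e-12)
})
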