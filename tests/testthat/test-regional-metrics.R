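test_that("boundary trimming removes exactly the slices within 6 mm", {
  mask <- array(TRUE, c(4L, 4L, 30L))
  sp <- rep(0.6, 3)
  expect_identical(trimMask(mask, sp, trimMm = 0), mask)
  out <- trimMask(mask, sp, trimMm = 6.0)
  kept <- apply(out, 3, any)
  expect_identical(which(!kept), c(1:10, 21:30))   # 10 slices per end
  expect_error(trimMask(array(TRUE, c(4L, 4L, 15L)), sp, trimMm = 6.0),
               "empty")
})

test_that("aeration range is the per-voxel intratidal HU range", {
  arr <- array(0, c(2, 1, 1, 3))
  arr[1, 1, 1, ] <- c(-900, -800, -850)
  arr[2, 1, 1, ] <- -700
  mask <- array(TRUE, c(2, 1, 1))
  out <- aerationRange(arr, mask)
  expect_equal(out[1, 1, 1], 100)
  expect_equal(out[2, 1, 1], 0)
  ## invalid samples excluded per voxel; < 2 valid phases flagged missing
  arr[1, 1, 1, 2] <- NA
  out <- aerationRange(arr, mask)
  expect_equal(out[1, 1, 1], 50)
  expect_true(attr(out, "incomplete")[1, 1, 1])
  arr[1, 1, 1, ] <- c(NA, NA, -850)
  expect_true(is.na(aerationRange(arr, mask)[1, 1, 1]))
})

test_that("strain is referenced to the per-voxel minimum volume", {
  v <- array(0, c(1, 1, 1, 3))
  v[1, 1, 1, ] <- c(1.0, 1.2, 1.1)
  mask <- array(TRUE, c(1, 1, 1))
  st <- strainSeries(v, mask)
  expect_equal(as.vector(st$strain), c(0, 0.2, 0.1))
  expect_equal(st$range[1, 1, 1], 0.2)
  st0 <- strainSeries(array(2, c(1, 1, 1, 4)), mask)
  expect_equal(max(abs(st0$strain)), 0)
  v[1, 1, 1, 1] <- -0.1
  expect_error(strainSeries(v, mask), "non-physical")
})

test_that("strain rate uses periodic forward differences", {
  e <- array(0, c(1, 1, 1, 3))
  e[1, 1, 1, ] <- c(0, 0.2, 0.1)
  sr <- strainRateSeries(e, dt = 0.1)
  expect_equal(as.vector(sr$rate), c(2, -1, -1))
  expect_equal(sr$range[1, 1, 1], 3)
  ## any periodic series telescopes to zero over a cycle, and the range
  ## bounds the largest instantaneous rate
  set.seed(5)
  e <- array(stats::rnorm(7 * 11), c(7, 1, 1, 11))
  sr <- strainRateSeries(e, dt = 1 / 55)
  sums <- apply(sr$rate, 1:3, sum) / 55
  expect_lt(max(abs(sums)), 1e-10)
  expect_true(all(sr$range >= apply(abs(sr$rate), 1:3, max) - 1e-12))
  ## invariant to cyclic phase relabelling
  sr2 <- strainRateSeries(e[, , , c(4:11, 1:3), drop = FALSE], dt = 1 / 55)
  expect_equal(sr2$range, sr$range, tolerance = 1e-12)
})

test_that("spatial summaries recover linear fields exactly", {
  d <- c(9L, 9L, 9L)
  sp <- c(0.5, 0.6, 0.7)
  y <- strain4d:::.axisGrid(d, sp, 2L)
  field <- 3 + 2 * y
  mask <- array(TRUE, d)
  ss <- spatialSummary(field, mask, sp)
  expect_equal(ss$gradients$slope, c(0, 2, 0), tolerance = 1e-12)
  expect_equal(ss$mean, mean(field))
  ## CoV of a linear ramp: popSD(y) * |slope| / mean
  expect_equal(ss$cov, popSD(as.vector(y)) * 2 / mean(field),
               tolerance = 1e-12)
  expect_equal(ss$gradients$normSlope[2], 2 / mean(field), tolerance = 1e-12)
  ssc <- spatialSummary(array(5, d), mask, sp)
  expect_equal(ssc$cov, 0)
  expect_equal(ssc$gradients$slope, rep(0, 3))
  ssz <- spatialSummary(field - mean(field), mask, sp)
  expect_true(all(is.na(ssz$gradients$normSlope)))
})

test_that("pipeline recovers the prescribed dorsal-ventral strain gradient", {
  vm <- bigMetrics("CMV")
  ph <- bigPhantom("CMV")
  msk <- maskArray(vm)
  ss <- spatialSummary(vm@strainRange, msk, voxelSpacing(vm))
  truthSlope <- spatialSummary(truthStrainRange(ph$truth), msk,
                               voxelSpacing(vm))$gradients$slope[2]
  expect_gt(ss$gradients$slope[2], 0)
  expect_equal(ss$gradients$slope[2], truthSlope, tolerance = 0.05)
})

test_that("per-voxel strain range matches the analytic prescription in the core", {
  vm <- bigMetrics("CMV")
  ph <- bigPhantom("CMV")
  core <- maskArray(vm) & ph$truth@rho <= 0.5
  rel <- abs(vm@strainRange - truthStrainRange(ph$truth)) /
    truthStrainRange(ph$truth)
  expect_lt(max(rel[core]), 0.02)
})

test_that("aeration range tracks the true volume excursion in a noiseless phantom", {
  vm <- bigMetrics("HFOV")
  ph <- bigPhantom("HFOV")
  msk <- maskArray(vm) & ph$truth@rho <= 0.9
  r <- stats::cor(vm@aerationRange[msk], truthStrainRange(ph$truth)[msk])
  expect_gt(r, 0.9)
})

test_that("strain invariants hold on the phantom pipeline", {
  vm <- bigMetrics("HFOV")
  msk <- maskArray(vm)
  d <- dim(vm@strain)
  eps <- matrix(vm@strain, ncol = d[4])[msk, ]
  expect_lt(max(abs(apply(eps, 1, min))), 1e-12)         # min strain = 0
  expect_equal(apply(eps, 1, max), vm@strainRange[msk], tolerance = 1e-12)
  rates <- matrix(vm@strainRate, ncol = d[4])[msk, ]
  expect_lt(max(abs(rowSums(rates) * vm@dt)), 1e-9)      # periodic telescoping
  expect_equal(vm@dt, 1 / (5 * 21))
})

test_that("range metrics are insensitive to the arbitrary reference phase", {
  ph <- bigPhantom("CMV")
  vm1 <- bigMetrics("CMV")
  vm2 <- cachedValue("vm_CMV_ref11",
    regionalMetrics(ph$sequence, ph$truth@transforms, refPhase = 11L))
  m <- maskArray(vm1) & maskArray(vm2) & ph$truth@rho <= 0.8
  s1 <- vm1@strainRange[m]; s2 <- vm2@strainRange[m]
  expect_lt(abs(mean(s1) - mean(s2)) / mean(s1), 0.03)
  a1 <- vm1@aerationRange[m]; a2 <- vm2@aerationRange[m]
  expect_lt(abs(mean(a1) - mean(a2)) / mean(a1), 0.05)
})
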