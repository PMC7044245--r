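test_that("zero strain amplitude gives identity deformation and static images", {
  ph <- makePhantom(phantomConfig(gridShape = c(16, 16, 16), N = 4,
                                  strainAmplitude = 0, noiseSdHu = 0))
  expect_equal(max(abs(ph$truth@detJ - 1)), 0)
  expect_equal(max(abs(displacement(ph$truth@transforms))), 0)
  img <- imageArray(ph$sequence)
  for (n in 2:4) expect_identical(img[, , , n], img[, , , 1])
  expect_identical(maskArray(ph$sequence, 2), maskArray(ph$sequence, 1))
})

test_that("tissue volume is conserved per voxel across phases", {
  ph <- smallPhantom("CMV", noiseSdHu = 0)
  tr <- ph$truth
  d <- dim(tr@detJ)
  deltaV <- prod(voxelSpacing(tr@transforms))
  ## F_n = F_0 / detJ_n; tissue volume F_n * V_n must equal F_0 * deltaV
  for (n in c(2L, d[4])) {
    Fn <- tr@tissueFraction / tr@detJ[, , , n]
    tissueVol <- Fn * tr@volume[, , , n]
    expect_lt(max(abs(tissueVol - tr@tissueFraction * deltaV)),
              1e-10 * deltaV)
  }
})

test_that("reference-phase intensities follow the gas/tissue mixture model", {
  ph <- smallPhantom("HFOV", noiseSdHu = 0)
  ## phase 1 is minimum inflation: identity transform, F = F_0 exactly
  expect_equal(ph$truth@modulation[1], 0)
  hu <- imageArray(ph$sequence)[, , , 1]
  expect_equal(hu, -1000 * (1 - ph$truth@tissueFraction) +
                     40 * ph$truth@tissueFraction,
               tolerance = 1e-12, ignore_attr = TRUE)
  ## aerated lung around -790 HU, outside body is gas
  m <- ph$truth@refMask
  expect_lt(stats::median(hu[m]), -700)
  expect_equal(min(hu), -1000)
})

test_that("dorsal-ventral gradient of the true strain field matches the prescription", {
  ph <- makePhantom(phantomConfig(gridShape = c(24, 24, 24), N = 6,
                                  dvGradient = 0.5, noiseSdHu = 0,
                                  modality = "CMV", f0 = 0.4))
  epsT <- truthStrainRange(ph$truth)
  m <- ph$truth@refMask
  sl <- spatialSummary(epsT, m, c(0.6, 0.6, 0.6))
  expect_gt(sl$gradients$slope[2], 0)
  ## flipping the prescribed modulation flips the recovered slope
  ph2 <- makePhantom(phantomConfig(gridShape = c(24, 24, 24), N = 6,
                                   dvGradient = -0.5, noiseSdHu = 0,
                                   modality = "CMV", f0 = 0.4))
  sl2 <- spatialSummary(truthStrainRange(ph2$truth), ph2$truth@refMask,
                        c(0.6, 0.6, 0.6))
  expect_lt(sl2$gradients$slope[2], 0)
  ## magnitudes agree: the geometry is mirror-symmetric in y
  expect_equal(sl$gradients$slope[2], -sl2$gradients$slope[2],
               tolerance = 1e-6)
})

test_that("injured condition suppresses deformation and aerates nothing dorsally", {
  ph <- makePhantom(phantomConfig(gridShape = c(24, 24, 24), N = 6,
                                  condition = "injured",
                                  consolidationFraction = 0.4,
                                  noiseSdHu = 0, modality = "CMV", f0 = 0.4))
  tr <- ph$truth
  epsT <- truthStrainRange(tr)
  d <- dim(tr@refMask)
  wy <- (seq_len(d[2]) - 1) * 0.6
  yThr <- strain4d:::.phantomGeom(phantomConfig(gridShape = c(24, 24, 24),
    N = 6, condition = "injured", consolidationFraction = 0.4,
    modality = "CMV", f0 = 0.4))$yThr
  dorsal <- tr@refMask & (strain4d:::.axisGrid(d, rep(0.6, 3), 2L) <
                          yThr - 2.4)
  ventral <- tr@refMask & (strain4d:::.axisGrid(d, rep(0.6, 3), 2L) >
                           yThr + 2.4)
  expect_lt(max(epsT[dorsal]), 1e-12)          # consolidated: no deformation
  expect_gt(mean(epsT[ventral]), 0.01)         # recruited lung still strains
  expect_equal(max(tr@tissueFraction[dorsal]), 1)  # airless consolidation
})

test_that("phantom generation is reproducible and seed-sensitive", {
  cfg <- phantomConfig(gridShape = c(16, 16, 16), N = 4, noiseSdHu = 5,
                       seed = 11)
  a <- makePhantom(cfg)
  b <- makePhantom(cfg)
  expect_identical(imageArray(a$sequence), imageArray(b$sequence))
  cfg2 <- phantomConfig(gridShape = c(16, 16, 16), N = 4, noiseSdHu = 5,
                        seed = 12)
  expect_false(identical(imageArray(a$sequence),
                         imageArray(makePhantom(cfg2)$sequence)))
})

test_that("invalid configurations are rejected", {
  expect_error(phantomConfig(condition = "baseline",
                             consolidationFraction = 0.3),
               "consolidation")
  expect_error(phantomConfig(N = 2), "N = 3")
  expect_error(phantomConfig(f0 = 0), "f0")
  expect_error(phantomConfig(strainAmplitude = -0.1), "strainAmplitude")
  expect_error(phantomConfig(consolidationFraction = 1,
                             condition = "injured"), "consolidationFraction")
  ## a deformation violently exceeding the grid must be rejected with a
  ## positivity diagnostic
  expect_error(makePhantom(phantomConfig(gridShape = c(16, 16, 16), N = 4,
                                         strainAmplitude = 60,
                                         dvGradient = 0.9, noiseSdHu = 0)),
               "det J")
})

test_that("gas panels emulate the protocol's conditions", {
  set.seed(3)
  base <- makeGasPanel("baseline", "CMV")
  inj <- makeGasPanel("injured", "CMV")
  expect_equal(base$fio2, 0.40)
  expect_gt(base$pao2 / base$fio2, 300)   # healthy P/F ratio
  expect_lt(inj$pao2 / inj$fio2, 300)     # injury definition
  expect_true(inj$paco2 >= 30 && inj$paco2 <= 60)
})
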