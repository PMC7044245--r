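healthyParams <- list(R = 8.9, Iaw = 0.11, eta = 0.17, H = 121)

test_that("forced-oscillation synthesis enforces its frequency-grid contract", {
  expect_error(makeImpedanceRecord(healthyParams, freqs = c(0.1, 1)),
               "25.6")
  expect_error(makeImpedanceRecord(healthyParams, duration = 30), "three")
  set.seed(1)
  rec <- makeImpedanceRecord(healthyParams, noiseSd = 0)
  expect_equal(length(rec$time), 89.6 * 40)
})

test_that("Welch estimation is exact on noiseless constant-phase records", {
  set.seed(2)
  rec <- makeImpedanceRecord(healthyParams, noiseSd = 0)
  sp <- estimateImpedance(rec$pressure, rec$flow, rec$fs)
  Zt <- constantPhaseImpedance(rec$freqs, healthyParams$R, healthyParams$Iaw,
                               healthyParams$eta, healthyParams$H)
  expect_lt(max(Mod(sp@Z - Zt) / Mod(Zt)), 1e-6)
  expect_equal(sp@coherence, rep(1, 9), tolerance = 1e-9)
  ## elastic dominance at the lowest tone: negative reactance
  expect_lt(reactance(sp)[1], 0)
  ## estimator invariance to common amplitude scaling
  sp2 <- estimateImpedance(3.7 * rec$pressure, 3.7 * rec$flow, rec$fs)
  expect_equal(sp2@Z, sp@Z, tolerance = 1e-12)
})

test_that("a pure resistance gives in-phase pressure and |Z| = R", {
  fs <- 40; t <- seq(0, 76.8 - 1 / fs, by = 1 / fs)
  f <- 5 / 25.6
  q <- 0.3 * cos(2 * pi * f * t)
  p <- 7.5 * q
  sp <- estimateImpedance(p, q, fs, freqs = f)
  expect_equal(Re(sp@Z), 7.5, tolerance = 1e-9)
  expect_equal(Im(sp@Z), 0, tolerance = 1e-9)
  expect_error(estimateImpedance(p, q, fs, freqs = 0.123), "grid")
  expect_error(estimateImpedance(p[1:100], q[1:100], fs, freqs = f),
               "shorter")
})

test_that("noisy records reduce coherence without biasing Z", {
  set.seed(42)
  Zerr <- replicate(25, {
    rec <- makeImpedanceRecord(healthyParams, noiseSd = 1.0)
    sp <- estimateImpedance(rec$pressure, rec$flow, rec$fs)
    c(min(sp@coherence),
      Mod(sp@Z[5] - constantPhaseImpedance(rec$freqs[5], healthyParams$R,
          healthyParams$Iaw, healthyParams$eta, healthyParams$H)))
  })
  expect_true(all(Zerr[1, ] < 1))
  ## mean error across replicates stays small relative to |Z| (~ 12)
  expect_lt(mean(Zerr[2, ]), 1.0)
})

test_that("resonant frequency interpolates the reactance zero-crossing", {
  ## a linear reactance profile: the spline root equals the straight line's
  f <- 1:9
  x <- f - 4.5
  sp <- new("ImpedanceSpectrum", freq = f, Z = complex(real = 5, imaginary = x),
            coherence = rep(1, 9))
  expect_equal(as.numeric(resonantFrequency(sp)), 4.5, tolerance = 1e-6)
  ## all-negative reactance: undefined, flagged
  spNeg <- new("ImpedanceSpectrum", freq = f,
               Z = complex(real = 5, imaginary = -abs(x) - 1),
               coherence = rep(1, 9))
  fres <- resonantFrequency(spNeg)
  expect_true(is.na(fres))
  expect_false(attr(fres, "defined"))
})

test_that("spline f_res agrees with the closed-form constant-phase root", {
  freqs <- oscillationFrequencies()
  Z <- constantPhaseImpedance(freqs, healthyParams$R, healthyParams$Iaw,
                              healthyParams$eta, healthyParams$H)
  sp <- new("ImpedanceSpectrum", freq = freqs, Z = Z,
            coherence = rep(1, 9))
  fres <- as.numeric(resonantFrequency(sp))
  ## oracle: dense-grid root of the model reactance
  g <- seq(0.1, 8.9, length.out = 20000)
  xg <- Im(constantPhaseImpedance(g, healthyParams$R, healthyParams$Iaw,
                                  healthyParams$eta, healthyParams$H))
  oracle <- g[which(diff(sign(xg)) > 0)[1]]
  expect_equal(oracle, 6.44, tolerance = 0.01)
  expect_equal(fres, oracle, tolerance = 0.1)  # spline interpolation error
  expect_equal(constantPhaseResonance(healthyParams), oracle,
               tolerance = 1e-3)
})

test_that("constant-phase fitting recovers noiseless parameters to 0.1%", {
  freqs <- oscillationFrequencies()
  Z <- constantPhaseImpedance(freqs, healthyParams$R, healthyParams$Iaw,
                              healthyParams$eta, healthyParams$H)
  sp <- new("ImpedanceSpectrum", freq = freqs, Z = Z, coherence = rep(1, 9))
  fit <- fitConstantPhase(sp)
  pars <- cpParams(fit)
  truth <- c(R = 8.9, Iaw = 0.11, eta = 0.17, H = 121)
  for (nm in names(truth))
    expect_lt(abs(pars[[nm]] - truth[[nm]]) / truth[[nm]], 1e-3)
  expect_equal(pars[["alpha"]], (2 / pi) * atan(1 / pars[["eta"]]),
               tolerance = 1e-12)
  expect_lt(fit@residualNorm, 1e-10)
  expect_true(fit@converged)
  expect_error(fitConstantPhase(
    new("ImpedanceSpectrum", freq = freqs[1:3], Z = Z[1:3],
        coherence = rep(1, 3))), "at least 4")
})

test_that("parameter recovery stays within 5% median error at 5% noise", {
  set.seed(11)
  truth <- c(8.9, 0.11, 0.17, 121)
  errs <- replicate(25, {
    rec <- makeImpedanceRecord(healthyParams, noiseSd = 0)
    prms <- 0.05 * sqrt(mean(rec$pressure^2))
    rec <- makeImpedanceRecord(healthyParams, noiseSd = prms)
    fit <- fitConstantPhase(estimateImpedance(rec$pressure, rec$flow, rec$fs))
    abs(c(fit@R, fit@Iaw, fit@eta, fit@H) - truth) / truth
  })
  expect_true(all(apply(errs, 1, stats::median) < 0.05))
})
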