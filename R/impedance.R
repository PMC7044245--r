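## Respiratory input impedance: Welch cross-spectral estimation at the
## driving tones, resonant-frequency interpolation, and constant-phase model
## fitting.

#' Estimate respiratory impedance by the Welch periodogram technique
#'
#' Averages auto- and cross-spectra of flow and pressure over overlapping
#' rectangular-windowed segments and forms the H1 transfer estimate
#' Z = S_qp / S_qq (flow to pressure) with ordinary coherence
#' gamma^2 = |S_qp|^2 / (S_qq S_pp). The spectrum is evaluated only at the
#' driving frequencies of the forcing signal, which must lie on the
#' segment's frequency grid.
#'
#' @param pressure pressure series, cmH2O.
#' @param flow flow series, L/s.
#' @param fs sampling rate, Hz.
#' @param freqs driving frequencies, Hz.
#' @param segmentS segment length in s (default 25.6, one period of the
#'   control signal).
#' @param overlap fractional segment overlap (default 0.8).
#' @return an [ImpedanceSpectrum-class].
#' @export
estimateImpedance <- function(pressure, flow, fs,
                              freqs = oscillationFrequencies(),
                              segmentS = 25.6, overlap = 0.8) {
  if (length(pressure) != length(flow)) stop("series lengths differ")
  nseg <- round(segmentS * fs)
  if (nseg > length(flow)) stop("record shorter than one segment")
  bins <- freqs * segmentS
  if (max(abs(bins - round(bins))) > 1e-6)
    stop("driving frequencies must lie on the segment frequency grid (multiples of 1/segmentS)")
  bins <- round(bins) + 1L
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(flow) - nseg + 1L, by = hop)
  Sqq <- Spp <- numeric(length(freqs))
  Sqp <- complex(length(freqs))
  for (s in starts) {
    i <- s:(s + nseg - 1L)
    Q <- stats::fft(flow[i])[bins]
    P <- stats::fft(pressure[i])[bins]
    Sqq <- Sqq + Mod(Q)^2
    Spp <- Spp + Mod(P)^2
    Sqp <- Sqp + P * Conj(Q)
  }
  Z <- Sqp / Sqq
  coh <- Mod(Sqp)^2 / (Sqq * Spp)
  new("ImpedanceSpectrum", freq = freqs, Z = Z,
      coherence = pmin(pmax(coh, 0), 1))
}

#' Resonant frequency from the reactance zero-crossing
#'
#' Interpolates the reactance spectrum X_rs(f) through the measured tones
#' with a cubic spline and returns the smallest in-band root. When the
#' reactance does not change sign within the measured band (as happens after
#' severe injury, with resonance pushed above the measurement range) the
#' resonant frequency is undefined and NA is returned with attribute
#' `"defined" = FALSE`.
#'
#' @param spectrum an [ImpedanceSpectrum-class].
#' @return f_res in Hz, or NA when undefined.
#' @export
resonantFrequency <- function(spectrum) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  o <- order(spectrum@freq)
  f <- spectrum@freq[o]
  x <- reactance(spectrum)[o]
  if (all(x > 0) || all(x < 0)) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  sf <- stats::splinefun(f, x, method = "natural")
  grid <- seq(f[1], f[length(f)], length.out = 4096L)
  gx <- sf(grid)
  sgn <- which(gx[-1] * gx[-length(gx)] <= 0)
  if (!length(sgn)) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  i <- sgn[1]
  root <- stats::uniroot(sf, lower = grid[i], upper = grid[i + 1L],
                         tol = 1e-10)$root
  attr(root, "defined") <- TRUE
  root
}

## Sum of squared complex residuals of the constant-phase model.
.cpObjective <- function(par, freq, Z) {
  Zhat <- constantPhaseImpedance(freq, par[1], par[2], max(par[3], 1e-9),
                                 par[4])
  sum(Mod(Z - Zhat)^2)
}

#' Fit the constant-phase model to an impedance spectrum
#'
#' Minimises the sum of squared complex residuals
#' sum_f |Z(f) - Zhat(f)|^2 over (R, Iaw, eta, H), all constrained
#' non-negative, using a deterministic multi-start grid (data-scaled starts
#' over resistance, inertance, hysteresivity and elastance; 16 starts)
#' followed by box-constrained local optimisation ([stats::nlminb()]). The derived
#' exponent alpha = (2/pi) atan(1/eta) is reported with the parameters.
#'
#' @param spectrum an [ImpedanceSpectrum-class] with at least 4 valid
#'   frequencies.
#' @return a [ConstantPhaseFit-class].
#' @export
fitConstantPhase <- function(spectrum) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  ok <- is.finite(spectrum@Z) & spectrum@freq > 0
  f <- spectrum@freq[ok]
  Z <- spectrum@Z[ok]
  if (length(f) < 4L) stop("need at least 4 frequencies with valid Z")
  ## data-driven scales: R from the high-frequency resistance, H from the
  ## low-frequency elastic reactance
  Rhat <- max(min(Re(Z)), 0.1)
  fLow <- f[which.min(f)]
  Hhat <- max(-Im(Z)[which.min(f)] * (2 * pi * fLow)^0.9, 1)
  starts <- expand.grid(R = Rhat * c(0.5, 1),
                        Iaw = c(0.01, 0.2),
                        eta = c(0.1, 0.3),
                        H = Hhat * c(0.5, 1.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(as.numeric(starts[i, ]), .cpObjective,
                    lower = c(0, 0, 1e-6, 0), freq = f, Z = Z,
                    control = list(iter.max = 500L, eval.max = 1000L,
                                   rel.tol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop("constant-phase fit failed to converge from all starts")
  par <- best$par
  eta <- max(par[3], 1e-9)
  new("ConstantPhaseFit", R = par[1], Iaw = par[2], eta = eta, H = par[4],
      alpha = (2 / pi) * atan(1 / eta),
      residualNorm = best$objective,
      converged = best$convergence == 0L,
      freq = f,
      Zfit = constantPhaseImpedance(f, par[1], par[2], eta, par[4]))
}

#' Closed-form resonant frequency of a constant-phase model
#'
#' Root of the reactance 2 pi f Iaw = H / (2 pi f)^alpha, i.e.
#' (2 pi f)^(1 + alpha) = H / Iaw. Used as an independent check on the
#' spline-interpolated estimate.
#'
#' @param fit a [ConstantPhaseFit-class], or a named list with `Iaw`, `H`,
#'   `eta`.
#' @return f_res in Hz (Inf when Iaw = 0).
#' @export
constantPhaseResonance <- function(fit) {
  p <- if (is(fit, "ConstantPhaseFit")) list(Iaw = fit@Iaw, H = fit@H,
                                             eta = fit@eta) else as.list(fit)
  if (p$Iaw <= 0) return(Inf)
  alpha <- (2 / pi) * atan(1 / p$eta)
  (p$H / p$Iaw)^(1 / (1 + alpha)) / (2 * pi)
}
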