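## Forced-oscillation record synthesis for the constant-phase model.
##
## The forcing is a multi-sine flow waveform whose nine component frequencies
## lie on the frequency grid of the 25.6 s periodic control signal
## (multiples of 1/25.6 Hz) and span 0.078 to 8.9 Hz. Pressure is the exact
## frequency-domain response of the constant-phase model, plus optional
## additive Gaussian noise.

#' Constant-phase model impedance
#'
#' Evaluates Z(f) = R + j 2 pi f Iaw + (eta - j) H / (2 pi f)^alpha with
#' alpha = (2/pi) atan(1/eta).
#'
#' @param freq frequencies in Hz (> 0).
#' @param R Newtonian resistance, cmH2O s/L.
#' @param Iaw airway inertance, cmH2O s^2/L.
#' @param eta tissue hysteresivity (> 0).
#' @param H tissue elastance, cmH2O/L at 1 rad/s.
#' @return complex impedance vector.
#' @export
constantPhaseImpedance <- function(freq, R, Iaw, eta, H) {
  stopifnot(all(freq > 0))
  alpha <- (2 / pi) * atan(1 / eta)
  w <- 2 * pi * freq
  R + 1i * w * Iaw + (eta - 1i) * H / w^alpha
}

#' Default nine-tone forcing frequencies
#'
#' A non-sum/non-difference set of nine frequencies on the 25.6 s grid
#' spanning 0.078 to 8.9 Hz.
#'
#' @return numeric(9) frequencies in Hz.
#' @export
oscillationFrequencies <- function() {
  c(2, 5, 11, 23, 47, 79, 121, 171, 228) / 25.6
}

#' Synthesize a forced-oscillation pressure/flow record
#'
#' Builds a multi-sine flow forcing with the given tones (randomized phases)
#' and the exact constant-phase pressure response, sampled at `fs` over
#' `duration` seconds, with optional additive Gaussian pressure noise.
#'
#' @param params named list or vector with `R`, `Iaw`, `eta`, `H`.
#' @param freqs driving frequencies in Hz; each must be an integer multiple
#'   of 1/25.6 Hz.
#' @param fs sampling rate, Hz (default 40).
#' @param duration record length, s; must cover at least three 25.6 s periods
#'   of the control signal (default ~90 s).
#' @param noiseSd additive pressure noise SD, cmH2O.
#' @param flowAmplitude per-tone flow amplitude, L/s.
#' @return list with `time`, `pressure`, `flow`, `fs`, `freqs`.
#' @export
makeImpedanceRecord <- function(params, freqs = oscillationFrequencies(),
                                fs = 40, duration = 89.6, noiseSd = 0,
                                flowAmplitude = 0.2) {
  grid <- freqs * 25.6
  if (max(abs(grid - round(grid))) > 1e-9)
    stop("all driving frequencies must be integer multiples of 1/25.6 Hz")
  if (duration < 3 * 25.6)
    stop("duration must cover at least three 25.6 s periods")
  if (fs <= 2 * max(freqs)) stop("fs must exceed twice the highest tone")
  p <- as.list(params)
  Z <- constantPhaseImpedance(freqs, p$R, p$Iaw, p$eta, p$H)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  flow <- numeric(length(t))
  pressure <- numeric(length(t))
  for (i in seq_along(freqs)) {
    flow <- flow + flowAmplitude * cos(2 * pi * freqs[i] * t + phases[i])
    pressure <- pressure + flowAmplitude * Mod(Z[i]) *
      cos(2 * pi * freqs[i] * t + phases[i] + Arg(Z[i]))
  }
  if (noiseSd > 0)
    pressure <- pressure + stats::rnorm(length(t), sd = noiseSd)
  list(time = t, pressure = pressure, flow = flow, fs = fs, freqs = freqs)
}
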