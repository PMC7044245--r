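## Ventilator waveform synthesis for the three modalities studied:
##   CMV  - pressure-controlled square wave, I:E 1:2, rate 20-32 /min;
##          volume follows a single-compartment first-order response.
##   HFOV - single sinusoidal flow at the 5 Hz fundamental.
##   MFOV - superimposed 5/10/15/20 Hz sinusoids with uniform flow
##          amplitudes, so volume amplitudes scale as 1/k.

## Periodic steady-state volume of a first-order compartment driven by a
## square pressure wave with inspiratory fraction `duty`, in units of the
## asymptotic tidal volume. `tf` is the cycle fraction in [0, 1); `tauFrac`
## the time constant as a fraction of the period.
.cmvVolumeShape <- function(tf, duty = 1 / 3, tauFrac = 0.08) {
  ri <- exp(-duty / tauFrac)
  re <- exp(-(1 - duty) / tauFrac)
  v0 <- re * (1 - ri) / (1 - ri * re)
  v1 <- 1 + (v0 - 1) * ri
  insp <- tf < duty
  v <- numeric(length(tf))
  v[insp] <- 1 + (v0 - 1) * exp(-tf[insp] / tauFrac)
  v[!insp] <- v1 * exp(-(tf[!insp] - duty) / tauFrac)
  v
}

.cmvFlowShape <- function(tf, duty = 1 / 3, tauFrac = 0.08) {
  ri <- exp(-duty / tauFrac)
  re <- exp(-(1 - duty) / tauFrac)
  v0 <- re * (1 - ri) / (1 - ri * re)
  v1 <- 1 + (v0 - 1) * ri
  insp <- tf < duty
  q <- numeric(length(tf))
  q[insp] <- (1 - v0) / tauFrac * exp(-tf[insp] / tauFrac)
  q[!insp] <- -v1 / tauFrac * exp(-(tf[!insp] - duty) / tauFrac)
  q
}

## Normalised per-phase modulation waveform g_n for the phantom: the modality
## volume waveform sampled at N phases, shifted and rotated so that g_1 = 0
## at the minimum-inflation phase and max(g) = 1.
.modulation <- function(modality, N, mfovPhases = c(0, 0, 0, 0)) {
  tf <- (seq_len(N) - 1) / N
  v <- switch(modality,
    HFOV = sin(2 * pi * tf),
    MFOV = {
      k <- 1:4
      rowSums(sapply(seq_along(k), function(i)
        sin(2 * pi * k[i] * tf + mfovPhases[i]) / k[i]))
    },
    CMV = .cmvVolumeShape(tf),
    stop("unknown modality: ", modality))
  i0 <- which.min(v)
  g <- v[c(i0:N, seq_len(i0 - 1L))] - v[i0]
  g / max(g)
}

#' Default phantom strain amplitude per ventilation modality
#'
#' Peak fractional volume excursion used by [phantomConfig()] when none is
#' given. Amplitudes are scaled so that the rms of the delivered volume
#' waveform across modalities reproduces the protocol's eucapnia-titrated
#' delivery ratios (HFOV 42% and MFOV 25% of the CMV V_rms), starting from a
#' conventional tidal strain of `sCMV` for CMV.
#'
#' @param modality `"CMV"`, `"HFOV"`, or `"MFOV"`.
#' @param sCMV peak fractional volume excursion for CMV (default 0.25).
#' @return a single positive amplitude.
#' @export
defaultStrainAmplitude <- function(modality, sCMV = 0.25) {
  modality <- match.arg(modality, c("CMV", "HFOV", "MFOV"))
  vrmsRatio <- c(CMV = 1, HFOV = 0.42, MFOV = 0.25)
  rms0 <- function(m) {
    g <- .modulation(m, 512L)
    sqrt(mean((g - mean(g))^2))
  }
  unname(sCMV * vrmsRatio[modality] * rms0("CMV") / rms0(modality))
}

#' Synthesize a ventilator waveform record
#'
#' Generates time-sampled airway pressure, flow, and volume for one of the
#' three ventilation modalities. CMV is a square pressure wave between PEEP
#' and PIP with inspiratory:expiratory ratio 1:2 and volume as the
#' periodic steady state of a first-order single-compartment response; HFOV is
#' a single sinusoidal flow at `f0`; MFOV superimposes sinusoidal flows at
#' 1..4 times `f0` with uniform flow amplitudes, giving volume amplitudes
#' proportional to 1/k.
#'
#' @param modality `"CMV"`, `"HFOV"`, or `"MFOV"`.
#' @param f0 fundamental frequency in Hz (breathing rate for CMV, typically
#'   0.33-0.53 Hz; 5 Hz for oscillatory modes).
#' @param amplitudeSpec named list. For CMV: `peep` and `pip` (cmH2O),
#'   `compliance` (L/cmH2O), `tauFrac` (time constant as fraction of the
#'   period). For HFOV/MFOV: `flowAmplitude` (L/s, per component for MFOV),
#'   `pawMean` and `pawAmplitude` (cmH2O), and for MFOV `phases` (radians,
#'   per component, default all 0).
#' @param duration record length in s.
#' @param fs sampling rate in Hz (must exceed twice the highest component
#'   frequency).
#' @return a [WaveformRecord-class].
#' @examples
#' rec <- makeWaveform("HFOV", f0 = 5,
#'   amplitudeSpec = list(flowAmplitude = 1.5), duration = 2, fs = 200)
#' max(rec@volume) - min(rec@volume)  # ~ 2 * 1.5 / (2 * pi * 5)
#' @export
makeWaveform <- function(modality, f0, amplitudeSpec = list(),
                         duration = 10 / f0, fs = 200) {
  modality <- match.arg(modality, c("CMV", "HFOV", "MFOV"))
  if (f0 <= 0) stop("f0 must be positive")
  fmax <- if (modality == "MFOV") 4 * f0 else f0
  if (fs <= 2 * fmax)
    stop("sampling rate fs must exceed twice the highest component frequency")
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  spec <- amplitudeSpec
  if (modality == "CMV") {
    peep <- spec$peep %||% 5
    pip <- spec$pip %||% 18
    compliance <- spec$compliance %||% 0.0067
    tauFrac <- spec$tauFrac %||% 0.08
    if (pip <= peep) stop("pip must exceed peep")
    if (compliance <= 0) stop("compliance must be positive")
    tf <- (t * f0) %% 1
    vta <- compliance * (pip - peep)
    paw <- ifelse(tf < 1 / 3, pip, peep)
    vol <- vta * .cmvVolumeShape(tf, tauFrac = tauFrac)
    flow <- vta * f0 * .cmvFlowShape(tf, tauFrac = tauFrac)
  } else {
    q <- spec$flowAmplitude %||% 1.5
    if (q <= 0) stop("flow amplitude must be positive")
    pawMean <- spec$pawMean %||% 12
    pawAmp <- spec$pawAmplitude %||% (if (modality == "MFOV") 8 else 5)
    k <- if (modality == "MFOV") 1:4 else 1L
    ph <- spec$phases %||% rep(0, length(k))
    flow <- rowSums(sapply(seq_along(k), function(i)
      q * cos(2 * pi * k[i] * f0 * t + ph[i])))
    vol <- rowSums(sapply(seq_along(k), function(i)
      q / (2 * pi * k[i] * f0) * sin(2 * pi * k[i] * f0 * t + ph[i])))
    paw <- pawMean + pawAmp * flow / max(abs(flow))
  }
  new("WaveformRecord", time = t, paw = paw, flow = flow, volume = vol,
      fs = fs, f0 = f0, modality = modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
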