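## Scalar ventilation and gas-exchange indices from ventilator waveforms and
## arterial blood-gas panels.

## Default analysis window: one breath for CMV, exactly 1 s for HFOV/MFOV.
.analysisWindow <- function(record, window = NULL) {
  if (is.null(window))
    window <- if (record@modality == "CMV") 1 / record@f0 else 1.0
  nwin <- round(window * record@fs)
  if (nwin > length(record@time)) stop("analysis window longer than record")
  if (nwin < 2L) stop("analysis window too short")
  seq_len(nwin)
}

#' Oxygenation index
#'
#' OI = mean airway pressure x inspired oxygen fraction / arterial oxygen
#' tension. With `percent = TRUE` (default, the clinical convention) FiO2
#' enters as a percentage, so OI = Paw * (FiO2 * 100) / PaO2 in
#' cmH2O %/mmHg; with `percent = FALSE` the fraction is used directly.
#'
#' @param panel gas panel list with `pao2` (mmHg) and `fio2` (fraction),
#'   e.g. from [makeGasPanel()].
#' @param pawMean mean airway pressure, cmH2O.
#' @param percent report with the x100 clinical convention (default TRUE).
#' @return OI, with attribute `"convention"` recording the scaling.
#' @examples
#' oxygenationIndex(list(pao2 = 100, fio2 = 0.40), pawMean = 12)  # 4.8
#' @export
oxygenationIndex <- function(panel, pawMean, percent = TRUE) {
  if (panel$pao2 <= 0) stop("PaO2 must be positive")
  if (panel$fio2 <= 0 || panel$fio2 > 1)
    stop("FiO2 must be a fraction in (0, 1]")
  oi <- pawMean * (panel$fio2 * if (percent) 100 else 1) / panel$pao2
  attr(oi, "convention") <- if (percent) "FiO2 as percent" else
    "FiO2 as fraction"
  oi
}

#' Volume waveform statistics
#'
#' Mean, root-mean-square (about the mean, so invariant to volume offset),
#' and peak-to-peak range of the volume waveform over the analysis window:
#' one breath for CMV, 1 s (five fundamental cycles at 5 Hz) for HFOV/MFOV.
#' The rms integral is approximated by the mean of squares over samples.
#'
#' @param record a [WaveformRecord-class].
#' @param window window length in s; default per modality as above.
#' @return list with `vMean`, `vRms`, `vPp` (L).
#' @export
volumeStats <- function(record, window = NULL) {
  stopifnot(is(record, "WaveformRecord"))
  i <- .analysisWindow(record, window)
  v <- record@volume[i]
  vbar <- mean(v)
  list(vMean = vbar, vRms = sqrt(mean((v - vbar)^2)),
       vPp = max(v) - min(v))
}

#' Ventilatory cost function
#'
#' V_C = V_rms^2 * PaCO2 / Wt (L^2 mmHg / kg): the volume delivery cost of
#' CO2 elimination; lower is more efficient.
#'
#' @param vRms root-mean-square volume, L.
#' @param paco2 arterial CO2 tension, mmHg.
#' @param weightKg body weight, kg.
#' @return V_C.
#' @export
ventilatoryCost <- function(vRms, paco2, weightKg) {
  if (weightKg <= 0) stop("weight must be positive")
  vRms^2 * paco2 / weightKg
}

#' Driving pressure and dynamic elastance
#'
#' Driving pressure dPaw = max - min of airway pressure over the analysis
#' window, and dynamic respiratory system elastance E_rs = dPaw / V_pp.
#' E_rs is meaningful only for CMV records, where pressure swings reflect
#' elastic distension; for oscillatory modalities it is returned as NA (the
#' pressure amplitude is dominated by resistive/inertial losses).
#'
#' @param record a [WaveformRecord-class].
#' @param window window length in s; default per modality.
#' @return list with `dPaw` (cmH2O) and `ers` (cmH2O/L; NA for non-CMV
#'   records or when V_pp = 0).
#' @export
drivingPressureElastance <- function(record, window = NULL) {
  stopifnot(is(record, "WaveformRecord"))
  i <- .analysisWindow(record, window)
  dPaw <- max(record@paw[i]) - min(record@paw[i])
  ers <- NA_real_
  if (record@modality == "CMV") {
    vpp <- max(record@volume[i]) - min(record@volume[i])
    if (vpp > 0) ers <- dPaw / vpp
  }
  list(dPaw = dPaw, ers = ers)
}

#' All ventilation outcomes for one record and gas panel
#'
#' Convenience wrapper collecting OI, V_rms, V_pp, dPaw, E_rs, V_C, and the
#' weight-normalized volumes for one subject-condition-modality cell.
#'
#' @param record a [WaveformRecord-class].
#' @param panel gas panel list (see [makeGasPanel()]).
#' @param pawMean mean airway pressure, cmH2O; defaults to the record's mean.
#' @return named list of outcomes.
#' @export
ventOutcomes <- function(record, panel, pawMean = mean(record@paw)) {
  vs <- volumeStats(record)
  dp <- drivingPressureElastance(record)
  list(oi = as.numeric(oxygenationIndex(panel, pawMean)),
       vRms = vs$vRms, vPp = vs$vPp, dPaw = dp$dPaw, ers = dp$ers,
       vc = ventilatoryCost(vs$vRms, panel$paco2, panel$weightKg),
       vPpPerKg = vs$vPp / panel$weightKg,
       vRmsPerKg = vs$vRms / panel$weightKg)
}
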