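#' Number of ventilatory phases
#' @param x an object holding a periodic phase dimension.
#' @return integer phase count N.
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' Voxel spacing in mm
#' @param x an object on a regular grid.
#' @return numeric(3) spacing.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Fundamental ventilation frequency in Hz
#' @param x an object with a fundamental frequency.
#' @return numeric scalar.
#' @export
setGeneric("fundamentalFreq", function(x) standardGeneric("fundamentalFreq"))

#' @describeIn nPhases phase count of an image sequence.
#' @export
setMethod("nPhases", "PeriodicImageSequence",
          function(x) dim(x@images)[4])
#' @describeIn nPhases phase count of a transform set.
#' @export
setMethod("nPhases", "TransformSet", function(x) dim(x@disp)[5])
#' @describeIn nPhases phase count of the metric series.
#' @export
setMethod("nPhases", "VoxelMetricMaps", function(x) dim(x@strain)[4])

#' @describeIn voxelSpacing spacing of an image sequence.
#' @export
setMethod("voxelSpacing", "PeriodicImageSequence", function(x) x@spacing)
#' @describeIn voxelSpacing spacing of a transform set.
#' @export
setMethod("voxelSpacing", "TransformSet", function(x) x@spacing)
#' @describeIn voxelSpacing spacing of metric maps.
#' @export
setMethod("voxelSpacing", "VoxelMetricMaps", function(x) x@spacing)

#' @describeIn fundamentalFreq of an image sequence.
#' @export
setMethod("fundamentalFreq", "PeriodicImageSequence", function(x) x@f0)
#' @describeIn fundamentalFreq of a transform set.
#' @export
setMethod("fundamentalFreq", "TransformSet", function(x) x@f0)
#' @describeIn fundamentalFreq of a waveform record.
#' @export
setMethod("fundamentalFreq", "WaveformRecord", function(x) x@f0)

#' Image array accessor
#' @param x a [PeriodicImageSequence-class].
#' @return 4D HU array (x, y, z, phase).
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))
#' @describeIn imageArray image accessor.
#' @export
setMethod("imageArray", "PeriodicImageSequence", function(x) x@images)

#' Mask array accessor
#' @param x an object carrying masks.
#' @param phase optional phase index (1-based); if missing, all phases.
#' @return logical array.
#' @export
setGeneric("maskArray", function(x, phase) standardGeneric("maskArray"))
#' @describeIn maskArray per-phase lung mask(s).
#' @export
setMethod("maskArray", "PeriodicImageSequence", function(x, phase) {
  if (missing(phase)) x@masks else x@masks[, , , phase, drop = TRUE]
})
#' @describeIn maskArray the analysis mask of metric maps.
#' @export
setMethod("maskArray", "VoxelMetricMaps", function(x, phase) x@mask)

#' Displacement field accessor
#' @param x a [TransformSet-class].
#' @param phase 1-based phase index; if missing, the full 5D array.
#' @return displacement array in mm, (x, y, z, 3[, phase]).
#' @export
setGeneric("displacement", function(x, phase) standardGeneric("displacement"))
#' @describeIn displacement displacement field(s) in mm.
#' @export
setMethod("displacement", "TransformSet", function(x, phase) {
  if (missing(phase)) return(x@disp)
  x@disp[, , , , ((phase - 1L) %% dim(x@disp)[5]) + 1L, drop = TRUE]
})

#' ROI labels accessor
#' @param x a [Decomposition-class].
#' @return integer 3D label array (0 outside the mask).
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @describeIn roiLabels label volume.
#' @export
setMethod("roiLabels", "Decomposition", function(x) x@labels)

#' Resistance (real part) of an impedance spectrum
#' @param x an [ImpedanceSpectrum-class].
#' @return numeric R_rs, cmH2O s/L.
#' @export
setGeneric("resistance", function(x) standardGeneric("resistance"))
#' @describeIn resistance real part of Z_rs.
#' @export
setMethod("resistance", "ImpedanceSpectrum", function(x) Re(x@Z))

#' Reactance (imaginary part) of an impedance spectrum
#' @param x an [ImpedanceSpectrum-class].
#' @return numeric X_rs, cmH2O s/L.
#' @export
setGeneric("reactance", function(x) standardGeneric("reactance"))
#' @describeIn reactance imaginary part of Z_rs.
#' @export
setMethod("reactance", "ImpedanceSpectrum", function(x) Im(x@Z))

#' Constant-phase parameters as a named vector
#' @param x a [ConstantPhaseFit-class].
#' @return named numeric: R, Iaw, eta, H, alpha.
#' @export
setGeneric("cpParams", function(x) standardGeneric("cpParams"))
#' @describeIn cpParams parameter vector.
#' @export
setMethod("cpParams", "ConstantPhaseFit", function(x)
  c(R = x@R, Iaw = x@Iaw, eta = x@eta, H = x@H, alpha = x@alpha))

setMethod("show", "PeriodicImageSequence", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "PeriodicImageSequence: %d x %d x %d voxels, %d phases\n  spacing %s mm, f0 %.3g Hz, %s / %s\n  lung voxels (phase 1): %d\n",
    d[1], d[2], d[3], d[4],
    paste(signif(object@spacing, 3), collapse = " x "),
    object@f0, object@modality, object@condition,
    sum(object@masks[, , , 1])))
})

setMethod("show", "TransformSet", function(object) {
  d <- dim(object@disp)
  cat(sprintf(
    "TransformSet: %d phases on a %d x %d x %d grid (spacing %s mm)\n  max |u| = %.3g mm\n",
    d[5], d[1], d[2], d[3],
    paste(signif(object@spacing, 3), collapse = " x "),
    max(abs(object@disp))))
})

setMethod("show", "VoxelMetricMaps", function(object) {
  m <- object@mask
  cat(sprintf(
    "VoxelMetricMaps: %d analysis voxels, %d phases, dt = %.4g s\n  mean aeration range %.1f HU, mean strain range %.4g, mean strain-rate range %.4g 1/s\n",
    sum(m), nPhases(object), object@dt,
    mean(object@aerationRange[m]), mean(object@strainRange[m]),
    mean(object@strainRateRange[m])))
})

setMethod("show", "HarmonicMaps", function(object) {
  cat(sprintf(
    "HarmonicMaps: K = %d harmonics of f0 = %.3g Hz; median-referenced phases\n",
    object@K, object@f0))
})

setMethod("show", "Decomposition", function(object) {
  cat(sprintf(
    "Decomposition (%s): %d ROIs over %d mask voxels; mean ROI fraction %.4g\n",
    object@method, nrow(object@census), object@maskSize,
    mean(object@census$size) / object@maskSize))
})

setMethod("show", "WaveformRecord", function(object) {
  cat(sprintf(
    "WaveformRecord (%s): %.3g s at %g Hz, f0 = %.3g Hz\n  Paw %.3g..%.3g cmH2O, V %.4g..%.4g L\n",
    object@modality, length(object@time) / object@fs, object@fs, object@f0,
    min(object@paw), max(object@paw), min(object@volume), max(object@volume)))
})

setMethod("show", "ImpedanceSpectrum", function(object) {
  cat(sprintf(
    "ImpedanceSpectrum: %d frequencies %.3g..%.3g Hz, min coherence %.4g\n",
    length(object@freq), min(object@freq), max(object@freq),
    min(object@coherence)))
})

setMethod("show", "ConstantPhaseFit", function(object) {
  cat(sprintf(
    "ConstantPhaseFit: R = %.4g, Iaw = %.4g, eta = %.4g, H = %.4g (alpha = %.4g)\n  residual norm %.4g, converged: %s\n",
    object@R, object@Iaw, object@eta, object@H, object@alpha,
    object@residualNorm, object@converged))
})
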