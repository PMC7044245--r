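#' @import methods
NULL

## Axis convention used throughout: array dimension 1 = right-left (x),
## 2 = dorsal-ventral (y, increasing ventral), 3 = caudal-rostral (z).
## Voxel (i, j, k) sits at world coordinate ((i,j,k) - 1) * spacing, in mm.

#' Periodic 4DCT image sequence
#'
#' Container for a phase-binned sequence of N volumetric images covering one
#' ventilatory cycle, with per-phase lung masks. Intensities are in Hounsfield
#' units. The fourth array dimension indexes ventilatory phase; the sequence is
#' periodic in that dimension, so phase indices are understood modulo N.
#'
#' @slot images numeric 4D array (x, y, z, phase), HU.
#' @slot masks logical 4D array, same dimensions; per-phase lung masks.
#' @slot spacing numeric(3), voxel size in mm per axis
#'   (right-left, dorsal-ventral, caudal-rostral).
#' @slot f0 fundamental ventilation frequency in Hz.
#' @slot modality one of `"CMV"`, `"HFOV"`, `"MFOV"`.
#' @slot condition one of `"baseline"`, `"injured"`.
#' @export
setClass("PeriodicImageSequence",
  representation(images = "array", masks = "array", spacing = "numeric",
                 f0 = "numeric", modality = "character",
                 condition = "character"))

setValidity("PeriodicImageSequence", function(object) {
  d <- dim(object@images)
  if (length(d) != 4L) return("images must be a 4D array (x, y, z, phase)")
  if (d[4] < 3L) return("need at least 3 phases per cycle")
  if (!identical(dim(object@masks), d)) return("masks must match images dims")
  if (!is.logical(object@masks)) return("masks must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  if (length(object@f0) != 1L || object@f0 <= 0)
    return("f0 must be a single positive frequency (Hz)")
  if (!object@modality %in% c("CMV", "HFOV", "MFOV"))
    return("modality must be CMV, HFOV or MFOV")
  if (!object@condition %in% c("baseline", "injured"))
    return("condition must be baseline or injured")
  TRUE
})

#' Set of periodic per-phase transformations
#'
#' Dense displacement fields u_n on the reference grid X, defining the mapping
#' phi_n(X) = X + u_n(X) from the reference frame to the frame of phase n.
#' Displacements are in mm, sampled at the reference grid voxel centres.
#'
#' @slot disp numeric 5D array (x, y, z, component, phase); component indexes
#'   the three displacement components in mm.
#' @slot spacing numeric(3), mm.
#' @slot f0 fundamental frequency in Hz.
#' @export
setClass("TransformSet",
  representation(disp = "array", spacing = "numeric", f0 = "numeric"))

setValidity("TransformSet", function(object) {
  d <- dim(object@disp)
  if (length(d) != 5L || d[4] != 3L)
    return("disp must be a 5D array (x, y, z, 3, phase)")
  if (!all(is.finite(object@disp))) return("displacement fields must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  TRUE
})

#' Pullback mapping between two phase frames
#'
#' The composed mapping T_{n->m}(x_m) = phi_n(phi_m^{-1}(x_m)) evaluated on the
#' m-frame grid, in world (mm) coordinates, together with a validity mask
#' marking voxels whose intermediate or target points left the image domain.
#'
#' @slot map numeric 4D array (x, y, z, 3): target world coordinates in mm.
#' @slot valid logical 3D array.
#' @slot spacing numeric(3), mm.
#' @export
setClass("PullbackMap",
  representation(map = "array", valid = "array", spacing = "numeric"))

setValidity("PullbackMap", function(object) {
  d <- dim(object@map)
  if (length(d) != 4L || d[4] != 3L)
    return("map must be a 4D array (x, y, z, 3)")
  if (!identical(dim(object@valid), d[1:3])) return("valid mask dims mismatch")
  TRUE
})

#' Jacobian field of a pullback mapping
#'
#' Per-voxel 3x3 Jacobian matrices of a mapping and their determinants.
#' The determinant is the local volume-change ratio: values below 1 indicate
#' deflation relative to the target frame, above 1 expansion, and exactly 1
#' isovolumetric deformation.
#'
#' @slot det numeric 3D array of determinants (NA where the map was invalid).
#' @slot J numeric 5D array (x, y, z, 3, 3) of Jacobian matrices, or a
#'   zero-length array if not retained.
#' @slot spacing numeric(3), mm.
#' @export
setClass("JacobianField",
  representation(det = "array", J = "array", spacing = "numeric"))

#' Ground truth bundled with a synthetic phantom
#'
#' Analytic ground truth for [makePhantom()]: exact transformations, analytic
#' Jacobian determinants to the reference (minimum-inflation) phase, the
#' per-voxel volume series, reference-phase tissue fraction, the static
#' amplitude field of the deformation, and the per-phase modulation waveform.
#' Tissue volume is conserved by construction: F_n * V_n = F_0 * deltaV at
#' every voxel and phase (noiselessly, to machine precision).
#'
#' @slot transforms a [TransformSet-class] with the exact displacement fields.
#' @slot detJ numeric 4D array (x, y, z, phase): analytic det J_{n->0} on the
#'   reference grid.
#' @slot volume numeric 4D array: V_n = deltaV * detJ, mm^3.
#' @slot tissueFraction numeric 3D array: F_0 in 0..1 at the reference phase.
#' @slot ampField numeric 3D array: local deformation amplitude a(X)
#'   (dimensionless); zero outside the lungs.
#' @slot modulation numeric(N): per-phase waveform g_n in 0..1, g_0 = 0.
#' @slot refMask logical 3D array: lung mask at the reference phase.
#' @slot rho numeric 3D array: elliptic radius about the nearest hilum
#'   (< 1 inside a lung); useful for selecting interior shells away from the
#'   fixed lung boundary.
#' @export
setClass("GroundTruth",
  representation(transforms = "TransformSet", detJ = "array",
                 volume = "array", tissueFraction = "array",
                 ampField = "array", modulation = "numeric",
                 refMask = "array", rho = "array"))

#' Per-voxel intratidal metric maps
#'
#' Reference-frame maps of aeration change, volumetric strain, and strain
#' rate, plus the underlying per-phase series. All maps are NA outside the
#' analysis mask.
#'
#' @slot aerationRange numeric 3D array: intratidal HU range per voxel.
#' @slot strain numeric 4D array (x, y, z, phase): strain series, referenced
#'   per voxel to its minimum volume over the cycle (so min_n strain = 0).
#' @slot strainRange numeric 3D array: max_n strain per voxel.
#' @slot strainRate numeric 4D array: periodic forward-difference strain rate,
#'   1/s.
#' @slot strainRateRange numeric 3D array: max - min strain rate, 1/s.
#' @slot volume numeric 4D array: per-voxel volume series V_n, mm^3.
#' @slot dt phase interval in s, 1/(f0 * N).
#' @slot mask logical 3D array: analysis mask (boundary-trimmed, valid voxels).
#' @slot spacing numeric(3), mm.
#' @export
setClass("VoxelMetricMaps",
  representation(aerationRange = "array", strain = "array",
                 strainRange = "array", strainRate = "array",
                 strainRateRange = "array", volume = "array",
                 dt = "numeric", mask = "array", spacing = "numeric"))

#' Per-voxel harmonic decomposition maps
#'
#' One-sided DFT amplitude and phase maps at harmonics k = 1..K of the
#' fundamental, plus a harmonic distortion index map. Phases are reported
#' relative to the per-harmonic median phase over lung voxels, wrapped to
#' (-pi, pi].
#'
#' @slot amplitude numeric 4D array (x, y, z, K).
#' @slot phase numeric 4D array (x, y, z, K), radians, median-referenced.
#' @slot hdi numeric 3D array: fraction of oscillatory spectral power above
#'   the fundamental, in 0..1 (NA where all amplitudes vanish).
#' @slot f0 fundamental frequency, Hz.
#' @slot K number of harmonics.
#' @slot medianPhase numeric(K): the subtracted per-harmonic median phase.
#' @export
setClass("HarmonicMaps",
  representation(amplitude = "array", phase = "array", hdi = "array",
                 f0 = "numeric", K = "integer", medianPhase = "numeric"))

#' Recursive heterogeneity decomposition
#'
#' Result of octree or supervoxel decomposition of a scalar field over a lung
#' mask. ROI labels partition the mask: every masked voxel carries exactly one
#' positive label and unmasked voxels are 0.
#'
#' @slot labels integer 3D array: ROI id per voxel (0 outside the mask).
#' @slot census data.frame with one row per ROI: `roi`, `size` (masked
#'   voxels), `sd` (population SD of the field over the ROI).
#' @slot method `"octree"` or `"supervoxel"`.
#' @slot maskSize total masked voxels.
#' @export
setClass("Decomposition",
  representation(labels = "array", census = "data.frame", method = "character",
                 maskSize = "integer"))

setValidity("Decomposition", function(object) {
  if (!object@method %in% c("octree", "supervoxel"))
    return("method must be octree or supervoxel")
  if (sum(object@census$size) != object@maskSize)
    return("ROI sizes must sum to the mask size (partition)")
  TRUE
})

#' Sampled ventilator waveform record
#'
#' Uniformly sampled airway pressure, flow, and volume at the airway opening.
#'
#' @slot time numeric, s.
#' @slot paw numeric, airway pressure, cmH2O.
#' @slot flow numeric, L/s.
#' @slot volume numeric, L.
#' @slot fs sampling rate, Hz.
#' @slot f0 fundamental frequency, Hz (breathing rate for CMV).
#' @slot modality `"CMV"`, `"HFOV"`, or `"MFOV"`.
#' @export
setClass("WaveformRecord",
  representation(time = "numeric", paw = "numeric", flow = "numeric",
                 volume = "numeric", fs = "numeric", f0 = "numeric",
                 modality = "character"))

setValidity("WaveformRecord", function(object) {
  n <- length(object@time)
  if (length(object@paw) != n || length(object@flow) != n ||
      length(object@volume) != n)
    return("time, paw, flow, volume must have equal length")
  if (n >= 2) {
    dt <- diff(object@time)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) return("sampling must be uniform")
  }
  if (object@fs <= 0 || object@f0 <= 0) return("fs and f0 must be positive")
  TRUE
})

#' Respiratory impedance spectrum
#'
#' Complex input impedance Z_rs = P/Q (cmH2O s/L) at the driving frequencies
#' of a forced-oscillation measurement, with ordinary coherence per frequency.
#'
#' @slot freq numeric, Hz.
#' @slot Z complex impedance.
#' @slot coherence numeric in 0..1.
#' @export
setClass("ImpedanceSpectrum",
  representation(freq = "numeric", Z = "complex", coherence = "numeric"))

setValidity("ImpedanceSpectrum", function(object) {
  if (length(object@Z) != length(object@freq) ||
      length(object@coherence) != length(object@freq))
    return("freq, Z, coherence lengths must match")
  if (any(object@coherence < -1e-9 | object@coherence > 1 + 1e-9))
    return("coherence must lie in [0, 1]")
  TRUE
})

#' Fitted constant-phase model
#'
#' Four-parameter constant-phase respiratory impedance model
#' Z(f) = R + j 2 pi f I_aw + (eta - j) H / (2 pi f)^alpha, with
#' alpha = (2/pi) atan(1/eta).
#'
#' @slot R Newtonian resistance, cmH2O s/L.
#' @slot Iaw airway inertance, cmH2O s^2/L.
#' @slot eta tissue hysteresivity (dimensionless).
#' @slot H tissue elastance, cmH2O/L at 1 rad/s.
#' @slot alpha derived exponent in (0, 1].
#' @slot residualNorm sum of squared complex residuals at the fit optimum.
#' @slot converged logical.
#' @slot freq frequencies used in the fit, Hz.
#' @slot Zfit model impedance at `freq`.
#' @export
setClass("ConstantPhaseFit",
  representation(R = "numeric", Iaw = "numeric", eta = "numeric",
                 H = "numeric", alpha = "numeric", residualNorm = "numeric",
                 converged = "logical", freq = "numeric", Zfit = "complex"))
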