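## Per-voxel intratidal metrics in the reference frame: aeration range,
## volumetric strain and strain rate, and their spatial summaries.

#' Trim the lung mask away from the axial field-of-view boundaries
#'
#' Removes mask voxels whose caudal-rostral world coordinate lies within
#' `trimMm` of either axial image boundary, where registration artifacts from
#' tissue moving into or out of the field of view are expected.
#'
#' @param mask logical 3D array.
#' @param spacing numeric(3) mm.
#' @param trimMm trim distance in mm (default 6.0; at 0.6 mm slices this
#'   removes 10 slices per end).
#' @return trimmed logical mask.
#' @export
trimMask <- function(mask, spacing, trimMm = 6.0) {
  stopifnot(length(dim(mask)) == 3L, trimMm >= 0)
  if (trimMm == 0) return(mask)
  nz <- dim(mask)[3]
  wz <- .worldAxis(nz, spacing[3])
  tol <- 1e-9 * max(trimMm, spacing[3])
  keep <- wz - wz[1] >= trimMm - tol & wz[nz] - wz >= trimMm - tol
  out <- mask
  out[, , !keep] <- FALSE
  if (!any(out))
    stop("mask is empty after boundary trimming; reduce trimMm")
  out
}

#' Intratidal aeration range per voxel
#'
#' The per-voxel range (max - min over phases) of HU intensity in images
#' aligned to the reference frame. Invalid (NA) samples are excluded per
#' voxel; voxels with fewer than 2 valid phases are flagged missing (NA).
#'
#' @param aligned numeric 4D array (x, y, z, phase) of aligned images, HU.
#' @param mask logical 3D array.
#' @return numeric 3D array of HU ranges, NA outside the mask, with attribute
#'   `"incomplete"`: logical 3D array marking masked voxels with at least one
#'   invalid phase sample.
#' @export
aerationRange <- function(aligned, mask) {
  stopifnot(length(dim(aligned)) == 4L,
            identical(dim(aligned)[1:3], dim(mask)))
  d <- dim(aligned)
  m <- matrix(aligned, nrow = prod(d[1:3]), ncol = d[4])
  nValid <- rowSums(is.finite(m))
  hi <- suppressWarnings(.rowMax(m, na.rm = TRUE))
  lo <- suppressWarnings(.rowMin(m, na.rm = TRUE))
  out <- hi - lo
  out[nValid < 2L] <- NA_real_
  out <- array(out, d[1:3])
  out[!mask] <- NA_real_
  incomplete <- array(nValid < d[4], d[1:3]) & mask
  attr(out, "incomplete") <- incomplete
  out
}

#' Per-voxel volumetric strain series and range
#'
#' Strain of each region relative to its own minimum-inflation state over the
#' cycle: strain_n = (V_n - min_n V_n) / min_n V_n, so min_n strain = 0 by
#' construction, and the strain range equals max_n strain.
#'
#' @param volume numeric 4D array (x, y, z, phase) of per-voxel volumes V_n
#'   (or, equivalently up to a constant factor, Jacobian determinants).
#' @param mask logical 3D array.
#' @return list with `strain` (4D array) and `range` (3D array), NA outside
#'   the mask.
#' @export
strainSeries <- function(volume, mask) {
  stopifnot(length(dim(volume)) == 4L,
            identical(dim(volume)[1:3], dim(mask)))
  d <- dim(volume)
  m <- matrix(volume, nrow = prod(d[1:3]), ncol = d[4])
  m[!mask, ] <- NA_real_
  vmin <- .rowMin(m)
  if (any(!is.na(vmin) & vmin <= 0))
    stop("non-positive minimum volume inside the mask (non-physical Jacobian)")
  eps <- (m - vmin) / vmin
  rng <- .rowMax(eps)
  rng[!is.finite(rng)] <- NA_real_
  list(strain = array(eps, d), range = array(rng, d[1:3]))
}

#' Per-voxel strain-rate series and range
#'
#' Periodic forward differences of the strain series:
#' rate_n = (strain_{(n+1) mod N} - strain_n) / dt with dt = 1/(f0 N). The
#' range max - min per voxel totals the fastest inflation plus the fastest
#' deflation rate. Over a full cycle the rates telescope to zero.
#'
#' @param strain numeric 4D array (x, y, z, phase).
#' @param dt phase interval in s (1 / (f0 * N)).
#' @return list with `rate` (4D array, 1/s) and `range` (3D array).
#' @export
strainRateSeries <- function(strain, dt) {
  d <- dim(strain)
  stopifnot(length(d) == 4L, d[4] >= 2L, dt > 0)
  nxt <- c(seq_len(d[4])[-1L], 1L)
  rate <- (strain[, , , nxt, drop = FALSE] - strain) / dt
  m <- matrix(rate, nrow = prod(d[1:3]), ncol = d[4])
  rng <- .rowMax(m) - .rowMin(m)
  rng[!is.finite(rng)] <- NA_real_
  list(rate = rate, range = array(rng, d[1:3]))
}

#' Spatial summary of a scalar field over the lung mask
#'
#' Mean, coefficient of variation (population SD / mean), and per-axis
#' spatial gradients. Each gradient is the OLS slope of the field value
#' against world coordinate along one anatomic axis, using every masked voxel
#' as one observation (three independent univariate regressions). Signed
#' slope, magnitude, and both divided by the spatial mean are reported.
#'
#' @param field numeric 3D array.
#' @param mask logical 3D array.
#' @param spacing numeric(3) mm.
#' @return list with `mean`, `cov`, and `gradients`: a data.frame with one
#'   row per axis (`right_left`, `dorsal_ventral`, `caudal_rostral`) and
#'   columns `slope` (per mm), `absSlope`, `normSlope`, `absNormSlope`
#'   (normalized values are NA when the spatial mean is 0).
#' @export
spatialSummary <- function(field, mask, spacing) {
  stopifnot(identical(dim(field), dim(mask)))
  sel <- mask & is.finite(field)
  v <- field[sel]
  if (length(v) < 2L) stop("need at least 2 finite masked voxels")
  mu <- mean(v)
  degenerate <- abs(mu) <= 1e-10 * max(.popSD(v), .Machine$double.eps)
  cv <- if (!degenerate) .popSD(v) / abs(mu) else NA_real_
  d <- dim(field)
  slope <- vapply(1:3, function(ax) {
    w <- .axisGrid(d, spacing, ax)[sel]
    vw <- stats::var(w)
    if (vw == 0) return(0)
    stats::cov(w, v) / vw
  }, numeric(1))
  norm <- if (!degenerate) slope / mu else rep(NA_real_, 3L)
  list(mean = mu, cov = cv,
       gradients = data.frame(
         axis = c("right_left", "dorsal_ventral", "caudal_rostral"),
         slope = slope, absSlope = abs(slope),
         normSlope = norm, absNormSlope = abs(norm)))
}

#' Full regional metric pipeline for one image sequence
#'
#' Aligns every phase to a reference phase via pullback composition, computes
#' the per-voxel aeration range, Jacobian-determinant volume series,
#' volumetric strain and strain-rate series and ranges, and the analysis
#' mask. The analysis mask is the reference-phase lung mask, boundary-trimmed
#' along the caudal-rostral axis, restricted to voxels valid at every phase
#' with positive Jacobian determinants.
#'
#' @param sequence a [PeriodicImageSequence-class].
#' @param transforms a [TransformSet-class] on the same grid.
#' @param refPhase reference phase index (1-based; default 1). The choice is
#'   arbitrary for range metrics, up to interpolation error.
#' @param trimMm axial boundary trim in mm (default 6).
#' @return a [VoxelMetricMaps-class].
#' @export
regionalMetrics <- function(sequence, transforms, refPhase = 1L,
                            trimMm = 6.0) {
  stopifnot(is(sequence, "PeriodicImageSequence"), is(transforms, "TransformSet"))
  .checkSameGeometry(dim(sequence@images)[1:3], sequence@spacing,
                     dim(transforms@disp)[1:3], transforms@spacing,
                     "images and transforms")
  N <- nPhases(sequence)
  if (nPhases(transforms) != N) stop("phase count mismatch")
  d <- dim(sequence@images)[1:3]
  spacing <- sequence@spacing
  deltaV <- prod(spacing)
  dt <- 1 / (sequence@f0 * N)

  invRef <- invertTransform(transforms, phase = refPhase)
  aligned <- array(NA_real_, c(d, N))
  det <- array(NA_real_, c(d, N))
  valid <- array(TRUE, d)
  for (n in seq_len(N)) {
    pb <- composePullback(transforms, n, refPhase, inverseM = invRef)
    aligned[, , , n] <- warpImage(sequence@images[, , , n], pb)
    det[, , , n] <- jacobianField(pb)@det
    valid <- valid & pb@valid
  }
  mask <- trimMask(maskArray(sequence, refPhase), spacing, trimMm)
  mask <- mask & valid
  detOK <- matrix(det, nrow = prod(d), ncol = N)
  mask <- mask & array(rowSums(!is.finite(detOK) | detOK <= 0) == 0L, d)
  if (!any(mask)) stop("analysis mask is empty")

  dI <- aerationRange(aligned, mask)
  attr(dI, "incomplete") <- NULL
  st <- strainSeries(det * deltaV, mask)
  sr <- strainRateSeries(st$strain, dt)

  new("VoxelMetricMaps", aerationRange = dI, strain = st$strain,
      strainRange = st$range, strainRate = sr$rate,
      strainRateRange = sr$range, volume = det * deltaV, dt = dt,
      mask = mask, spacing = spacing)
}
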