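## Synthetic 4D deforming-lung phantom with analytic ground truth.
##
## Geometry: two ellipsoidal lungs inside an elliptic body cylinder. Each lung
## deforms by a radial expansion about its hilum h with a spatially varying
## amplitude field a(X):
##     u_n(X) = g_n * a(X) * (X - h),     phi_n(X) = X + u_n(X)
## where g_n in [0, 1] is the modality volume-waveform modulation (rotated so
## that phase 1 is the minimum-inflation phase, g_1 = 0, making phi at the
## reference phase the identity). The amplitude field is
##     a(X) = A * m(y) * t(rho),   t(rho) = cos^2(pi rho / 2) for rho < 1
## with rho the elliptic radius about the hilum (so the lung boundary is
## fixed, as against the chest wall), and m(y) the dorsal-ventral modulation
## (1 + G * yhat) times a smooth consolidation ramp w(y) that suppresses
## deformation in the dorsal consolidated region of injured lungs.
##
## Because a depends on X only through rho and y, the Jacobian determinant is
## closed-form: with c = 1 + g a and d = grad(a) . (X - h),
##     det J_n(X) = c^2 * (c + g * d),
##     d = A * [ m'(y) t (y - h_y) + m(y) t'(rho) rho ].
##
## Intensity model (gas/tissue mixture): I = -1000 (1 - F) + 40 F HU with
## tissue fraction F_n = F_0 / det J_n, which conserves per-voxel tissue
## volume F_n * V_n = F_0 * deltaV exactly.

#' Phantom configuration
#'
#' Builds and validates the configuration for [makePhantom()].
#'
#' @param gridShape integer(3): voxels per axis
#'   (right-left, dorsal-ventral, caudal-rostral).
#' @param spacing voxel size in mm (isotropic scalar or length-3).
#' @param N phases per ventilatory cycle (>= 3; 21 emulates the densest
#'   phase binning used in practice).
#' @param f0 fundamental frequency in Hz (5 for HFOV/MFOV; 0.33-0.53 for CMV).
#' @param modality `"CMV"`, `"HFOV"`, or `"MFOV"`.
#' @param condition `"baseline"` or `"injured"`.
#' @param strainAmplitude peak fractional volume excursion of the most
#'   compliant tissue; defaults to [defaultStrainAmplitude()] for the
#'   modality.
#' @param dvGradient fractional modulation of deformation amplitude along the
#'   dorsal-ventral axis (amplitude scales with 1 + dvGradient * yhat,
#'   yhat in -1..1 from dorsal to ventral); |dvGradient| < 1.
#' @param consolidationFraction fraction of the dorsal lung rendered
#'   non-deforming and airless (injured condition only; 0 <= f < 1).
#' @param noiseSdHu additive Gaussian intensity noise SD in HU.
#' @param aeratedTissueFraction tissue fraction of aerated lung at the
#'   reference phase (default 0.2, about -790 HU).
#' @param seed RNG seed for the intensity noise.
#' @return a validated `PhantomConfig` list.
#' @export
phantomConfig <- function(gridShape = c(48L, 48L, 48L), spacing = 0.6,
                          N = 21L, f0 = 5, modality = "HFOV",
                          condition = "baseline",
                          strainAmplitude = defaultStrainAmplitude(modality),
                          dvGradient = 0.3,
                          consolidationFraction =
                            if (condition == "injured") 0.4 else 0,
                          noiseSdHu = 5, aeratedTissueFraction = 0.2,
                          seed = 1L) {
  modality <- match.arg(modality, c("CMV", "HFOV", "MFOV"))
  condition <- match.arg(condition, c("baseline", "injured"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 8L),
            length(spacing) == 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (N < 3L) stop("need at least N = 3 phases per cycle")
  if (f0 <= 0) stop("f0 must be positive")
  if (strainAmplitude < 0) stop("strainAmplitude must be non-negative")
  if (abs(dvGradient) >= 1) stop("|dvGradient| must be < 1")
  if (consolidationFraction < 0 || consolidationFraction >= 1)
    stop("consolidationFraction must be in [0, 1)")
  if (consolidationFraction > 0 && condition == "baseline")
    stop("consolidation requested at baseline: set condition = \"injured\"")
  if (noiseSdHu < 0) stop("noiseSdHu must be non-negative")
  if (aeratedTissueFraction <= 0 || aeratedTissueFraction >= 1)
    stop("aeratedTissueFraction must be in (0, 1)")
  structure(list(gridShape = gridShape, spacing = spacing, N = as.integer(N),
                 f0 = f0, modality = modality, condition = condition,
                 strainAmplitude = strainAmplitude, dvGradient = dvGradient,
                 consolidationFraction = consolidationFraction,
                 noiseSdHu = noiseSdHu,
                 aeratedTissueFraction = aeratedTissueFraction,
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

#' @export
print.PhantomConfig <- function(x, ...) {
  cat(sprintf(
    "PhantomConfig: %s grid, %d phases, f0 %.3g Hz, %s/%s\n  strainAmplitude %.4g, dvGradient %.3g, consolidation %.3g, noise %.3g HU, seed %d\n",
    paste(x$gridShape, collapse = "x"), x$N, x$f0, x$modality, x$condition,
    x$strainAmplitude, x$dvGradient, x$consolidationFraction, x$noiseSdHu,
    x$seed))
  invisible(x)
}

## Geometry derived from a config: body ellipse, two lungs, consolidation ramp.
.phantomGeom <- function(cfg) {
  L <- (cfg$gridShape - 1) * cfg$spacing
  ctr <- L / 2
  semi <- c(0.16 * L[1], 0.30 * L[2], 0.38 * L[3])
  hila <- list(c(ctr[1] - 0.22 * L[1], ctr[2], ctr[3]),
               c(ctr[1] + 0.22 * L[1], ctr[2], ctr[3]))
  yThr <- (ctr[2] - semi[2]) + cfg$consolidationFraction * 2 * semi[2]
  list(L = L, ctr = ctr, body = 0.46 * L[1:2], semi = semi, hila = hila,
       A = (1 + cfg$strainAmplitude)^(1 / 3) - 1,
       G = cfg$dvGradient, yThr = yThr, sigma = 2 * cfg$spacing[2],
       Faer = cfg$aeratedTissueFraction,
       injured = cfg$condition == "injured" && cfg$consolidationFraction > 0)
}

## Smooth consolidation ramp w(y) (0 in the dorsal consolidated zone,
## 1 ventrally) and its derivative.
.consolidationRamp <- function(geom, py) {
  if (!geom$injured)
    return(list(w = rep(1, length(py)), dw = rep(0, length(py))))
  s <- pmin(pmax((py - geom$yThr) / (2 * geom$sigma) + 0.5, 0), 1)
  list(w = s^2 * (3 - 2 * s), dw = 6 * s * (1 - s) / (2 * geom$sigma))
}

## Evaluate phantom fields at arbitrary world points (vectors px, py, pz).
## Returns amplitude a, its radial pairing d = grad(a).(X - h), the summed
## lung offset terms, tissue fraction F0, and lung membership.
.phantomFields <- function(geom, px, py, pz) {
  n <- length(px)
  a <- numeric(n); d <- numeric(n)
  ex <- numeric(n); ey <- numeric(n); ez <- numeric(n)
  inLung <- logical(n)
  rhoMin <- rep(Inf, n)
  ramp <- .consolidationRamp(geom, py)
  for (h in geom$hila) {
    rx <- px - h[1]; ry <- py - h[2]; rz <- pz - h[3]
    rho <- sqrt((rx / geom$semi[1])^2 + (ry / geom$semi[2])^2 +
                (rz / geom$semi[3])^2)
    rhoMin <- pmin(rhoMin, rho)
    inside <- rho < 1
    if (!any(inside)) next
    tfun <- numeric(n); tprime <- numeric(n)
    tfun[inside] <- cos(pi * rho[inside] / 2)^2
    tprime[inside] <- -(pi / 2) * sin(pi * rho[inside])
    yhat <- ry / geom$semi[2]
    m <- (1 + geom$G * yhat) * ramp$w
    mprime <- (geom$G / geom$semi[2]) * ramp$w + (1 + geom$G * yhat) * ramp$dw
    aL <- geom$A * m * tfun
    dL <- geom$A * (mprime * tfun * ry + m * tprime * rho)
    a[inside] <- a[inside] + aL[inside]
    d[inside] <- d[inside] + dL[inside]
    ex[inside] <- ex[inside] + aL[inside] * rx[inside]
    ey[inside] <- ey[inside] + aL[inside] * ry[inside]
    ez[inside] <- ez[inside] + aL[inside] * rz[inside]
    inLung <- inLung | inside
  }
  inBody <- ((px - geom$ctr[1]) / geom$body[1])^2 +
            ((py - geom$ctr[2]) / geom$body[2])^2 <= 1
  F0 <- ifelse(inLung, 1 - ramp$w * (1 - geom$Faer), ifelse(inBody, 1, 0))
  list(a = a, d = d, ax = ex, ay = ey, az = ez, F0 = F0, inLung = inLung,
       rho = rhoMin)
}

## Displacement (mm) at world points for modulation value g.
.phantomDisp <- function(geom, px, py, pz, g) {
  f <- .phantomFields(geom, px, py, pz)
  list(ux = g * f$ax, uy = g * f$ay, uz = g * f$az)
}

## Analytic det J at world points for modulation value g.
.phantomDet <- function(geom, px, py, pz, g) {
  f <- .phantomFields(geom, px, py, pz)
  cc <- 1 + g * f$a
  cc^2 * (cc + g * f$d)
}

## Invert x = X + u(X) by fixed-point iteration with analytic u evaluation.
.phantomInverse <- function(geom, px, py, pz, g, tol = 1e-6, maxIter = 60L) {
  X <- px; Y <- py; Z <- pz
  for (i in seq_len(maxIter)) {
    u <- .phantomDisp(geom, X, Y, Z, g)
    nx <- px - u$ux; ny <- py - u$uy; nz <- pz - u$uz
    delta <- max(abs(nx - X), abs(ny - Y), abs(nz - Z))
    X <- nx; Y <- ny; Z <- nz
    if (delta < tol) break
  }
  list(x = X, y = Y, z = Z)
}

#' Generate a synthetic 4D deforming-lung phantom
#'
#' Produces a periodic image sequence (HU intensities, per-phase lung masks)
#' together with exact ground truth: the analytic per-phase transformations,
#' analytic Jacobian determinants relative to the reference phase, per-voxel
#' volume series, and the reference tissue-fraction field. The reference
#' phase (index 1) is the minimum-inflation phase, at which the
#' transformation is the identity. Per-voxel tissue volume is conserved
#' across phases by construction.
#'
#' @param config a [phantomConfig()] object.
#' @return a list with elements `sequence` (a [PeriodicImageSequence-class])
#'   and `truth` (a [GroundTruth-class]).
#' @examples
#' ph <- makePhantom(phantomConfig(gridShape = c(24, 24, 24), N = 6,
#'                                 noiseSdHu = 0))
#' ph$sequence
#' range(ph$truth@detJ)
#' @export
makePhantom <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  cfg <- config
  geom <- .phantomGeom(cfg)
  d <- cfg$gridShape
  g <- .modulation(cfg$modality, cfg$N)
  wx <- .worldAxis(d[1], cfg$spacing[1])
  wy <- .worldAxis(d[2], cfg$spacing[2])
  wz <- .worldAxis(d[3], cfg$spacing[3])
  px <- rep(wx, times = d[2] * d[3])
  py <- rep(rep(wy, each = d[1]), times = d[3])
  pz <- rep(wz, each = d[1] * d[2])

  ref <- .phantomFields(geom, px, py, pz)
  deltaV <- prod(cfg$spacing)

  ## analytic ground truth on the reference grid
  detJ <- array(NA_real_, c(d, cfg$N))
  disp <- array(0, c(d, 3L, cfg$N))
  for (n in seq_len(cfg$N)) {
    cc <- 1 + g[n] * ref$a
    dn <- cc^2 * (cc + g[n] * ref$d)
    if (min(dn) <= 0) {
      bad <- which.min(dn)
      stop(sprintf(
        "deformation pushes det J <= 0 (min %.4g at voxel linear index %d, phase %d); reduce strainAmplitude or dvGradient",
        min(dn), bad, n))
    }
    detJ[, , , n] <- dn
    disp[, , , 1L, n] <- g[n] * ref$ax
    disp[, , , 2L, n] <- g[n] * ref$ay
    disp[, , , 3L, n] <- g[n] * ref$az
  }

  ## render images and masks in each phase's own frame
  set.seed(cfg$seed)
  images <- array(NA_real_, c(d, cfg$N))
  masks <- array(FALSE, c(d, cfg$N))
  for (n in seq_len(cfg$N)) {
    if (g[n] == 0) {
      X <- list(x = px, y = py, z = pz)
    } else {
      X <- .phantomInverse(geom, px, py, pz, g[n])
    }
    fX <- .phantomFields(geom, X$x, X$y, X$z)
    cc <- 1 + g[n] * fX$a
    dn <- cc^2 * (cc + g[n] * fX$d)
    Fn <- pmin(pmax(fX$F0 / dn, 0), 1)
    hu <- -1000 * (1 - Fn) + 40 * Fn
    if (cfg$noiseSdHu > 0)
      hu <- hu + stats::rnorm(length(hu), sd = cfg$noiseSdHu)
    images[, , , n] <- hu
    masks[, , , n] <- fX$inLung
  }

  seq4d <- new("PeriodicImageSequence", images = images, masks = masks,
               spacing = cfg$spacing, f0 = cfg$f0, modality = cfg$modality,
               condition = cfg$condition)
  tset <- new("TransformSet", disp = disp, spacing = cfg$spacing, f0 = cfg$f0)
  truth <- new("GroundTruth", transforms = tset, detJ = detJ,
               volume = detJ * deltaV,
               tissueFraction = array(ref$F0, d),
               ampField = array(ref$a, d), modulation = g,
               refMask = array(ref$inLung, d), rho = array(ref$rho, d))
  list(sequence = seq4d, truth = truth)
}

#' Synthetic arterial blood-gas panel
#'
#' Draws a plausible blood-gas panel for a synthetic subject under the given
#' condition and modality, emulating the study protocol: FiO2 0.40 at
#' baseline (raised to 0.60 after injury to hold SpO2 >= 90%), PaO2:FiO2
#' above 300 mmHg at baseline and below after oleic-acid-like injury, and
#' PaCO2 titrated into the 30-60 mmHg eucapnia band.
#'
#' @param condition `"baseline"` or `"injured"`.
#' @param modality `"CMV"`, `"HFOV"`, or `"MFOV"`.
#' @param weightKg body weight in kg (study animals were 9-13 kg).
#' @return a list with `pao2` (mmHg), `paco2` (mmHg), `fio2` (fraction),
#'   `spo2` (%), `weightKg`.
#' @export
makeGasPanel <- function(condition = "baseline", modality = "CMV",
                         weightKg = 11) {
  condition <- match.arg(condition, c("baseline", "injured"))
  modality <- match.arg(modality, c("CMV", "HFOV", "MFOV"))
  if (condition == "baseline") {
    fio2 <- 0.40
    pao2 <- stats::rnorm(1, 180, 15)
    spo2 <- stats::rnorm(1, 98, 0.5)
  } else {
    fio2 <- 0.60
    pao2 <- stats::rnorm(1, 75, 8)
    spo2 <- stats::rnorm(1, 92, 1.5)
  }
  paco2 <- stats::rnorm(1, switch(modality, CMV = 40, HFOV = 46, MFOV = 42), 3)
  list(pao2 = max(pao2, 40), paco2 = min(max(paco2, 30), 60), fio2 = fio2,
       spo2 = min(spo2, 100), weightKg = weightKg)
}
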