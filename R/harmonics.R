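## Per-voxel DFT harmonic decomposition of periodic metric series and
## harmonic-distortion quantification.

## One-sided DFT amplitudes/phases of rows of a matrix (one period per row).
## Returns K columns; A_k = (2/N) |X_k| except at the Nyquist bin of an even
## N, where A = |X|/N (its power contributes A^2, not A^2/2).
.dftRows <- function(m, K) {
  N <- ncol(m)
  n <- 0:(N - 1)
  amp <- matrix(NA_real_, nrow(m), K)
  phs <- matrix(NA_real_, nrow(m), K)
  for (k in seq_len(K)) {
    e <- exp(-2i * pi * k * n / N)
    Xk <- m %*% e
    scale <- if (2L * k == N) 1 / N else 2 / N
    amp[, k] <- scale * Mod(Xk)
    phs[, k] <- Arg(Xk)
  }
  list(amplitude = amp, phase = phs)
}

#' Per-voxel harmonic amplitude and phase maps
#'
#' Decomposes a periodic per-voxel series (one ventilatory cycle, N phases)
#' into one-sided DFT amplitudes and phases at harmonics k = 1..K of the
#' fundamental. Phase maps are reported relative to the per-harmonic median
#' phase over lung voxels, wrapped to (-pi, pi], so a voxel leading the bulk
#' of the lung has positive phase. A harmonic distortion index map (fraction
#' of oscillatory spectral power above the fundamental) is included.
#'
#' @param series numeric 4D array (x, y, z, phase), e.g. the strain series of
#'   a [VoxelMetricMaps-class], or aligned intensities or strain rates.
#' @param mask logical 3D array.
#' @param f0 fundamental frequency, Hz.
#' @param K number of harmonics (default 4, the 5/10/15/20 Hz analysis band
#'   at a 5 Hz fundamental). Requires N > 2K.
#' @return a [HarmonicMaps-class].
#' @export
dftMaps <- function(series, mask, f0, K = 4L) {
  d <- dim(series)
  stopifnot(length(d) == 4L, identical(d[1:3], dim(mask)))
  N <- d[4]
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (2L * K >= N)
    stop("K = ", K, " harmonics alias with only ", N, " phases (need N > 2K)")
  sel <- which(mask)
  m <- matrix(series, nrow = prod(d[1:3]), ncol = N)[sel, , drop = FALSE]
  ft <- .dftRows(m, K)
  medPhase <- vapply(seq_len(K), function(k)
    stats::median(ft$phase[, k], na.rm = TRUE), numeric(1))
  refPhase <- .wrapPi(sweep(ft$phase, 2L, medPhase))
  power <- ft$amplitude^2
  tot <- rowSums(power)
  hdi <- ifelse(tot > 0, rowSums(power[, -1L, drop = FALSE]) / tot, NA_real_)

  amp <- array(NA_real_, c(d[1:3], K))
  phase <- array(NA_real_, c(d[1:3], K))
  nvox <- prod(d[1:3])
  for (k in seq_len(K)) {
    amp[sel + (k - 1L) * nvox] <- ft$amplitude[, k]
    phase[sel + (k - 1L) * nvox] <- refPhase[, k]
  }
  hdiMap <- array(NA_real_, d[1:3])
  hdiMap[sel] <- hdi
  new("HarmonicMaps", amplitude = amp, phase = phase, hdi = hdiMap,
      f0 = f0, K = K, medianPhase = medPhase)
}

#' Harmonic distortion index
#'
#' Fraction of a periodic signal's oscillatory spectral power residing above
#' the fundamental: HDI = sum_{k>=2} A_k^2 / sum_{k>=1} A_k^2 (`"power"`,
#' the default). The root-power alternative
#' THD = sqrt(sum_{k>=2} A_k^2) / A_1 is available as `type = "root"`.
#' HDI is invariant to overall amplitude scaling and 0 for a pure
#' fundamental.
#'
#' @param amplitudes numeric vector of harmonic amplitudes A_1..A_K (K >= 2),
#'   or a matrix with one row per observation.
#' @param type `"power"` (bounded in 0..1) or `"root"` (unbounded).
#' @return HDI value(s); NA where all amplitudes are zero.
#' @export
harmonicDistortion <- function(amplitudes, type = c("power", "root")) {
  type <- match.arg(type)
  m <- if (is.matrix(amplitudes)) amplitudes else matrix(amplitudes, nrow = 1)
  if (ncol(m) < 2L) stop("need at least 2 harmonic amplitudes")
  p <- m^2
  tot <- rowSums(p)
  out <- switch(type,
    power = ifelse(tot > 0, rowSums(p[, -1L, drop = FALSE]) / tot, NA_real_),
    root = ifelse(m[, 1L] > 0,
                  sqrt(rowSums(p[, -1L, drop = FALSE])) / m[, 1L], NA_real_))
  if (!is.matrix(amplitudes)) out <- out[[1L]]
  out
}

#' Harmonic content of a ventilator waveform
#'
#' DFT amplitudes of the airway-opening volume waveform (or flow/pressure) at
#' harmonics k*f0, computed over an integer number of fundamental cycles.
#' Records spanning a non-integer cycle count are trimmed to the largest
#' integer number of cycles, with a warning.
#'
#' @param record a [WaveformRecord-class].
#' @param K number of harmonics (default 4).
#' @param channel `"volume"` (default), `"flow"`, or `"paw"`.
#' @return list with `freq` (Hz), `amplitude`, `phase`, and `hdi` (power
#'   fraction above the fundamental).
#' @export
waveformHarmonics <- function(record, K = 4L, channel = "volume") {
  stopifnot(is(record, "WaveformRecord"))
  channel <- match.arg(channel, c("volume", "flow", "paw"))
  x <- slot(record, channel)
  sampPerCyc <- record@fs / record@f0
  ncyc <- floor(length(x) / sampPerCyc)
  if (ncyc < 1L) stop("record shorter than one fundamental cycle")
  nUse <- round(ncyc * sampPerCyc)
  if (nUse < length(x)) {
    warning("record trimmed to ", ncyc, " whole cycles for the DFT")
    x <- x[seq_len(nUse)]
  }
  X <- stats::fft(x)
  bins <- seq_len(K) * ncyc + 1L
  if (max(bins) > floor(length(x) / 2) + 1L)
    stop("K harmonics exceed the Nyquist frequency of the record")
  amp <- 2 * Mod(X[bins]) / length(x)
  phs <- Arg(X[bins])
  list(freq = seq_len(K) * record@f0, amplitude = amp, phase = phs,
       hdi = harmonicDistortion(amp))
}
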