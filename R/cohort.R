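## Synthetic cohort: phantom-derived image metrics plus waveform/gas-exchange
## outcomes for n subjects x 2 conditions x 3 modalities, emulating the
## study design for the statistics pipeline.

## Flow amplitude giving an oscillatory record a target volume rms (L).
.flowAmpForVrms <- function(modality, f0, targetVrms) {
  k <- if (modality == "MFOV") 1:4 else 1L
  ## per unit flow amplitude, volume rms = sqrt(sum_k (1/(2 pi k f0))^2 / 2)
  unitRms <- sqrt(sum((1 / (2 * pi * k * f0))^2) / 2)
  targetVrms / unitRms
}

#' Simulate a study cohort outcome table
#'
#' Runs the full image pipeline once per condition x modality cell on a
#' phantom, synthesises matching ventilator waveforms (volume delivery scaled
#' to the eucapnia-titrated V_rms ratios across modalities) and per-subject
#' blood-gas panels, and assembles an outcome table with one row per
#' subject x condition x modality. Between-subject variability is emulated
#' by multiplicative lognormal scatter on the image-derived metrics
#' (coefficient of variation `subjectCV`) plus the per-subject gas draws;
#' within-cell image metrics therefore share one phantom realisation per
#' cell, which keeps the table cheap while preserving the cell contrasts.
#'
#' @param nSubjects synthetic subjects (default 10).
#' @param gridShape phantom grid (default 32^3 for speed).
#' @param N phases per cycle (default 8).
#' @param trimMm axial boundary trim passed to [regionalMetrics()]; default
#'   1.5 mm, scaled to the small grid.
#' @param subjectCV between-subject lognormal coefficient of variation.
#' @param noiseSdHu phantom intensity noise, HU.
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `condition`, `modality` and
#'   outcomes `deltaI_mean`, `deltaEps_mean`, `deltaEps_cov`,
#'   `deltaEps_dvGradient`, `deltaEpsdot_mean`, `vROI_octree`, `oi`, `vc`,
#'   `vRms`, `vPp`, `dPaw`.
#' @export
simulateCohort <- function(nSubjects = 10L, gridShape = c(32L, 32L, 32L),
                           N = 8L, trimMm = 1.5, subjectCV = 0.15,
                           noiseSdHu = 5, seed = 1L) {
  set.seed(seed)
  conditions <- c("baseline", "injured")
  modalities <- c("CMV", "HFOV", "MFOV")
  cmvRec <- makeWaveform("CMV", f0 = 0.4, duration = 10, fs = 200)
  cmvVrms <- volumeStats(cmvRec)$vRms
  vrmsRatio <- c(CMV = 1, HFOV = 0.42, MFOV = 0.25)

  cellMetrics <- list()
  for (cond in conditions) for (mod in modalities) {
    cfg <- phantomConfig(gridShape = gridShape, N = N,
                         f0 = if (mod == "CMV") 0.4 else 5,
                         modality = mod, condition = cond,
                         noiseSdHu = noiseSdHu,
                         seed = sample.int(1e6, 1L))
    ph <- makePhantom(cfg)
    vm <- regionalMetrics(ph$sequence, ph$truth@transforms, trimMm = trimMm)
    msk <- maskArray(vm)
    eps <- vm@strainRange
    ss <- spatialSummary(eps, msk, vm@spacing)
    ssI <- spatialSummary(vm@aerationRange, msk, vm@spacing)
    ssR <- spatialSummary(vm@strainRateRange, msk, vm@spacing)
    oct <- octreeDecompose(eps / ss$mean, msk)
    cellMetrics[[paste(cond, mod)]] <- c(
      deltaI_mean = ssI$mean, deltaEps_mean = ss$mean,
      deltaEps_cov = ss$cov,
      deltaEps_dvGradient = ss$gradients$slope[2],
      deltaEpsdot_mean = ssR$mean,
      vROI_octree = clusterStats(oct)$vROI)
  }

  rows <- list()
  for (s in seq_len(nSubjects)) {
    wt <- stats::runif(1, 9, 13)
    for (cond in conditions) for (mod in modalities) {
      base <- cellMetrics[[paste(cond, mod)]]
      jitter <- stats::rlnorm(length(base),
                              meanlog = -0.5 * log(1 + subjectCV^2),
                              sdlog = sqrt(log(1 + subjectCV^2)))
      met <- base * jitter
      panel <- makeGasPanel(cond, mod, weightKg = wt)
      rec <- if (mod == "CMV") cmvRec else
        makeWaveform(mod, f0 = 5,
                     amplitudeSpec = list(flowAmplitude =
                       .flowAmpForVrms(mod, 5, vrmsRatio[[mod]] * cmvVrms)),
                     duration = 2, fs = 500)
      vo <- ventOutcomes(rec, panel)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, condition = cond, modality = mod, t(met),
        oi = vo$oi * stats::rlnorm(1, 0, 0.1),
        vc = vo$vc * stats::rlnorm(1, 0, 0.1),
        vRms = vo$vRms, vPp = vo$vPp, dPaw = vo$dPaw)
    }
  }
  out <- do.call(rbind, rows)
  out$condition <- factor(out$condition, levels = conditions)
  out$modality <- factor(out$modality, levels = modalities)
  out
}
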