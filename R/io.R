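## File IO: NIfTI volumes and displacement fields, CSV waveform records with
## a JSON metadata sidecar.

#' Write a volumetric image or displacement field to NIfTI
#'
#' Scalar volumes are 3D arrays; displacement fields are 4D arrays with three
#' components in the fourth dimension (mm). Data are stored as float64, so a
#' read-back round trip reproduces voxel values and axis order bit-exactly
#' (spacing at the float32 precision of the NIfTI header).
#'
#' @param data numeric 3D or 4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing numeric(3) voxel size in mm.
#' @return the path, invisibly.
#' @export
writeVolume <- function(data, path, spacing) {
  nd <- length(dim(data))
  stopifnot(nd %in% c(3L, 4L), length(spacing) == 3L)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- if (nd == 3L) spacing else c(spacing, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a volumetric image or displacement field from NIfTI
#'
#' @param path a `.nii`/`.nii.gz` file.
#' @return list with `data` (array) and `spacing` (numeric(3), mm).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  ## pixdim is stored as float32 in the NIfTI header; strip the cast noise
  list(data = data, spacing = signif(unname(RNifti::pixdim(img)[1:3]), 7))
}

#' Read a displacement field, enforcing the 3-component contract
#'
#' @param path a NIfTI file holding a 4D array (x, y, z, component).
#' @return list with `data` (4D array, 3 components, mm) and `spacing`.
#' @export
readDisplacementField <- function(path) {
  vol <- readVolume(path)
  d <- dim(vol$data)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement fields must be 4D with exactly 3 components, got ",
         paste(d, collapse = "x"))
  vol
}

#' Check two volumes share a grid geometry
#'
#' Errors when dimensions or spacing differ (e.g. an image paired with a
#' mask from a different reconstruction).
#'
#' @param volA,volB lists as returned by [readVolume()], or arrays (then
#'   give `spacingA`/`spacingB`).
#' @param spacingA,spacingB spacing vectors for raw arrays.
#' @return TRUE, invisibly.
#' @export
checkSameGeometry <- function(volA, volB, spacingA = NULL, spacingB = NULL) {
  dA <- if (is.list(volA)) dim(volA$data) else dim(volA)
  dB <- if (is.list(volB)) dim(volB$data) else dim(volB)
  sA <- if (is.list(volA)) volA$spacing else spacingA
  sB <- if (is.list(volB)) volB$spacing else spacingB
  .checkSameGeometry(dA[1:3], sA, dB[1:3], sB)
}

#' Write a waveform record to CSV with a JSON sidecar
#'
#' Columns are `time_s`, `paw_cmH2O`, `flow_Lps`, `vol_L`. Sampling rate,
#' fundamental frequency, and modality go to `<path>.json`.
#'
#' @param record a [WaveformRecord-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeWaveform <- function(record, path) {
  stopifnot(is(record, "WaveformRecord"))
  utils::write.csv(data.frame(time_s = record@time, paw_cmH2O = record@paw,
                              flow_Lps = record@flow, vol_L = record@volume),
                   path, row.names = FALSE)
  jsonlite::write_json(list(fs = record@fs, f0 = record@f0,
                            modality = record@modality),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a waveform record written by [writeWaveform()]
#'
#' @param path the CSV path (its `.json` sidecar must sit alongside).
#' @return a [WaveformRecord-class].
#' @export
readWaveform <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing metadata sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  need <- c("time_s", "paw_cmH2O", "flow_Lps", "vol_L")
  if (!all(need %in% names(df)))
    stop("waveform CSV must have columns ", paste(need, collapse = ", "))
  new("WaveformRecord", time = df$time_s, paw = df$paw_cmH2O,
      flow = df$flow_Lps, volume = df$vol_L, fs = meta$fs, f0 = meta$f0,
      modality = meta$modality)
}
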