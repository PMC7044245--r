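## Shared fixtures: phantoms are generated once per test run and cached, so
## the expensive 48^3 cases are reused across files.

phantom_cache <- new.env(parent = emptyenv())

cachedValue <- function(key, expr) {
  if (is.null(phantom_cache[[key]])) phantom_cache[[key]] <- force(expr)
  phantom_cache[[key]]
}

## Full-scale phantom at the study's imaging conditions (48^3 at 0.6 mm,
## 21 phases), noiseless so recovery errors isolate the numerics.
bigPhantom <- function(modality, condition = "baseline") {
  cachedValue(paste0("big_", modality, "_", condition),
    makePhantom(phantomConfig(gridShape = c(48L, 48L, 48L), N = 21L,
                              f0 = if (modality == "CMV") 1 / 3 else 5,
                              modality = modality, condition = condition,
                              noiseSdHu = 0, seed = 42L)))
}

bigMetrics <- function(modality, condition = "baseline") {
  cachedValue(paste0("vm_", modality, "_", condition), {
    ph <- bigPhantom(modality, condition)
    regionalMetrics(ph$sequence, ph$truth@transforms)
  })
}

## Small, fast phantom for structural tests.
smallPhantom <- function(modality = "HFOV", condition = "baseline",
                         noiseSdHu = 0, N = 6L, seed = 7L) {
  cachedValue(paste0("small_", modality, "_", condition, "_", noiseSdHu,
                     "_", N, "_", seed),
    makePhantom(phantomConfig(gridShape = c(24L, 24L, 24L), N = N,
                              f0 = if (modality == "CMV") 0.4 else 5,
                              modality = modality, condition = condition,
                              noiseSdHu = noiseSdHu, seed = seed)))
}

## Ground-truth strain range per voxel from the analytic determinant series.
truthStrainRange <- function(truth) {
  d <- dim(truth@detJ)
  m <- matrix(truth@detJ, ncol = d[4])
  hi <- do.call(pmax, lapply(seq_len(d[4]), function(j) m[, j]))
  lo <- do.call(pmin, lapply(seq_len(d[4]), function(j) m[, j]))
  array(hi / lo - 1, d[1:3])
}

## Population SD, duplicated here so tests do not lean on the package's own
## helper.
popSD <- function(x) sqrt(mean((x - mean(x))^2))
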