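## Independent brute-force recursive octree reference: returns the partition
## as a list of sorted linear-index vectors.
octreeReference <- function(field, mask, thr = 0.3, minFrac = 0.002) {
  d <- dim(mask)
  maskSize <- sum(mask)
  out <- list()
  recur <- function(b) {
    xs <- b[1]:b[2]; ys <- b[3]:b[4]; zs <- b[5]:b[6]
    sub <- mask[xs, ys, zs, drop = FALSE]
    w <- which(sub)
    if (!length(w)) return(invisible())
    ai <- arrayInd(w, dim(sub))
    lin <- xs[ai[, 1]] + (ys[ai[, 2]] - 1) * d[1] +
           (zs[ai[, 3]] - 1) * d[1] * d[2]
    v <- field[lin]
    sdv <- sqrt(mean((v - mean(v))^2))
    ext <- c(length(xs), length(ys), length(zs))
    if (sdv >= thr && length(w) >= minFrac * maskSize && any(ext > 1)) {
      sp <- function(lo, hi) {
        if (hi > lo) {
          m <- (lo + hi) %/% 2
          list(c(lo, m), c(m + 1, hi))
        } else list(c(lo, hi))
      }
      for (hx in sp(b[1], b[2])) for (hy in sp(b[3], b[4]))
        for (hz in sp(b[5], b[6])) recur(c(hx, hy, hz))
    } else {
      out[[length(out) + 1L]] <<- sort(lin)
    }
    invisible()
  }
  idx <- which(mask, arr.ind = TRUE)
  recur(c(range(idx[, 1]), range(idx[, 2]), range(idx[, 3])))
  out
}

partitionSignature <- function(rois) {
  sort(vapply(rois, function(v) paste(v, collapse = ","), character(1)))
}

labelsToPartition <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  lapply(ids, function(i) sort(which(labels == i)))
}


## Hand-computed Kruskal-Wallis H for untied data (brute-force rank formula).
handKW <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  n <- tapply(r, groups, length)
  R <- tapply(r, groups, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

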