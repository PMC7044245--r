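## Recursive heterogeneity decomposition of a scalar field (canonically the
## mean-normalized strain range) over the lung mask. Both methods start from
## one ROI holding the whole mask and recursively subdivide any ROI whose
## masked-voxel standard deviation is at or above `stdThreshold` and whose
## size is at least `minFraction` of the mask; subdivision stops otherwise,
## so every leaf is either homogeneous or smaller than the size floor
## (default 0.2% of the lung mask).

.labelVoxels <- function(labels, lin, id) {
  labels[lin] <- id
  labels
}

#' Octree decomposition
#'
#' Recursive eight-way subdivision: an inhomogeneous ROI is split into eight
#' octants by bisecting each axis of its current bounding box (floor split
#' for odd extents); empty octants are discarded, axes of extent 1 are not
#' split. The field should already be mean-normalized when using the default
#' threshold of 0.3.
#'
#' @param field numeric 3D array (NA allowed outside the mask).
#' @param mask logical 3D array; must contain at least one voxel.
#' @param stdThreshold split when the population SD of masked field values in
#'   the ROI is >= this (default 0.3, for mean-normalized strain range).
#' @param minFraction do not split ROIs smaller than this fraction of the
#'   mask (default 0.002).
#' @return a [Decomposition-class].
#' @export
octreeDecompose <- function(field, mask, stdThreshold = 0.3,
                            minFraction = 0.002) {
  stopifnot(identical(dim(field), dim(mask)))
  maskSize <- sum(mask)
  if (maskSize == 0L) stop("empty mask")
  d <- dim(mask)
  minSize <- minFraction * maskSize
  idx <- which(mask, arr.ind = TRUE)
  box0 <- c(range(idx[, 1]), range(idx[, 2]), range(idx[, 3]))
  labels <- array(0L, d)
  census <- list()
  nextId <- 0L
  stack <- list(box0)
  while (length(stack)) {
    b <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    xs <- b[1]:b[2]; ys <- b[3]:b[4]; zs <- b[5]:b[6]
    sub <- mask[xs, ys, zs, drop = FALSE]
    w <- which(sub)
    if (!length(w)) next
    ai <- arrayInd(w, dim(sub))
    lin <- xs[ai[, 1]] + (ys[ai[, 2]] - 1L) * d[1] +
           (zs[ai[, 3]] - 1L) * d[1] * d[2]
    sdv <- .popSD(field[lin])
    ext <- c(b[2] - b[1], b[4] - b[3], b[6] - b[5]) + 1L
    splittable <- any(ext > 1L)
    if (!is.na(sdv) && sdv >= stdThreshold && length(w) >= minSize &&
        splittable) {
      halves <- lapply(1:3, function(ax) {
        lo <- b[2 * ax - 1L]; hi <- b[2 * ax]
        if (hi > lo) {
          mid <- (lo + hi) %/% 2L
          list(c(lo, mid), c(mid + 1L, hi))
        } else list(c(lo, hi))
      })
      for (hx in halves[[1]]) for (hy in halves[[2]]) for (hz in halves[[3]])
        stack[[length(stack) + 1L]] <- c(hx, hy, hz)
    } else {
      nextId <- nextId + 1L
      labels[lin] <- nextId
      census[[nextId]] <- data.frame(roi = nextId, size = length(w),
                                     sd = sdv)
    }
  }
  new("Decomposition", labels = labels, census = do.call(rbind, census),
      method = "octree", maskSize = as.integer(maskSize))
}

## Deterministic approximate farthest pair in feature space: the point
## farthest from the centroid, then the point farthest from it.
.farthestPair <- function(X) {
  ctr <- colMeans(X)
  d1 <- rowSums(sweep(X, 2L, ctr)^2)
  i <- which.max(d1)
  d2 <- rowSums(sweep(X, 2L, X[i, ])^2)
  j <- which.max(d2)
  if (d2[j] == 0) return(NULL)
  rbind(X[i, ], X[j, ])
}

#' Supervoxel decomposition
#'
#' Recursive binary subdivision by weighted 2-means clustering of voxels on
#' intensity similarity and spatial proximity. Feature vectors are
#' `[wI * z-scored field value, (x, y, z) / L]` with L the ROI bounding-box
#' diagonal (mm) and `wI = 1 / proximityWeight`; larger `proximityWeight`
#' therefore favours spatially compact clusters. 2-means uses Lloyd
#' iterations from a deterministic farthest-pair initialization, so results
#' are reproducible. Stop rules match [octreeDecompose()]; ROIs with
#' degenerate (identical) features are treated as below threshold. Because
#' cluster boundaries are not constrained to planes, this method typically
#' yields larger contiguous ROIs than the octree under the same criteria.
#'
#' @inheritParams octreeDecompose
#' @param spacing numeric(3) mm, for the spatial features.
#' @param proximityWeight balance between spatial proximity and intensity
#'   similarity (default 1: equal weight). A sensitivity knob: larger values
#'   produce more compact, less field-adapted clusters.
#' @param iterMax Lloyd iteration cap per split.
#' @return a [Decomposition-class].
#' @export
supervoxelDecompose <- function(field, mask, spacing, stdThreshold = 0.3,
                                minFraction = 0.002, proximityWeight = 1,
                                iterMax = 100L) {
  stopifnot(identical(dim(field), dim(mask)), proximityWeight > 0)
  maskSize <- sum(mask)
  if (maskSize == 0L) stop("empty mask")
  d <- dim(mask)
  minSize <- minFraction * maskSize
  lin0 <- which(mask)
  ai <- arrayInd(lin0, d)
  coords <- sweep(ai - 1, 2L, spacing, `*`)
  vals <- field[lin0]
  wI <- 1 / proximityWeight

  labels <- array(0L, d)
  census <- list()
  nextId <- 0L
  stack <- list(seq_along(lin0))
  while (length(stack)) {
    rows <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- vals[rows]
    sdv <- .popSD(v)
    leaf <- TRUE
    if (!is.na(sdv) && sdv > 0 && sdv >= stdThreshold &&
        length(rows) >= max(minSize, 2)) {
      cc <- coords[rows, , drop = FALSE]
      span <- apply(cc, 2L, function(x) diff(range(x)))
      L <- sqrt(sum(span^2))
      if (L == 0) L <- 1
      X <- cbind(wI * (v - mean(v)) / sdv,
                 sweep(cc, 2L, apply(cc, 2L, min)) / L)
      ctrs <- .farthestPair(X)
      if (!is.null(ctrs)) {
        km <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = ctrs,
                                         iter.max = iterMax,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(km) && all(km$size > 0L) && length(km$size) == 2L) {
          stack[[length(stack) + 1L]] <- rows[km$cluster == 1L]
          stack[[length(stack) + 1L]] <- rows[km$cluster == 2L]
          leaf <- FALSE
        }
      }
    }
    if (leaf) {
      nextId <- nextId + 1L
      labels[lin0[rows]] <- nextId
      census[[nextId]] <- data.frame(roi = nextId, size = length(rows),
                                     sd = sdv)
    }
  }
  new("Decomposition", labels = labels, census = do.call(rbind, census),
      method = "supervoxel", maskSize = as.integer(maskSize))
}

#' ROI census and mean ROI volume fraction
#'
#' Summarises a decomposition by the mean ROI volume as a fraction of the
#' lung mask (the heterogeneity index: 1 for a single homogeneous ROI,
#' smaller values for patchier fields) and the per-ROI census.
#'
#' @param decomposition a [Decomposition-class].
#' @return list with `vROI` (mean ROI voxel count / mask voxel count),
#'   `nROI`, and `census` (data.frame of per-ROI size and SD).
#' @export
clusterStats <- function(decomposition) {
  stopifnot(is(decomposition, "Decomposition"))
  cen <- decomposition@census
  list(vROI = mean(cen$size) / decomposition@maskSize,
       nROI = nrow(cen), census = cen)
}
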