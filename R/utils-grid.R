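## Grid utilities: world coordinates, trilinear interpolation, finite
## differences. Voxel i (1-based) is centred at world (i - 1) * spacing mm.

.worldAxis <- function(n, h) (seq_len(n) - 1) * h

## 3D array whose value is the world coordinate along `axis`.
.axisGrid <- function(dims, spacing, axis) {
  w <- .worldAxis(dims[axis], spacing[axis])
  rep_each <- prod(dims[seq_len(axis - 1L)])
  array(rep(w, each = rep_each), dims)
}

## Subset array `v` along `axis` with index vector `i` (other axes kept).
.sliceAxis <- function(v, axis, i) {
  d <- dim(v)
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- i
  do.call(`[`, c(list(v), args, list(drop = FALSE)))
}

## Broadcast a per-slice vector along `axis` into a full array.
.expandAxis <- function(vec, dims, axis) {
  array(rep(vec, each = prod(dims[seq_len(axis - 1L)])), dims)
}

## d/dx along one axis by central differences: order-4 stencil where the
## five-point support fits, order-2 next to the boundary, one-sided at the
## edge slices.
.gradAxis <- function(v, axis, h, order = 4L) {
  n <- dim(v)[axis]
  if (n < 2L) stop("cannot differentiate along an axis of extent 1")
  i <- seq_len(n)
  ip <- pmin(i + 1L, n)
  im <- pmax(i - 1L, 1L)
  num <- .sliceAxis(v, axis, ip) - .sliceAxis(v, axis, im)
  g2 <- num / .expandAxis((ip - im) * h, dim(v), axis)
  if (order == 2L || n < 5L) return(g2)
  ip2 <- pmin(i + 2L, n)
  im2 <- pmax(i - 2L, 1L)
  g4 <- (-.sliceAxis(v, axis, ip2) + 8 * .sliceAxis(v, axis, ip) -
         8 * .sliceAxis(v, axis, im) + .sliceAxis(v, axis, im2)) / (12 * h)
  inner <- i >= 3L & i <= n - 2L
  sel <- .expandAxis(inner, dim(v), axis)
  ifelse(sel, g4, g2)
}

## Vectorised trilinear interpolation of a 3D volume at fractional 1-based
## voxel coordinates. Out-of-domain queries return `outside` unless clamped.
.interp3 <- function(vol, qx, qy, qz, clamp = FALSE, outside = NA_real_) {
  d <- dim(vol)
  stopifnot(length(d) == 3L, all(d >= 2L))
  if (clamp) {
    qx <- pmin(pmax(qx, 1), d[1])
    qy <- pmin(pmax(qy, 1), d[2])
    qz <- pmin(pmax(qz, 1), d[3])
    ok <- TRUE
  } else {
    ok <- qx >= 1 & qx <= d[1] & qy >= 1 & qy <= d[2] & qz >= 1 & qz <= d[3]
    ok[is.na(ok)] <- FALSE
    qx <- pmin(pmax(qx, 1), d[1])
    qy <- pmin(pmax(qy, 1), d[2])
    qz <- pmin(pmax(qz, 1), d[3])
  }
  i0 <- pmin(floor(qx), d[1] - 1); fx <- qx - i0
  j0 <- pmin(floor(qy), d[2] - 1); fy <- qy - j0
  k0 <- pmin(floor(qz), d[3] - 1); fz <- qz - k0
  s1 <- d[1]; s2 <- d[1] * d[2]
  base <- i0 + (j0 - 1) * s1 + (k0 - 1) * s2
  v000 <- vol[base];          v100 <- vol[base + 1]
  v010 <- vol[base + s1];     v110 <- vol[base + s1 + 1]
  v001 <- vol[base + s2];     v101 <- vol[base + s2 + 1]
  v011 <- vol[base + s1 + s2]; v111 <- vol[base + s1 + s2 + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  out <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz
  if (!isTRUE(all(ok))) out[!ok] <- outside
  out
}

## Row-wise max/min over matrix columns via pmax/pmin (fast for wide data).
.rowMax <- function(m, na.rm = FALSE) {
  do.call(pmax, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                  list(na.rm = na.rm)))
}
.rowMin <- function(m, na.rm = FALSE) {
  do.call(pmin, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                  list(na.rm = na.rm)))
}

## Wrap angles to (-pi, pi].
.wrapPi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[!is.na(w) & w == -pi] <- pi
  w
}

## Population standard deviation (divisor n, not n - 1).
.popSD <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

.checkSameGeometry <- function(dimA, spacingA, dimB, spacingB,
                               what = "volumes") {
  if (!identical(as.integer(dimA), as.integer(dimB)))
    stop("dimension mismatch between ", what)
  if (max(abs(spacingA - spacingB)) > 1e-6)
    stop("spacing mismatch between ", what)
  invisible(TRUE)
}
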