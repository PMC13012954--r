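# Internal helpers shared across modules. Matrices are row = image row (y),
# col = image column (x) throughout the package.

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that touch
# only diagonally are merged with a union-find pass over diagonal adjacencies.
label8 <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1L) return(canonicalRelabel(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab[] <- c(0L, root)[lab + 1L]
  canonicalRelabel(lab)
}

# Relabel objects as contiguous 1..n in raster-scan order of first occurrence
# (column-major here; any fixed order gives determinism up to a convention).
canonicalRelabel <- function(lab) {
  v <- as.integer(lab)
  ids <- unique(v[v > 0L])
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- v
  out[v > 0L] <- map[v[v > 0L]]
  matrix(out, nrow(lab), ncol(lab))
}

# Reflection-padded Gaussian smoothing (separable kernel applied as one 2-D
# FFT convolution on the padded image).
gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

padReflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(p, nr))), seq_len(nr), nr + 1 - seq_len(min(p, nr)))
  if (p > nr) ri <- c(rep(1L, p - nr), ri[seq_len(min(p, nr))], ri[-seq_len(min(p, nr))])
  ci <- c(rev(seq_len(min(p, nc))), seq_len(nc), nc + 1 - seq_len(min(p, nc)))
  m[ri, ci, drop = FALSE]
}

gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussKernel1d(sigma)
  p <- (length(k) - 1L) / 2L
  mp <- padReflect(m, p)
  sm <- EBImage::filter2(mp, outer(k, k), boundary = "circular")
  sm[(p + 1):(p + nrow(m)), (p + 1):(p + ncol(m)), drop = FALSE]
}

# Central differences with replicated borders.
diffX <- function(m) { # along columns (x direction)
  nc <- ncol(m)
  (m[, c(2:nc, nc), drop = FALSE] - m[, c(1, 1:(nc - 1)), drop = FALSE]) / 2
}
diffY <- function(m) {
  nr <- nrow(m)
  (m[c(2:nr, nr), , drop = FALSE] - m[c(1, 1:(nr - 1)), , drop = FALSE]) / 2
}

# Odd-sized disc brush of (approximate) diameter d.
discBrush <- function(d) {
  s <- max(3L, as.integer(d))
  if (s %% 2L == 0L) s <- s + 1L
  EBImage::makeBrush(s, shape = "disc")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear interpolation of per-tile values (at tile centers) to pixel grid.
interpTiles <- function(vals, centersR, centersC, nr, nc) {
  interp1 <- function(centers, n) {
    # for each pixel coordinate 1..n return (lower index, upper index, weight)
    pos <- seq_len(n)
    if (length(centers) == 1L) return(list(i0 = rep(1L, n), i1 = rep(1L, n), w = rep(0, n)))
    i1 <- findInterval(pos, centers, all.inside = TRUE)
    i2 <- i1 + 1L
    w <- (pos - centers[i1]) / (centers[i2] - centers[i1])
    w <- clamp(w, 0, 1)
    list(i0 = i1, i1 = i2, w = w)
  }
  ry <- interp1(centersR, nr)
  cx <- interp1(centersC, nc)
  a <- vals[ry$i0, cx$i0, drop = FALSE]
  b <- vals[ry$i1, cx$i0, drop = FALSE]
  cc <- vals[ry$i0, cx$i1, drop = FALSE]
  d <- vals[ry$i1, cx$i1, drop = FALSE]
  wy <- matrix(ry$w, nr, nc)
  wx <- matrix(cx$w, nr, nc, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + cc * (1 - wy) * wx + d * wy * wx
}

# Per-object summaries from a label matrix.
objectSummary <- function(lab) {
  v <- as.integer(lab)
  keep <- v > 0L
  if (!any(keep)) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      border = logical(0)))
  }
  nr <- nrow(lab)
  idx <- which(keep)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  lv <- v[keep]
  area <- tabulate(lv)
  labs <- which(area > 0L)
  cr <- vapply(split(rr, lv), mean, numeric(1))
  ccm <- vapply(split(cc, lv), mean, numeric(1))
  onBorder <- rr == 1L | rr == nr | cc == 1L | cc == ncol(lab)
  bflag <- vapply(split(onBorder, lv), any, logical(1))
  data.frame(label = labs, area_px = area[labs],
             centroid_r = as.numeric(cr), centroid_c = as.numeric(ccm),
             border = as.logical(bflag), row.names = NULL)
}

#' The five NETosis stage labels in their fixed order
#'
#' The order (negative, spread, disintegrated, netosis, dead) is also the
#' tie-break order for stage classification: exact probability ties resolve
#' to the earlier class.
#'
#' @return character vector of length 5
#' @export
stageLevels <- function() c("negative", "spread", "disintegrated", "netosis", "dead")
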