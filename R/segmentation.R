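# Object segmentation: adaptive Otsu thresholding with declumping, the DNA /
# Annexin preprocessing steps, parent-child relations, per-parent merging and
# NET derivation as size-filtered extracellular DNA.

#' Segmentation parameter sets, rescaled for pixel size
#'
#' All sizes are in pixels and calibrated for 0.62 um/px acquisition
#' (20x / NA 0.45): cells are white probability-map regions >= 15 px
#' (about 5.8 um^2, excluding non-cellular debris), DNA and Annexin objects
#' are <= 1000 px, NETs are extracellular DNA regions >= 150 px. When the
#' pixel size differs, area thresholds are rescaled by (0.62/pixelSize)^2 so
#' the physical size cut-offs are preserved.
#'
#' @param pixelSize micrometres per pixel
#' @param dnaLowerLimit lower bound on the adaptive DNA threshold, on the
#'   [0,1] intensity scale; the useful range is 0.005--0.03 depending on
#'   background (default 0.01)
#' @param declumpSmooth declumping smoothing filter size in pixels
#'   (default 10, suited to objects of roughly 20 px diameter and larger;
#'   reduce for smaller objects)
#' @param declumpTolerance watershed peak prominence for declumping
#' @return nested parameter list (cells, dna, annexin, nets)
#' @export
segmentationParams <- function(pixelSize = 0.62, dnaLowerLimit = 0.01,
                               declumpSmooth = 10L, declumpTolerance = 1) {
  f <- (0.62 / pixelSize)^2
  list(
    cells = list(minArea = max(1, round(15 * f)), classes = 2L,
                 correction = 0.3, window = 50L, suppressSize = 10L,
                 declumpSmooth = declumpSmooth,
                 declumpTolerance = declumpTolerance),
    dna = list(minArea = max(1, round(6 * f)),
               maxArea = max(1, round(1000 * f)), classes = 2L,
               correction = 0.8, window = 50L,
               bounds = c(dnaLowerLimit, 1), declumpSmooth = declumpSmooth,
               declumpTolerance = declumpTolerance),
    annexin = list(minArea = max(1, round(6 * f)),
                   maxArea = max(1, round(1000 * f)), classes = 3L,
                   middleForeground = TRUE, correction = 1, window = 50L,
                   bounds = c(2e-4, 1), speckleSize = 20L,
                   declumpSmooth = declumpSmooth,
                   declumpTolerance = declumpTolerance),
    nets = list(minArea = max(1, round(150 * f)), expandPx = 1L),
    pixelSize = pixelSize)
}

#' Global Otsu threshold (256-level histogram)
#'
#' Maximises the between-class variance of the two-class split of the
#' 256-bin histogram of a [0,1] image. Returns NA for a constant input.
#'
#' @param x numeric vector or matrix scaled to [0,1]
#' @param levels histogram resolution
#' @return threshold on the [0,1] scale (mask is \code{x > threshold}), or NA
#' @export
otsuThreshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  if (max(v) - min(v) < .Machine$double.eps) return(NA_real_)
  b <- pmin(pmax(ceiling(v * levels), 1L), levels)
  h <- tabulate(b, levels)
  p <- h / sum(h)
  w <- cumsum(p)
  mids <- (seq_len(levels) - 0.5) / levels
  mu <- cumsum(p * mids)
  muT <- mu[levels]
  valid <- w > 0 & w < 1
  if (!any(valid)) return(NA_real_)
  sb <- rep(-Inf, levels)
  sb[valid] <- (muT * w[valid] - mu[valid])^2 / (w[valid] * (1 - w[valid]))
  t <- which.max(sb)
  t / levels
}

#' Three-class Otsu thresholds (256-level histogram)
#'
#' Exhaustive search for the two cuts maximising the between-class variance
#' of the three-class split.
#'
#' @inheritParams otsuThreshold
#' @return numeric c(lower, upper) thresholds on [0,1], or c(NA, NA)
#' @export
otsuThreshold3 <- function(x, levels = 256L) {
  v <- as.numeric(x)
  if (max(v) - min(v) < .Machine$double.eps) return(c(NA_real_, NA_real_))
  b <- pmin(pmax(ceiling(v * levels), 1L), levels)
  h <- tabulate(b, levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  W <- c(0, cumsum(p))
  M <- c(0, cumsum(p * mids))
  best <- -Inf; bt <- c(NA_integer_, NA_integer_)
  for (t1 in 1:(levels - 2L)) {
    w1 <- W[t1 + 1L]
    if (w1 <= 0) next
    m1 <- M[t1 + 1L]^2 / w1
    t2 <- (t1 + 1L):(levels - 1L)
    w2 <- W[t2 + 1L] - W[t1 + 1L]
    w3 <- 1 - W[t2 + 1L]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (M[t2 + 1L] - M[t1 + 1L])^2 / pmax(w2, 1e-300)
    m3 <- (M[levels + 1L] - M[t2 + 1L])^2 / pmax(w3, 1e-300)
    sb <- ifelse(ok, m1 + m2 + m3, -Inf)
    j <- which.max(sb)
    if (sb[j] > best) { best <- sb[j]; bt <- c(t1, t2[j]) }
  }
  bt / levels
}

#' Adaptive Otsu thresholding
#'
#' Per-tile Otsu thresholds on a grid of \code{window}-pixel tiles are
#' bilinearly interpolated to per-pixel thresholds, multiplied by the
#' correction factor and clamped to \code{bounds}. With \code{classes = 3}
#' the lower of the two multilevel cuts is used when the middle intensity
#' class counts as foreground, the upper otherwise. Constant tiles fall back
#' to the global Otsu of the whole image; a fully constant image yields an
#' empty mask.
#'
#' @param image numeric matrix scaled to [0,1]
#' @param classes 2 or 3
#' @param correction threshold correction factor
#' @param window adaptive window size in pixels (>= 2)
#' @param bounds c(lower, upper) clamp for the final per-pixel threshold
#' @param middleForeground for classes = 3: middle class is foreground
#' @return logical mask; per-pixel thresholds in attr "thresholds"
#' @export
adaptiveOtsuThreshold <- function(image, classes = 2L, correction = 1,
                                  window = 50L, bounds = c(0, 1),
                                  middleForeground = TRUE) {
  stopifnot(window >= 2L, classes %in% c(2L, 3L))
  nr <- nrow(image); nc <- ncol(image)
  tileThr <- function(v) {
    if (classes == 2L) return(otsuThreshold(v))
    tt <- otsuThreshold3(v)
    # fewer than three populated grey levels: no three-class split exists,
    # fall back to the two-class cut
    if (anyNA(tt)) otsuThreshold(v)
    else if (middleForeground) tt[1] else tt[2]
  }
  globalThr <- tileThr(image)
  if (is.na(globalThr)) {
    mask <- matrix(FALSE, nr, nc)
    attr(mask, "thresholds") <- matrix(NA_real_, nr, nc)
    return(mask)
  }
  ntr <- max(1L, floor(nr / window)); ntc <- max(1L, floor(nc / window))
  rEdges <- round(seq(0, nr, length.out = ntr + 1L))
  cEdges <- round(seq(0, nc, length.out = ntc + 1L))
  vals <- matrix(NA_real_, ntr, ntc)
  centR <- numeric(ntr); centC <- numeric(ntc)
  for (i in seq_len(ntr)) {
    rows <- (rEdges[i] + 1L):rEdges[i + 1L]
    centR[i] <- mean(rows)
    for (j in seq_len(ntc)) {
      cols <- (cEdges[j] + 1L):cEdges[j + 1L]
      if (i == 1L) centC[j] <- mean(cols)
      vals[i, j] <- tileThr(image[rows, cols])
    }
  }
  vals[is.na(vals)] <- globalThr
  thr <- interpTiles(vals, centR, centC, nr, nc)
  thr <- clamp(thr * correction, bounds[1], bounds[2])
  mask <- image > thr
  attr(mask, "thresholds") <- thr
  mask
}

#' Identify primary objects
#'
#' Threshold, 8-connected components, shape-based declumping (seeds at the
#' local maxima of the smoothed distance transform; dividing lines following
#' intensity gradients via constrained propagation), hole filling, size
#' filtering and border exclusion.
#'
#' @param image preprocessed [0,1] image to threshold
#' @param family object family for the result
#' @param minArea,maxArea inclusive size filter bounds in pixels (NULL = off)
#' @param classes,correction,window,bounds,middleForeground see
#'   \code{\link{adaptiveOtsuThreshold}}
#' @param declumpSmooth smoothing filter size (pixels) for the distance
#'   transform before seed detection; 10 px suits objects of roughly 20 px
#'   diameter and up -- reduce it for smaller objects
#' @param declumpTolerance watershed minimum peak prominence; smaller values
#'   split clumps more aggressively
#' @param excludeBorder drop objects touching the image border
#' @param declump set FALSE to keep plain connected components
#' @param mask optional precomputed logical foreground mask (e.g. from
#'   \code{\link{thresholdDNA}}); skips the thresholding step
#' @return an \linkS4class{ObjectMap}
#' @export
identifyPrimaryObjects <- function(image, family = "cells",
                                   minArea = NULL, maxArea = NULL,
                                   classes = 2L, correction = 1,
                                   window = 50L, bounds = c(0, 1),
                                   middleForeground = TRUE,
                                   declumpSmooth = 10L,
                                   declumpTolerance = 1,
                                   excludeBorder = TRUE, declump = TRUE,
                                   mask = NULL) {
  if (is.null(mask))
    mask <- adaptiveOtsuThreshold(image, classes, correction, window, bounds,
                                  middleForeground)
  lab <- declumpObjects(mask, image, declumpSmooth, declump, declumpTolerance)
  lab <- EBImage::fillHull(lab)
  keepObjects(lab, family, minArea, maxArea, excludeBorder)
}

declumpObjects <- function(mask, intensity, declumpSmooth = 10L,
                           declump = TRUE, tolerance = 1) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(1L, nrow(mask), ncol(mask)))
  cc <- label8(mask)
  if (!declump) return(cc)
  d <- EBImage::distmap(mask * 1)
  ds <- gaussSmooth(d, declumpSmooth / 2.355)
  ws <- EBImage::watershed(ds * (mask > 0), tolerance = tolerance, ext = 1)
  ws <- matrix(as.integer(ws), nrow(mask), ncol(mask))
  if (max(ws) <= max(cc)) return(cc)
  # one seed pixel per watershed basin, at its smoothed-distance maximum
  seeds <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(ws > 0L)
  sp <- split(idx, ws[idx])
  for (lb in names(sp)) {
    px <- sp[[lb]]
    seeds[px[which.max(ds[px])]] <- as.integer(lb)
  }
  seg <- EBImage::propagate(intensity, seeds = seeds, mask = mask > 0,
                            lambda = 1e-3)
  matrix(as.integer(seg), nrow(mask), ncol(mask))
}

keepObjects <- function(lab, family, minArea = NULL, maxArea = NULL,
                        excludeBorder = TRUE, parent = NULL,
                        requireParent = FALSE) {
  tab <- objectSummary(lab)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(minArea)) keep <- keep & tab$area_px >= minArea
  if (!is.null(maxArea)) keep <- keep & tab$area_px <= maxArea
  if (excludeBorder) keep <- keep & !tab$border
  if (!is.null(parent) && requireParent)
    keep <- keep & !is.na(parent[tab$label])
  kept <- tab$label[keep]
  out <- lab
  out[!(out %in% kept)] <- 0L
  if (!is.null(parent)) {
    # re-index the parent vector to the canonical relabeling of kept objects
    newLab <- canonicalRelabel(out)
    parentKept <- rep(NA_integer_, max(newLab))
    for (o in unique(as.integer(out)[as.integer(out) > 0L]))
      parentKept[newLab[which(out == o)[1]]] <- parent[o]
    return(newObjectMap(newLab, family, parent = parentKept))
  }
  newObjectMap(out, family)
}

#' Log-transform DNA images
#'
#' Range-preserving base-2 log gain for faint DNA signal:
#' \code{log2(1 + 255 x) / 8} on a [0,1] image, so 0 maps to 0 and 1 to 1
#' while low intensities are strongly enhanced.
#'
#' @param green [0,1] matrix
#' @return transformed [0,1] matrix
#' @export
preprocessDNA <- function(green) {
  if (any(green < 0)) stop("negative pixels in DNA image", call. = FALSE)
  log2(1 + green * 255) / 8
}

# Inverse of preprocessDNA: map a threshold computed on the log-transformed
# scale back to the raw [0,1] intensity scale.
invPreprocessDNA <- function(t) (2^(8 * t) - 1) / 255

#' Threshold the DNA channel (log-space Otsu, raw-scale bounds)
#'
#' The adaptive Otsu cut is computed on the log2-transformed image (where
#' the faint-DNA mode is separable), then inverse-transformed to the raw
#' intensity scale where the correction factor and the lower/upper bounds
#' apply -- the bound range 0.005--0.03 refers to raw [0,1] intensities.
#'
#' @param green background-subtracted [0,1] DNA image
#' @param correction threshold correction factor
#' @param window adaptive window size (pixels)
#' @param bounds c(lower, upper) clamp on the raw-scale threshold
#' @return logical mask; raw-scale per-pixel thresholds in attr "thresholds"
#' @export
thresholdDNA <- function(green, correction = 0.8, window = 50L,
                         bounds = c(0.01, 1)) {
  lg <- preprocessDNA(green)
  mlog <- adaptiveOtsuThreshold(lg, classes = 2L, correction = 1,
                                window = window, bounds = c(0, 1))
  tlog <- attr(mlog, "thresholds")
  if (all(is.na(tlog))) {
    mask <- matrix(FALSE, nrow(green), ncol(green))
    attr(mask, "thresholds") <- tlog
    return(mask)
  }
  thr <- clamp(invPreprocessDNA(tlog) * correction, bounds[1], bounds[2])
  mask <- green > thr
  attr(mask, "thresholds") <- thr
  mask
}

#' Enhance speckles (white top-hat)
#'
#' White top-hat with a disc structuring element of the given diameter:
#' bright features smaller than the element are kept, larger structures and
#' smooth background are suppressed. Characteristic Annexin V puncta are
#' about 20 px at 0.62 um/px.
#'
#' @param x [0,1] matrix
#' @param size structuring element diameter in pixels
#' @return nonnegative matrix of speckle residuals
#' @export
enhanceSpeckles <- function(x, size = 20L) {
  EBImage::whiteTopHat(x, discBrush(size))
}

#' Suppress small bright features (morphological opening)
#'
#' Grayscale opening with a disc of the given diameter, removing bright
#' features smaller than the element (used to clean small-scale noise from
#' probability maps before segmentation). Idempotent.
#'
#' @param x [0,1] matrix
#' @param size structuring element diameter in pixels
#' @return opened matrix
#' @export
suppressFeatures <- function(x, size = 10L) {
  EBImage::opening(x, discBrush(size))
}

#' Relate child objects to parent cells
#'
#' Each child overlapping at least one parent is assigned to the parent with
#' the largest pixel overlap (ties broken toward the lower parent label);
#' children with no overlap are unassigned (NA) and excluded downstream.
#'
#' @param parents,children \linkS4class{ObjectMap}s on the same raster
#' @return integer vector indexed by child label: parent label or NA; the
#'   per-parent child counts are in attr "childrenCount"
#' @export
relateObjects <- function(parents, children) {
  pl <- labelMatrix(parents); cl <- labelMatrix(children)
  stopifnot(identical(dim(pl), dim(cl)))
  nChild <- nObjects(children)
  assign <- rep(NA_integer_, nChild)
  sel <- cl > 0L & pl > 0L
  if (any(sel)) {
    ov <- stats::aggregate(list(n = rep(1L, sum(sel))),
                           by = list(child = cl[sel], parent = pl[sel]), FUN = sum)
    ov <- ov[order(ov$child, -ov$n, ov$parent), ]
    first <- !duplicated(ov$child)
    assign[ov$child[first]] <- ov$parent[first]
  }
  counts <- integer(nObjects(parents))
  tb <- table(assign[!is.na(assign)])
  counts[as.integer(names(tb))] <- as.integer(tb)
  attr(assign, "childrenCount") <- counts
  assign
}

#' Merge child objects per parent cell
#'
#' All children assigned to the same parent become one (possibly
#' disconnected) merged object whose area is the sum of the child areas.
#' Parents with no children contribute no merged object.
#'
#' @param children \linkS4class{ObjectMap}
#' @param assign child-to-parent assignment from \code{\link{relateObjects}}
#' @return merged \linkS4class{ObjectMap} with the parent link retained
#' @export
mergePerParent <- function(children, assign) {
  cl <- labelMatrix(children)
  parentsUsed <- sort(unique(assign[!is.na(assign)]))
  out <- matrix(0L, nrow(cl), ncol(cl))
  parentOf <- integer(length(parentsUsed))
  for (k in seq_along(parentsUsed)) {
    kids <- which(!is.na(assign) & assign == parentsUsed[k])
    out[cl %in% kids] <- k
    parentOf[k] <- parentsUsed[k]
  }
  newObjectMap(out, objectFamily(children), merged = TRUE, parent = parentOf)
}

#' Segment NETs as extracellular DNA
#'
#' DNA objects are intersected with the complement of the cell mask,
#' relabelled as 8-connected components, expanded by \code{expandPx} pixels
#' so each NET touches its parent cell, relatedto cells, filtered (area >=
#' \code{minArea} px and at least one parent) and merged per parent.
#'
#' @param dna unmerged DNA \linkS4class{ObjectMap}
#' @param cells cell \linkS4class{ObjectMap} from the same frame
#' @param minArea NET size filter in pixels (150 at 0.62 um/px)
#' @param expandPx expansion radius in pixels
#' @param sizePreExpand apply the size filter before the expansion instead of
#'   after it
#' @return list: \code{unmerged} and \code{merged} NET
#'   \linkS4class{ObjectMap}s (unmerged for counting, merged for per-cell
#'   features)
#' @export
segmentNETs <- function(dna, cells, minArea = 150L, expandPx = 1L,
                        sizePreExpand = FALSE) {
  cl <- labelMatrix(cells)
  extra <- labelMatrix(dna) > 0L & cl == 0L
  lab <- label8(extra)
  if (sizePreExpand && max(lab) > 0L) {
    tab <- objectSummary(lab)
    drop <- tab$label[tab$area_px < minArea]
    lab[lab %in% drop] <- 0L
    lab <- canonicalRelabel(lab)
  }
  if (expandPx > 0L && max(lab) > 0L) {
    dil <- EBImage::dilate((lab > 0L) * 1, discBrush(2L * expandPx + 1L))
    lab <- label8(dil > 0)
  }
  netsAll <- newObjectMap(lab, "nets")
  assign <- relateObjects(cells, netsAll)
  unmerged <- keepObjects(labelMatrix(netsAll), "nets",
                          minArea = if (sizePreExpand) NULL else minArea,
                          excludeBorder = FALSE, parent = assign,
                          requireParent = TRUE)
  assign2 <- relateObjects(cells, unmerged)
  merged <- mergePerParent(unmerged, assign2)
  list(unmerged = unmerged, merged = merged)
}

#' Image-level NET metrics
#'
#' @param netsMerged merged NET \linkS4class{ObjectMap}
#' @param green DNA channel raster in native intensity units
#' @return list(count, area_px, total_intensity); all zero when no NETs
#' @export
imageLevelNetMetrics <- function(netsMerged, green) {
  lab <- labelMatrix(netsMerged)
  px <- lab > 0L
  list(count = nObjects(netsMerged),
       area_px = sum(px),
       total_intensity = sum(green[px]))
}

#' Render an RGB overlay of the segmentation
#'
#' Cells are mapped to the blue channel, DNA to green, Annexin V to red
#' (each channel's raster masked by its merged objects and normalised), and
#' the outer borders of merged NETs are outlined in fuchsia (255, 0, 255).
#'
#' @param frame a \linkS4class{FrameSet}
#' @param cells,dnaMerged,annexinMerged,netsMerged
#'   \linkS4class{ObjectMap}s from the same frame
#' @param path optional output path for an 8-bit RGB TIFF
#' @return 8-bit integer array (h x w x 3), invisibly when written
#' @export
renderOverlay <- function(frame, cells, dnaMerged, annexinMerged, netsMerged,
                          path = NULL) {
  norm01 <- function(m) { r <- range(m); if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0 }
  blue <- norm01(channelData(frame, "phase")) * (labelMatrix(cells) > 0L)
  green <- norm01(channelData(frame, "green")) * (labelMatrix(dnaMerged) > 0L)
  red <- norm01(channelData(frame, "red")) * (labelMatrix(annexinMerged) > 0L)
  rgb <- array(0, dim = c(dim(blue), 3L))
  rgb[, , 1] <- red; rgb[, , 2] <- green; rgb[, , 3] <- blue
  border <- objectBorders(labelMatrix(netsMerged) > 0L)
  rgb[, , 1][border] <- 1; rgb[, , 2][border] <- 0; rgb[, , 3][border] <- 1
  out <- round(rgb * 255)
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(out / 255, path, bits.per.sample = 8, compression = "none")
    return(invisible(out))
  }
  out
}

# Boundary pixels of a binary mask: foreground with a 4-neighbour outside.
objectBorders <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-nr, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -nc, drop = FALSE])
  mask & !(up & dn & lf & rt)
}
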