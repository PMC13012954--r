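# Per-object feature families: intensity statistics, granularity spectrum,
# radial intensity distribution, shape/Zernike descriptors and Haralick
# texture, assembled into the per-cell FeatureTable used by the stage
# classifier.

#' Intensity statistics of an object
#'
#' @param values pixel intensities inside the object mask (native units)
#' @return named vector: max, min, mean, median, lower_quartile,
#'   upper_quartile, std, mad. MAD is the unscaled median absolute deviation
#'   \code{median(|x - median(x)|)}; quartiles use linear interpolation.
#'   All-NA for an empty mask.
#' @export
measureIntensity <- function(values) {
  nm <- c("max", "min", "mean", "median", "lower_quartile", "upper_quartile",
          "std", "mad")
  if (!length(values)) return(stats::setNames(rep(NA_real_, 8L), nm))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  stats::setNames(c(max(values), min(values), mean(values), q[2], q[1], q[3],
                    stats::sd(values), stats::median(abs(values - q[2]))), nm)
}

#' Granularity spectrum of an object
#'
#' Opening spectrum with disc structuring elements of radius 1..16 px: with
#' \eqn{I_0} the masked image and \eqn{I_s} its grayscale opening at radius
#' s, entry s is \eqn{100 (mean(I_{s-1}) - mean(I_s)) / mean(I_0)} (means
#' over the mask). A plain opening spectrum without the subsampling and
#' background-reconstruction refinements of some implementations; spectra
#' are clipped monotone so entries are nonnegative and sum to at most 100.
#'
#' @param mask logical matrix for one object
#' @param raster intensity matrix
#' @param sizes structuring-element radii
#' @return named numeric vector of length \code{length(sizes)}
#' @export
measureGranularity <- function(mask, raster, sizes = 1:16) {
  nm <- paste0("gs", sizes)
  if (!any(mask)) return(stats::setNames(rep(NA_real_, length(sizes)), nm))
  bb <- bboxOf(mask, margin = max(sizes) + 1L)
  m <- mask[bb$r, bb$c]
  x <- raster[bb$r, bb$c] * m
  m0 <- mean(x[m])
  if (m0 <= 0) return(stats::setNames(rep(0, length(sizes)), nm))
  means <- numeric(length(sizes))
  for (k in seq_along(sizes)) {
    op <- EBImage::opening(x, discBrush(2L * sizes[k] + 1L))
    means[k] <- mean(op[m])
  }
  means <- cummin(pmin(c(m0, means), m0))
  stats::setNames(100 * (-diff(means)) / m0, nm)
}

#' Radial intensity distribution relative to the cell edge
#'
#' Signed distance to the parent cell boundary (negative inside the cell) is
#' computed at every object pixel, binned into \code{nBins} equal-width bins
#' spanning the object's distance range; the fraction of total object
#' intensity per bin (FracAtD, summing to 1), that fraction normalised by
#' the bin's pixel fraction (MeanFrac, 1 everywhere for a uniform object)
#' and the coefficient of variation of per-wedge intensity over
#' \code{nWedges} angular wedges (RadialCV) are reported.
#'
#' @param objectMask logical matrix of the (DNA or NET) object
#' @param cellMask logical matrix of the parent cell
#' @param raster intensity matrix
#' @param nBins number of radial bins
#' @param nWedges number of angular wedges for the CV
#' @return named vector FracAtD_k, MeanFrac_k, RadialCV_k; NA when the
#'   object's total intensity is zero
#' @export
measureRadialDistribution <- function(objectMask, cellMask, raster,
                                      nBins = 4L, nWedges = 8L) {
  nm <- c(paste0("FracAtD_", seq_len(nBins)), paste0("MeanFrac_", seq_len(nBins)),
          paste0("RadialCV_", seq_len(nBins)))
  idx <- which(objectMask)
  if (!length(idx)) return(stats::setNames(rep(NA_real_, 3L * nBins), nm))
  intens <- raster[idx]
  tot <- sum(intens)
  if (tot <= 0) return(stats::setNames(rep(NA_real_, 3L * nBins), nm))
  dIn <- EBImage::distmap(cellMask * 1)
  dOut <- EBImage::distmap((!cellMask) * 1)
  signed <- dOut - dIn
  d <- signed[idx]
  rng <- range(d)
  bin <- if (rng[2] > rng[1])
    pmin(pmax(floor((d - rng[1]) / (rng[2] - rng[1]) * nBins) + 1L, 1L), nBins)
  else rep(1L, length(d))
  frac <- vapply(seq_len(nBins), function(k) sum(intens[bin == k]) / tot,
                 numeric(1))
  pixfrac <- vapply(seq_len(nBins), function(k) mean(bin == k), numeric(1))
  meanfrac <- ifelse(pixfrac > 0, frac / pixfrac, 0)
  nr <- nrow(objectMask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ci <- which(cellMask)
  cr <- mean(((ci - 1L) %% nr) + 1L); ccl <- mean(((ci - 1L) %/% nr) + 1L)
  wedge <- pmin(floor((atan2(rr - cr, cc - ccl) + pi) / (2 * pi) * nWedges) + 1L,
                nWedges)
  cv <- vapply(seq_len(nBins), function(k) {
    sel <- bin == k
    if (!any(sel)) return(0)
    wm <- vapply(split(intens[sel], wedge[sel]), mean, numeric(1))
    if (length(wm) < 2L || mean(wm) == 0) return(0)
    stats::sd(wm) / mean(wm)
  }, numeric(1))
  stats::setNames(c(frac, meanfrac, cv), nm)
}

#' Shape features of an object
#'
#' Area (pixel count), outer perimeter, eccentricity from second central
#' moments, radii from the distance transform, and rotation-invariant
#' Zernike moment magnitudes up to degree 9 (30 values) of the mask mapped
#' to the unit disc.
#'
#' @param mask logical matrix for one object
#' @return named numeric vector
#' @export
measureShape <- function(mask) {
  m <- mask * 1
  sh <- EBImage::computeFeatures.shape(m)
  mo <- EBImage::computeFeatures.moment(m)
  z <- zernikeMagnitudes(mask, degree = 9L)
  c(area = unname(sh[1, "s.area"]),
    perimeter = unname(sh[1, "s.perimeter"]),
    eccentricity = unname(mo[1, "m.eccentricity"]),
    min_radius = unname(sh[1, "s.radius.min"]),
    max_radius = unname(sh[1, "s.radius.max"]),
    mean_radius = unname(sh[1, "s.radius.mean"]),
    z)
}

#' Zernike moment magnitudes of a binary mask
#'
#' The mask is centred on its centroid and scaled by its maximal pixel
#' radius to the unit disc; magnitudes |A_nm| of the Zernike moments for
#' n = 0..degree, 0 <= m <= n, n - m even are returned (rotation invariant).
#'
#' @param mask logical matrix
#' @param degree maximal polynomial degree
#' @return named vector zernike_n_m
#' @export
zernikeMagnitudes <- function(mask, degree = 9L) {
  idx <- which(mask)
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  y <- rr - mean(rr); x <- cc - mean(cc)
  rmax <- max(sqrt(x^2 + y^2), 1e-9)
  rho <- sqrt(x^2 + y^2) / rmax
  theta <- atan2(y, x)
  keep <- rho <= 1
  rho <- rho[keep]; theta <- theta[keep]
  out <- c()
  for (n in 0:degree) for (m in seq(n %% 2L, n, by = 2L)) {
    s <- 0:((n - m) / 2)
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    R <- rowSums(outer(rho, n - 2 * s, `^`) *
                   matrix(coef, length(rho), length(s), byrow = TRUE))
    A <- (n + 1) / pi * sum(R * exp(-1i * m * theta)) / rmax^2
    out <- c(out, stats::setNames(Mod(A), sprintf("zernike_%d_%d", n, m)))
  }
  out
}

#' Haralick texture features of an object
#'
#' Pixel intensities inside the mask are quantised to \code{levels} grey
#' levels over the object's own range; co-occurrence matrices are
#' accumulated at the given distance for the four offsets (0, 45, 90,
#' 135 degrees), symmetrised and normalised, and the Haralick statistics
#' are averaged over offsets. Entropies use log base 2; sum variance uses
#' the original definition centred on the sum entropy.
#'
#' @param mask logical matrix for one object (>= 2 px)
#' @param raster intensity matrix
#' @param levels number of grey levels
#' @param distance co-occurrence offset in pixels
#' @return named vector: contrast, correlation, variance, entropy,
#'   inverse_difference_moment, sum_variance, sum_entropy,
#'   difference_variance. A constant object has zero contrast and entropy
#'   and missing correlation.
#' @export
measureTexture <- function(mask, raster, levels = 256L, distance = 3L) {
  nm <- c("contrast", "correlation", "variance", "entropy",
          "inverse_difference_moment", "sum_variance", "sum_entropy",
          "difference_variance")
  if (sum(mask) < 2L) return(stats::setNames(rep(NA_real_, 8L), nm))
  bb <- bboxOf(mask, margin = distance)
  m <- mask[bb$r, bb$c]
  x <- raster[bb$r, bb$c]
  rng <- range(x[m])
  if (rng[2] <= rng[1]) {
    return(stats::setNames(c(0, NA, 0, 0, 1, 0, 0, 0), nm))
  }
  q <- matrix(0L, nrow(m), ncol(m))
  q[m] <- pmin(floor((x[m] - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  offs <- list(c(0L, distance), c(-distance, distance),
               c(-distance, 0L), c(-distance, -distance))
  acc <- matrix(NA_real_, length(offs), 8L)
  for (oi in seq_along(offs)) {
    o <- offs[[oi]]
    p <- glcmPairs(q, o[1], o[2])
    if (is.null(p)) next
    acc[oi, ] <- haralickFromGLCM(p, levels)
  }
  res <- colMeans(acc, na.rm = TRUE)
  res[is.nan(res)] <- NA_real_
  stats::setNames(res, nm)
}

# Co-occurrence counts (symmetrised, normalised) for one offset, as a sparse
# data.frame (i, j, p). NULL when no valid pairs.
glcmPairs <- function(q, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  sel <- a > 0L & b > 0L
  if (!any(sel)) return(NULL)
  i <- c(a[sel], b[sel]); j <- c(b[sel], a[sel])  # symmetrise
  key <- paste(i, j)
  cnt <- table(key)
  ij <- matrix(as.integer(unlist(strsplit(names(cnt), " "))), ncol = 2,
               byrow = TRUE)
  data.frame(i = ij[, 1], j = ij[, 2], p = as.numeric(cnt) / sum(cnt))
}

haralickFromGLCM <- function(g, levels) {
  i <- g$i; j <- g$j; p <- g$p
  px <- vapply(split(p, i), sum, numeric(1))
  lv <- as.integer(names(px))
  mu <- sum(lv * px)
  sig2 <- sum((lv - mu)^2 * px)
  sig <- sqrt(sig2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sig > 0) (sum(i * j * p) - mu^2) / sig2 else NA_real_
  variance <- sig2
  entropy <- -sum(p * log2(p))
  idm <- sum(p / (1 + (i - j)^2))
  psum <- vapply(split(p, i + j), sum, numeric(1))
  ks <- as.integer(names(psum))
  sum_entropy <- -sum(psum * log2(psum))
  sum_variance <- sum((ks - sum_entropy)^2 * psum)
  pdiff <- vapply(split(p, abs(i - j)), sum, numeric(1))
  kd <- as.integer(names(pdiff))
  mud <- sum(kd * pdiff)
  difference_variance <- sum((kd - mud)^2 * pdiff)
  c(contrast, correlation, variance, entropy, idm, sum_variance, sum_entropy,
    difference_variance)
}

bboxOf <- function(mask, margin = 0L) {
  idx <- which(mask)
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  list(r = max(1L, min(rr) - margin):min(nr, max(rr) + margin),
       c = max(1L, min(cc) - margin):min(ncol(mask), max(cc) + margin))
}

#' Assemble the per-cell feature table for one frame
#'
#' One row per segmented cell: cell shape (including Zernike magnitudes);
#' intensity and Haralick texture of the cell and of its merged DNA, Annexin
#' and NET objects across all three channels; the granularity spectrum of
#' the cell on each channel and of the child objects on their own channel;
#' the radial intensity distribution of DNA and NET objects relative to the
#' cell edge (green channel); and children counts per family. Features of
#' absent child objects are missing (NA) -- absence is not zero intensity --
#' and children counts carry the absence explicitly.
#'
#' @param frame a \linkS4class{FrameSet}
#' @param cells cell \linkS4class{ObjectMap}
#' @param dnaMerged,annexinMerged,netsMerged merged child
#'   \linkS4class{ObjectMap}s (parent-linked)
#' @param textureDistance GLCM offset in pixels
#' @param childrenCounts optional named list (dna, annexin, nets) of
#'   per-parent unmerged child counts (the "childrenCount" attribute of
#'   \code{\link{relateObjects}}); defaults to merged-object presence
#' @return data.frame, one row per cell, metadata keys first
#' @export
assembleFeatureTable <- function(frame, cells, dnaMerged, annexinMerged,
                                 netsMerged, textureDistance = 3L,
                                 childrenCounts = NULL) {
  meta <- frameMeta(frame)
  chans <- list(Phase = channelData(frame, "phase"),
                DNA = channelData(frame, "green"),
                AnnexinV = channelData(frame, "red"))
  cl <- labelMatrix(cells)
  n <- nObjects(cells)
  fams <- list(dna = dnaMerged, annexin = annexinMerged, nets = netsMerged)
  famChan <- c(dna = "DNA", annexin = "AnnexinV", nets = "DNA")
  # parent cell -> merged child label lookup
  childOf <- lapply(fams, function(om) {
    tb <- objectTable(om)
    lk <- rep(NA_integer_, n)
    if (nrow(tb) && "parent" %in% names(tb))
      lk[tb$parent[!is.na(tb$parent)]] <- tb$label[!is.na(tb$parent)]
    lk
  })
  pixOf <- function(lab) split(which(lab > 0L), lab[lab > 0L])
  cellPix <- pixOf(cl)
  famPix <- lapply(fams, function(om) pixOf(labelMatrix(om)))

  rows <- vector("list", n)
  for (ci in seq_len(n)) {
    cmask <- matrix(FALSE, nrow(cl), ncol(cl))
    cmask[cellPix[[as.character(ci)]]] <- TRUE
    row <- list(plate = meta$plate %||% NA_character_,
                well = meta$well %||% NA_character_,
                field = meta$field %||% NA_integer_,
                hours_elapsed = meta$hours_elapsed %||% NA_real_,
                treatment = meta$treatment %||% NA_character_,
                cell_id = ci)
    sh <- measureShape(cmask)
    names(sh) <- paste0("Shape_", names(sh), "_cell")
    row <- c(row, as.list(sh))
    masks <- list(cell = cmask)
    for (f in names(fams)) {
      lb <- childOf[[f]][ci]
      # masks[f] <- list(...) keeps the element even when the child is
      # absent (NULL); masks[[f]] <- NULL would delete it and desynchronise
      # the column sets across cells
      masks[f] <- if (is.na(lb)) list(NULL) else {
        mm <- matrix(FALSE, nrow(cl), ncol(cl))
        mm[famPix[[f]][[as.character(lb)]]] <- TRUE
        list(mm)
      }
    }
    for (of in names(masks)) {
      m <- masks[[of]]
      for (ch in names(chans)) {
        vals <- if (is.null(m)) numeric(0) else chans[[ch]][m]
        iv <- measureIntensity(vals)
        names(iv) <- paste0("Intensity_", names(iv), "_", ch, "_", of)
        row <- c(row, as.list(iv))
        tv <- if (is.null(m))
          stats::setNames(rep(NA_real_, 8L),
                          c("contrast", "correlation", "variance", "entropy",
                            "inverse_difference_moment", "sum_variance",
                            "sum_entropy", "difference_variance"))
        else measureTexture(m, chans[[ch]], distance = textureDistance)
        names(tv) <- paste0("Texture_", names(tv), "_", ch, "_", of)
        row <- c(row, as.list(tv))
      }
      granChans <- if (of == "cell") names(chans) else famChan[[of]]
      for (ch in granChans) {
        gv <- if (is.null(m)) stats::setNames(rep(NA_real_, 16L),
                                              paste0("gs", 1:16))
        else measureGranularity(m, chans[[ch]])
        names(gv) <- paste0("Granularity_", names(gv), "_", ch, "_", of)
        row <- c(row, as.list(gv))
      }
    }
    for (of in c("dna", "nets")) {
      m <- masks[[of]]
      rv <- if (is.null(m))
        stats::setNames(rep(NA_real_, 12L),
                        c(paste0("FracAtD_", 1:4), paste0("MeanFrac_", 1:4),
                          paste0("RadialCV_", 1:4)))
      else measureRadialDistribution(m, cmask, chans$DNA)
      names(rv) <- paste0("RadialDist_", names(rv), "_DNA_", of)
      row <- c(row, as.list(rv))
    }
    rows[[ci]] <- row
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  # children counts per family: unmerged counts when supplied, else
  # merged-object presence
  for (f in names(fams)) {
    cnt <- childrenCounts[[f]]
    df[[paste0("Children_count_", f)]] <-
      if (!is.null(cnt)) as.integer(cnt[seq_len(n)])
      else as.integer(!is.na(childOf[[f]]))
  }
  df
}
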