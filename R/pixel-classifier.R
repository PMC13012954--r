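# Random-forest pixel classification of phase-contrast images into
# Cells / Background probability maps, from multiscale intensity, edge and
# texture descriptors.

#' Default scale ladder for pixel features
#' @return numeric vector of Gaussian sigmas (pixels)
#' @export
pixelScales <- function() c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0)

#' Extract the multiscale per-pixel feature stack
#'
#' The image is normalised to [0,1]; at every scale sigma the Gaussian-smoothed
#' intensity, gradient magnitude (edge), Laplacian, the two Hessian
#' eigenvalues and the two structure-tensor eigenvalues are computed with
#' reflective boundary handling, giving 7 features per scale.
#'
#' @param phase numeric matrix (any nonnegative scale; normalised internally)
#' @param scales Gaussian sigmas
#' @return list: \code{features} (npix x nfeat matrix, column-major pixel
#'   order), \code{names}, \code{scales}, \code{dim}
#' @export
extractPixelFeatures <- function(phase, scales = pixelScales()) {
  if (any(!is.finite(phase))) stop("non-finite pixels in input", call. = FALSE)
  stopifnot(all(scales > 0))
  rng <- range(phase)
  x <- if (rng[2] > rng[1]) (phase - rng[1]) / (rng[2] - rng[1]) else phase * 0
  feats <- vector("list", length(scales) * 7L)
  nms <- character(length(feats))
  k <- 0L
  for (s in scales) {
    sm <- gaussSmooth(x, s)
    gx <- diffX(sm); gy <- diffY(sm)
    gxx <- diffX(gx); gyy <- diffY(gy); gxy <- diffY(gx)
    grad <- sqrt(gx^2 + gy^2)
    lap <- gxx + gyy
    hdisc <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
    h1 <- (gxx + gyy) / 2 + hdisc
    h2 <- (gxx + gyy) / 2 - hdisc
    jxx <- gaussSmooth(gx * gx, s); jyy <- gaussSmooth(gy * gy, s)
    jxy <- gaussSmooth(gx * gy, s)
    jdisc <- sqrt(((jxx - jyy) / 2)^2 + jxy^2)
    t1 <- (jxx + jyy) / 2 + jdisc
    t2 <- (jxx + jyy) / 2 - jdisc
    for (f in list(sm, grad, lap, h1, h2, t1, t2)) {
      k <- k + 1L
      feats[[k]] <- as.vector(f)
    }
    nms[(k - 6L):k] <- paste0(c("gauss", "gradmag", "laplacian",
                                "hessian_e1", "hessian_e2",
                                "structure_e1", "structure_e2"), "_s", s)
  }
  fm <- do.call(cbind, feats)
  colnames(fm) <- nms
  list(features = fm, names = nms, scales = scales, dim = dim(phase))
}

#' Train the Cells/Background pixel classifier
#'
#' Sparse scribble labels are supplied as a label raster per image
#' (0 = unlabeled, 1 = cell, 2 = background); the interactive annotation loop
#' of the original workflow is replaced by a batch train/evaluate cycle.
#'
#' @param stacks list of feature stacks from
#'   \code{\link{extractPixelFeatures}}
#' @param labels list of integer label matrices matching the stacks' dims
#' @param nTrees number of trees (default 100)
#' @param seed integer seed: fixed seed gives a deterministic forest
#' @return pixelClassifier object; training accuracy on the labelled pixels
#'   is stored in \code{$trainAccuracy}
#' @export
trainPixelClassifier <- function(stacks, labels, nTrees = 100L, seed = 1L) {
  stopifnot(length(stacks) == length(labels))
  xs <- list(); ys <- list()
  for (i in seq_along(stacks)) {
    stopifnot(identical(stacks[[i]]$dim, dim(labels[[i]])))
    lv <- as.integer(labels[[i]])
    sel <- lv > 0L
    xs[[i]] <- stacks[[i]]$features[sel, , drop = FALSE]
    ys[[i]] <- lv[sel]
  }
  X <- do.call(rbind, xs)
  y <- factor(c("cell", "background")[unlist(ys)],
              levels = c("cell", "background"))
  if (nrow(X) < 2L || length(unique(y)) < 2L)
    stop("need labelled pixels from both classes", call. = FALSE)
  df <- as.data.frame(X)
  df$.class <- y
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = nTrees, probability = TRUE,
                        seed = as.integer(seed), num.threads = 1L)
  pred <- predict(fit, df, num.threads = 1L)$predictions
  acc <- mean((pred[, "cell"] >= 0.5) == (y == "cell"))
  structure(list(forest = fit, scales = stacks[[1]]$scales,
                 featureNames = stacks[[1]]$names, nTrees = nTrees,
                 seed = seed, trainAccuracy = acc),
            class = "pixelClassifier")
}

#' @export
print.pixelClassifier <- function(x, ...) {
  cat(sprintf("pixelClassifier: %d trees, %d features (%d scales), train acc %.3f\n",
              x$nTrees, length(x$featureNames), length(x$scales),
              x$trainAccuracy))
  invisible(x)
}

#' Predict a Cells/Background probability map
#'
#' @param model from \code{\link{trainPixelClassifier}}
#' @param phase phase-contrast raster, or a precomputed feature stack
#' @return a \linkS4class{ProbabilityMap}; P(cell)+P(background)=1 everywhere
#' @export
predictProbabilityMap <- function(model, phase) {
  stack <- if (is.matrix(phase)) extractPixelFeatures(phase, model$scales)
           else phase
  if (!identical(stack$names, model$featureNames))
    stop("feature configuration mismatch between model and input", call. = FALSE)
  pr <- predict(model$forest, as.data.frame(stack$features),
                num.threads = 1L)$predictions
  pc <- matrix(pr[, "cell"], stack$dim[1], stack$dim[2])
  methods::new("ProbabilityMap", cell = pc, background = 1 - pc)
}

#' Scribble labels from ground-truth masks
#'
#' Convenience for training on synthetic scenes: samples sparse pixel labels
#' from a ground-truth cell mask (eroded so scribbles stay well inside each
#' class).
#'
#' @param cellMask label or binary matrix of true cell pixels
#' @param nPerClass scribble pixels per class
#' @param seed integer seed
#' @param erode erosion brush size separating the classes (pixels)
#' @return integer matrix: 0 unlabeled, 1 cell, 2 background
#' @export
scribbleFromTruth <- function(cellMask, nPerClass = 400L, seed = 1L, erode = 3L) {
  set.seed(seed)
  cm <- cellMask > 0
  core <- EBImage::erode(cm * 1, discBrush(erode)) > 0
  # distance of every non-cell pixel to the nearest cell pixel
  d <- EBImage::distmap((!cm) * 1)
  ring <- !cm & d >= 2 & d <= 6   # near background incl. phase halos
  far <- !cm & d > 6
  lab <- matrix(0L, nrow(cellMask), ncol(cellMask))
  ci <- which(core); ri <- which(ring); fi <- which(far)
  lab[sample(ci, min(nPerClass, length(ci)))] <- 1L
  nRing <- min(ceiling(nPerClass / 2), length(ri))
  lab[sample(ri, nRing)] <- 2L
  lab[sample(fi, min(nPerClass - nRing, length(fi)))] <- 2L
  lab
}
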