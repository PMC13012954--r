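# End-to-end frame and run processing: probability map -> cell / DNA /
# Annexin / NET segmentation -> per-cell features -> per-image metrics ->
# optional stage classification.

#' Process a single frame through the full segmentation pipeline
#'
#' Runs the phase image through the pixel classifier, segments cells from
#' the smoothed probability map (adaptive Otsu, correction 0.3, 50-px
#' window, declumping, >= 15 px), DNA objects from the log-transformed green
#' channel (correction 0.8, adaptive threshold bounded below, <= 1000 px)
#' and Annexin objects from the speckle-enhanced red channel (three-class
#' Otsu with the middle class as foreground, <= 1000 px), relates children
#' to their parent cells and merges them per parent, derives NETs as
#' size-filtered extracellular DNA, and assembles the per-cell feature table
#' and the per-image summary row.
#'
#' @param frame a \linkS4class{FrameSet}
#' @param pixelModel a pixelClassifier, or a precomputed
#'   \linkS4class{ProbabilityMap}
#' @param params parameter set from \code{\link{segmentationParams}}
#' @return list: probability, cells, dna, annexin, nets (unmerged + merged),
#'   merged child maps, \code{features} (per-cell data.frame),
#'   \code{imageRow} (one-row per-image data.frame)
#' @export
processFrame <- function(frame, pixelModel,
                         params = segmentationParams(frame@pixelSize)) {
  phase <- channelData(frame, "phase")
  green <- channelData(frame, "green")
  red <- channelData(frame, "red")
  # fluorescence channels carry a constant camera/background offset; subtract
  # the median (background dominates the frame) so the log-gain DNA transform
  # and the adaptive-threshold lower bound operate on signal above background
  g01 <- pmax(green / 65535 - stats::median(green) / 65535, 0)
  r01 <- pmax(red / 65535 - stats::median(red) / 65535, 0)

  pm <- if (methods::is(pixelModel, "ProbabilityMap")) pixelModel
        else predictProbabilityMap(pixelModel, phase)
  pc <- params$cells
  cellImg <- suppressFeatures(pm@cell, pc$suppressSize)
  cells <- identifyPrimaryObjects(cellImg, "cells", minArea = pc$minArea,
                                  classes = pc$classes,
                                  correction = pc$correction,
                                  window = pc$window,
                                  declumpSmooth = pc$declumpSmooth,
                                  declumpTolerance = pc$declumpTolerance)

  pd <- params$dna
  dnaMask <- thresholdDNA(g01, correction = pd$correction,
                          window = pd$window, bounds = pd$bounds)
  dna <- identifyPrimaryObjects(preprocessDNA(g01), "dna",
                                minArea = pd$minArea, maxArea = pd$maxArea,
                                declumpSmooth = pd$declumpSmooth,
                                declumpTolerance = pd$declumpTolerance,
                                excludeBorder = FALSE, mask = dnaMask)

  pa <- params$annexin
  annImg <- enhanceSpeckles(r01, pa$speckleSize)
  annexin <- identifyPrimaryObjects(annImg, "annexin",
                                    minArea = pa$minArea,
                                    maxArea = pa$maxArea,
                                    classes = pa$classes,
                                    middleForeground = pa$middleForeground,
                                    correction = pa$correction,
                                    window = pa$window, bounds = pa$bounds,
                                    declumpSmooth = pa$declumpSmooth,
                                    declumpTolerance = pa$declumpTolerance,
                                    excludeBorder = FALSE)

  aDna <- relateObjects(cells, dna)
  aAnn <- relateObjects(cells, annexin)
  dnaMerged <- mergePerParent(dna, aDna)
  annexinMerged <- mergePerParent(annexin, aAnn)
  nets <- segmentNETs(dna, cells, minArea = params$nets$minArea,
                      expandPx = params$nets$expandPx)
  aNet <- relateObjects(cells, nets$unmerged)

  features <- assembleFeatureTable(
    frame, cells, dnaMerged, annexinMerged, nets$merged,
    childrenCounts = list(dna = attr(aDna, "childrenCount"),
                          annexin = attr(aAnn, "childrenCount"),
                          nets = attr(aNet, "childrenCount")))

  meta <- frameMeta(frame)
  nm <- imageLevelNetMetrics(nets$merged, green)
  imageRow <- data.frame(
    plate = meta$plate %||% NA_character_,
    well = meta$well %||% NA_character_,
    field = meta$field %||% NA_integer_,
    hours_elapsed = meta$hours_elapsed %||% NA_real_,
    treatment = meta$treatment %||% NA_character_,
    Image_Count_Cells = nObjects(cells),
    Image_Count_NETs_merged = nm$count,
    Image_AreaOccupied_NETs_merged = nm$area_px,
    Image_Intensity_TotalIntensity_DNA_NETs_merged = nm$total_intensity,
    stringsAsFactors = FALSE)

  list(probability = pm, cells = cells, dna = dna, annexin = annexin,
       dnaMerged = dnaMerged, annexinMerged = annexinMerged, nets = nets,
       features = features, imageRow = imageRow)
}

#' Process an on-disk imaging run
#'
#' Walks the Phase/Green/Red folder tree of an Incucyte-style export,
#' processes every frame with \code{\link{processFrame}}, attaches
#' treatments from the run's treatment map and optionally classifies every
#' cell with a trained stage model.
#'
#' @param runDir directory holding Phase/, Green/, Red/ and (optionally)
#'   treatments.csv
#' @param pixelModel a pixelClassifier
#' @param stageModel optional stageClassifier; when given, per-cell labels
#'   and the per-image HitTable are included
#' @param params segmentation parameters
#' @param pixelSize micrometres per pixel
#' @return list: \code{perImage}, \code{features}, and with a stage model
#'   \code{labels} and \code{hitTable}
#' @export
processRun <- function(runDir, pixelModel, stageModel = NULL,
                       params = segmentationParams(pixelSize),
                       pixelSize = 0.62) {
  phasePaths <- sort(list.files(file.path(runDir, "Phase"),
                                pattern = "\\.png$", full.names = TRUE))
  if (length(phasePaths) == 0L)
    stop("no phase images under ", runDir, call. = FALSE)
  tmapPath <- file.path(runDir, "treatments.csv")
  tmap <- if (file.exists(tmapPath)) loadTreatmentMap(tmapPath) else NULL
  imgRows <- list(); featRows <- list()
  for (pp in phasePaths) {
    stem <- sub("\\.png$", "", basename(pp))
    frame <- loadFrameSet(
      pp,
      file.path(runDir, "Green", paste0(stem, ".tif")),
      file.path(runDir, "Red", paste0(stem, ".tif")),
      pixelSize = pixelSize)
    if (!is.null(tmap))
      frame@meta$treatment <- lookupTreatment(tmap, frame@meta$well)
    res <- processFrame(frame, pixelModel, params)
    if (!is.null(tmap)) {
      res$imageRow$treatment <- frame@meta$treatment
      if (nrow(res$features))
        res$features$treatment <- frame@meta$treatment
    }
    imgRows[[stem]] <- res$imageRow
    featRows[[stem]] <- res$features
  }
  perImage <- do.call(rbind, imgRows)
  rownames(perImage) <- NULL
  features <- do.call(rbind, featRows[vapply(featRows, nrow, 0L) > 0])
  rownames(features) <- NULL
  out <- list(perImage = perImage, features = features)
  if (!is.null(stageModel)) {
    ct <- classifyAndTally(stageModel, features)
    out$labels <- ct$labels
    out$hitTable <- ct$hitTable
  }
  out
}
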