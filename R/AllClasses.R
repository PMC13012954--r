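#' @import methods
NULL

#' FrameSet: one field of view at one timepoint
#'
#' Container for the three registered channel rasters of a single field of
#' view at a single timepoint, together with its parsed acquisition metadata.
#' The phase-contrast channel is kept on its native 8-bit scale (0--255) and
#' the two fluorescence channels on their native 16-bit scale (0--65535);
#' normalisation to [0,1] happens inside downstream operations.
#'
#' @slot phase numeric matrix, 8-bit phase-contrast raster.
#' @slot green numeric matrix, 16-bit DNA (cytotox dye) raster.
#' @slot red numeric matrix, 16-bit Annexin V raster.
#' @slot meta list with plate, well, field, day, hour, minute, hours_elapsed
#'   and (optionally) treatment.
#' @slot pixelSize numeric, micrometres per pixel (0.62 for the 20x reference
#'   acquisition).
#'
#' @exportClass FrameSet
setClass("FrameSet",
  representation(phase = "matrix", green = "matrix", red = "matrix",
                 meta = "list", pixelSize = "numeric"),
  prototype(meta = list(), pixelSize = 0.62))

setValidity("FrameSet", function(object) {
  d <- dim(object@phase)
  if (!identical(d, dim(object@green)) || !identical(d, dim(object@red)))
    return("phase, green and red rasters must share identical dimensions")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' ProbabilityMap: per-pixel Cells/Background class probabilities
#'
#' Two-channel raster of per-pixel posterior probabilities from the pixel
#' classifier. The two channels sum to one at every pixel.
#'
#' @slot cell numeric matrix of P(cell) in [0,1].
#' @slot background numeric matrix of P(background) in [0,1].
#'
#' @exportClass ProbabilityMap
setClass("ProbabilityMap",
  representation(cell = "matrix", background = "matrix"))

setValidity("ProbabilityMap", function(object) {
  if (!identical(dim(object@cell), dim(object@background)))
    return("cell and background rasters must share dimensions")
  if (any(object@cell < -1e-9) || any(object@cell > 1 + 1e-9))
    return("P(cell) must lie in [0,1]")
  if (max(abs(object@cell + object@background - 1)) > 1e-6)
    return("P(cell) + P(background) must equal 1 (tolerance 1e-6)")
  TRUE
})

#' ObjectMap: labelled segmentation mask for one object family
#'
#' A label raster (0 = background, k = object k, contiguous positive
#' integers, 8-connected after declumping) plus a per-object table with
#' area, centroid, border flag and, for child families, the parent cell.
#'
#' @slot labels integer matrix of object labels.
#' @slot family character, one of "cells", "dna", "annexin", "nets".
#' @slot merged logical, whether objects have been merged per parent cell.
#' @slot table data.frame with columns label, area_px, centroid_r,
#'   centroid_c, border and (for non-cell families) parent.
#'
#' @exportClass ObjectMap
setClass("ObjectMap",
  representation(labels = "matrix", family = "character",
                 merged = "logical", table = "data.frame"),
  prototype(merged = FALSE))

setValidity("ObjectMap", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% c("cells", "dna", "annexin", "nets"))
    return("family must be one of cells, dna, annexin, nets")
  v <- as.integer(object@labels)
  n <- if (length(v)) max(v) else 0L
  if (n > 0L) {
    present <- sort(unique(v[v > 0L]))
    if (!identical(present, seq_len(n)))
      return("labels must be contiguous positive integers 1..n")
    if (!setequal(object@table$label, present))
      return("table rows must match raster labels")
  }
  TRUE
})

newObjectMap <- function(labels, family, merged = FALSE, parent = NULL) {
  labels <- canonicalRelabel(labels)
  tab <- objectSummary(labels)
  if (!is.null(parent)) tab$parent <- parent[tab$label]
  methods::new("ObjectMap", labels = labels, family = family,
               merged = merged, table = tab)
}
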