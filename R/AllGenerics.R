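#' Number of objects in an ObjectMap
#' @param x an \linkS4class{ObjectMap}
#' @return integer count of labelled objects
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' Label raster of an ObjectMap
#' @param x an \linkS4class{ObjectMap}
#' @return integer matrix of labels (0 = background)
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' Per-object table of an ObjectMap
#' @param x an \linkS4class{ObjectMap}
#' @return data.frame with one row per object
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' Object family of an ObjectMap
#' @param x an \linkS4class{ObjectMap}
#' @return character scalar: "cells", "dna", "annexin" or "nets"
#' @export
setGeneric("objectFamily", function(x) standardGeneric("objectFamily"))

#' Channel accessor for FrameSet
#' @param x a \linkS4class{FrameSet}
#' @param which one of "phase", "green", "red"
#' @return numeric matrix on the channel's native integer scale
#' @export
setGeneric("channelData", function(x, which) standardGeneric("channelData"))

#' Frame metadata accessor
#' @param x a \linkS4class{FrameSet}
#' @return list of parsed metadata fields
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))

#' @rdname nObjects
#' @export
setMethod("nObjects", "ObjectMap", function(x) nrow(x@table))

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "ObjectMap", function(x) x@labels)

#' @rdname objectTable
#' @export
setMethod("objectTable", "ObjectMap", function(x) x@table)

#' @rdname objectFamily
#' @export
setMethod("objectFamily", "ObjectMap", function(x) x@family)

#' @rdname channelData
#' @export
setMethod("channelData", "FrameSet", function(x, which = c("phase", "green", "red")) {
  which <- match.arg(which)
  slot(x, which)
})

#' @rdname frameMeta
#' @export
setMethod("frameMeta", "FrameSet", function(x) x@meta)

setMethod("show", "FrameSet", function(object) {
  d <- dim(object@phase)
  m <- object@meta
  cat(sprintf("FrameSet %dx%d px (%.2f um/px)", d[1], d[2], object@pixelSize))
  if (length(m))
    cat(sprintf(" | plate=%s well=%s field=%s t=%.2fh",
                m$plate %||% "?", m$well %||% "?",
                as.character(m$field %||% "?"),
                m$hours_elapsed %||% NA_real_))
  cat("\n")
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap %dx%d px | mean P(cell)=%.3f\n",
              nrow(object@cell), ncol(object@cell), mean(object@cell)))
})

setMethod("show", "ObjectMap", function(object) {
  cat(sprintf("ObjectMap<%s%s> %dx%d px | %d objects\n",
              object@family, if (object@merged) ", merged" else "",
              nrow(object@labels), ncol(object@labels), nrow(object@table)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
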