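# Channel image I/O and Incucyte-style metadata handling.

#' Default Incucyte-style filename pattern
#'
#' The default export convention is \code{{plate}_{well}_{field}_{DD}d{HH}h{MM}m}
#' with the channel encoded by the parent folder (Phase, Green, Red,
#' Probability). The regular expression is exposed so site-specific dialects
#' (different separators or zero-padding) can be configured.
#'
#' @return character scalar, a PCRE with capture groups plate, well, field,
#'   day, hour, minute.
#' @export
incucytePattern <- function() {
  "^(?<plate>[^_]+)_(?<well>[A-Za-z]+[0-9]+)_(?<field>[0-9]+)_(?<day>[0-9]+)d(?<hour>[0-9]+)h(?<minute>[0-9]+)m$"
}

channelFromFolder <- function(folder) {
  switch(tolower(folder),
         phase = "phase", green = "green", red = "red",
         probability = "probability",
         stop("unknown channel folder '", folder, "'", call. = FALSE))
}

#' Parse an Incucyte-style image filename into metadata
#'
#' @param path file path or bare filename; the channel is inferred from the
#'   parent folder name (Phase/Green/Red/Probability) when present, or can be
#'   supplied explicitly.
#' @param pattern filename regex with named capture groups (see
#'   \code{\link{incucytePattern}}).
#' @param channel optional channel override ("phase", "green", "red",
#'   "probability").
#' @return list with plate, well, field, day, hour, minute, hours_elapsed and
#'   channel. \code{hours_elapsed = 24*day + hour + minute/60}.
#' @examples
#' parseIncucyteName("Phase/PlateA_B2_1_00d08h00m.png")
#' @export
parseIncucyteName <- function(path, pattern = incucytePattern(), channel = NULL) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  m <- regexpr(pattern, stem, perl = TRUE)
  if (m == -1L) {
    toks <- strsplit(stem, "_", fixed = TRUE)[[1]]
    bad <- if (length(toks) >= 3 && !grepl("^[0-9]+$", toks[3])) toks[3] else stem
    stop("cannot parse image name '", stem, "': offending token '", bad, "'",
         call. = FALSE)
  }
  st <- attr(m, "capture.start")[1, ]
  len <- attr(m, "capture.length")[1, ]
  tok <- function(nm) substr(stem, st[nm], st[nm] + len[nm] - 1L)
  day <- as.integer(tok("day")); hour <- as.integer(tok("hour"))
  minute <- as.integer(tok("minute"))
  if (hour > 23L || minute > 59L)
    stop("cannot parse image name '", stem, "': offending token '",
         sprintf("%02dd%02dh%02dm", day, hour, minute), "'", call. = FALSE)
  if (is.null(channel)) {
    folder <- basename(dirname(path))
    channel <- if (folder %in% c(".", "", "/")) NA_character_
               else channelFromFolder(folder)
  }
  list(plate = tok("plate"), well = tok("well"),
       field = as.integer(tok("field")),
       day = day, hour = hour, minute = minute,
       hours_elapsed = 24 * day + hour + minute / 60,
       channel = channel)
}

#' Format metadata back into the default Incucyte-style stem
#' @param meta metadata list as returned by \code{\link{parseIncucyteName}}
#' @return character filename stem (no extension, no folder)
#' @export
formatIncucyteName <- function(meta) {
  sprintf("%s_%s_%d_%02dd%02dh%02dm", meta$plate, meta$well,
          as.integer(meta$field), meta$day, meta$hour, meta$minute)
}

#' Read a channel raster losslessly
#'
#' 8-bit grayscale PNG (phase) and 16-bit grayscale TIFF (fluorescence) are
#' read back to their native integer scales so sample values are preserved
#' exactly.
#'
#' @param path image path
#' @param kind "png8" or "tiff16"
#' @param strict error (default) on bit-depth mismatch; if FALSE, convert
#'   with a warning.
#' @return numeric matrix of integer-valued samples
#' @export
readChannelImage <- function(path, kind = c("png8", "tiff16"), strict = TRUE) {
  kind <- match.arg(kind)
  if (kind == "png8") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- info$bit.depth %||% 8
    if (length(dim(img)) == 3L) {
      if (strict) stop("expected single-channel 8-bit PNG: ", path, call. = FALSE)
      warning("multi-channel PNG converted to grayscale: ", path)
      img <- img[, , 1]
    }
    if (depth != 8 && strict)
      stop("expected 8-bit PNG, got ", depth, "-bit: ", path, call. = FALSE)
    stripAttrs(round(img * (2^depth - 1)))
  } else {
    img <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE, info = TRUE))
    bits <- attr(img, "bits.per.sample") %||% 16
    if (length(dim(img)) == 3L) {
      if (strict) stop("expected single-channel TIFF: ", path, call. = FALSE)
      warning("multi-channel TIFF converted to first channel: ", path)
      img <- img[, , 1]
    }
    if (bits != 16) {
      if (strict) stop("expected 16-bit TIFF, got ", bits, "-bit: ", path, call. = FALSE)
      warning("converting ", bits, "-bit TIFF to 16-bit scale: ", path)
      img <- round(img / (2^bits - 1) * 65535)
    }
    storage.mode(img) <- "double"
    stripAttrs(img)
  }
}

# Drop reader metadata attributes so channel rasters are plain matrices.
stripAttrs <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

#' Write a channel raster losslessly
#' @param m integer-valued matrix (0..255 for png8, 0..65535 for tiff16)
#' @param path output path (directories created as needed)
#' @param kind "png8" or "tiff16"
#' @return invisible path
#' @export
writeChannelImage <- function(m, path, kind = c("png8", "tiff16")) {
  kind <- match.arg(kind)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (kind == "png8") {
    stopifnot(all(m >= 0 & m <= 255))
    png::writePNG(m / 255, path)
  } else {
    stopifnot(all(m >= 0 & m <= 65535))
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16, compression = "none")
  }
  invisible(path)
}

#' Load a FrameSet from its three channel images
#'
#' @param phasePath,greenPath,redPath channel image paths; their parsed
#'   metadata keys must agree.
#' @param pixelSize micrometres per pixel (default 0.62).
#' @param pattern filename regex (see \code{\link{incucytePattern}}).
#' @param strict enforce bit depths strictly (default TRUE).
#' @return a \linkS4class{FrameSet}
#' @export
loadFrameSet <- function(phasePath, greenPath, redPath, pixelSize = 0.62,
                         pattern = incucytePattern(), strict = TRUE) {
  mp <- parseIncucyteName(phasePath, pattern, channel = "phase")
  mg <- parseIncucyteName(greenPath, pattern, channel = "green")
  mr <- parseIncucyteName(redPath, pattern, channel = "red")
  key <- function(m) m[c("plate", "well", "field", "day", "hour", "minute")]
  if (!identical(key(mp), key(mg)) || !identical(key(mp), key(mr)))
    stop("channel paths refer to different frames", call. = FALSE)
  phase <- readChannelImage(phasePath, "png8", strict)
  green <- readChannelImage(greenPath, "tiff16", strict)
  red <- readChannelImage(redPath, "tiff16", strict)
  if (!identical(dim(phase), dim(green)) || !identical(dim(phase), dim(red)))
    stop("channel rasters are not registered (shape mismatch)", call. = FALSE)
  meta <- mp[c("plate", "well", "field", "day", "hour", "minute", "hours_elapsed")]
  methods::new("FrameSet", phase = phase, green = green, red = red,
               meta = meta, pixelSize = pixelSize)
}

#' Write a ProbabilityMap as a 32-bit two-channel TIFF
#' @param pm a \linkS4class{ProbabilityMap}
#' @param path output path
#' @return invisible path
#' @export
writeProbabilityMap <- function(pm, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  a <- array(c(pm@cell, pm@background), dim = c(dim(pm@cell), 2L))
  tiff::writeTIFF(a, path, bits.per.sample = 32, compression = "none")
  invisible(path)
}

#' Read a ProbabilityMap from a 32-bit two-channel TIFF
#' @param path input path
#' @return a \linkS4class{ProbabilityMap}
#' @export
readProbabilityMap <- function(path) {
  a <- suppressWarnings(tiff::readTIFF(path))
  stopifnot(length(dim(a)) == 3L, dim(a)[3] >= 2L)
  methods::new("ProbabilityMap", cell = a[, , 1], background = a[, , 2])
}

#' Load a well-to-treatment annotation CSV
#'
#' @param csvPath CSV with header columns \code{well} and \code{treatment}.
#' @return named character vector mapping well to treatment.
#' @export
loadTreatmentMap <- function(csvPath) {
  df <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("well", "treatment") %in% names(df)))
    stop("treatment CSV must have 'well' and 'treatment' columns", call. = FALSE)
  sp <- split(df$treatment, df$well)
  bad <- names(sp)[vapply(sp, function(x) length(unique(x)) > 1L, logical(1))]
  if (length(bad))
    stop("conflicting treatments for well(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  vapply(sp, function(x) x[[1]], character(1))
}

#' Look up a well's treatment
#' @param map named vector from \code{\link{loadTreatmentMap}}
#' @param well well identifier
#' @return treatment string, or NA with a warning when the well is unlisted
#' @export
lookupTreatment <- function(map, well) {
  if (!well %in% names(map)) {
    warning("well '", well, "' not present in treatment map")
    return(NA_character_)
  }
  unname(map[[well]])
}

#' Export per-image and per-object tables
#'
#' Writes \code{per_image.csv}, \code{per_object.csv} and a small
#' \code{properties.json} descriptor (table names, key columns, class list)
#' so the exported run is self-describing and round-trips bit-identically
#' through \code{read.csv}.
#'
#' @param perImage data.frame with one row per image; must carry the metadata
#'   key columns plate, well, field, hours_elapsed, treatment plus
#'   Image_Count_Cells, Image_Count_NETs_merged, Image_AreaOccupied_NETs_merged,
#'   Image_Intensity_TotalIntensity_DNA_NETs_merged.
#' @param perObject data.frame with one row per cell.
#' @param outDir output directory (created as needed).
#' @return invisible named vector of written paths
#' @export
exportTables <- function(perImage, perObject, outDir) {
  keys <- c("plate", "well", "field", "hours_elapsed", "treatment")
  imgCols <- c("Image_Count_Cells", "Image_Count_NETs_merged",
               "Image_AreaOccupied_NETs_merged",
               "Image_Intensity_TotalIntensity_DNA_NETs_merged")
  if (!all(keys %in% names(perImage)) || !all(imgCols %in% names(perImage)))
    stop("per_image table is missing key or metric columns", call. = FALSE)
  if (!all(keys %in% names(perObject)))
    stop("per_object table is missing key columns", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pImg <- file.path(outDir, "per_image.csv")
  pObj <- file.path(outDir, "per_object.csv")
  pProp <- file.path(outDir, "properties.json")
  utils::write.csv(perImage, pImg, row.names = FALSE)
  utils::write.csv(perObject, pObj, row.names = FALSE)
  jsonlite::write_json(
    list(tables = list(per_image = "per_image.csv", per_object = "per_object.csv"),
         key_columns = keys, classes = stageLevels(),
         classification_type = "object"),
    pProp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(per_image = pImg, per_object = pObj, properties = pProp))
}
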