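# Ground-truthed synthetic three-channel scene generator.
#
# Emulates hourly 20x live-cell acquisition at 0.62 um/px: low-contrast cell
# discs with a bright halo on a textured phase background, per-stage DNA
# patterns in green, Annexin V perimeter staining in red, and extracellular
# DNA clouds (>= 150 px) attached to NETosing cells, with Gaussian read noise
# plus signal-dependent Poisson shot noise on the fluorescence channels.

#' Synthetic scene configuration
#'
#' Stage geometry and intensity constants for the generator. The five
#' phenotypes follow the standard morphological criteria: negative (no
#' fluorescence), spread (flattened cell, compact nucleus), disintegrated
#' nucleus (DNA through the cytoplasm), NETosis (extracellular DNA cloud plus
#' perimeter Annexin V), dead (shrunken irregular DNA blob with Annexin V).
#'
#' @param shape image height/width in pixels
#' @param noise list: \code{gaussian_sd_phase}, \code{gaussian_sd_fluor}
#'   (additive read noise, 8-/16-bit units), \code{poisson_gain}
#'   (electrons-per-count scaling of shot noise) and \code{poisson} (logical).
#'   \code{zeroNoise()} disables all of it.
#' @param ... overrides for individual defaults
#' @return configuration list
#' @export
synthConfig <- function(shape = c(160L, 160L),
                        noise = list(gaussian_sd_phase = 2,
                                     gaussian_sd_fluor = 120,
                                     poisson_gain = 60, poisson = TRUE),
                        ...) {
  cfg <- list(
    shape = as.integer(shape),
    radius = list(negative = c(7, 9), spread = c(11, 14),
                  disintegrated = c(8, 11), netosis = c(8, 11),
                  dead = c(5, 7)),
    halo_width = 2, rim_width = 2,
    phase_bg = 110, phase_cell = -18, phase_halo = 45,
    texture_amp = 6, texture_sigma = 8,
    green_bg = 300, red_bg = 250,
    dna_level = 20000, annexin_level = 15000,
    nucleus_frac = 0.45,
    net_area_range = c(160, 350), net_aspect = 1.8,
    noise = noise)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Zero-noise setting for the generator
#' @return noise list with all noise sources disabled
#' @export
zeroNoise <- function() list(gaussian_sd_phase = 0, gaussian_sd_fluor = 0,
                             poisson_gain = 60, poisson = FALSE)

#' Build cell specifications for one frame
#'
#' Places \code{sum(stageCounts)} cells on a jittered grid with enough margin
#' that cell bodies and NET clouds fit inside the frame.
#'
#' @param stageCounts named integer vector over the five stages
#' @param config from \code{\link{synthConfig}}
#' @param seed optional integer seed fixing the placement draws; NULL uses
#'   the current RNG stream
#' @return data.frame: center_r, center_c, radius_px, stage, net_area_px,
#'   dna_level, annexin_level
#' @export
makeCellSpecs <- function(stageCounts, config = synthConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(stageCounts) %in% stageLevels()))
  n <- sum(stageCounts)
  stages <- rep(names(stageCounts), stageCounts)
  if (n == 0L)
    return(data.frame(center_r = numeric(0), center_c = numeric(0),
                      radius_px = numeric(0), stage = character(0),
                      net_area_px = integer(0), dna_level = numeric(0),
                      annexin_level = numeric(0)))
  stages <- sample(stages)
  shp <- config$shape
  margin <- max(unlist(config$radius)) + ceiling(sqrt(max(config$net_area_range))) + 2
  k <- ceiling(sqrt(n))
  if (shp[1] - 2 * margin < k || shp[2] - 2 * margin < k)
    stop("frame too small for requested cell count", call. = FALSE)
  gr <- seq(margin, shp[1] - margin, length.out = k)
  gc <- seq(margin, shp[2] - margin, length.out = k)
  pos <- expand.grid(r = gr, c = gc)[sample(k * k, n), ]
  jit <- min(3, (gr[2] - gr[1]) / 4, na.rm = TRUE)
  rad <- vapply(stages, function(s) stats::runif(1, config$radius[[s]][1],
                                                 config$radius[[s]][2]), numeric(1))
  netArea <- ifelse(stages == "netosis",
                    round(stats::runif(n, config$net_area_range[1],
                                       config$net_area_range[2])), 0L)
  data.frame(
    center_r = round(pos$r + stats::runif(n, -jit, jit)),
    center_c = round(pos$c + stats::runif(n, -jit, jit)),
    radius_px = rad, stage = stages, net_area_px = as.integer(netArea),
    dna_level = ifelse(stages == "negative", 0, config$dna_level),
    annexin_level = ifelse(stages %in% c("netosis", "dead"),
                           config$annexin_level, 0),
    row.names = NULL)
}

#' Render one synthetic frame with ground truth
#'
#' @param specs cell specification data.frame (see \code{\link{makeCellSpecs}});
#'   a \code{stage = "netosis"} row must have \code{net_area_px >= 150} so its
#'   ground-truth NET passes the downstream size filter.
#' @param config from \code{\link{synthConfig}}
#' @param seed integer; fixes every random draw in the rendering
#' @param meta optional metadata list attached to the FrameSet
#' @return list with \code{frame} (a \linkS4class{FrameSet}) and
#'   \code{truth}: cells data.frame (id, stage, geometry, ambiguous flag),
#'   \code{cellMask} and \code{netMask} label rasters (netMask values are
#'   parent cell ids).
#' @export
renderFrame <- function(specs, config = synthConfig(), seed = 1L, meta = list()) {
  # force the arguments before seeding: makeCellSpecs(seed = ...) evaluated
  # lazily after set.seed() would silently reseed the rendering stream
  force(specs); force(config)
  set.seed(seed)
  shp <- config$shape
  nr <- shp[1]; nc <- shp[2]
  if (nrow(specs)) {
    bad <- specs$stage == "netosis" & specs$net_area_px < 150
    if (any(bad)) stop("netosis cells must have net_area_px >= 150", call. = FALSE)
    if (any(specs$stage == "negative" &
            (specs$dna_level > 0 | specs$annexin_level > 0)))
      stop("negative cells must have zero dna_level and annexin_level", call. = FALSE)
  }
  phase <- matrix(config$phase_bg, nr, nc) +
    config$texture_amp * scaleTexture(gaussSmooth(matrix(stats::rnorm(nr * nc), nr, nc),
                                                  config$texture_sigma))
  green <- matrix(0, nr, nc)
  red <- matrix(0, nr, nc)
  cellMask <- matrix(0L, nr, nc)
  netMask <- matrix(0L, nr, nc)
  ambiguous <- logical(nrow(specs))

  rowIdx <- matrix(seq_len(nr), nr, nc)
  colIdx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  # Pass 1: geometry. The full cell mask must exist before any NET cloud is
  # placed, so extracellular DNA never ends up underneath a later cell disc.
  dList <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    r0 <- s$center_r; c0 <- s$center_c; R <- s$radius_px
    if (r0 - R < 1 || r0 + R > nr || c0 - R < 1 || c0 + R > nc)
      stop("cell disc does not fit inside the frame", call. = FALSE)
    d <- sqrt((rowIdx - r0)^2 + (colIdx - c0)^2)
    dList[[i]] <- d
    disc <- d <= R
    halo <- d > R & d <= R + config$halo_width
    phase[disc] <- phase[disc] + config$phase_cell
    phase[halo] <- phase[halo] + config$phase_halo
    cellMask[disc] <- i
  }

  # Pass 2: fluorescence against the complete cell mask.
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    r0 <- s$center_r; c0 <- s$center_c; R <- s$radius_px
    d <- dList[[i]]
    disc <- d <= R

    if (s$stage == "spread") {
      green[d <= config$nucleus_frac * R] <-
        green[d <= config$nucleus_frac * R] + s$dna_level
    } else if (s$stage == "disintegrated") {
      green[disc] <- green[disc] + 0.7 * s$dna_level
    } else if (s$stage == "dead") {
      th <- stats::runif(1, 0, pi)
      u <- (rowIdx - r0) * cos(th) + (colIdx - c0) * sin(th)
      v <- -(rowIdx - r0) * sin(th) + (colIdx - c0) * cos(th)
      blob <- (u / (0.6 * R))^2 + (v / (0.35 * R))^2 <= 1
      green[blob] <- green[blob] + s$dna_level
    } else if (s$stage == "netosis") {
      green[disc] <- green[disc] + 0.5 * s$dna_level
      th <- stats::runif(1, 0, 2 * pi)
      a <- sqrt(s$net_area_px * config$net_aspect / pi) * 1.2
      b <- a / config$net_aspect
      cr <- r0 + (R + 0.55 * a) * sin(th)
      cc <- c0 + (R + 0.55 * a) * cos(th)
      u <- (rowIdx - cr) * sin(th) + (colIdx - cc) * cos(th)   # radial axis
      v <- -(rowIdx - cr) * cos(th) + (colIdx - cc) * sin(th)
      q <- (u / a)^2 + (v / b)^2
      cand <- which(cellMask == 0L & q <= 4)
      if (length(cand) < s$net_area_px)
        stop("NET cloud does not fit inside the frame", call. = FALSE)
      sel <- cand[order(q[cand])[seq_len(s$net_area_px)]]
      taken <- netMask[sel] > 0L
      if (any(taken)) {
        ambiguous[i] <- TRUE
        ambiguous[unique(netMask[sel][taken])] <- TRUE
        sel <- sel[!taken]
      }
      green[sel] <- green[sel] + s$dna_level * (0.4 + 0.6 * exp(-q[sel]))
      netMask[sel] <- i
    }
    if (s$annexin_level > 0) {
      rim <- d <= R & d > R - config$rim_width
      red[rim] <- red[rim] + s$annexin_level
    }
  }

  nz <- config$noise
  green <- green + config$green_bg
  red <- red + config$red_bg
  if (isTRUE(nz$poisson)) {
    g <- nz$poisson_gain
    green <- stats::rpois(length(green), green / g) * g
    red <- stats::rpois(length(red), red / g) * g
  }
  if (nz$gaussian_sd_fluor > 0) {
    green <- green + stats::rnorm(length(green), 0, nz$gaussian_sd_fluor)
    red <- red + stats::rnorm(length(red), 0, nz$gaussian_sd_fluor)
  }
  if (nz$gaussian_sd_phase > 0)
    phase <- phase + stats::rnorm(length(phase), 0, nz$gaussian_sd_phase)
  phase <- matrix(round(clamp(phase, 0, 255)), nr, nc)
  green <- matrix(round(clamp(green, 0, 65535)), nr, nc)
  red <- matrix(round(clamp(red, 0, 65535)), nr, nc)

  truth <- cbind(specs, data.frame(id = seq_len(nrow(specs)),
                                   ambiguous = ambiguous))
  frame <- methods::new("FrameSet", phase = phase, green = green, red = red,
                        meta = meta, pixelSize = 0.62)
  list(frame = frame, truth = truth, cellMask = cellMask, netMask = netMask)
}

scaleTexture <- function(m) {
  s <- stats::sd(m)
  if (s == 0) return(m)
  (m - mean(m)) / s
}

#' Treatment-dependent stage transition schedule
#'
#' Each non-negative stage follows a logistic rise
#' \eqn{f_s(t) = plateau_s / (1 + exp(-rate_s (t - onset_s)))}; the negative
#' fraction is the remainder. Stage fractions must stay nonnegative and sum
#' to at most 1 at every timepoint of the grid.
#'
#' @param treatment label
#' @param stages named list over (a subset of) spread, disintegrated,
#'   netosis, dead; each entry \code{list(onset = h, rate = 1/h,
#'   plateau = fraction)}
#' @param duration total duration in hours (12 or 24 typical)
#' @param interval frame interval in hours (1 typical)
#' @return schedule object (list) for \code{\link{stageFractions}} /
#'   \code{\link{simulateRun}}
#' @export
transitionSchedule <- function(treatment, stages, duration = 12, interval = 1) {
  stopifnot(all(names(stages) %in% setdiff(stageLevels(), "negative")))
  sch <- list(treatment = treatment, stages = stages,
              duration = duration, interval = interval)
  fr <- stageFractions(sch, seq(0, duration, by = interval))
  if (any(fr < -1e-9) || any(rowSums(fr[, -1, drop = FALSE]) > 1 + 1e-9))
    stop("stage fractions must be nonnegative and sum to <= 1", call. = FALSE)
  class(sch) <- "transitionSchedule"
  sch
}

#' Stage fractions of a schedule at given times
#' @param schedule from \code{\link{transitionSchedule}}
#' @param t numeric vector of times (hours)
#' @return matrix (length(t) x 5) with columns negative, spread,
#'   disintegrated, netosis, dead; rows sum to 1
#' @export
stageFractions <- function(schedule, t) {
  out <- matrix(0, length(t), 5, dimnames = list(NULL, stageLevels()))
  for (s in names(schedule$stages)) {
    p <- schedule$stages[[s]]
    out[, s] <- p$plateau / (1 + exp(-p$rate * (t - p$onset)))
  }
  out[, "negative"] <- 1 - rowSums(out[, -1, drop = FALSE])
  out
}

#' Simulate an Incucyte-style imaging run
#'
#' Draws per-frame stage counts multinomially from each well's schedule,
#' renders every frame, and writes the Phase/Green/Red file tree in the
#' default naming convention together with ground-truth tables and the
#' treatment CSV, so the result is readable by the ingestion functions with
#' no special-casing.
#'
#' @param schedules named list: treatment -> schedule
#'   (\code{\link{transitionSchedule}}); all schedules must share duration
#'   and interval.
#' @param wells named character vector: well -> treatment
#' @param fovs fields of view per well
#' @param cellsPerFov cells per field
#' @param config from \code{\link{synthConfig}}
#' @param seed integer master seed; every frame derives its own stream
#' @param outDir output directory, or NULL to keep frames in memory only
#' @param plate plate label
#' @return list: frames (list of renderFrame results, named by image stem),
#'   counts (ground-truth per-frame stage counts), cells (ground-truth
#'   per-cell table), paths of written CSVs when outDir is given
#' @export
simulateRun <- function(schedules, wells, fovs = 2L, cellsPerFov = 20L,
                        config = synthConfig(), seed = 1L, outDir = NULL,
                        plate = "P1") {
  stopifnot(all(wells %in% names(schedules)))
  sch0 <- schedules[[1]]
  times <- seq(0, sch0$duration, by = sch0$interval)
  frames <- list()
  countRows <- list()
  cellRows <- list()
  fi <- 0L
  for (w in names(wells)) {
    sch <- schedules[[wells[[w]]]]
    fr <- stageFractions(sch, times)
    for (fov in seq_len(fovs)) {
      for (ti in seq_along(times)) {
        fi <- fi + 1L
        frameSeed <- (as.integer(seed) %% 100000L) * 20011L + fi * 7L
        set.seed(frameSeed)
        counts <- as.integer(stats::rmultinom(1, cellsPerFov, fr[ti, ]))
        names(counts) <- stageLevels()
        specs <- makeCellSpecs(counts, config)
        tt <- times[ti]
        meta <- list(plate = plate, well = w, field = fov,
                     day = tt %/% 24, hour = floor(tt %% 24),
                     minute = round((tt %% 1) * 60),
                     hours_elapsed = tt, treatment = wells[[w]])
        rf <- renderFrame(specs, config, seed = frameSeed + 1L, meta = meta)
        stem <- formatIncucyteName(meta)
        frames[[stem]] <- rf
        countRows[[fi]] <- data.frame(plate = plate, well = w, field = fov,
                                      hours_elapsed = tt,
                                      treatment = wells[[w]],
                                      t(counts), total = sum(counts))
        if (nrow(rf$truth))
          cellRows[[fi]] <- cbind(data.frame(plate = plate, well = w,
                                             field = fov, hours_elapsed = tt,
                                             treatment = wells[[w]]),
                                  rf$truth)
        if (!is.null(outDir)) {
          writeChannelImage(channelData(rf$frame, "phase"),
                            file.path(outDir, "Phase", paste0(stem, ".png")), "png8")
          writeChannelImage(channelData(rf$frame, "green"),
                            file.path(outDir, "Green", paste0(stem, ".tif")), "tiff16")
          writeChannelImage(channelData(rf$frame, "red"),
                            file.path(outDir, "Red", paste0(stem, ".tif")), "tiff16")
        }
      }
    }
  }
  counts <- do.call(rbind, countRows)
  cells <- if (length(cellRows)) do.call(rbind, cellRows) else NULL
  out <- list(frames = frames, counts = counts, cells = cells)
  if (!is.null(outDir)) {
    utils::write.csv(counts, file.path(outDir, "ground_truth_counts.csv"),
                     row.names = FALSE)
    if (!is.null(cells))
      utils::write.csv(cells, file.path(outDir, "ground_truth_cells.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(well = names(wells),
                                treatment = unname(wells)),
                     file.path(outDir, "treatments.csv"), row.names = FALSE)
    out$paths <- c(counts = file.path(outDir, "ground_truth_counts.csv"),
                   treatments = file.path(outDir, "treatments.csv"))
  }
  out
}
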