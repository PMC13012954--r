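# Shared fixtures for tests that run the imaging pipeline on synthetic
# scenes. Synthetic cells are 7-14 px in radius, so declumping uses a
# smoothing scale matched to that object size (the 10-px default suits the
# larger cells the defaults are calibrated for).

synthTestParams <- function() {
  segmentationParams(declumpSmooth = 4, declumpTolerance = 0.3)
}

defaultStageCounts <- function() {
  c(negative = 4, spread = 4, disintegrated = 4, netosis = 3, dead = 3)
}

makeTestScene <- function(counts = defaultStageCounts(),
                          noise = zeroNoise(), placeSeed = 7,
                          renderSeed = 11, meta = list()) {
  cfg <- synthConfig(noise = noise)
  specs <- makeCellSpecs(counts, cfg, seed = placeSeed)
  renderFrame(specs, cfg, seed = renderSeed, meta = meta)
}

# One pixel classifier per session, trained on a fixed zero-noise scene.
testPixelModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rf <- makeTestScene()
      stack <- extractPixelFeatures(channelData(rf$frame, "phase"))
      scrib <- scribbleFromTruth(rf$cellMask, seed = 2)
      cache <<- trainPixelClassifier(list(stack), list(scrib), seed = 3)
    }
    cache
  }
})

# Majority-overlap matching of segmented cells to ground-truth stages.
matchTruthStages <- function(res, rf) {
  cl <- labelMatrix(res$cells)
  tm <- rf$cellMask
  vapply(seq_len(nObjects(res$cells)), function(ci) {
    tv <- tm[cl == ci & tm > 0]
    if (!length(tv)) return(NA_character_)
    rf$truth$stage[match(as.integer(names(which.max(table(tv)))), rf$truth$id)]
  }, character(1))
}

# Well-separated 5-class Gaussian feature clusters (no imaging involved).
separableFeatures <- function(nPerClass = 200, seed = 1, sd = 0.05) {
  set.seed(seed)
  lv <- c("negative", "spread", "disintegrated", "netosis", "dead")
  labels <- rep(lv, each = nPerClass)
  centers <- seq_along(lv) * 10
  idx <- rep(seq_along(lv), each = nPerClass)
  feats <- data.frame(
    f1 = rnorm(length(labels), centers[idx], sd),
    f2 = rnorm(length(labels), rev(centers)[idx], sd),
    f3 = rnorm(length(labels), 0, 1))
  list(features = feats, labels = labels)
}
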