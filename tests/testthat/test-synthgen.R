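test_that("rendering is deterministic for a fixed seed", {
  cfg <- synthConfig()
  specs <- makeCellSpecs(defaultStageCounts(), cfg, seed = 5)
  a <- renderFrame(specs, cfg, seed = 9)
  b <- renderFrame(specs, cfg, seed = 9)
  expect_identical(channelData(a$frame, "phase"), channelData(b$frame, "phase"))
  expect_identical(channelData(a$frame, "green"), channelData(b$frame, "green"))
  expect_identical(a$truth, b$truth)
})

test_that("ground truth respects the stage semantics", {
  rf <- makeTestScene()
  tr <- rf$truth
  # negative cells have no fluorescence signal at all
  neg <- tr$id[tr$stage == "negative"]
  green <- channelData(rf$frame, "green")
  for (id in neg) {
    sel <- rf$cellMask == id
    expect_equal(max(green[sel]) - min(green[sel]), 0)
  }
  # every netosis cell's extracellular NET is >= 150 px
  for (id in tr$id[tr$stage == "netosis"]) {
    expect_gte(sum(rf$netMask == id), 150)
  }
  # NET pixels are extracellular
  expect_equal(sum(rf$netMask > 0 & rf$cellMask > 0), 0)
})

test_that("an overcrowded frame errors rather than clipping cells", {
  cfg <- synthConfig(shape = c(64L, 64L))
  expect_error(makeCellSpecs(c(negative = 100), cfg, seed = 1), "too small")
})

test_that("transition schedules produce valid stage fractions", {
  sch <- transitionSchedule("pma", list(
    spread = list(plateau = 0.4, onset = 2, rate = 1.5),
    netosis = list(plateau = 0.3, onset = 4, rate = 1)))
  fr <- stageFractions(sch, seq(0, 12, by = 1))
  expect_true(all(fr >= 0) && all(fr <= 1))
  expect_equal(rowSums(fr), rep(1, nrow(fr)))
  # logistic midpoint: half the plateau at the onset time
  frOn <- stageFractions(sch, 2)
  expect_equal(unname(frOn[1, "spread"]), 0.2, tolerance = 1e-9)
  # plateaus summing over 1 are rejected
  expect_error(transitionSchedule("x", list(
    spread = list(plateau = 0.7, onset = 1, rate = 1),
    dead = list(plateau = 0.6, onset = 1, rate = 1))))
})

test_that("simulateRun writes an ingestible file tree", {
  d <- withr::local_tempdir()
  sch <- list(veh = transitionSchedule(
    "veh", list(spread = list(plateau = 0.2, onset = 1, rate = 1)),
    duration = 2, interval = 2))
  run <- simulateRun(sch, c(B1 = "veh"), fovs = 1, cellsPerFov = 6,
                     config = synthConfig(noise = zeroNoise()), seed = 21,
                     outDir = d)
  expect_equal(nrow(run$counts), 2L)
  expect_true(file.exists(file.path(d, "treatments.csv")))
  stems <- names(run$frames)
  phase <- file.path(d, "Phase", paste0(stems[1], ".png"))
  expect_true(file.exists(phase))
  fs <- loadFrameSet(phase,
                     file.path(d, "Green", paste0(stems[1], ".tif")),
                     file.path(d, "Red", paste0(stems[1], ".tif")))
  expect_identical(channelData(fs, "phase"),
                   channelData(run$frames[[1]]$frame, "phase"))
})
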