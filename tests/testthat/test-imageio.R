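test_that("Incucyte names parse and format round-trip", {
  p <- "run/Phase/PlateA_B2_3_1d04h30m.png"
  m <- parseIncucyteName(p)
  expect_equal(m$plate, "PlateA")
  expect_equal(m$well, "B2")
  expect_equal(m$field, 3L)
  expect_equal(m$hours_elapsed, 24 + 4 + 0.5)
  expect_equal(m$channel, "phase")
  expect_equal(formatIncucyteName(m), "PlateA_B2_3_01d04h30m")
})

test_that("malformed names error naming the offending token", {
  expect_error(parseIncucyteName("x/Phase/PlateA_B2_3_1d25h00m.png"), "25h")
  expect_error(parseIncucyteName("x/Phase/PlateA_B2_3_1d04h61m.png"), "61m")
  expect_error(parseIncucyteName("x/Phase/not-a-name.png"))
})

test_that("channel images round-trip losslessly", {
  d <- withr::local_tempdir()
  m8 <- matrix(sample(0:255, 64, replace = TRUE), 8)
  p8 <- file.path(d, "a.png")
  writeChannelImage(m8, p8, "png8")
  expect_identical(readChannelImage(p8, "png8"), m8 + 0)
  m16 <- matrix(sample(0:65535, 64, replace = TRUE), 8)
  p16 <- file.path(d, "a.tif")
  writeChannelImage(m16, p16, "tiff16")
  expect_identical(readChannelImage(p16, "tiff16"), m16 + 0)
})

test_that("probability maps round-trip through 32-bit TIFF", {
  d <- withr::local_tempdir()
  p <- matrix(runif(64), 8)
  pm <- new("ProbabilityMap", cell = p, background = 1 - p)
  path <- file.path(d, "pm.tif")
  writeProbabilityMap(pm, path)
  back <- readProbabilityMap(path)
  expect_equal(back@cell, pm@cell, tolerance = 1e-7)
})

test_that("treatment maps reject conflicts and warn on unlisted wells", {
  d <- withr::local_tempdir()
  ok <- file.path(d, "t.csv")
  write.csv(data.frame(well = c("B1", "B2"), treatment = c("veh", "pma")),
            ok, row.names = FALSE)
  map <- loadTreatmentMap(ok)
  expect_equal(lookupTreatment(map, "B2"), "pma")
  expect_warning(res <- lookupTreatment(map, "C9"), "C9")
  expect_true(is.na(res))
  bad <- file.path(d, "bad.csv")
  write.csv(data.frame(well = c("B1", "B1"), treatment = c("veh", "pma")),
            bad, row.names = FALSE)
  expect_error(loadTreatmentMap(bad), "B1")
})

test_that("exportTables writes a self-describing trio and validates keys", {
  d <- withr::local_tempdir()
  pi <- data.frame(plate = "P", well = "B1", field = 1, hours_elapsed = 0,
                   treatment = "veh", Image_Count_Cells = 3L,
                   Image_Count_NETs_merged = 1L,
                   Image_AreaOccupied_NETs_merged = 200L,
                   Image_Intensity_TotalIntensity_DNA_NETs_merged = 5e5)
  po <- data.frame(plate = "P", well = "B1", field = 1, hours_elapsed = 0,
                   treatment = "veh", cell_id = 1:3, f = rnorm(3))
  paths <- exportTables(pi, po, file.path(d, "out"))
  expect_true(all(file.exists(paths)))
  expect_equal(read.csv(paths[["per_image"]])$Image_Count_Cells, 3L)
  props <- jsonlite::read_json(paths[["properties"]])
  expect_equal(props$classification_type, "object")
  expect_error(exportTables(pi[, -6], po, file.path(d, "out2")), "missing")
})
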