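test_that("connected components are 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- m[2, 2] <- m[3, 3] <- TRUE  # diagonal chain
  expect_equal(max(netprof:::label8(m)), 1L)
  m2 <- matrix(FALSE, 5, 5)
  m2[1, 1] <- m2[1, 3] <- TRUE           # separated by a gap
  expect_equal(max(netprof:::label8(m2)), 2L)
})

test_that("Otsu matches brute-force between-class variance maximisation", {
  set.seed(4)
  x <- pmin(pmax(matrix(c(rnorm(500, 0.3, 0.05), rnorm(500, 0.7, 0.05)), 25),
                 0), 1)
  t1 <- otsuThreshold(x)
  v <- as.numeric(x)
  b <- pmin(pmax(ceiling(v * 256), 1L), 256L)
  bc <- vapply(1:255, function(t) {
    g <- b > t
    if (!any(g) || all(g)) return(-Inf)
    mean(!g) * mean(g) * (mean(v[g]) - mean(v[!g]))^2
  }, numeric(1))
  expect_equal(t1, which.max(bc) / 256)
  expect_true(is.na(otsuThreshold(matrix(0.5, 4, 4))))
})

test_that("three-class Otsu separates a three-level toy image", {
  x <- matrix(c(rep(0.1, 40), rep(0.5, 30), rep(0.9, 30)), 10)
  tt <- otsuThreshold3(x)
  # masks are x > threshold: the cuts must split the three populations
  expect_equal(sum(x <= tt[1]), 40L)
  expect_equal(sum(x > tt[1] & x <= tt[2]), 30L)
  expect_equal(sum(x > tt[2]), 30L)
})

test_that("adaptive thresholding interpolates tiles and applies bounds", {
  # gradient background with bright blobs: per-tile cuts must differ
  nr <- 100
  img <- matrix(rep(seq(0.1, 0.3, length.out = nr), nr), nr, byrow = TRUE)
  img[20:25, 20:25] <- 0.9
  img[70:75, 70:75] <- 0.9
  m <- adaptiveOtsuThreshold(img, window = 50)
  expect_true(all(m[21:24, 21:24]) && all(m[71:74, 71:74]))
  thr <- attr(m, "thresholds")
  expect_true(sd(thr) > 0)
  mB <- adaptiveOtsuThreshold(img, window = 50, bounds = c(0.95, 1))
  expect_equal(sum(mB), 0)
  # constant image: empty mask, no error
  expect_equal(sum(adaptiveOtsuThreshold(matrix(0.4, 60, 60))), 0)
})

test_that("declumping splits a dumbbell but not a disc", {
  m <- matrix(FALSE, 40, 60)
  for (ctr in list(c(20, 18), c(20, 42))) {
    for (r in 1:40) for (cc in 1:60)
      if ((r - ctr[1])^2 + (cc - ctr[2])^2 <= 81) m[r, cc] <- TRUE
  }
  m[19:21, 26:34] <- TRUE  # 3-px-wide bridge
  lab <- netprof:::declumpObjects(m, m * 1, declumpSmooth = 4,
                                  tolerance = 0.3)
  expect_equal(max(lab), 2L)
  disc <- matrix(FALSE, 30, 30)
  for (r in 1:30) for (cc in 1:30)
    if ((r - 15)^2 + (cc - 15)^2 <= 100) disc[r, cc] <- TRUE
  expect_equal(max(netprof:::declumpObjects(disc, disc * 1, 4,
                                            tolerance = 0.3)), 1L)
})

test_that("size filters are inclusive at the boundary", {
  lab <- matrix(0L, 40, 80)
  lab[2:16, 2:11] <- 1L   # 150 px
  lab[25:35, 30:40] <- 0L
  # second object: 149 px
  lab[20:38, 50:60] <- 0L
  lab[2:16, 50:59] <- 2L
  lab[16, 59] <- 0L       # 150 - 1 = 149 px
  om <- netprof:::keepObjects(lab, "nets", minArea = 150,
                              excludeBorder = FALSE)
  expect_equal(nObjects(om), 1L)
  expect_equal(objectTable(om)$area_px, 150L)
  om2 <- netprof:::keepObjects(lab, "dna", maxArea = 149,
                               excludeBorder = FALSE)
  expect_equal(objectTable(om2)$area_px, 149L)
})

test_that("NETs are extracellular DNA >= 150 px linked to a parent", {
  nr <- 80
  cells <- matrix(0L, nr, nr)
  cells[30:50, 10:30] <- 1L
  dnaLab <- matrix(0L, nr, nr)
  dnaLab[35:45, 25:45] <- 1L   # overlaps the cell, extends 15 px beyond
  dna <- netprof:::newObjectMap(dnaLab, "dna")
  cellsOm <- netprof:::newObjectMap(cells, "cells")
  nets <- segmentNETs(dna, cellsOm, minArea = 150, expandPx = 1)
  expect_equal(nObjects(nets$merged), 1L)
  expect_equal(objectTable(nets$merged)$parent, 1L)
  # extracellular part is 11 x 15 = 165 px >= 150; shrink below 150 and the
  # NET disappears
  dnaLab2 <- matrix(0L, nr, nr)
  dnaLab2[35:45, 25:43] <- 1L  # extracellular 11 x 13 = 143 px
  nets2 <- segmentNETs(netprof:::newObjectMap(dnaLab2, "dna"), cellsOm,
                       minArea = 150, expandPx = 1, sizePreExpand = TRUE)
  expect_equal(nObjects(nets2$merged), 0L)
  # orphan extracellular DNA (no adjacent cell) is not a NET
  dnaLab3 <- matrix(0L, nr, nr)
  dnaLab3[55:75, 55:75] <- 1L
  nets3 <- segmentNETs(netprof:::newObjectMap(dnaLab3, "dna"), cellsOm,
                       minArea = 150, expandPx = 1)
  expect_equal(nObjects(nets3$merged), 0L)
})

test_that("children relate to the maximum-overlap parent with stable ties", {
  parents <- matrix(0L, 20, 20)
  parents[2:10, 2:10] <- 1L
  parents[2:10, 12:19] <- 2L
  kids <- matrix(0L, 20, 20)
  kids[4:6, 8:14] <- 1L   # overlaps parent 1 on cols 8:10, parent 2 on 12:14
  a <- relateObjects(netprof:::newObjectMap(parents, "cells"),
                     netprof:::newObjectMap(kids, "dna"))
  expect_equal(unname(a[1]), 1L)  # 9 px each: tie -> lower parent label
  expect_equal(attr(a, "childrenCount"), c(1L, 0L))
})

test_that("merging children per parent preserves total area", {
  kids <- matrix(0L, 20, 20)
  kids[2:4, 2:4] <- 1L
  kids[10:12, 10:12] <- 2L
  kids[16:18, 16:18] <- 3L
  km <- netprof:::newObjectMap(kids, "dna")
  assign <- c(1L, 1L, 2L)
  merged <- mergePerParent(km, assign)
  expect_true(merged@merged)
  expect_equal(sort(objectTable(merged)$area_px), c(9L, 18L))
  expect_equal(objectTable(merged)$parent, c(1L, 2L))
})

test_that("DNA thresholding applies bounds on the raw intensity scale", {
  set.seed(11)
  g <- matrix(abs(rnorm(160 * 160, 0, 0.002)), 160)  # pure noise floor
  g[40:60, 40:60] <- 0.3                             # one bright nucleus
  m <- thresholdDNA(g, correction = 0.8, bounds = c(0.01, 1))
  expect_true(all(m[41:59, 41:59]))
  expect_lt(mean(m[g < 0.01]), 0.001)
  expect_true(all(attr(m, "thresholds") >= 0.01))
})
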