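test_that("intensity statistics match hand-computed values", {
  v <- c(1, 2, 3, 4, 10)
  s <- measureIntensity(v)
  expect_equal(unname(s["max"]), 10)
  expect_equal(unname(s["min"]), 1)
  expect_equal(unname(s["mean"]), 4)
  expect_equal(unname(s["median"]), 3)
  expect_equal(unname(s["lower_quartile"]), 2)
  expect_equal(unname(s["upper_quartile"]), 4)
  expect_equal(unname(s["std"]), sd(v))
  # unscaled MAD: median(|x - median|) = median(2,1,0,1,7)
  expect_equal(unname(s["mad"]), 1)
  expect_true(all(is.na(measureIntensity(numeric(0)))))
})

test_that("granularity spectrum localises structure size", {
  img <- matrix(0, 60, 60)
  mask <- matrix(TRUE, 60, 60)
  for (ctr in list(c(15, 15), c(15, 45), c(45, 15), c(45, 45))) {
    d <- sqrt(outer((1:60 - ctr[1])^2, (1:60 - ctr[2])^2, `+`))
    img[d <= 2] <- 1
  }
  gs <- measureGranularity(mask, img)
  expect_true(all(gs >= 0))
  expect_lte(sum(gs), 100 + 1e-8)
  # radius-2 speckles vanish entirely under openings of radius > 2
  expect_gt(sum(gs[1:3]), 99)
  expect_lt(sum(gs[6:16]), 1e-8)
  # zero signal: all-zero spectrum, not NaN
  expect_equal(unname(measureGranularity(mask, img * 0)), rep(0, 16))
})

test_that("radial distribution is normalised and flat for uniform objects", {
  cell <- matrix(FALSE, 40, 40)
  d <- sqrt(outer((1:40 - 20)^2, (1:40 - 20)^2, `+`))
  cell[d <= 12] <- TRUE
  obj <- d <= 8
  r <- measureRadialDistribution(obj, cell, matrix(1, 40, 40), nBins = 4)
  frac <- r[paste0("FracAtD_", 1:4)]
  expect_equal(sum(frac), 1)
  # uniform intensity: per-bin intensity fraction equals pixel fraction
  expect_equal(unname(r[paste0("MeanFrac_", 1:4)]), rep(1, 4))
  expect_true(all(r[paste0("RadialCV_", 1:4)] >= 0))
  expect_true(all(is.na(
    measureRadialDistribution(obj, cell, matrix(0, 40, 40)))))
})

test_that("Haralick features match the 2x2 hand-derived oracle", {
  raster <- matrix(c(0, 0, 0, 1), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  tx <- measureTexture(mask, raster, levels = 2L, distance = 1L)
  # averaged over the four symmetrised offsets, derived by hand
  expect_equal(unname(tx["contrast"]), 0.5)
  expect_equal(unname(tx["correlation"]), -5 / 9)
  expect_equal(unname(tx["variance"]), 0.15625)
  expect_equal(unname(tx["entropy"]), 1)
  expect_equal(unname(tx["inverse_difference_moment"]), 0.75)
  expect_equal(unname(tx["sum_variance"]), 4.5)
  expect_equal(unname(tx["sum_entropy"]), 0.5)
  expect_equal(unname(tx["difference_variance"]), 0.125)
})

test_that("constant-intensity objects get defined degenerate texture", {
  mask <- matrix(TRUE, 5, 5)
  tx <- measureTexture(mask, matrix(0.3, 5, 5))
  expect_equal(unname(tx["contrast"]), 0)
  expect_true(is.na(tx["correlation"]))
  expect_equal(unname(tx["entropy"]), 0)
  expect_equal(unname(tx["inverse_difference_moment"]), 1)
  expect_true(all(is.na(measureTexture(matrix(FALSE, 5, 5),
                                       matrix(0.3, 5, 5)))))
})

test_that("Zernike magnitudes are rotation invariant", {
  set.seed(3)
  m <- matrix(FALSE, 41, 41)
  d <- sqrt(outer((1:41 - 21)^2, (1:41 - 21)^2, `+`))
  th <- atan2(outer(1:41 - 21, rep(1, 41)), outer(rep(1, 41), 1:41 - 21))
  m[d <= 12 + 4 * cos(3 * th)] <- TRUE   # asymmetric trefoil blob
  z0 <- zernikeMagnitudes(m)
  rot90 <- t(m)[, rev(seq_len(ncol(m)))]  # 90-degree rotation
  z90 <- zernikeMagnitudes(rot90)
  expect_equal(z0, z90, tolerance = 1e-8)
  expect_gt(z0["zernike_0_0"], 0)
  expect_length(z0, 30L)
})

test_that("shape features report the pixel area", {
  m <- matrix(FALSE, 20, 20)
  m[5:14, 5:14] <- TRUE
  s <- measureShape(m)
  expect_equal(unname(s["area"]), 100)
  expect_gt(s["max_radius"], s["min_radius"])
  expect_gte(s["eccentricity"], 0)
})

test_that("feature table columns stay aligned when children are missing", {
  rf <- makeTestScene()
  res <- processFrame(rf$frame, testPixelModel(), params = synthTestParams())
  df <- res$features
  expect_true(all(c("cell_id", "Children_count_dna", "Children_count_annexin",
                    "Children_count_nets") %in% names(df)))
  expect_gt(nrow(df), 0)
  # cells without a DNA child must have NA DNA features, not shifted columns
  noDna <- is.na(df$Intensity_mean_DNA_dna)
  expect_true(any(noDna) && any(!noDna))
  dnaCols <- grep("^(Intensity|Texture)_.*_dna$", names(df), value = TRUE)
  expect_gt(length(dnaCols), 10)
  expect_true(all(is.na(df[noDna, dnaCols])))
  expect_true(all(!is.na(df[!noDna, "Intensity_mean_DNA_dna"])))
  # children counts agree with feature presence for merged DNA objects
  expect_true(all(df$Children_count_dna[!noDna] >= 1))
})
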