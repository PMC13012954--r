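test_that("IQR filtering removes the hand-picked outlier and logs it", {
  v <- c(1, 2, 3, 4, 100)
  f <- iqrFilter(v, wells = c("B1", "B1", "B2", "B2", "B3"))
  expect_equal(f$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(f$log$n_removed, 1L)
  expect_equal(f$removalByWell$n_removed[f$removalByWell$well == "B3"], 1L)
  # fewer than 4 finite values: everything passes, with a warning
  expect_warning(f2 <- iqrFilter(c(1, 2, 1000)), "fewer than 4")
  expect_true(all(f2$keep))
})

test_that("temporal integral is the trapezoid rule", {
  expect_equal(temporalIntegral(c(0, 1, 2), c(0, 10, 20)), 20)
  expect_equal(temporalIntegral(c(0, 2), c(5, 5)), 10)
  expect_error(temporalIntegral(1, 5))
  expect_error(temporalIntegral(c(0, 0, 1), c(1, 2, 3)))
})

test_that("timing metrics match hand calculations on a linear ramp", {
  t <- c(0, 1, 2)
  y <- c(0, 1, 2)
  tm <- timingMetrics(t, y)
  expect_equal(tm$onset10, 0.2)
  expect_equal(tm$t50, 1)
  expect_equal(tm$centroid, 5 / 3)
  # a trace already above threshold at the first point starts there
  expect_equal(timingMetrics(c(2, 3), c(5, 6))$onset10, 2)
  expect_true(all(is.na(unlist(timingMetrics(t, c(0, 0, 0))))))
})

test_that("timing metrics recover the parameters of a sampled logistic", {
  t <- seq(0, 24, by = 1)
  plateau <- 30; onset <- 9; rate <- 1.2
  y <- plateau / (1 + exp(-rate * (t - onset)))
  tm <- timingMetrics(t, y)
  # t50 is where the curve reaches half its maximum: near the midpoint
  expect_lt(abs(tm$t50 - onset), 1)
  expect_lt(tm$onset10, tm$t50)
})

test_that("CLR vectors sum to zero and respect compositional scaling", {
  ti <- c(spread = 3, disintegrated = 12, netosis = 0.4)
  z <- clrCompose(ti)
  expect_equal(sum(z), 0)
  # scaling the composition and the pseudocount together changes nothing
  expect_equal(clrCompose(5 * ti, pseudocount = 2.5), z)
  expect_error(clrCompose(c(-1, 2, 3)))
})

test_that("PERMANOVA separates shifted groups and matches vegan", {
  set.seed(20)
  a <- matrix(rnorm(30), 10)
  b <- matrix(rnorm(30, 2), 10)
  x <- rbind(a, b)
  g <- rep(c("veh", "pma"), each = 10)
  res <- permanova(x, g, nPerm = 999, seed = 5)
  expect_equal(res$p, 1 / 1000)   # add-one convention floor
  expect_equal(unname(res$df), c(1L, 18L))
  ad <- vegan::adonis2(dist(x) ~ g, permutations = 99)
  expect_equal(res$F, ad$F[1])
  # exchangeable data: p well above significance
  resNull <- permanova(matrix(rnorm(60), 20), g, nPerm = 199, seed = 6)
  expect_gt(resNull$p, 0.05)
  expect_error(permanova(x, rep("one", 20)), ">= 2 groups")
})

test_that("pairwise PERMANOVA reports adjusted p per group pair", {
  set.seed(21)
  x <- rbind(matrix(rnorm(12), 4), matrix(rnorm(12, 3), 4),
             matrix(rnorm(12, 6), 4))
  g <- rep(c("a", "b", "c"), each = 4)
  res <- permanova(x, g, nPerm = 199, seed = 2, pairwise = TRUE)
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p))
})

test_that("contribution decomposition is a percentage split of the shift", {
  a <- matrix(c(3, 4, 0), 1)
  b <- matrix(0, 1, 3)
  colnames(a) <- colnames(b) <- c("spread", "disintegrated", "netosis")
  ct <- clrContribution(a, b)
  expect_equal(unname(ct), c(36, 64, 0))
  expect_equal(sum(ct), 100)
  expect_true(all(is.na(clrContribution(a, a))))
  expect_error(clrContribution(a[0, , drop = FALSE], b), "non-empty")
})

test_that("agreement statistics satisfy their identities", {
  x <- c(3, 8, 2, 9, 5, 7)
  s <- agreementStats(x, x)
  expect_equal(s$icc2, 1)
  expect_equal(s$icc3, 1)
  expect_equal(s$lin_ccc, 1)
  expect_equal(s$bias, 0)
  expect_equal(s$mae, 0)
  expect_equal(s$rmse, 0)
  expect_true(is.na(s$rank_biserial))
  # constant offset: consistency (ICC3) is perfect, absolute agreement is not
  so <- agreementStats(x, x + 2)
  expect_equal(so$icc3, 1)
  expect_lt(so$icc2, 1)
  expect_lt(so$lin_ccc, 1)
  expect_equal(so$bias, -2)
  expect_equal(so$mae, 2)
  expect_equal(so$rank_biserial, -1)
  expect_error(agreementStats(1:2, 1:2), "at least 3")
})

test_that("independent methods show near-zero agreement at large n", {
  set.seed(33)
  n <- 10000
  x <- rnorm(n)
  y <- rnorm(n)
  s <- agreementStats(x, y)
  expect_lt(abs(s$icc2), 0.05)
  expect_lt(abs(s$lin_ccc), 0.05)
})

test_that("time courses aggregate fields, wells and treatments correctly", {
  grid <- c(0, 6, 12)
  hits <- expand.grid(well = c("B1", "B2"), field = 1:2,
                      hours_elapsed = grid, stringsAsFactors = FALSE)
  hits$treatment <- "pma"
  hits$total <- 50L
  hits$negative <- 40L
  hits$spread <- 5L
  hits$disintegrated <- 0L
  hits$netosis <- 5L
  hits$dead <- 0L
  tc <- buildTimecourses(hits)
  net <- tc$perTreatment[tc$perTreatment$stage == "netosis", ]
  expect_equal(net$median_pct, rep(10, 3))
  tiNet <- tc$tiPerWell[tc$tiPerWell$stage == "netosis", ]
  expect_equal(tiNet$ti, rep(120, 2))  # constant 10% over 12 h
  expect_error(buildTimecourses(hits[, -5]), "missing columns")
})

test_that("replicate compositions are CLR rows with a groups attribute", {
  ti <- data.frame(treatment = rep(c("veh", "pma"), each = 3),
                   well = rep(c("B1", "B2"), each = 3),
                   stage = rep(c("spread", "disintegrated", "netosis"), 2),
                   ti = c(1, 2, 0, 30, 10, 90),
                   onset10 = NA, t50 = NA, centroid = NA)
  m <- composeReplicates(ti)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(rowSums(m)), c(0, 0))
  expect_equal(unname(attr(m, "groups")),
               c(B1 = "veh", B2 = "pma")[rownames(m)], ignore_attr = TRUE)
})
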