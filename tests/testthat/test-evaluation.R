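test_that("AICc follows the small-sample formula and its guards", {
  aicc <- pestRisk:::aiccValue
  expect_equal(aicc(3, -120, 50), 246 + 24 / 46)
  expect_true(is.na(aicc(49, -120, 50)))   # k = n - 1
  expect_true(is.na(aicc(60, -120, 50)))
  expect_true(is.na(aicc(0, -120, 50)))
  ## penalty is monotone in k at fixed likelihood
  expect_lt(aicc(2, -100, 50), aicc(40, -100, 50))
})

test_that("model AICc uses raw scores renormalised over the grid", {
  fit <- fitMaxEnt(tinyPresVals, tinyBgVals, classes = "LQ")
  gridVals <- stackValues(tinyStack, pestRisk:::validCells(tinyStack))
  a <- computeAicc(fit, tinyPresVals, gridVals)
  rawOcc <- predictSuitability(fit, tinyPresVals, "raw")
  rawGrid <- predictSuitability(fit, gridVals, "raw")
  lnL <- sum(log(rawOcc / sum(rawGrid)))
  n <- nrow(tinyPresVals); k <- countParameters(fit)
  expect_equal(a, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1))
  ## lnL is invariant to rescaling raw scores before renormalisation
  lnL2 <- sum(log((7.3 * rawOcc) / sum(7.3 * rawGrid)))
  expect_equal(lnL, lnL2, tolerance = 1e-12)
  ## a uniform model assigns lnL = -n ln G over a G-cell grid
  unif <- fitMaxEnt(tinyPresVals, tinyBgVals, classes = "LQ",
                    regMultiplier = 1e6)
  rawU <- predictSuitability(unif, tinyPresVals, "raw")
  rawUG <- predictSuitability(unif, gridVals, "raw")
  expect_equal(sum(log(rawU / sum(rawUG))), -n * log(nrow(gridVals)),
               tolerance = 1e-9)
})

test_that("AUC equals brute-force pair counting, including ties", {
  expect_equal(computeAuc(rep(0.9, 4), rep(0.1, 7)), 1)
  expect_equal(computeAuc(rep(0.5, 4), rep(0.5, 7)), 0.5)
  expect_equal(computeAuc(c(0.8, 0.4), c(0.6, 0.2, 0.4)), 0.75)
  for (case in 1:30) {
    set.seed(case)
    sp <- sample(seq(0, 1, by = 0.1), sample(2:20, 1L), replace = TRUE)
    sb <- sample(seq(0, 1, by = 0.1), sample(2:20, 1L), replace = TRUE)
    expect_equal(computeAuc(sp, sb), bruteAuc(sp, sb))
  }
})

test_that("train/test splitting partitions reproducibly", {
  s <- splitTrainTest(100, 0.25, seed = 5)
  expect_length(s$test, 25L)
  expect_length(s$train, 75L)
  expect_setequal(c(s$train, s$test), 1:100)
  expect_length(intersect(s$train, s$test), 0L)
  expect_identical(splitTrainTest(100, 0.25, seed = 5), s)
  expect_length(splitTrainTest(tinyOcc, 0.2, seed = 1)$test,
                round(0.2 * nRecords(tinyOcc)))
})

test_that("CBI detects concentration, inversion and noise", {
  set.seed(9)
  land <- runif(20000)
  concentrated <- sample(land, 400, prob = land^4)
  expect_gte(computeCbi(concentrated, land), 0.9)
  inverted <- sample(land, 400, prob = (1 - land)^4)
  expect_lte(computeCbi(inverted, land), -0.9)
  unif <- vapply(1:20, function(s) {
    set.seed(s); computeCbi(sample(land, 300), land)
  }, numeric(1L))
  expect_lte(abs(mean(unif)), 0.3)
  ## rank-based: stable under a strictly increasing transform
  expect_lt(abs(computeCbi(concentrated, land) -
                computeCbi(concentrated^3, land^3)), 0.1)
  ## degenerate inputs yield the undefined marker
  expect_true(is.na(computeCbi(c(0.5, 0.6), rep(0.5, 10))))
})

test_that("tuning evaluates the grid and selects the AICc minimum", {
  smallGrid <- tuningGrid(regMultipliers = c(1, 2), classSets = c("L", "LQ"))
  rep <- tuneModels(tinyOcc, tinyBackground, tinyStack, grid = smallGrid,
                    seed = 3)
  expect_equal(nrow(rep$candidates), 4L)
  expect_equal(rep$candidates$AICc[rep$selected],
               min(rep$candidates$AICc, na.rm = TRUE))
  expect_true(all(rep$candidates$AUC_train >= 0 &
                  rep$candidates$AUC_train <= 1, na.rm = TRUE))
  ## a one-cell grid selects its only candidate
  one <- tuneModels(tinyOcc, tinyBackground, tinyStack,
                    grid = tuningGrid(1.5, "LQ"), seed = 3)
  expect_equal(one$selected, 1L)
  expect_equal(one$candidates$rm, 1.5)
  ## the selected model is returned and scores the landscape
  pred <- predictSuitability(one$model, tinyStack)
  expect_true(all(gridValues(pred) >= 0 & gridValues(pred) <= 1, na.rm = TRUE))
})

test_that("a strong niche passes the null-model significance test", {
  sharp <- nicheSpec(optimum = rep(0, 5), tolerance = rep(0.8, 5),
                     maxProb = 0.95)
  occ <- samplePresences(generateVirtualSpecies(tinyStack, sharp), 60,
                         seed = 21)
  bg <- suppressWarnings(
    selectBackground(occ, tinyZones, tinyStack, nPoints = 600, seed = 5))
  res <- suppressWarnings(nullModelTest(
    occ, bg, tinyStack, classes = "LQ", regMultiplier = 1,
    nNull = 20, seed = 17))
  expect_length(res$nullAucs, 20L)
  expect_true(res$significant)
  expect_equal(res$percentile, 100)
  ## reproducible under the same seed
  res2 <- suppressWarnings(nullModelTest(
    occ, bg, tinyStack, classes = "LQ", regMultiplier = 1,
    nNull = 20, seed = 17))
  expect_equal(res$nullAucs, res2$nullAucs)
  expect_equal(res$empiricalAuc, res2$empiricalAuc)
})
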