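test_that("surface normalization maps to [0, 1] with degenerate handling", {
  r <- rasterGrid(matrix(c(2, 4, 6, NA), 2, 2))
  n <- normalizeSurface(r)
  expect_equal(as.vector(gridValues(n)), c(0, 0.5, 1, NA))
  already <- rasterGrid(matrix(c(0, 0.25, 1, 0.5), 2, 2))
  expect_equal(gridValues(normalizeSurface(already)), gridValues(already))
  expect_warning(z <- normalizeSurface(rasterGrid(matrix(3, 2, 2))), "constant")
  expect_equal(unique(as.vector(gridValues(z))), 0)
})

test_that("invasion risk is the cellwise product with nodata propagation", {
  suit <- rasterGrid(matrix(c(0.8, 0.2, NA, 1), 2, 2))
  intro <- rasterGrid(matrix(c(0.5, 1, 0.3, 0), 2, 2))
  risk <- invasionRisk(suit, intro)
  expect_equal(as.vector(gridValues(risk)), c(0.4, 0.2, NA, 0))
  ## product never exceeds either operand
  ok <- !is.na(gridValues(risk))
  expect_true(all(gridValues(risk)[ok] <= gridValues(suit)[ok]))
  expect_true(all(gridValues(risk)[ok] <= gridValues(intro)[ok]))
  ## zero introduction kills all risk
  none <- invasionRisk(suit, rasterGrid(matrix(0, 2, 2)))
  expect_equal(as.vector(gridValues(none)), c(0, 0, NA, 0))
  ## misaligned introduction surfaces are resampled onto the suitability grid
  fine <- rasterGrid(matrix(runif(64), 8, 8), 0, 0, cellSize = 0.25)
  expect_message(r2 <- invasionRisk(suit, fine), "resampled")
  expect_equal(gridDim(r2), c(2L, 2L))
})

test_that("Jenks breaks find the obvious gap and isolate outliers", {
  expect_equal(jenksBreaks(c(1, 2, 10, 11), 2)[1L], 2)
  ## outlier forced into its own class
  v <- c(seq(5, 6, length.out = 8), 100)
  br <- jenksBreaks(v, 2)
  expect_equal(br[1L], 6)                     # outlier isolated
  expect_equal(ssdFromBreaks(v, br), bruteJenksSSD(v, 2))
  ## isolating the outlier beats any split inside the tight cluster
  expect_lt(ssdFromBreaks(v, br), ssdFromBreaks(v, c(5.5)))
  expect_error(jenksBreaks(1:10, 1), "k")
  expect_error(jenksBreaks(c(1, 1, 1, 2), 3), "distinct")
})

test_that("the Jenks DP matches exhaustive partition search on fuzzed samples", {
  for (case in 1:100) {
    set.seed(case)
    n <- sample(5:12, 1L)
    k <- sample(2:4, 1L)
    if (k > n) next
    v <- round(runif(n, 0, 10), 2)
    if (length(unique(v)) < k) next
    br <- jenksBreaks(v, k)
    expect_equal(ssdFromBreaks(v, br), bruteJenksSSD(v, k), tolerance = 1e-9)
  }
})

test_that("map classification is exhaustive with right-closed boundaries", {
  set.seed(3)
  vals <- matrix(runif(400), 20, 20)
  vals[1, 1] <- NA
  cm <- classifyMap(rasterGrid(vals), k = 4)
  labs <- gridValues(cm)
  expect_equal(sum(!is.na(labs)), sum(!is.na(vals)))
  expect_true(all(labs[!is.na(labs)] %in% 1:4))
  ## a value exactly on a break belongs to the lower class
  four <- classifyMap(rasterGrid(matrix(c(1, 2, 10, 11), 2, 2)), k = 2,
                      labels = c("low", "high"))
  expect_equal(four@breaks, 2)                       # break value is a datum
  expect_equal(as.vector(gridValues(four)), c(1, 1, 2, 2))
  ## reclassifying per-class midpoints reproduces the class sequence
  mids <- c((min(vals, na.rm = TRUE) + cm@breaks[1L]) / 2,
            (cm@breaks[1L] + cm@breaks[2L]) / 2,
            (cm@breaks[2L] + cm@breaks[3L]) / 2,
            (cm@breaks[3L] + max(vals, na.rm = TRUE)) / 2)
  expect_equal(1L + rowSums(outer(mids, cm@breaks, ">")), 1:4)
})

test_that("zonal means equal the per-cell point-in-polygon oracle", {
  vals <- matrix(seq(0, 1, length.out = 100), 10, 10)
  r <- rasterGrid(vals)  # unit cells, origin (0, 0)
  ## polygon covering exactly cells (1,1) and (2,1): values at centres
  ring <- cbind(c(0, 1, 1, 0), c(0, 0, 2, 2))
  zm <- zonalMean(r, polygonSet("A", list(ring)))
  expect_equal(zm$mean_suitability, mean(vals[1:2, 1L]))
  expect_equal(zm$n_cells, 2L)
  ## nested polygon over a uniform raster returns the constant
  u <- rasterGrid(matrix(0.42, 10, 10))
  zu <- zonalMean(u, polygonSet("B", list(cbind(c(2, 7, 7, 2), c(2, 2, 7, 7)))))
  expect_equal(zu$mean_suitability, 0.42)
  ## synthetic tiling agrees with a direct membership computation
  anc <- generateAncillarySurfaces(tinySpec, seed = 31)
  zm2 <- zonalMean(tinySurface, anc$municipalities)
  ctr <- cellCenters(tinySurface)
  v <- as.vector(gridValues(tinySurface))
  for (i in c(1L, 7L, 25L)) {
    inside <- pointsInRing(anc$municipalities@rings[[i]], ctr)
    expect_equal(zm2$mean_suitability[i], mean(v[inside]))
  }
  ## polygons with no cell centre give NA with a warning
  expect_warning(
    empty <- zonalMean(r, polygonSet("C", list(cbind(c(0.6, 0.9, 0.9, 0.6),
                                                     c(0.6, 0.6, 0.9, 0.9))))),
    "no raster cell centre")
  expect_true(is.na(empty$mean_suitability))
})

test_that("plantation overlap fractions are exact on constructed geometry", {
  ## four value plateaus by column block: classes 1..4 are column bands
  vals <- cbind(matrix(0.1, 10, 2), matrix(0.35, 10, 3),
                matrix(0.65, 10, 3), matrix(0.9, 10, 2))
  cm <- classifyMap(rasterGrid(vals), k = 4)
  ## two equal 2x2-cell plantations, one in class 1, one in class 4
  p <- polygonSet(c("P1", "P2"),
                  list(cbind(c(0, 2, 2, 0), c(1, 1, 3, 3)),
                       cbind(c(8, 10, 10, 8), c(1, 1, 3, 3))))
  ov <- plantationOverlap(cm, p, targetCellSize = 0.5)
  expect_equal(sum(ov$fraction), 1, tolerance = 1e-12)
  expect_equal(ov$fraction[ov$class == 1], 0.5)
  expect_equal(ov$fraction[ov$class == 4], 0.5)
  ## a plantation entirely inside one class takes the whole mass
  pIn <- polygonSet("P", list(cbind(c(5.5, 7.5, 7.5, 5.5), c(2, 2, 8, 8))))
  ovIn <- plantationOverlap(cm, pIn, targetCellSize = 0.5)
  expect_equal(ovIn$fraction[ovIn$class == 3], 1)
  ## invariant to vertex order and to splitting a polygon in two
  pRev <- polygonSet(c("P1", "P2"),
                     lapply(p@rings, function(r) r[rev(seq_len(nrow(r))), ]))
  expect_equal(plantationOverlap(cm, pRev, targetCellSize = 0.5)$fraction,
               ov$fraction)
  pSplit <- polygonSet(c("a", "b", "P2"),
                       list(cbind(c(0, 1, 1, 0), c(1, 1, 3, 3)),
                            cbind(c(1, 2, 2, 1), c(1, 1, 3, 3)),
                            p@rings[[2L]]))
  expect_equal(plantationOverlap(cm, pSplit, targetCellSize = 0.5)$fraction,
               ov$fraction)
})
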