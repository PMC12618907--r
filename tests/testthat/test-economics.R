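## small hand-checkable table: municipality A dominates the product
handTable <- productionTable(
  muni_id = c("A", "B", "C", "D"),
  vp_product = c(50, 10, 5, 0),
  vp_forestry_total = c(100, 200, 100, 600))

test_that("the location quotient follows its printed formula", {
  ## VP_ij/VP_j = VP_inat/VP_nat everywhere: LQ is identically 1
  neutral <- productionTable(c("A", "B", "C"), c(10, 20, 30), c(100, 200, 300))
  expect_equal(unname(computeLq(neutral)), rep(1, 3))
  ## direct arithmetic: (50/100) / (200/1000) = 2.5
  one <- productionTable(c("A", "B"), c(50, 150), c(100, 900))
  expect_equal(unname(computeLq(one))[1L], 2.5)
  ## element-wise oracle on a random table
  set.seed(5)
  tb <- productionTable(sprintf("M%02d", 1:20), vp <- runif(20, 0, 100),
                        vp + runif(20, 0, 400))
  d <- as.data.frame(tb)
  oracle <- (d$vp_product / d$vp_forestry_total) /
    (sum(d$vp_product) / sum(d$vp_forestry_total))
  expect_equal(unname(computeLq(tb)), oracle)
  ## no forestry production at all means LQ = 0, not NaN
  zero <- productionTable(c("A", "B"), c(10, 0), c(10, 0))
  expect_equal(unname(computeLq(zero))[2L], 0)
})

test_that("HHI and RP satisfy their identities", {
  hhi <- computeHhi(handTable)
  expect_equal(sum(hhi), 0, tolerance = 1e-12)
  ## sole national producer with a tiny forestry share approaches +1
  conc <- productionTable(c("A", "B"), c(100, 0), c(100, 1e6))
  expect_gt(computeHhi(conc)[["A"]], 0.99)
  ## proportional shares zero the index
  neutral <- productionTable(c("A", "B"), c(10, 30), c(100, 300))
  expect_equal(unname(computeHhi(neutral)), c(0, 0))
  rp <- computeRp(handTable)
  expect_equal(sum(rp), 1)
  expect_equal(unname(computeRp(productionTable(c("A", "B"), c(7, 0), c(7, 1)))),
               c(1, 0))
  even <- productionTable(letters[1:5], rep(3, 5), rep(10, 5))
  expect_equal(unname(computeRp(even)), rep(0.2, 5))
})

test_that("PCA weights respect symmetry and equivariance", {
  ## exactly orthogonal equal-variance columns: weights are 1/3 each
  X <- cbind(LQ = rep(c(1, -1), 4), RP = rep(c(1, 1, -1, -1), 2),
             HHI = rep(c(1, -1, -1, 1), 2))
  expect_equal(unname(computeWeights(X)), rep(1 / 3, 3))
  ## two perfectly correlated columns get equal weights
  set.seed(8)
  a <- rnorm(40); b <- rnorm(40)
  Y <- cbind(LQ = a, RP = a, HHI = b)
  w <- computeWeights(Y)
  expect_equal(w[["LQ"]], w[["RP"]], tolerance = 1e-10)
  ## permuting columns permutes the weights identically
  Z <- cbind(LQ = rnorm(30), RP = rnorm(30), HHI = rnorm(30))
  wz <- computeWeights(Z)
  wp <- computeWeights(Z[, c("HHI", "LQ", "RP")])
  expect_equal(unname(wp), unname(wz[c("HHI", "LQ", "RP")]))
  expect_error(computeWeights(cbind(LQ = rep(1, 10), RP = rnorm(10),
                                    HHI = rnorm(10))), "LQ")
})

test_that("the nCI is the weighted sum it claims to be", {
  idx <- cbind(LQ = c(3, 0, 1, 2), RP = c(0, 1, 0.5, 0.2),
               HHI = c(0, 0, 0.1, -0.1))
  ## unit weight on LQ returns the (standardized) LQ column
  expect_equal(computeNci(idx, c(1, 0, 0)), as.vector(scale(idx[, "LQ"])))
  ## without standardization the plain dot product comes back
  expect_equal(computeNci(idx, c(1 / 3, 1 / 3, 1 / 3), standardize = FALSE)[1L],
               1.0)
  set.seed(11)
  tb <- generateProductionTable(20, 2, 0.8, seed = 11)
  ei <- economicIndices(tb)
  theta <- attr(ei, "theta")
  oracle <- scale(cbind(ei$LQ, ei$RP, ei$HHI)) %*%
    theta[c("LQ", "RP", "HHI")]
  expect_equal(ei$nCI, as.vector(oracle), tolerance = 1e-12)
  expect_equal(sum(theta), 1)
  expect_true(all(theta >= 0))
})

test_that("index conservation and scale invariance hold on random tables", {
  for (s in 1:20) {
    tb <- generateProductionTable(sample(10:80, 1L), 3, 0.85, seed = 300 + s)
    expect_equal(sum(computeRp(tb)), 1, tolerance = 1e-10)
    expect_equal(sum(computeHhi(tb)), 0, tolerance = 1e-10)
    ## currency rescaling leaves every index unchanged
    d <- as.data.frame(tb)
    tb2 <- productionTable(d$muni_id, d$vp_product * 7.3,
                           d$vp_forestry_total * 7.3)
    expect_equal(computeLq(tb2), computeLq(tb), tolerance = 1e-12)
    expect_equal(computeHhi(tb2), computeHhi(tb), tolerance = 1e-12)
    expect_equal(computeRp(tb2), computeRp(tb), tolerance = 1e-12)
  }
})

test_that("a municipality built to dominate attains the maximum nCI", {
  for (s in 1:5) {
    tb <- generateProductionTable(40, 1, 0.9, seed = 400 + s)
    ei <- economicIndices(tb)
    ## the single concentrated producer is always municipality M001
    expect_equal(ei$muni_id[which.max(ei$nCI)], "M001")
  }
})

test_that("the risk matrix maps class pairs through the printed breakpoints", {
  ## five tight value clusters per input force known Jenks classes
  suit <- setNames(rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 2) +
                   rep(c(0, 0.001), 5), sprintf("M%02d", 1:10))
  nci <- setNames(rep(c(-2, -1, 0, 1, 2), each = 2) +
                  rep(c(0, 0.001), 5), sprintf("M%02d", 1:10))
  rc <- classifyEconomicRisk(suit, nci)
  expect_equal(rc$occ_class, rep(1:5, each = 2))
  expect_equal(rc$nci_class, rep(1:5, each = 2))
  expect_equal(rc$mean_score, rep(1:5, each = 2))
  expect_equal(as.character(rc$risk_level),
               rep(c("very low", "low", "moderate", "high", "high"), each = 2))
  ## mixed pairs: (1,2) -> 1.5 "very low"; (2,3) -> 2.5 "moderate";
  ## (5,5) -> 5 "high" under the right-closed boundaries
  nci2 <- setNames(nci[c(3:10, 1:2)], names(nci))   # shift classes by one
  rc2 <- classifyEconomicRisk(suit, nci2)
  lookup <- function(o, n) as.character(
    rc2$risk_level[rc2$occ_class == o & rc2$nci_class == n][1L])
  expect_equal(lookup(1, 2), "very low")   # mean 1.5, boundary case
  expect_equal(lookup(2, 3), "moderate")   # mean 2.5
  expect_equal(as.character(
    classifyEconomicRisk(suit, nci)$risk_level[rc$mean_score == 5][1L]), "high")
})

test_that("raising suitability never lowers a municipality's risk level", {
  suit <- setNames(rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 2) +
                   rep(c(0, 0.001), 5), sprintf("M%02d", 1:10))
  nci <- setNames(seq(-2, 2, length.out = 10), sprintf("M%02d", 1:10))
  base <- classifyEconomicRisk(suit, nci)
  for (target in c("M01", "M03", "M05")) {
    bumped <- suit
    bumped[target] <- 0.95   # push into the top suitability cluster
    rc <- classifyEconomicRisk(bumped, nci)
    expect_gte(as.integer(rc$risk_level[rc$muni_id == target]),
               as.integer(base$risk_level[base$muni_id == target]))
  }
})

test_that("mismatched municipality sets are rejected with their ids", {
  suit <- setNames(runif(6), sprintf("M%02d", 1:6))
  nci <- setNames(rnorm(6), sprintf("M%02d", 2:7))
  expect_error(classifyEconomicRisk(suit, nci), "M07")
})
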