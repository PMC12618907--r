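test_that("feature expansion has the documented composition and scaling", {
  set.seed(1)
  bg <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(nFeatures(buildFeatures(bg, "LQ")), 6L)
  ## 3 L + 3 Q + C(3,2) P + 3 vars x 2 directions x 10 knots
  expect_equal(nFeatures(buildFeatures(bg, "LQHP", nHingeKnots = 10)), 69L)
  expect_error(buildFeatures(bg, "LQX"), "unknown")
  expect_error(buildFeatures(bg[, 1L, drop = FALSE], "LP"), "2 variables")
  ## all features live in [0, 1] on the background
  fs <- buildFeatures(bg, "LQHP", nHingeKnots = 10)
  Fm <- featureMatrix(fs, bg)
  expect_true(all(Fm >= 0 & Fm <= 1))
  ## values outside the background range are clamped
  Fout <- featureMatrix(fs, matrix(c(99, -99, 0), 1, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  expect_true(all(Fout >= 0 & Fout <= 1))
})

test_that("hinge features match the ramp formula cell by cell", {
  set.seed(2)
  bg <- matrix(runif(200, -3, 7), ncol = 1, dimnames = list(NULL, "x"))
  fs <- buildFeatures(bg, "H", nHingeKnots = 5)
  Fm <- featureMatrix(fs, bg)
  defs <- fs@definitions
  lo <- min(bg); hi <- max(bg)
  for (k in seq_len(nrow(defs))) {
    t <- defs$knot[k]
    manual <- if (defs$dir[k] == "forward") {
      pmin(pmax((bg[, 1L] - t) / (hi - t), 0), 1)
    } else {
      pmin(pmax((t - bg[, 1L]) / (t - lo), 0), 1)
    }
    expect_equal(Fm[, k], manual, tolerance = 1e-12)
  }
  ## knots sit strictly inside the background range
  expect_true(all(defs$knot > lo & defs$knot < hi))
})

test_that("unpenalised fits reproduce analytic Gibbs solutions", {
  set.seed(3)
  bg <- matrix(rbinom(400, 1, 0.3), ncol = 1, dimnames = list(NULL, "x"))
  pr <- matrix(rbinom(40, 1, 0.7), ncol = 1, dimnames = list(NULL, "x"))
  fit <- fitMaxEnt(pr, bg, classes = "L", betaOverride = 0,
                   addPresences = FALSE, tol = 1e-12)
  pbar <- mean(pr); bbar <- mean(bg)
  lambdaTrue <- log(pbar / (1 - pbar)) - log(bbar / (1 - bbar))
  expect_equal(unname(coef(fit)), lambdaTrue, tolerance = 1e-6)
  ## two binary features: compare with direct numerical maximisation of the
  ## exact log-likelihood (independent optimiser)
  set.seed(4)
  bg2 <- cbind(x = rbinom(500, 1, 0.4), y = rbinom(500, 1, 0.25))
  pr2 <- cbind(x = rbinom(50, 1, 0.7), y = rbinom(50, 1, 0.5))
  fit2 <- fitMaxEnt(pr2, bg2, classes = "L", betaOverride = 0,
                    addPresences = FALSE, tol = 1e-12)
  negLL <- function(l) {
    eta <- bg2 %*% l
    -(sum(pr2 %*% l) - nrow(pr2) * (max(eta) + log(sum(exp(eta - max(eta))))))
  }
  opt <- optim(c(0, 0), negLL, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(coef(fit2)), opt$par, tolerance = 1e-5)
})

test_that("regularization dominates in the strong-penalty limit", {
  fit <- fitMaxEnt(tinyPresVals, tinyBgVals, classes = "LQ",
                   regMultiplier = 1e6)
  expect_true(all(coef(fit) == 0))
  expect_equal(countParameters(fit), 0L)
  raw <- predictSuitability(fit, tinyBgVals, "raw")
  expect_equal(raw, rep(1 / (nrow(tinyBgVals) + nrow(tinyPresVals)),
                        nrow(tinyBgVals)), tolerance = 1e-12)
})

test_that("the normalised objective is invariant to duplicating presences", {
  set.seed(5)
  bg <- matrix(rnorm(600), ncol = 2, dimnames = list(NULL, c("a", "b")))
  pr <- matrix(rnorm(40, 0.8), ncol = 2, dimnames = list(NULL, c("a", "b")))
  f1 <- fitMaxEnt(pr, bg, classes = "LQ", betaOverride = 0,
                  addPresences = FALSE, tol = 1e-12)
  f2 <- suppressWarnings(
    fitMaxEnt(rbind(pr, pr), bg, classes = "LQ", betaOverride = 0,
              addPresences = FALSE, tol = 1e-12))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
})

test_that("predictions normalise, and cloglog preserves the raw ranking", {
  fit <- fitMaxEnt(tinyPresVals, tinyBgVals, classes = "LQ")
  trainBg <- rbind(tinyBgVals, tinyPresVals)   # presences appended by default
  raw <- predictSuitability(fit, trainBg, "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-10)
  cll <- predictSuitability(fit, trainBg, "cloglog")
  expect_true(all(cll >= 0 & cll <= 1))
  expect_identical(order(raw), order(cll))
  expect_true(all(diff(cll[order(raw)]) >= 0))
})

test_that("the optimiser's objective log is monotone non-decreasing", {
  for (cl in c("LQ", "LQH")) {
    fit <- fitMaxEnt(tinyPresVals, tinyBgVals, classes = cl, nHingeKnots = 10)
    expect_false(is.unsorted(fit@convergence$objective))
    expect_true(fit@convergence$converged)
  }
})

test_that("stronger regularization never adds parameters on a fixed fit", {
  ks <- vapply(seq(0.5, 5, by = 0.5), function(rm)
    countParameters(fitMaxEnt(tinyPresVals, tinyBgVals, classes = "LQH",
                              nHingeKnots = 10, regMultiplier = rm)),
    numeric(1L))
  expect_true(all(diff(ks) <= 0))
})

test_that("parameter counting sees exactly the nonzero weights", {
  fit <- fitMaxEnt(tinyPresVals, tinyBgVals, classes = "LQ")
  expect_lte(countParameters(fit), nFeatures(fit@featureSet))
  hand <- fit
  hand@lambda <- c(1.2, 0, -0.3, 0, 0.01, rep(0, length(coef(fit)) - 5L))
  expect_equal(countParameters(hand), 3L)
})

test_that("permutation importance favours informative predictors", {
  ## species driven by bio1 only
  st <- tinyStack
  niche1 <- nicheSpec(c(0, rep(0, 4)), c(0.5, rep(1e6, 4)), maxProb = 0.9)
  surf1 <- generateVirtualSpecies(st, niche1)
  occ1 <- samplePresences(surf1, 60, seed = 13)
  pv <- stackValues(st, cellFromXY(st, coords(occ1)))
  fit <- fitMaxEnt(pv, tinyBgVals, classes = "LQ")
  imp <- permutationImportance(fit, pv, tinyBgVals, seed = 3)
  expect_equal(sum(imp), 100, tolerance = 1e-9)
  expect_equal(names(which.max(imp)), "bio1")
})
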