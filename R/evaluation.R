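## Model tuning and evaluation: the regularization-by-feature-class grid
## selected by AICc, train/test AUC, the randomized null-model significance
## test, and the Continuous Boyce Index.

#' Default tuning grid
#'
#' Ten regularization multipliers (0.5 to 5 in steps of 0.5) crossed with
#' five feature-class combinations (L, Q, LQ, LQH, LQHP): 50 candidates.
#'
#' @param regMultipliers regularization multipliers.
#' @param classSets feature-class strings.
#' @return List of class \code{"TuningGrid"} with the two components; its
#'   size is their product.
#' @export
tuningGrid <- function(regMultipliers = seq(0.5, 5, by = 0.5),
                       classSets = c("L", "Q", "LQ", "LQH", "LQHP")) {
  structure(list(regMultipliers = regMultipliers, classSets = classSets),
            class = "TuningGrid")
}

## AICc arithmetic; undefined (NA) when k = 0 or k >= n - 1.
aiccValue <- function(k, lnL, n) {
  if (k == 0 || k >= n - 1) return(NA_real_)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Corrected Akaike Information Criterion of a fitted model
#'
#' The log-likelihood is computed from raw scores renormalized to sum to 1
#' over the prediction grid: lnL = sum_occ ln(raw(x) / sum_grid raw).
#' k is the number of nonzero feature weights and n the occurrence count.
#' Returns NA when k = 0 or k >= n - 1 (the small-sample correction is
#' undefined there).
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @param occValues predictor table at the occurrence locations.
#' @param gridValues predictor table of the full prediction grid.
#' @return AICc (scalar, possibly NA).
#' @export
computeAicc <- function(model, occValues, gridValues) {
  rawOcc <- predictSuitability(model, occValues, "raw")
  rawGrid <- predictSuitability(model, gridValues, "raw")
  p <- rawOcc / sum(rawGrid)
  lnL <- sum(log(p))
  aiccValue(countParameters(model), lnL, nrow(as.matrix(occValues)))
}

#' Area under the ROC curve (rank statistic)
#'
#' AUC = U / (n_p * n_b) with U the Mann-Whitney statistic; ties count 0.5.
#' Equals the probability that a random presence outscores a random
#' background point.
#'
#' @param scoresPresence,scoresBackground numeric score vectors.
#' @return AUC in [0, 1].
#' @export
computeAuc <- function(scoresPresence, scoresBackground) {
  np <- length(scoresPresence); nb <- length(scoresBackground)
  stopifnot(np > 0, nb > 0)
  r <- rank(c(scoresPresence, scoresBackground))
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * nb)
}

#' Random train/test split of record indices
#'
#' @param n number of records (or an \linkS4class{OccurrenceSet}).
#' @param fractionTest fraction withheld for testing; test size is
#'   \code{round(fractionTest * n)}.
#' @param seed RNG seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
splitTrainTest <- function(n, fractionTest = 0.25, seed = 1) {
  if (is(n, "OccurrenceSet")) n <- nRecords(n)
  set.seed(seed)
  nTest <- round(fractionTest * n)
  test <- sort(sample.int(n, nTest))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Continuous Boyce Index
#'
#' Over overlapping suitability windows spanning the landscape score range,
#' computes the predicted-to-expected ratio P/E = (fraction of presences in
#' window) / (fraction of landscape cells in window), drops windows with
#' E = 0, and returns the Spearman correlation between window midpoints and
#' P/E. Values near 1 indicate presences concentrate monotonically in
#' high-score cells; NA when fewer than 3 usable windows remain.
#'
#' @param scoresPresence scores at presence locations.
#' @param scoresLandscape scores over the evaluation landscape.
#' @param nWindows number of windows (default 101).
#' @param windowWidth window width as a fraction of the score range
#'   (default 0.1).
#' @return CBI in [-1, 1], or NA.
#' @export
computeCbi <- function(scoresPresence, scoresLandscape,
                       nWindows = 101, windowWidth = 0.1) {
  rng <- range(scoresLandscape)
  w <- windowWidth * diff(rng)
  if (w <= 0) return(NA_real_)
  mids <- seq(rng[1L] + w / 2, rng[2L] - w / 2, length.out = nWindows)
  pe <- vapply(mids, function(mid) {
    lo <- mid - w / 2; hi <- mid + w / 2
    e <- mean(scoresLandscape >= lo & scoresLandscape <= hi)
    p <- mean(scoresPresence >= lo & scoresPresence <= hi)
    if (e == 0) NA_real_ else p / e
  }, numeric(1L))
  ok <- !is.na(pe)
  if (sum(ok) < 3L) return(NA_real_)
  cor(mids[ok], pe[ok], method = "spearman")
}

## score a fitted model for one candidate row: returns the per-candidate
## evaluation fields shared by tune and the null test
evaluateCandidate <- function(model, occVals, bgVals, gridVals, split) {
  rawOcc <- predictSuitability(model, occVals, "raw")
  rawBg <- predictSuitability(model, bgVals, "raw")
  cll <- predictSuitability(model, occVals, "cloglog")
  cllLand <- predictSuitability(model, gridVals, "cloglog")
  list(
    k = countParameters(model),
    aucTrain = computeAuc(rawOcc[split$train], rawBg),
    aucTest = if (length(split$test))
      computeAuc(rawOcc[split$test], rawBg) else NA_real_,
    cbiTrain = computeCbi(cll[split$train], cllLand),
    cbiTest = if (length(split$test))
      computeCbi(cll[split$test], cllLand) else NA_real_)
}

#' Tune MaxEnt settings over a grid, selecting by AICc
#'
#' Fits one model per (feature classes, regularization multiplier) grid
#' cell on the full occurrence set, computes AICc with raw output
#' renormalized over the prediction grid, and selects the candidate with
#' minimal finite AICc (ties broken by smaller k, then smaller
#' regularization multiplier). AUC and CBI are reported from a single
#' random train/test occurrence split scored against the background.
#'
#' @param occ an \linkS4class{OccurrenceSet} (thinned records).
#' @param background a \linkS4class{BackgroundDefinition}.
#' @param stack the masked \linkS4class{ClimateStack} (prediction grid).
#' @param grid a \code{\link{tuningGrid}}.
#' @param fractionTest test fraction for the evaluation split.
#' @param nHingeKnots hinge knots per variable per direction.
#' @param seed RNG seed (split).
#' @param ... passed to \code{\link{fitMaxEnt}} (e.g. \code{tol},
#'   \code{maxIter}).
#' @return List of class \code{"EvaluationReport"}: \code{candidates}
#'   (data.frame with classes, rm, k, lnL, AICc, AUC_train, AUC_test,
#'   CBI_train, CBI_test), \code{selected} (row index), \code{model} (the
#'   selected fitted model), \code{split}.
#' @export
tuneModels <- function(occ, background, stack, grid = tuningGrid(),
                       fractionTest = 0.25, nHingeKnots = 20, seed = 1, ...) {
  occCells <- cellFromXY(stack, coords(occ))
  if (anyNA(occCells)) stop("occurrences outside the stack extent")
  occVals <- stackValues(stack, occCells)
  bgVals <- stackValues(stack, background@cells)
  gridVals <- stackValues(stack, validCells(stack))
  n <- nrow(occVals)
  split <- splitTrainTest(n, fractionTest, seed)

  cand <- expand.grid(classes = grid$classSets, rm = grid$regMultipliers,
                      stringsAsFactors = FALSE)
  models <- vector("list", nrow(cand))
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fit <- fitMaxEnt(occVals, bgVals, classes = cand$classes[i],
                     regMultiplier = cand$rm[i],
                     nHingeKnots = nHingeKnots, ...)
    models[[i]] <- fit
    rawOcc <- predictSuitability(fit, occVals, "raw")
    rawGrid <- predictSuitability(fit, gridVals, "raw")
    lnL <- sum(log(rawOcc / sum(rawGrid)))
    ev <- evaluateCandidate(fit, occVals, bgVals, gridVals, split)
    rows[[i]] <- data.frame(
      classes = cand$classes[i], rm = cand$rm[i], k = ev$k, lnL = lnL,
      AICc = aiccValue(ev$k, lnL, n),
      AUC_train = ev$aucTrain, AUC_test = ev$aucTest,
      CBI_train = ev$cbiTrain, CBI_test = ev$cbiTest,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$AICc)))
    stop("AICc undefined for every candidate (k >= n - 1 or k = 0 ",
         "everywhere); use more occurrences or stronger regularization")
  ## argmin AICc; ties by smaller k, then smaller reg multiplier
  ord <- order(tab$AICc, tab$k, tab$rm, na.last = TRUE)
  sel <- ord[1L]
  structure(list(candidates = tab, selected = sel, model = models[[sel]],
                 split = split, seed = seed),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  s <- x$candidates[x$selected, ]
  cat(sprintf("EvaluationReport: %d candidates; selected %s rm=%g (AICc %.2f, k=%d)\n",
              nrow(x$candidates), s$classes, s$rm, s$AICc, s$k))
  cat(sprintf("  AUC train/test: %.3f / %.3f; CBI train/test: %.3f / %.3f\n",
              s$AUC_train, s$AUC_test, s$CBI_train, s$CBI_test))
  invisible(x)
}

#' Null-model significance test of the empirical AUC
#'
#' Refits the selected settings on \code{nNull} replicates of the same
#' number of occurrences drawn uniformly at random from the background
#' area, recording the same test-split AUC as for the empirical model. The
#' empirical AUC is significant when it strictly exceeds at least 95% of
#' the null AUCs (ties count against significance).
#'
#' @param occ empirical occurrences (an \linkS4class{OccurrenceSet}).
#' @param background a \linkS4class{BackgroundDefinition}.
#' @param stack the masked \linkS4class{ClimateStack}.
#' @param classes,regMultiplier the selected model settings.
#' @param nNull number of null replicates (default 100).
#' @param fractionTest test fraction (as used for the empirical model).
#' @param nHingeKnots hinge knots.
#' @param seed RNG seed.
#' @param ... passed to \code{\link{fitMaxEnt}}.
#' @return List: \code{empiricalAuc}, \code{nullAucs}, \code{percentile}
#'   (percent of null AUCs strictly below the empirical one),
#'   \code{significant}.
#' @export
nullModelTest <- function(occ, background, stack, classes, regMultiplier,
                          nNull = 100, fractionTest = 0.25,
                          nHingeKnots = 20, seed = 1, ...) {
  occCells <- cellFromXY(stack, coords(occ))
  occVals <- stackValues(stack, occCells)
  bgVals <- stackValues(stack, background@cells)
  n <- nrow(occVals)
  maskCells <- which(as.vector(background@mask) &
                     !is.na(as.vector(stack@bands[[1L]])))

  testAuc <- function(vals, splitSeed) {
    split <- splitTrainTest(nrow(vals), fractionTest, splitSeed)
    fit <- fitMaxEnt(vals[split$train, , drop = FALSE], bgVals,
                     classes = classes, regMultiplier = regMultiplier,
                     nHingeKnots = nHingeKnots, ...)
    sc <- predictSuitability(fit, vals[split$test, , drop = FALSE], "raw")
    computeAuc(sc, predictSuitability(fit, bgVals, "raw"))
  }
  empirical <- testAuc(occVals, seed)
  set.seed(seed)
  nullSeeds <- sample.int(.Machine$integer.max, nNull)
  nullAucs <- vapply(seq_len(nNull), function(r) {
    set.seed(nullSeeds[r])
    cells <- maskCells[sample.int(length(maskCells), n)]
    testAuc(stackValues(stack, cells), nullSeeds[r])
  }, numeric(1L))
  exceed <- sum(empirical > nullAucs)
  list(empiricalAuc = empirical, nullAucs = nullAucs,
       percentile = 100 * exceed / nNull,
       significant = exceed >= ceiling(0.95 * nNull))
}
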