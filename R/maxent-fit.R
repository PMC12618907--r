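## Minimal MaxEnt fit: the Gibbs distribution over background cells,
## p_lambda(x) = exp(lambda . f(x)) / Z, estimated by maximising the
## L1-penalised presence log-likelihood
##   J(lambda) = sum_presence lambda.f(x) - m * ln Z(lambda)
##                 - sum_j beta_j |lambda_j|
## with Z(lambda) = sum_background exp(lambda . f(b)). The optimizer (C++,
## src/maxent_fit.cpp) is a proximal Newton scheme: an outer quadratic
## model of the smooth part, an inner coordinate descent with
## soft-thresholding for the L1 term, and a halving line search on the
## exact objective, so the per-iteration objective is non-decreasing.

## Phillips-style default class-level beta, interpolated by presence count:
## linear/quadratic/product decay from 1.0 (m <= 10) to 0.05 (m >= 100);
## hinge is a constant 0.5.
defaultClassBeta <- function(kind, m) {
  lqp <- stats::approx(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05),
                       xout = min(max(m, 10), 100))$y
  ifelse(kind == "hinge", 0.5, lqp)
}

logSumExp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Fit a minimal MaxEnt model
#'
#' Maximises the penalised presence log-likelihood over the background by
#' proximal Newton steps (a quadratic model of the log-likelihood solved
#' by coordinate descent with soft-thresholding for the L1 term), each
#' safeguarded by a line search on the exact objective, so the recorded
#' objective is non-decreasing across iterations. Per-feature
#' penalties are beta_j = regMultiplier * classBeta_j(m) * s_j / sqrt(m),
#' with s_j the background standard deviation of feature j and m the
#' presence count. Iteration stops when a full cycle improves the objective
#' by less than \code{tol} or after \code{maxIter} cycles (then the best
#' iterate is returned with a warning).
#'
#' @param presence presence predictor table (rows = presence locations).
#' @param background background predictor table.
#' @param classes feature-class string ("L", "LQ", "LQH", "LQHP", ...),
#'   ignored when \code{featureSet} is supplied.
#' @param regMultiplier global regularization multiplier (paper grid:
#'   0.5 to 5).
#' @param nHingeKnots hinge knots per variable per direction.
#' @param featureSet optional prebuilt \linkS4class{FeatureSet}.
#' @param addPresences append the presence rows to the background for the
#'   partition function (standard MaxEnt convention; default TRUE).
#' @param betaOverride optional scalar or per-feature vector replacing the
#'   computed penalties (0 gives the unpenalised maximum-likelihood Gibbs
#'   fit used by the analytic checks).
#' @param tol convergence tolerance on the objective improvement.
#' @param maxIter iteration cap.
#' @return A \linkS4class{MaxEntModel}.
#' @export
fitMaxEnt <- function(presence, background, classes = "LQH",
                      regMultiplier = 1, nHingeKnots = 20,
                      featureSet = NULL, addPresences = TRUE,
                      betaOverride = NULL, tol = 1e-7, maxIter = 5000) {
  bgX <- as.matrix(background)
  prX <- as.matrix(presence)
  m <- nrow(prX)
  if (m < 2L) stop("need at least 2 presence records")
  if (nrow(bgX) < 10L * m)
    warning("background has fewer than 10x the presences (",
            nrow(bgX), " vs ", m, ")")
  fs <- if (is.null(featureSet))
    buildFeatures(bgX, classes, nHingeKnots) else featureSet
  Fp <- featureMatrix(fs, prX)
  Fb <- featureMatrix(fs, bgX)
  if (addPresences) Fb <- rbind(Fb, Fp)
  if (any(!is.finite(Fp)) || any(!is.finite(Fb)))
    stop("non-finite feature values")
  nf <- ncol(Fb)
  sj <- apply(Fb, 2L, sd)
  beta <- if (is.null(betaOverride)) {
    regMultiplier * defaultClassBeta(fs@definitions$kind, m) * sj / sqrt(m)
  } else rep_len(betaOverride, nf)

  res <- .maxentFitPN(Fp, Fb, beta, tol, as.integer(maxIter))
  if (!res$converged)
    warning("MaxEnt fit did not converge in ", maxIter,
            " iterations; returning best iterate")
  new("MaxEntModel", lambda = as.numeric(res$lambda), featureSet = fs,
      regMultiplier = regMultiplier, beta = as.numeric(beta),
      logZ = res$logZ, entropy = res$entropy,
      convergence = list(objective = as.numeric(res$objective),
                         iterations = res$iterations,
                         converged = res$converged))
}

#' Number of model parameters
#'
#' The parameter count used by AICc: the number of features with nonzero
#' weight.
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @return Integer k.
#' @export
countParameters <- function(model) sum(model@lambda != 0)

#' Predict suitability from a fitted model
#'
#' \code{output = "raw"} gives the Gibbs density exp(lambda.f(x)) / Z
#' (sums to 1 over the training background); \code{"cloglog"} gives the
#' map-scale transform 1 - exp(-exp(H) * raw) in [0, 1], with H the entropy
#' of the fitted background distribution.
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @param newdata predictor table, or a \linkS4class{ClimateStack}.
#' @param output "cloglog" (default) or "raw".
#' @return Numeric vector, or a \linkS4class{RasterGrid} when
#'   \code{newdata} is a stack.
#' @export
predictSuitability <- function(model, newdata, output = c("cloglog", "raw")) {
  output <- match.arg(output)
  if (is(newdata, "ClimateStack")) {
    d <- gridShape(newdata)
    cells <- validCells(newdata)
    vals <- rep(NA_real_, prod(d))
    vals[cells] <- predictSuitability(model, stackValues(newdata, cells),
                                      output)
    return(rasterGrid(matrix(vals, d[1L], d[2L]),
                      newdata@xmin, newdata@ymin, newdata@cellSize))
  }
  Fm <- featureMatrix(model@featureSet, newdata)
  raw <- exp(as.vector(Fm %*% model@lambda) - model@logZ)
  if (output == "raw") raw else 1 - exp(-exp(model@entropy) * raw)
}

#' Permutation importance of each predictor
#'
#' Permutes one variable's values at a time over a held evaluation sample,
#' measures the drop in AUC (presences vs background) relative to the
#' intact model, and normalizes the drops to percentages. An importance
#' metric in the spirit of MaxEnt's internal routine; exact parity with it
#' is not claimed.
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @param presence,background predictor tables used for scoring.
#' @param nPermutations permutations per variable (drops are averaged).
#' @param seed RNG seed.
#' @return Named numeric vector of percentages summing to 100 (all zeros if
#'   no permutation lowers AUC).
#' @export
permutationImportance <- function(model, presence, background,
                                  nPermutations = 3, seed = 1) {
  prX <- as.matrix(presence); bgX <- as.matrix(background)
  vars <- colnames(model@featureSet@varRange)
  base <- computeAuc(predictSuitability(model, prX, "raw"),
                     predictSuitability(model, bgX, "raw"))
  set.seed(seed)
  nPr <- nrow(prX)
  drops <- vapply(vars, function(v) {
    d <- numeric(nPermutations)
    for (r in seq_len(nPermutations)) {
      all <- rbind(prX, bgX)
      all[, v] <- sample(all[, v])
      sc <- predictSuitability(model, all, "raw")
      d[r] <- base - computeAuc(sc[seq_len(nPr)], sc[-seq_len(nPr)])
    }
    mean(d)
  }, numeric(1L))
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) return(setNames(rep(0, length(vars)), vars))
  100 * drops / sum(drops)
}
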