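## Economic concentration indices and the two-dimensional risk matrix.
##
## For product i (the focal plantation crop) and municipality j, with VP_ij
## the municipal value of the product, VP_j the municipal total forestry
## value, and national totals VP_inat = sum_j VP_ij, VP_nat = sum_j VP_j:
##   LQ_ij  = (VP_ij / VP_j) / (VP_inat / VP_nat)   (location quotient)
##   HHI_ij = VP_ij / VP_inat - VP_j / VP_nat       (modified Hirschman-Herfindahl)
##   RP_ij  = VP_ij / VP_inat                      (relative participation)
## and the normalized Concentration Index is the PCA-weighted combination
##   nCI_ij = theta1 * LQ_ij + theta2 * RP_ij + theta3 * HHI_ij
## computed on z-standardized index columns (Crocco-style convention).

#' Location quotient per municipality
#'
#' LQ_ij = (VP_ij / VP_j) / (VP_inat / VP_nat); a municipality with no
#' forestry production at all (VP_j = 0, hence VP_ij = 0) gets LQ = 0.
#'
#' @param table a \linkS4class{ProductionTable}.
#' @return Named numeric vector (names = muni_id).
#' @export
computeLq <- function(table) {
  tb <- table@table
  natShare <- sum(tb$vp_product) / sum(tb$vp_forestry_total)
  lq <- ifelse(tb$vp_forestry_total > 0,
               (tb$vp_product / tb$vp_forestry_total) / natShare, 0)
  setNames(lq, tb$muni_id)
}

#' Modified Hirschman-Herfindahl index per municipality
#'
#' HHI_ij = VP_ij / VP_inat - VP_j / VP_nat. Positive values mean the product
#' is more concentrated in the municipality than forestry overall; the
#' index sums to zero across municipalities.
#'
#' @param table a \linkS4class{ProductionTable}.
#' @return Named numeric vector.
#' @export
computeHhi <- function(table) {
  tb <- table@table
  setNames(tb$vp_product / sum(tb$vp_product) -
           tb$vp_forestry_total / sum(tb$vp_forestry_total), tb$muni_id)
}

#' Relative participation per municipality
#'
#' RP_ij = VP_ij / VP_inat, the municipality's share of the national product
#' value; sums to 1.
#'
#' @param table a \linkS4class{ProductionTable}.
#' @return Named numeric vector in [0, 1].
#' @export
computeRp <- function(table) {
  tb <- table@table
  setNames(tb$vp_product / sum(tb$vp_product), tb$muni_id)
}

#' PCA-derived index weights
#'
#' Principal component analysis on the correlation matrix of the three
#' (standardized) index columns; each index's weight is the sum over
#' components of (explained-variance share) x (its absolute loading,
#' normalized within the component), renormalized to sum to 1. Using
#' absolute loadings removes the eigenvector sign ambiguity.
#'
#' @param indices matrix or data.frame with columns LQ, RP, HHI (>= 4 rows,
#'   no constant column).
#' @return Numeric weight vector theta (named as the columns, sums to 1).
#' @export
computeWeights <- function(indices) {
  X <- as.matrix(indices)
  if (nrow(X) < 4L) stop("need at least 4 municipalities")
  cst <- apply(X, 2L, sd) == 0
  if (any(cst))
    stop("constant index column(s): ", paste(colnames(X)[cst], collapse = ", "))
  C <- cor(X)
  e <- eigen(C, symmetric = TRUE)
  share <- e$values / sum(e$values)
  V <- abs(e$vectors)
  Vn <- sweep(V, 2L, colSums(V), "/")
  theta <- as.vector(Vn %*% share)
  theta <- theta / sum(theta)
  setNames(theta, colnames(X))
}

#' Normalized Concentration Index
#'
#' Weighted sum of the (optionally z-standardized) index columns:
#' nCI = theta1 * LQ + theta2 * RP + theta3 * HHI.
#'
#' @param indices matrix or data.frame with columns LQ, RP, HHI.
#' @param theta weight vector in the order (LQ, RP, HHI).
#' @param standardize z-standardize the columns first (default TRUE, the
#'   same convention under which the weights are derived).
#' @return Numeric nCI vector.
#' @export
computeNci <- function(indices, theta, standardize = TRUE) {
  X <- as.matrix(indices)
  if (standardize) X <- scale(X)
  as.vector(X %*% theta)
}

#' All concentration indices for a production table
#'
#' Convenience wrapper: LQ, HHI, RP, the PCA weights and the nCI in one
#' data.frame.
#'
#' @param table a \linkS4class{ProductionTable}.
#' @param standardize z-standardize before weighting (default TRUE).
#' @return data.frame with columns muni_id, LQ, HHI, RP, nCI; the weight
#'   vector is attached as \code{attr(, "theta")}.
#' @export
economicIndices <- function(table, standardize = TRUE) {
  lq <- computeLq(table); hhi <- computeHhi(table); rp <- computeRp(table)
  idx <- cbind(LQ = lq, RP = rp, HHI = hhi)
  theta <- computeWeights(idx)
  nci <- computeNci(idx, theta, standardize = standardize)
  out <- data.frame(muni_id = table@table$muni_id, LQ = unname(lq),
                    HHI = unname(hhi), RP = unname(rp), nCI = nci,
                    stringsAsFactors = FALSE)
  attr(out, "theta") <- theta
  out
}

#' Two-dimensional economic risk classification
#'
#' Classifies mean climate suitability and nCI into five Jenks classes each
#' (1 = lowest), averages the two class indices per municipality, and maps
#' the mean score to four risk levels with right-closed boundaries:
#' very low (0, 1.5], low (1.5, 2.0], moderate (2.0, 3.0], high (3.0, 5.0].
#'
#' @param meanSuitability data.frame with columns muni_id and
#'   mean_suitability (as from \code{\link{zonalMean}}), or a named vector.
#' @param nci data.frame with columns muni_id and nCI (as from
#'   \code{\link{economicIndices}}), or a named vector.
#' @return data.frame with columns muni_id, occ_class, nci_class,
#'   mean_score, risk_level (ordered factor).
#' @export
classifyEconomicRisk <- function(meanSuitability, nci) {
  toVec <- function(x, col) {
    if (is.data.frame(x)) setNames(x[[col]], x$muni_id) else x
  }
  suit <- toVec(meanSuitability, "mean_suitability")
  nciV <- toVec(nci, "nCI")
  missA <- setdiff(names(nciV), names(suit))
  missB <- setdiff(names(suit), names(nciV))
  if (length(missA) || length(missB))
    stop("municipality sets differ; missing from suitability: {",
         paste(missA, collapse = ", "), "}; missing from nCI: {",
         paste(missB, collapse = ", "), "}")
  suit <- suit[names(nciV)]
  occClass <- jenksClassify(unname(suit), 5L)$classes
  nciClass <- jenksClassify(unname(nciV), 5L)$classes
  meanScore <- (occClass + nciClass) / 2
  lev <- c("very low", "low", "moderate", "high")
  risk <- cut(meanScore, breaks = c(0, 1.5, 2, 3, 5), labels = lev,
              right = TRUE, include.lowest = TRUE)
  data.frame(muni_id = names(nciV), occ_class = occClass,
             nci_class = nciClass, mean_score = meanScore,
             risk_level = factor(risk, levels = lev, ordered = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}
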