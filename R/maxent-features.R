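## MaxEnt feature construction. Feature classes follow the standard tokens:
## L (linear), Q (quadratic), P (pairwise products), H (forward and reverse
## hinge ramps at quantile knots). All features are scaled into [0, 1] using
## the background's min/max, the convention MaxEnt uses so that the L1
## penalties are comparable across features.

parseFeatureClasses <- function(classes) {
  toks <- strsplit(toupper(classes), "")[[1L]]
  bad <- setdiff(toks, c("L", "Q", "H", "P"))
  if (length(bad))
    stop("unknown feature class token(s): ", paste(bad, collapse = ", "))
  unique(toks)
}

#' Build a MaxEnt feature set from background values
#'
#' Defines the feature expansion and freezes the [0, 1] scaling on the
#' background sample. Feature order is deterministic: all linear features in
#' variable order, then quadratic, then products (pairs in \code{combn}
#' order), then hinges (per variable: forward knots ascending, then reverse
#' knots ascending).
#'
#' @param values background predictor table (matrix or data.frame, one
#'   column per variable).
#' @param classes string of feature-class tokens, e.g. "LQ", "LQHP".
#' @param nHingeKnots number of knots per variable per hinge direction;
#'   knots sit at evenly spaced quantiles strictly inside the background
#'   range.
#' @return A \linkS4class{FeatureSet}.
#' @export
buildFeatures <- function(values, classes = "LQH", nHingeKnots = 20) {
  toks <- parseFeatureClasses(classes)
  X <- as.matrix(values)
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(X)))
  p <- ncol(X)
  if ("P" %in% toks && p < 2L)
    stop("product features need at least 2 variables")
  varRange <- apply(X, 2L, range)
  rownames(varRange) <- c("min", "max")
  colnames(varRange) <- vars

  defs <- data.frame(kind = character(0), var1 = character(0),
                     var2 = character(0), knot = numeric(0),
                     dir = character(0), stringsAsFactors = FALSE)
  addRows <- function(kind, var1, var2 = NA_character_, knot = NA_real_,
                      dir = NA_character_) {
    rbind(defs, data.frame(kind = kind, var1 = var1, var2 = var2,
                           knot = knot, dir = dir, stringsAsFactors = FALSE))
  }
  if ("L" %in% toks) defs <- addRows("linear", vars)
  if ("Q" %in% toks) defs <- addRows("quadratic", vars)
  if ("P" %in% toks) {
    pr <- combn(vars, 2L)
    defs <- addRows("product", pr[1L, ], pr[2L, ])
  }
  if ("H" %in% toks) {
    probs <- seq_len(nHingeKnots) / (nHingeKnots + 1)
    for (v in vars) {
      kn <- as.numeric(quantile(X[, v], probs, names = FALSE))
      defs <- addRows("hinge", v, knot = kn, dir = "forward")
      defs <- addRows("hinge", v, knot = kn, dir = "reverse")
    }
  }
  fs <- new("FeatureSet", definitions = defs, varRange = varRange,
            featRange = matrix(numeric(0), 2L, 0L))
  raw <- rawFeatureMatrix(fs, X)
  fr <- apply(raw, 2L, range)
  ## hinge features are built in [0, 1] already; identity scaling
  hing <- defs$kind == "hinge"
  fr[1L, hing] <- 0; fr[2L, hing] <- 1
  rownames(fr) <- c("min", "max")
  fs@featRange <- fr
  fs
}

## unscaled feature columns (hinges are produced in [0,1] directly)
rawFeatureMatrix <- function(fs, X) {
  defs <- fs@definitions
  n <- nrow(X)
  out <- matrix(0, n, nrow(defs))
  vr <- fs@varRange
  for (k in seq_len(nrow(defs))) {
    kind <- defs$kind[k]; v <- defs$var1[k]
    if (kind == "linear") {
      out[, k] <- X[, v]
    } else if (kind == "quadratic") {
      out[, k] <- X[, v]^2
    } else if (kind == "product") {
      out[, k] <- X[, v] * X[, defs$var2[k]]
    } else {  # hinge
      t <- defs$knot[k]
      if (defs$dir[k] == "forward") {
        den <- vr["max", v] - t
        out[, k] <- if (den > 0) pmin(pmax((X[, v] - t) / den, 0), 1) else 0
      } else {
        den <- t - vr["min", v]
        out[, k] <- if (den > 0) pmin(pmax((t - X[, v]) / den, 0), 1) else 0
      }
    }
  }
  out
}

#' Evaluate a feature set on predictor values
#'
#' Applies the frozen background scaling: each non-hinge feature is mapped
#' through (f - min) / (max - min) and clamped to [0, 1] (clamping handles
#' values outside the background range); hinge features are computed
#' directly in [0, 1]. Features constant on the background evaluate to 0.
#'
#' @param fs a \linkS4class{FeatureSet}.
#' @param values predictor table with the variables the set was built on.
#' @return Numeric matrix, rows = observations, columns = features.
#' @export
featureMatrix <- function(fs, values) {
  X <- as.matrix(values)
  need <- setdiff(unique(c(fs@definitions$var1,
                           fs@definitions$var2[!is.na(fs@definitions$var2)])),
                  colnames(X))
  if (length(need))
    stop("values lack variable(s): ", paste(need, collapse = ", "))
  raw <- rawFeatureMatrix(fs, X)
  if (any(!is.finite(raw))) stop("non-finite feature values")
  lo <- fs@featRange["min", ]; hi <- fs@featRange["max", ]
  den <- hi - lo
  den[den == 0] <- 1   # constant-on-background features evaluate to 0
  sc <- sweep(sweep(raw, 2L, lo, "-"), 2L, den, "/")
  sc[, hi - lo == 0] <- 0
  pmin(pmax(sc, 0), 1)
}

#' Number of features in a set
#' @param fs a \linkS4class{FeatureSet}.
#' @export
nFeatures <- function(fs) nrow(fs@definitions)
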