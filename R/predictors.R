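## Predictor preparation: cropping/masking to the background area and
## iterative collinearity filtering by the variance inflation factor.

#' Crop and mask a stack to the background area
#'
#' Cells outside the background mask become nodata and the extent is trimmed
#' to the bounding box of mask-true cells. Values at retained cells are
#' untouched (bit-exact).
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param background a \linkS4class{BackgroundDefinition} aligned to it.
#' @return A cropped, masked \linkS4class{ClimateStack}.
#' @export
cropMask <- function(stack, background) {
  stopifnot(identical(gridShape(stack), dim(background@mask)))
  keep <- background@mask & !is.na(stack@bands[[1L]])
  if (!any(keep)) stop("background mask does not intersect the stack's data cells")
  ri <- range(which(rowSums(keep) > 0))
  cj <- range(which(colSums(keep) > 0))
  sub <- keep[ri[1L]:ri[2L], cj[1L]:cj[2L], drop = FALSE]
  bands <- lapply(stack@bands, function(b) {
    b <- b[ri[1L]:ri[2L], cj[1L]:cj[2L], drop = FALSE]
    b[!sub] <- NA
    b
  })
  climateStack(bands,
               xmin = stack@xmin + (cj[1L] - 1L) * stack@cellSize,
               ymin = stack@ymin + (ri[1L] - 1L) * stack@cellSize,
               cellSize = stack@cellSize)
}

#' Variance inflation factors
#'
#' VIF_v = 1 / (1 - R^2_v), where R^2_v comes from the ordinary least
#' squares regression of variable v on all other variables. Perfectly
#' collinear variables get VIF = Inf rather than an error.
#'
#' @param sample data.frame or matrix of predictor values (>= 3 rows,
#'   >= 2 columns, no constant column).
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
computeVif <- function(sample) {
  X <- as.data.frame(sample)
  if (nrow(X) < 3L) stop("need at least 3 observations")
  if (ncol(X) < 2L) stop("need at least 2 variables")
  cst <- vapply(X, function(v) sd(v) == 0, logical(1L))
  if (any(cst))
    stop("constant column(s): ", paste(names(X)[cst], collapse = ", "))
  vapply(seq_along(X), function(v) {
    fit <- lm(X[[v]] ~ ., data = X[-v])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L), USE.NAMES = FALSE) |> setNames(names(X))
}

#' Iterative VIF-based variable selection
#'
#' Repeatedly removes the non-forced variable with the largest VIF while
#' that VIF exceeds the threshold, recomputing VIFs after each removal.
#' Forced variables are never removed. VIFs are computed on a random sample
#' of non-nodata cells (full grids are unnecessary).
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param threshold VIF threshold (default 10).
#' @param forced variables never removed; defaults to whichever of
#'   \code{c("bio1", "bio12")} (annual mean temperature, annual
#'   precipitation) are present in the stack.
#' @param sampleSize maximum number of cells used for the VIF table.
#' @param seed RNG seed for the cell sample.
#' @return A list of class \code{"VifReport"}: \code{retained},
#'   \code{iterations} (data.frame variable/vif in removal order),
#'   \code{threshold}, \code{forced}, \code{sampleSize}, \code{seed}.
#' @export
selectVariables <- function(stack, threshold = 10,
                            forced = intersect(c("bio1", "bio12"),
                                               bandNames(stack)),
                            sampleSize = 10000, seed = 1) {
  nms <- bandNames(stack)
  missing <- setdiff(forced, nms)
  if (length(missing))
    stop("forced variable(s) not in stack: ", paste(missing, collapse = ", "))
  cells <- validCells(stack)
  set.seed(seed)
  if (length(cells) > sampleSize)
    cells <- sort(sample(cells, sampleSize))
  X <- as.data.frame(stackValues(stack, cells))
  current <- nms
  removed <- character(0); removedVif <- numeric(0)
  if (setequal(forced, nms)) {
    warning("all variables are forced; collinearity filtering skipped")
  } else {
    repeat {
      if (length(current) < 2L) break
      vifs <- computeVif(X[current])
      cand <- setdiff(current, forced)
      if (!length(cand)) break
      vc <- vifs[cand]
      if (max(vc) <= threshold) break
      ## ties in maximal VIF broken by band order (first listed removed)
      worstVal <- max(vc)
      worst <- cand[which(vc == worstVal)[1L]]
      removed <- c(removed, worst)
      removedVif <- c(removedVif, worstVal)
      current <- setdiff(current, worst)
    }
  }
  structure(list(
    retained = current,
    iterations = data.frame(variable = removed, vif = removedVif,
                            stringsAsFactors = FALSE),
    threshold = threshold, forced = forced,
    sampleSize = nrow(X), seed = seed), class = "VifReport")
}

#' @export
print.VifReport <- function(x, ...) {
  cat("VIF selection (threshold", x$threshold, "):\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$iterations)) {
    cat("  removed (in order):\n")
    for (i in seq_len(nrow(x$iterations)))
      cat(sprintf("    %s (VIF %.2f)\n", x$iterations$variable[i],
                  x$iterations$vif[i]))
  } else cat("  nothing removed\n")
  invisible(x)
}
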