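## Synthetic-world generators: every input the pipeline consumes, with known
## ground truth, so downstream stages are testable fully offline.

#' Create a world specification
#'
#' Defaults emulate the geometry of the real study inputs: a 2.5 arc-minute
#' predictor grid with 15 bands (14 bioclimatic variables plus elevation)
#' and smooth spatial structure.
#'
#' @param nRows,nCols grid size in cells.
#' @param cellSizeDeg cell size in degrees (default 2.5 arc-minutes).
#' @param originLon,originLat lower-left corner of the extent.
#' @param nPredictors number of predictor bands.
#' @param collinearPairs list of c(i, j, rho) designed-collinearity targets
#'   (1-based band indices, |rho| < 1).
#' @param smoothness spatial correlation length in cells.
#' @param seed RNG seed.
#' @return A \linkS4class{WorldSpec}.
#' @export
worldSpec <- function(nRows = 100, nCols = 100, cellSizeDeg = 2.5 / 60,
                      originLon = -60, originLat = -35,
                      nPredictors = 15, collinearPairs = list(),
                      smoothness = 10, seed = 1) {
  new("WorldSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cellSizeDeg = cellSizeDeg, originLon = originLon, originLat = originLat,
      nPredictors = as.integer(nPredictors), collinearPairs = collinearPairs,
      smoothness = smoothness, seed = as.integer(seed))
}

#' Create a niche specification
#'
#' @param optimum niche optimum per predictor.
#' @param tolerance niche breadth (Gaussian sd) per predictor, > 0.
#' @param maxProb occurrence probability at the optimum, in (0, 1].
#' @return A \linkS4class{NicheSpec}.
#' @export
nicheSpec <- function(optimum, tolerance, maxProb = 1) {
  new("NicheSpec", optimum = as.numeric(optimum),
      tolerance = as.numeric(tolerance), maxProb = maxProb)
}

## Spatially autocorrelated standard-normal field: white noise smoothed with
## a separable Gaussian kernel (sd = sigma cells) on a padded grid, then
## standardized to zero mean / unit variance.
smoothGaussianField <- function(nRows, nCols, sigma) {
  p <- ceiling(3 * sigma)
  k <- exp(-((-p:p)^2) / (2 * sigma^2))
  k <- k / sum(k)
  e <- matrix(rnorm((nRows + 2 * p) * (nCols + 2 * p)),
              nRows + 2 * p, nCols + 2 * p)
  s <- stats::filter(e, k, sides = 2)              # along columns
  s <- t(stats::filter(t(s), k, sides = 2))        # along rows
  s <- s[(p + 1):(p + nRows), (p + 1):(p + nCols), drop = FALSE]
  s <- matrix(as.numeric(s), nRows, nCols)
  (s - mean(s)) / sd(s)
}

#' Generate a synthetic climate predictor stack
#'
#' Each band is a spatially autocorrelated Gaussian field standardized to
#' zero mean and unit variance; bands listed in \code{collinearPairs} are
#' rebuilt as rho * base + sqrt(1 - rho^2) * independent field so the
#' realised Pearson correlation is close to the target (within ~0.05 for
#' worlds that are large relative to the correlation length).
#'
#' @param spec a \linkS4class{WorldSpec}.
#' @return A \linkS4class{ClimateStack} with bands named bio1, bio2, ...
#'   (the last band is named "elevation" when there are >= 15 bands,
#'   mirroring a bioclim + elevation stack).
#' @export
generateClimateStack <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  nms <- paste0("bio", seq_len(spec@nPredictors))
  if (spec@nPredictors >= 15) nms[spec@nPredictors] <- "elevation"
  bands <- lapply(seq_len(spec@nPredictors), function(i)
    smoothGaussianField(spec@nRows, spec@nCols, spec@smoothness))
  names(bands) <- nms
  for (p in spec@collinearPairs) {
    i <- p[1L]; j <- p[2L]; rho <- p[3L]
    mix <- rho * bands[[i]] + sqrt(1 - rho^2) * bands[[j]]
    bands[[j]] <- (mix - mean(mix)) / sd(mix)
  }
  climateStack(bands, xmin = spec@originLon, ymin = spec@originLat,
               cellSize = spec@cellSizeDeg)
}

#' True occurrence-probability surface of a virtual species
#'
#' Cell probability is the product-Gaussian niche response
#' maxProb * prod_v exp(-(x_v - optimum_v)^2 / (2 tolerance_v^2)).
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param niche a \linkS4class{NicheSpec} with one entry per band.
#' @return A \linkS4class{RasterGrid} of probabilities in (0, maxProb].
#' @export
generateVirtualSpecies <- function(stack, niche) {
  validObject(niche)
  if (length(niche@optimum) != nBands(stack))
    stop("niche has ", length(niche@optimum), " dimensions but the stack has ",
         nBands(stack), " bands")
  d <- gridShape(stack)
  logp <- matrix(0, d[1L], d[2L])
  for (v in seq_len(nBands(stack))) {
    logp <- logp - (stack@bands[[v]] - niche@optimum[v])^2 /
      (2 * niche@tolerance[v]^2)
  }
  rasterGrid(niche@maxProb * exp(logp), stack@xmin, stack@ymin, stack@cellSize)
}

#' Sample presence records from a probability surface
#'
#' Draws cells with probability proportional to the surface value and places
#' one record at each sampled cell centre (no within-cell jitter, so thinning
#' distances are exactly computable).
#'
#' @param surface a \linkS4class{RasterGrid} of non-negative weights.
#' @param n number of records.
#' @param seed RNG seed.
#' @param species species label for the records.
#' @param replace sample cells with replacement (default FALSE).
#' @return An \linkS4class{OccurrenceSet}.
#' @export
samplePresences <- function(surface, n, seed = 1, species = "virtual species",
                            replace = FALSE) {
  v <- as.vector(surface@values)
  pos <- which(!is.na(v) & v > 0)
  if (!replace && n > length(pos))
    stop("n = ", n, " exceeds the ", length(pos),
         " cells with positive probability")
  set.seed(seed)
  cells <- pos[sample.int(length(pos), n, replace = replace, prob = v[pos])]
  ctr <- cellCenters(surface, cells)
  occurrenceSet(species, ctr[, 1L], ctr[, 2L],
                metadata = list(cells = cells, seed = seed))
}

#' Cluster climate space into categorical zones
#'
#' Plays the role of a Koeppen-Geiger style zonation: k-means on the
#' standardized predictor vectors of all non-nodata cells, labels 1..n.
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param nZones number of zones.
#' @param seed RNG seed (k-means initialisation).
#' @return A \linkS4class{ZoneRaster} with integer labels.
#' @export
generateZoneRaster <- function(stack, nZones, seed = 1) {
  stopifnot(nZones >= 1)
  d <- gridShape(stack)
  cells <- validCells(stack)
  X <- scale(stackValues(stack, cells))
  X[!is.finite(X)] <- 0   # constant bands carry no clustering information
  lab <- rep(NA_integer_, prod(d))
  if (nZones == 1L) {
    lab[cells] <- 1L
  } else {
    set.seed(seed)
    km <- kmeans(X, centers = nZones, nstart = 5, iter.max = 100)
    lab[cells] <- as.integer(km$cluster)
  }
  new("ZoneRaster", values = matrix(as.numeric(lab), d[1L], d[2L]),
      xmin = stack@xmin, ymin = stack@ymin, cellSize = stack@cellSize)
}

#' Generate a production table with known concentration structure
#'
#' A designed number of municipalities jointly hold a designed share of the
#' national product value (the concentrated producers); the remainder is
#' spread over the other municipalities. Each municipality's total forestry
#' value is its product value plus an independent non-product component, so
#' VP_ij <= VP_j holds by construction and all totals are exactly conserved.
#'
#' @param nMunicipalities number of municipalities.
#' @param nConcentrated number of dominant producers.
#' @param concentrationShare fraction of national product value they hold.
#' @param seed RNG seed.
#' @param nationalValue national product value VP_inat (scale only).
#' @return A \linkS4class{ProductionTable}.
#' @export
generateProductionTable <- function(nMunicipalities, nConcentrated,
                                    concentrationShare, seed = 1,
                                    nationalValue = 1e6) {
  stopifnot(nConcentrated >= 1, nConcentrated < nMunicipalities,
            concentrationShare > 0, concentrationShare < 1)
  set.seed(seed)
  wC <- stats::rgamma(nConcentrated, shape = 8)
  wO <- stats::rgamma(nMunicipalities - nConcentrated, shape = 2)
  vp <- c(concentrationShare * nationalValue * wC / sum(wC),
          (1 - concentrationShare) * nationalValue * wO / sum(wO))
  other <- stats::rgamma(nMunicipalities, shape = 2) *
    nationalValue / nMunicipalities
  productionTable(
    muni_id = sprintf("M%03d", seq_len(nMunicipalities)),
    vp_product = vp,
    vp_forestry_total = vp + other)
}

## axis-aligned rectangle ring (counter-clockwise)
rectRing <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Generate ancillary surfaces and polygons
#'
#' Produces the three remaining pipeline inputs: an arbitrary-ranged smooth
#' introduction-likelihood surface (to exercise normalization), a set of
#' municipality polygons tiling the central part of the world as an
#' \code{nTilesX} by \code{nTilesY} lattice of cell-aligned rectangles (so
#' cell membership is known exactly), and a few rectangular plantation
#' polygons.
#'
#' @param spec a \linkS4class{WorldSpec} (geometry source).
#' @param seed RNG seed.
#' @param nTilesX,nTilesY municipality lattice size.
#' @param nPlantations number of plantation rectangles.
#' @return List with elements \code{introduction} (RasterGrid),
#'   \code{municipalities} and \code{plantations} (PolygonSet).
#' @export
generateAncillarySurfaces <- function(spec, seed = 1,
                                      nTilesX = 5, nTilesY = 5,
                                      nPlantations = 3) {
  set.seed(seed)
  cs <- spec@cellSizeDeg
  f <- smoothGaussianField(spec@nRows, spec@nCols, spec@smoothness)
  intro <- rasterGrid(57 + 23 * f, spec@originLon, spec@originLat, cs)

  ## municipalities: cell-aligned tiling of the central ~80% of the grid
  r0 <- floor(spec@nRows * 0.1); c0 <- floor(spec@nCols * 0.1)
  nr <- floor(spec@nRows * 0.8); nc <- floor(spec@nCols * 0.8)
  rowsPer <- nr %/% nTilesY; colsPer <- nc %/% nTilesX
  stopifnot(rowsPer >= 1, colsPer >= 1)
  ids <- character(0); rings <- list()
  for (ty in seq_len(nTilesY)) for (tx in seq_len(nTilesX)) {
    i0 <- r0 + (ty - 1L) * rowsPer; j0 <- c0 + (tx - 1L) * colsPer
    ids <- c(ids, sprintf("M%03d", (ty - 1L) * nTilesX + tx))
    rings <- c(rings, list(rectRing(
      spec@originLon + j0 * cs, spec@originLat + i0 * cs,
      spec@originLon + (j0 + colsPer) * cs, spec@originLat + (i0 + rowsPer) * cs)))
  }
  munis <- polygonSet(ids, rings)

  ## plantations: random cell-aligned rectangles, >= 4 cells each
  pid <- character(0); prings <- list()
  for (k in seq_len(nPlantations)) {
    w <- sample(2:max(2, spec@nCols %/% 8), 1L)
    h <- sample(2:max(2, spec@nRows %/% 8), 1L)
    j0 <- sample.int(spec@nCols - w, 1L)
    i0 <- sample.int(spec@nRows - h, 1L)
    pid <- c(pid, sprintf("P%02d", k))
    prings <- c(prings, list(rectRing(
      spec@originLon + j0 * cs, spec@originLat + i0 * cs,
      spec@originLon + (j0 + w) * cs, spec@originLat + (i0 + h) * cs)))
  }
  list(introduction = intro, municipalities = munis,
       plantations = polygonSet(pid, prings))
}
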