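#' @import methods
#' @importFrom stats cor kmeans lm quantile rnorm sd setNames
#' @importFrom utils head read.csv write.csv combn
#' @importFrom Rcpp sourceCpp
#' @useDynLib pestRisk, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Gridded containers
##
## Grids are stored as plain matrices with row 1 the southernmost row:
## the centre of cell (i, j) is at
##   lon = xmin + (j - 0.5) * cellSize,  lat = ymin + (i - 0.5) * cellSize.
## NA encodes nodata. All bands of a stack share shape, georeference and mask.
## ---------------------------------------------------------------------------

#' Virtual parent for georeferenced grids
#'
#' Holds the geotransform shared by single- and multi-band grids: the
#' lower-left corner of the extent and the (square) cell size in degrees.
#'
#' @slot xmin,ymin longitude/latitude of the lower-left corner of the extent.
#' @slot cellSize cell edge length in degrees (cells are square).
#' @keywords internal
setClass("SpatialGrid", representation("VIRTUAL",
  xmin = "numeric", ymin = "numeric", cellSize = "numeric"))

#' Single-band raster grid
#'
#' A matrix of cell values plus a geotransform. Row 1 is the southernmost
#' row; \code{NA} marks nodata cells.
#'
#' @slot values numeric matrix of cell values.
#' @export
setClass("RasterGrid", contains = "SpatialGrid",
  representation(values = "matrix"),
  validity = function(object) {
    if (length(object@cellSize) != 1L || object@cellSize <= 0)
      return("cellSize must be a single positive number")
    TRUE
  })

#' Multi-band climate predictor stack
#'
#' Named list of predictor matrices (one per variable, e.g. bio1, bio12,
#' elevation) sharing shape, geotransform and nodata mask.
#'
#' @slot bands named list of numeric matrices, all of identical dimension.
#' @export
setClass("ClimateStack", contains = "SpatialGrid",
  representation(bands = "list"),
  validity = function(object) {
    if (length(object@bands) < 1L) return("stack needs at least one band")
    if (is.null(names(object@bands)) || anyDuplicated(names(object@bands)))
      return("bands must be uniquely named")
    d <- dim(object@bands[[1L]])
    for (b in object@bands) {
      if (!is.matrix(b) || !identical(dim(b), d))
        return("all bands must be matrices of identical dimension")
    }
    m <- is.na(object@bands[[1L]])
    for (b in object@bands)
      if (!identical(is.na(b), m)) return("all bands must share the nodata mask")
    TRUE
  })

#' Categorical climate-zone raster
#'
#' A \linkS4class{RasterGrid} whose non-nodata values are integer zone
#' labels 1..n. Plays the role of a Koeppen-Geiger style zonation used to
#' delimit the model-training background.
#' @export
setClass("ZoneRaster", contains = "RasterGrid")

#' Species occurrence records
#'
#' @slot species species label.
#' @slot coords two-column matrix (lon, lat) in decimal degrees.
#' @slot metadata free-form list (provenance, thinning report, ...).
#' @export
setClass("OccurrenceSet",
  representation(species = "character", coords = "matrix", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    if (ncol(object@coords) != 2L) return("coords must have two columns (lon, lat)")
    if (nrow(object@coords) > 0L) {
      lon <- object@coords[, 1L]; lat <- object@coords[, 2L]
      bad <- which(!is.finite(lon) | !is.finite(lat) |
                   lon < -180 | lon > 180 | lat < -90 | lat > 90)
      if (length(bad))
        return(sprintf("invalid coordinates at record(s): %s",
                       paste(head(bad, 5L), collapse = ", ")))
    }
    TRUE
  })

#' Background (available-environment) definition
#'
#' The set of climate zones containing at least one occurrence, the aligned
#' boolean mask of eligible cells, and the background sample drawn from it.
#'
#' @slot zoneIds integer labels of the selected zones.
#' @slot mask logical matrix aligned to the climate stack; TRUE = eligible.
#' @slot cells integer vector of linear cell indices of the sampled points.
#' @slot points two-column matrix of sampled cell-centre coordinates.
#' @export
setClass("BackgroundDefinition", contains = "SpatialGrid",
  representation(zoneIds = "integer", mask = "matrix",
                 cells = "integer", points = "matrix"))

#' Simple polygon collection
#'
#' Each feature is a single closed ring (matrix of lon/lat vertices); enough
#' to represent synthetic municipality tiles and plantation patches.
#'
#' @slot ids feature identifiers.
#' @slot rings list of two-column vertex matrices (not necessarily closed;
#'   the first vertex is implicitly repeated).
#' @export
setClass("PolygonSet",
  representation(ids = "character", rings = "list"),
  validity = function(object) {
    if (length(object@ids) != length(object@rings))
      return("ids and rings must have equal length")
    if (anyDuplicated(object@ids)) return("feature ids must be unique")
    for (r in object@rings)
      if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L)
        return("each ring must be a matrix with >= 3 vertices and 2 columns")
    TRUE
  })

## ---------------------------------------------------------------------------
## Synthetic-world specifications
## ---------------------------------------------------------------------------

#' Specification of a synthetic world
#'
#' Defines the grid geometry and the statistical structure of the synthetic
#' climate predictors: how many bands, which pairs are built collinear with
#' a target correlation, and the spatial autocorrelation length.
#'
#' @slot nRows,nCols grid size in cells (>= 10).
#' @slot cellSizeDeg cell size in degrees.
#' @slot originLon,originLat lower-left corner of the extent.
#' @slot nPredictors number of predictor bands.
#' @slot collinearPairs list of c(i, j, rho): band j is rebuilt as a mixture
#'   achieving Pearson correlation ~rho with band i (1-based indices, |rho| < 1).
#' @slot smoothness spatial correlation length in cells (Gaussian kernel sd).
#' @slot seed RNG seed.
#' @export
setClass("WorldSpec", representation(
    nRows = "integer", nCols = "integer", cellSizeDeg = "numeric",
    originLon = "numeric", originLat = "numeric",
    nPredictors = "integer", collinearPairs = "list",
    smoothness = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nRows < 10L || object@nCols < 10L)
      return("nRows and nCols must be >= 10")
    if (object@cellSizeDeg <= 0) return("cellSizeDeg must be positive")
    if (object@nPredictors < 1L) return("nPredictors must be >= 1")
    if (object@smoothness <= 0 ||
        object@smoothness >= min(object@nRows, object@nCols))
      return("smoothness must be in (0, min(nRows, nCols))")
    for (p in object@collinearPairs) {
      if (length(p) != 3L) return("collinear pairs must be c(i, j, rho)")
      if (abs(p[3L]) >= 1) return("collinearity target |rho| must be < 1.0")
      if (any(p[1:2] < 1) || any(p[1:2] > object@nPredictors) || p[1L] == p[2L])
        return("collinear pair indices must be distinct band indices")
    }
    TRUE
  })

#' Gaussian niche specification of a virtual species
#'
#' The true occurrence probability at a cell with predictor vector x is
#' maxProb * prod_v exp(-(x_v - optimum_v)^2 / (2 tolerance_v^2)).
#'
#' @slot optimum niche optimum per predictor (predictor units).
#' @slot tolerance niche breadth per predictor (> 0).
#' @slot maxProb probability at the optimum, in (0, 1].
#' @export
setClass("NicheSpec",
  representation(optimum = "numeric", tolerance = "numeric", maxProb = "numeric"),
  validity = function(object) {
    if (length(object@optimum) != length(object@tolerance))
      return("optimum and tolerance must have equal length")
    if (any(object@tolerance <= 0)) return("tolerance must be strictly positive")
    if (object@maxProb <= 0 || object@maxProb > 1)
      return("maxProb must be in (0, 1]")
    TRUE
  })

## ---------------------------------------------------------------------------
## MaxEnt model containers
## ---------------------------------------------------------------------------

#' MaxEnt feature set
#'
#' Feature definitions (linear, quadratic, product, forward/reverse hinge)
#' plus the background scaling that maps every feature into [0, 1].
#'
#' @slot definitions data.frame with columns kind, var1, var2, knot, dir.
#' @slot varRange 2 x p matrix of background min/max per predictor.
#' @slot featRange 2 x F matrix of background min/max per raw feature
#'   (hinge features are constructed in [0, 1] directly).
#' @export
setClass("FeatureSet",
  representation(definitions = "data.frame", varRange = "matrix",
                 featRange = "matrix"))

#' Fitted minimal MaxEnt model
#'
#' The Gibbs distribution over background cells
#' p(x) = exp(lambda . f(x)) / Z fitted by L1-penalised maximum likelihood.
#'
#' @slot lambda feature weights.
#' @slot featureSet the \linkS4class{FeatureSet} used.
#' @slot regMultiplier global regularization multiplier.
#' @slot beta per-feature L1 penalty scales.
#' @slot logZ log partition function over the training background.
#' @slot entropy entropy H of the fitted background distribution (used by
#'   the cloglog output transform).
#' @slot convergence list: objective trace, iterations, converged flag.
#' @export
setClass("MaxEntModel",
  representation(lambda = "numeric", featureSet = "FeatureSet",
                 regMultiplier = "numeric", beta = "numeric",
                 logZ = "numeric", entropy = "numeric", convergence = "list"))

## ---------------------------------------------------------------------------
## Economics containers
## ---------------------------------------------------------------------------

#' Municipal production table
#'
#' Per-municipality value of the focal product (VP_ij) and of total forestry
#' production (VP_j), with national totals VP_inat = sum_j VP_ij and
#' VP_nat = sum_j VP_j.
#'
#' @slot table data.frame with columns muni_id, vp_product, vp_forestry_total.
#' @export
setClass("ProductionTable",
  representation(table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    need <- c("muni_id", "vp_product", "vp_forestry_total")
    if (!all(need %in% names(tb)))
      return(paste("table needs columns", paste(need, collapse = ", ")))
    if (anyDuplicated(tb$muni_id)) return("muni_id must be unique")
    if (any(tb$vp_product < 0) || any(tb$vp_forestry_total < 0))
      return("production values must be non-negative")
    if (any(tb$vp_product > tb$vp_forestry_total + 1e-9 * pmax(1, tb$vp_forestry_total)))
      return("vp_product must not exceed vp_forestry_total")
    if (sum(tb$vp_product) <= 0) return("national product total must be positive")
    if (sum(tb$vp_forestry_total) <= 0) return("national forestry total must be positive")
    TRUE
  })

#' Classified map
#'
#' Integer class labels over a grid together with the Jenks break points
#' that produced them.
#'
#' @slot labels integer matrix of class labels (NA = nodata).
#' @slot breaks ascending vector of k - 1 upper class boundaries.
#' @slot labelNames class names, length k.
#' @export
setClass("ClassifiedMap", contains = "SpatialGrid",
  representation(labels = "matrix", breaks = "numeric", labelNames = "character"),
  validity = function(object) {
    if (is.unsorted(object@breaks, strictly = TRUE))
      return("breaks must be strictly ascending")
    if (length(object@labelNames) != length(object@breaks) + 1L)
      return("labelNames must have length length(breaks) + 1")
    TRUE
  })
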