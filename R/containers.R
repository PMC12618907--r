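## Constructors, accessors and show methods for the data containers.

#' Create a single-band raster grid
#'
#' @param values numeric matrix; row 1 is the southernmost row, NA = nodata.
#' @param xmin,ymin lower-left corner of the extent (degrees).
#' @param cellSize cell size in degrees.
#' @return A \linkS4class{RasterGrid}.
#' @export
rasterGrid <- function(values, xmin = 0, ymin = 0, cellSize = 1) {
  new("RasterGrid", values = values, xmin = xmin, ymin = ymin,
      cellSize = cellSize)
}

#' Create a multi-band climate stack
#'
#' @param bands named list of matrices sharing dimension and nodata mask.
#' @param xmin,ymin lower-left corner of the extent (degrees).
#' @param cellSize cell size in degrees.
#' @return A \linkS4class{ClimateStack}.
#' @export
climateStack <- function(bands, xmin = 0, ymin = 0, cellSize = 1) {
  new("ClimateStack", bands = bands, xmin = xmin, ymin = ymin,
      cellSize = cellSize)
}

#' Create an occurrence set
#'
#' @param species species label.
#' @param lon,lat coordinate vectors in decimal degrees.
#' @param metadata optional free-form list.
#' @return An \linkS4class{OccurrenceSet}.
#' @export
occurrenceSet <- function(species, lon, lat, metadata = list()) {
  stopifnot(length(lon) == length(lat))
  new("OccurrenceSet", species = species,
      coords = cbind(lon = as.numeric(lon), lat = as.numeric(lat)),
      metadata = metadata)
}

#' Create a polygon set
#'
#' @param ids feature identifiers.
#' @param rings list of two-column lon/lat vertex matrices.
#' @return A \linkS4class{PolygonSet}.
#' @export
polygonSet <- function(ids, rings) {
  new("PolygonSet", ids = as.character(ids), rings = rings)
}

#' Create a production table
#'
#' @param muni_id municipality identifiers.
#' @param vp_product value of the focal product per municipality (VP_ij).
#' @param vp_forestry_total total forestry production value per
#'   municipality (VP_j).
#' @return A \linkS4class{ProductionTable}.
#' @export
productionTable <- function(muni_id, vp_product, vp_forestry_total) {
  new("ProductionTable", table = data.frame(
    muni_id = as.character(muni_id),
    vp_product = as.numeric(vp_product),
    vp_forestry_total = as.numeric(vp_forestry_total),
    stringsAsFactors = FALSE))
}

## ---- generics --------------------------------------------------------------

#' Grid cell values
#' @param x a grid object.
#' @return For \code{gridValues}, the value matrix.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname gridValues
#' @export
setMethod("gridValues", "ClassifiedMap", function(x) x@labels)

#' Band names of a stack
#' @param x a \linkS4class{ClimateStack}.
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @rdname bandNames
#' @export
setMethod("bandNames", "ClimateStack", function(x) names(x@bands))

#' Number of bands
#' @param x a \linkS4class{ClimateStack}.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname nBands
#' @export
setMethod("nBands", "ClimateStack", function(x) length(x@bands))

#' Extract one band as a RasterGrid
#' @param x a \linkS4class{ClimateStack}.
#' @param name band name or index.
#' @export
setGeneric("getBand", function(x, name) standardGeneric("getBand"))

#' @rdname getBand
#' @export
setMethod("getBand", "ClimateStack", function(x, name) {
  rasterGrid(x@bands[[name]], x@xmin, x@ymin, x@cellSize)
})

#' Subset a stack to selected bands
#' @param x a \linkS4class{ClimateStack}.
#' @param bands character or integer vector of bands to keep.
#' @export
subsetStack <- function(x, bands) {
  climateStack(x@bands[bands], x@xmin, x@ymin, x@cellSize)
}

#' Occurrence coordinates
#' @param x an \linkS4class{OccurrenceSet} or
#'   \linkS4class{BackgroundDefinition}.
#' @return Two-column lon/lat matrix.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "OccurrenceSet", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("coords", "BackgroundDefinition", function(x) x@points)

#' Number of records
#' @param x an \linkS4class{OccurrenceSet}.
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname nRecords
#' @export
setMethod("nRecords", "OccurrenceSet", function(x) nrow(x@coords))

#' Grid dimension (rows, cols)
#' @param x a grid object.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname gridDim
#' @export
setMethod("gridDim", "RasterGrid", function(x) dim(x@values))

#' @rdname gridDim
#' @export
setMethod("gridDim", "ClimateStack", function(x) dim(x@bands[[1L]]))

#' @rdname gridDim
#' @export
setMethod("gridDim", "BackgroundDefinition", function(x) dim(x@mask))

#' @rdname gridDim
#' @export
setMethod("gridDim", "ClassifiedMap", function(x) dim(x@labels))

#' Model coefficients (feature weights)
#' @param object a \linkS4class{MaxEntModel}.
#' @param ... ignored.
#' @export
setMethod("coef", "MaxEntModel", function(object, ...) object@lambda)

#' Production table as a data.frame
#' @param x a \linkS4class{ProductionTable}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ProductionTable",
          function(x, ...) x@table)

#' Occurrences as a data.frame
#' @param x an \linkS4class{OccurrenceSet}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "OccurrenceSet", function(x, ...) {
  data.frame(species = rep(x@species, nrow(x@coords)),
             lon = x@coords[, 1L], lat = x@coords[, 2L],
             stringsAsFactors = FALSE)
})

## ---- show ------------------------------------------------------------------

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d cells, cell size %g deg, origin (%g, %g)\n",
              class(object), d[1L], d[2L], object@cellSize,
              object@xmin, object@ymin))
  v <- object@values[!is.na(object@values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v), max(v), sum(is.na(object@values))))
})

setMethod("show", "ClimateStack", function(object) {
  d <- dim(object@bands[[1L]])
  cat(sprintf("ClimateStack: %d band(s), %d x %d cells, cell size %g deg\n",
              length(object@bands), d[1L], d[2L], object@cellSize))
  cat("  bands:", paste(names(object@bands), collapse = ", "), "\n")
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d record(s) of '%s'\n",
              nrow(object@coords), object@species))
})

setMethod("show", "BackgroundDefinition", function(object) {
  cat(sprintf("BackgroundDefinition: zones {%s}, %d eligible cells, %d points\n",
              paste(object@zoneIds, collapse = ", "),
              sum(object@mask, na.rm = TRUE), length(object@cells)))
})

setMethod("show", "MaxEntModel", function(object) {
  cat(sprintf("MaxEntModel: %d feature(s), %d nonzero weight(s), rm = %g\n",
              length(object@lambda), sum(object@lambda != 0),
              object@regMultiplier))
  cat(sprintf("  logZ = %.4f, entropy = %.4f, converged = %s\n",
              object@logZ, object@entropy,
              isTRUE(object@convergence$converged)))
})

setMethod("show", "ProductionTable", function(object) {
  tb <- object@table
  cat(sprintf("ProductionTable: %d municipalities, VP_inat = %g, VP_nat = %g\n",
              nrow(tb), sum(tb$vp_product), sum(tb$vp_forestry_total)))
})

setMethod("show", "ClassifiedMap", function(object) {
  cat(sprintf("ClassifiedMap: %d classes (%s)\n  breaks: %s\n",
              length(object@labelNames),
              paste(object@labelNames, collapse = ", "),
              paste(signif(object@breaks, 5L), collapse = ", ")))
})

setMethod("show", "PolygonSet", function(object) {
  cat(sprintf("PolygonSet: %d feature(s)\n", length(object@ids)))
})
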