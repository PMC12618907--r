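## Risk mapping: normalization, combination with the introduction surface,
## exact Fisher-Jenks classification, zonal statistics per municipality and
## plantation-area overlap per suitability class.

#' Min-max normalize a raster to [0, 1]
#'
#' (x - min) / (max - min) over non-nodata cells. A constant raster maps to
#' all zeros with a warning.
#'
#' @param raster a \linkS4class{RasterGrid}.
#' @return A normalized \linkS4class{RasterGrid}.
#' @export
normalizeSurface <- function(raster) {
  v <- raster@values
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("constant raster; normalized to all zeros")
    out <- v * 0
  } else {
    out <- (v - rng[1L]) / diff(rng)
  }
  rasterGrid(out, raster@xmin, raster@ymin, raster@cellSize)
}

#' Invasion-risk surface
#'
#' Cellwise product of the climate suitability map and the normalized
#' introduction-likelihood map; nodata propagates. If the grids are not
#' aligned, the introduction surface is resampled bilinearly onto the
#' suitability grid first (with a message).
#'
#' @param suitability a \linkS4class{RasterGrid} in [0, 1].
#' @param introduction a normalized \linkS4class{RasterGrid}.
#' @return A \linkS4class{RasterGrid} of risk values.
#' @export
invasionRisk <- function(suitability, introduction) {
  aligned <- identical(dim(suitability@values), dim(introduction@values)) &&
    isTRUE(all.equal(c(suitability@xmin, suitability@ymin, suitability@cellSize),
                     c(introduction@xmin, introduction@ymin,
                       introduction@cellSize)))
  if (!aligned) {
    message("introduction surface resampled (bilinear) to the suitability grid")
    introduction <- resampleBilinear(introduction, suitability)
  }
  rasterGrid(suitability@values * introduction@values,
             suitability@xmin, suitability@ymin, suitability@cellSize)
}

#' Jenks natural breaks
#'
#' Exact Fisher-Jenks dynamic program minimising the total within-class sum
#' of squared deviations over all partitions of the sorted sample into k
#' contiguous classes.
#'
#' @param values numeric sample (NAs dropped); needs >= k distinct values.
#' @param k number of classes (>= 2).
#' @return Ascending vector of k - 1 break values: the upper boundary
#'   (largest member) of each of the first k - 1 classes.
#' @export
jenksBreaks <- function(values, k) {
  if (k < 2) stop("k must be >= 2")
  v <- sort(values[!is.na(values)])
  if (length(unique(v)) < k)
    stop("need at least ", k, " distinct values for ", k, " classes")
  idx <- .fisherJenksDP(v, as.integer(k))
  v[idx]
}

## classify a numeric vector by right-closed Jenks breaks:
## class = 1 + number of breaks strictly below the value
jenksClassify <- function(values, k) {
  br <- jenksBreaks(values, k)
  cls <- 1L + rowSums(outer(values, br, ">"))
  list(classes = as.integer(cls), breaks = br)
}

#' Classify a raster with Jenks natural breaks
#'
#' Breaks are computed on a uniform random sample of at most
#' \code{maxSample} non-nodata cells (the exact DP is O(k n^2)); the seed is
#' recorded. Boundary rule: a value equal to a break falls in the lower
#' class (first interval left-closed, all intervals right-closed).
#'
#' @param raster a \linkS4class{RasterGrid}.
#' @param k number of classes (default 4).
#' @param labels class names, lowest to highest; default the four
#'   suitability categories.
#' @param maxSample largest cell sample used for the break computation.
#' @param seed RNG seed for the sample.
#' @return A \linkS4class{ClassifiedMap}.
#' @export
classifyMap <- function(raster, k = 4,
                        labels = c("unsuitable", "marginally suitable",
                                   "moderately suitable", "highly suitable"),
                        maxSample = 10000, seed = 1) {
  stopifnot(length(labels) == k)
  v <- as.vector(raster@values)
  ok <- which(!is.na(v))
  sampleCells <- ok
  if (length(ok) > maxSample) {
    set.seed(seed)
    sampleCells <- sample(ok, maxSample)
  }
  br <- jenksBreaks(v[sampleCells], k)
  cls <- rep(NA_integer_, length(v))
  cls[ok] <- 1L + rowSums(outer(v[ok], br, ">"))
  d <- dim(raster@values)
  new("ClassifiedMap", labels = matrix(as.numeric(cls), d[1L], d[2L]),
      breaks = br, labelNames = labels,
      xmin = raster@xmin, ymin = raster@ymin, cellSize = raster@cellSize)
}

#' Mean suitability per municipality
#'
#' Averages raster values over the cells whose centres fall inside each
#' polygon (cell-centre rule). Polygons containing no cell centre get NA
#' with a warning.
#'
#' @param suitability a \linkS4class{RasterGrid}.
#' @param municipalities a \linkS4class{PolygonSet} with municipality ids.
#' @return data.frame with columns muni_id, mean_suitability, n_cells.
#' @export
zonalMean <- function(suitability, municipalities) {
  ctr <- cellCenters(suitability)
  v <- as.vector(suitability@values)
  res <- lapply(seq_along(municipalities@ids), function(i) {
    inside <- pointsInRing(municipalities@rings[[i]], ctr)
    vals <- v[inside]
    vals <- vals[!is.na(vals)]
    data.frame(muni_id = municipalities@ids[i],
               mean_suitability = if (length(vals)) mean(vals) else NA_real_,
               n_cells = length(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$mean_suitability))
    warning("municipalit(ies) with no raster cell centre: ",
            paste(out$muni_id[is.na(out$mean_suitability)], collapse = ", "))
  out
}

#' Plantation area fraction per suitability class
#'
#' Rasterizes the plantation polygons at the target resolution (a cell is
#' counted when its centre is covered by any polygon), assigns each covered
#' target cell the class of the classified map cell containing its centre,
#' and reports the fraction of plantation cells per class (summing to 1
#' over cells that fall on classified cells).
#'
#' @param classMap a \linkS4class{ClassifiedMap}.
#' @param plantations a \linkS4class{PolygonSet}.
#' @param targetCellSize rasterization resolution in degrees; defaults to a
#'   grid 5x finer than the class map (mirroring 30 arc-seconds against a
#'   2.5 arc-minute map).
#' @return data.frame with columns class, label, fraction.
#' @export
plantationOverlap <- function(classMap, plantations, targetCellSize = NULL) {
  if (is.null(targetCellSize)) targetCellSize <- classMap@cellSize / 5
  d <- gridShape(classMap)
  tgt <- rasterGrid(
    matrix(0, ceiling(d[1L] * classMap@cellSize / targetCellSize),
              ceiling(d[2L] * classMap@cellSize / targetCellSize)),
    classMap@xmin, classMap@ymin, targetCellSize)
  ctr <- cellCenters(tgt)
  covered <- rep(FALSE, nrow(ctr))
  for (r in plantations@rings)
    covered <- covered | pointsInRing(r, ctr)
  if (!any(covered)) stop("no target cell centre is covered by a plantation")
  cells <- cellFromXY(classMap, ctr[covered, , drop = FALSE])
  cls <- as.vector(classMap@labels)[cells]
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("plantations fall entirely on nodata cells")
  k <- length(classMap@labelNames)
  counts <- tabulate(cls, nbins = k)
  data.frame(class = seq_len(k), label = classMap@labelNames,
             fraction = counts / sum(counts), stringsAsFactors = FALSE)
}
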