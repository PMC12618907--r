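## Shared grid helpers: cell centres, point-to-cell lookup, stack <-> matrix
## conversion, polygon membership and bilinear resampling.

gridShape <- function(x) {
  if (is(x, "ClimateStack")) dim(x@bands[[1L]])
  else if (is(x, "BackgroundDefinition")) dim(x@mask)
  else if (is(x, "ClassifiedMap")) dim(x@labels)
  else dim(x@values)
}

#' Cell-centre coordinates
#'
#' Returns lon/lat of cell centres, either for all cells (in column-major
#' linear-index order, the order used by matrix indexing) or for a vector of
#' linear cell indices.
#'
#' @param grid any grid object.
#' @param cells optional integer vector of linear cell indices.
#' @return Two-column matrix (lon, lat).
#' @export
cellCenters <- function(grid, cells = NULL) {
  d <- gridShape(grid)
  if (is.null(cells)) cells <- seq_len(prod(d))
  i <- ((cells - 1L) %% d[1L]) + 1L       # row
  j <- ((cells - 1L) %/% d[1L]) + 1L      # col
  cbind(lon = grid@xmin + (j - 0.5) * grid@cellSize,
        lat = grid@ymin + (i - 0.5) * grid@cellSize)
}

#' Linear cell index containing each point
#'
#' @param grid any grid object.
#' @param xy two-column lon/lat matrix.
#' @return Integer vector of linear cell indices; NA for points outside the
#'   grid extent.
#' @export
cellFromXY <- function(grid, xy) {
  d <- gridShape(grid)
  j <- floor((xy[, 1L] - grid@xmin) / grid@cellSize) + 1
  i <- floor((xy[, 2L] - grid@ymin) / grid@cellSize) + 1
  out <- (j - 1) * d[1L] + i
  out[i < 1 | i > d[1L] | j < 1 | j > d[2L]] <- NA
  as.integer(out)
}

#' Stack values as a cells-by-bands matrix
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param cells optional linear cell indices (default: all cells).
#' @return Numeric matrix with one named column per band.
#' @export
stackValues <- function(stack, cells = NULL) {
  if (is.null(cells)) {
    out <- vapply(stack@bands, as.vector, numeric(prod(gridShape(stack))))
  } else {
    out <- vapply(stack@bands, function(b) b[cells], numeric(length(cells)))
    if (length(cells) == 1L) out <- matrix(out, nrow = 1L,
                                           dimnames = list(NULL, names(stack@bands)))
  }
  out
}

## linear indices of cells that are non-nodata in every band
validCells <- function(stack) {
  which(!is.na(as.vector(stack@bands[[1L]])))
}

#' Points inside a polygon ring
#'
#' Membership by the even-odd rule on the ring's boundary (cell-centre rule
#' used throughout the package for raster/polygon overlays).
#'
#' @param ring two-column vertex matrix.
#' @param xy two-column matrix of points.
#' @return Logical vector.
#' @export
pointsInRing <- function(ring, xy) {
  bnd <- rbind(ring, ring[1L, , drop = FALSE])
  mgcv::in.out(bnd, xy)
}

#' Bilinear resampling of a raster to a target grid
#'
#' Interpolates cell-centre values of \code{source} at the cell centres of
#' \code{target}. Target centres outside the source centre lattice get the
#' nearest-edge value (clamped); NA cells propagate through interpolation.
#'
#' @param source a \linkS4class{RasterGrid}.
#' @param target any grid object defining the output geometry.
#' @return A \linkS4class{RasterGrid} on the target geometry.
#' @export
resampleBilinear <- function(source, target) {
  d <- dim(source@values)
  td <- gridShape(target)
  ctr <- cellCenters(target)
  ## fractional row/col position on the source centre lattice
  fi <- (ctr[, 2L] - source@ymin) / source@cellSize + 0.5
  fj <- (ctr[, 1L] - source@xmin) / source@cellSize + 0.5
  fi <- pmin(pmax(fi, 1), d[1L])
  fj <- pmin(pmax(fj, 1), d[2L])
  i0 <- pmin(floor(fi), d[1L] - 1L); i1 <- i0 + 1L
  j0 <- pmin(floor(fj), d[2L] - 1L); j1 <- j0 + 1L
  if (d[1L] == 1L) { i0 <- i1 <- rep(1L, length(fi)) }
  if (d[2L] == 1L) { j0 <- j1 <- rep(1L, length(fj)) }
  wi <- fi - i0; wj <- fj - j0
  v <- source@values
  g <- function(i, j) v[cbind(i, j)]
  out <- (1 - wi) * (1 - wj) * g(i0, j0) + (1 - wi) * wj * g(i0, j1) +
         wi * (1 - wj) * g(i1, j0) + wi * wj * g(i1, j1)
  rasterGrid(matrix(out, td[1L], td[2L]),
             target@xmin, target@ymin, target@cellSize)
}

## great-circle distance matrix in km (haversine, Earth radius 6371 km);
## geosphere's default radius is the equatorial 6378137 m, and haversine
## distance is proportional to the radius, so rescale exactly.
haversineMatrixKm <- function(coords) {
  geosphere::distm(coords, fun = geosphere::distHaversine) * (6371 / 6378137)
}
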