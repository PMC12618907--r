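## Plain-text I/O: occurrence CSV, ESRI ASCII grids, production CSV and
## GeoJSON polygon collections.

#' Read occurrence records from CSV
#'
#' Expects a header with columns \code{species,lon,lat}.
#'
#' @param path CSV file path.
#' @return An \linkS4class{OccurrenceSet} (species taken from the first row).
#' @export
readOccurrences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV needs columns ", paste(need, collapse = ", "))
  occurrenceSet(df$species[1L], df$lon, df$lat,
                metadata = list(provenance = path))
}

#' Write occurrence records to CSV
#' @param occ an \linkS4class{OccurrenceSet}.
#' @param path output path.
#' @export
writeOccurrences <- function(occ, path) {
  write.csv(as.data.frame(occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text format: a six-line header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) followed by rows north to south.
#'
#' @param raster a \linkS4class{RasterGrid}.
#' @param path output path (.asc).
#' @param nodata nodata sentinel written for NA cells.
#' @export
writeAsciiGrid <- function(raster, path, nodata = -9999) {
  v <- raster@values
  d <- dim(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", d[2L]), paste("nrows", d[1L]),
    paste("xllcorner", format(raster@xmin, digits = 15)),
    paste("yllcorner", format(raster@ymin, digits = 15)),
    paste("cellsize", format(raster@cellSize, digits = 15)),
    paste("NODATA_value", nodata)), con)
  for (i in rev(seq_len(d[1L]))) {         # north to south
    row <- v[i, ]
    row[is.na(row)] <- nodata
    writeLines(paste(format(row, digits = 15, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path .asc file path.
#' @return A \linkS4class{RasterGrid}.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  v <- do.call(rbind, rows)
  v[v == hdr$nodata_value] <- NA
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # back to south-first rows
  rasterGrid(v, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write a climate stack as one ASCII grid per band
#'
#' Files are named \code{<band>.asc} inside \code{dir}.
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param dir output directory (created if needed).
#' @export
writeClimateStack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (b in bandNames(stack))
    writeAsciiGrid(getBand(stack, b), file.path(dir, paste0(b, ".asc")))
  invisible(dir)
}

#' Read a climate stack from a directory of ASCII grids
#' @param dir directory containing \code{*.asc} files (one per band).
#' @return A \linkS4class{ClimateStack}.
#' @export
readClimateStack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc files in ", dir)
  grids <- lapply(files, readAsciiGrid)
  bands <- lapply(grids, function(g) g@values)
  names(bands) <- sub("\\.asc$", "", basename(files))
  g1 <- grids[[1L]]
  climateStack(bands, g1@xmin, g1@ymin, g1@cellSize)
}

#' Read a production table from CSV
#'
#' Expects columns \code{muni_id,vp_product,vp_forestry_total}.
#'
#' @param path CSV file path.
#' @return A \linkS4class{ProductionTable}.
#' @export
readProductionTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  productionTable(df$muni_id, df$vp_product, df$vp_forestry_total)
}

#' Write a production table to CSV
#' @param table a \linkS4class{ProductionTable}.
#' @param path output path.
#' @export
writeProductionTable <- function(table, path) {
  write.csv(table@table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write polygons as GeoJSON
#' @param polys a \linkS4class{PolygonSet}.
#' @param path output path (.geojson).
#' @export
writePolygonsGeoJSON <- function(polys, path) {
  features <- lapply(seq_along(polys@ids), function(i) {
    ring <- polys@rings[[i]]
    ring <- rbind(ring, ring[1L, , drop = FALSE])   # close the ring
    list(type = "Feature",
         properties = list(muni_id = polys@ids[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(r) as.numeric(ring[r, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Supports FeatureCollections of single-ring Polygons with a
#' \code{muni_id} (or \code{id}) property.
#'
#' @param path .geojson file path.
#' @return A \linkS4class{PolygonSet}.
#' @export
readPolygonsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  ids <- character(0); rings <- list()
  for (f in gj$features) {
    id <- f$properties$muni_id
    if (is.null(id)) id <- f$properties$id
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(p) as.numeric(unlist(p))))
    ## drop the closing vertex if present
    if (all(ring[1L, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
    ids <- c(ids, as.character(id)); rings <- c(rings, list(ring))
  }
  polygonSet(ids, rings)
}

#' Write a thinning report as JSON
#'
#' Serializes the report attached by \code{\link{thinOccurrences}} (input,
#' deduplicated and output counts, method, replicate retention counts).
#'
#' @param occ a thinned \linkS4class{OccurrenceSet}.
#' @param path output path (.json).
#' @export
writeThinningReport <- function(occ, path) {
  rep <- occ@metadata$thinning
  if (is.null(rep)) stop("occurrence set carries no thinning report")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fitted MaxEnt model to JSON
#'
#' Stores the feature definitions, scaling, weights, penalties, log
#' partition function and entropy; \code{\link{readMaxEntModel}} restores a
#' model that predicts identically.
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @param path output path (.json).
#' @export
writeMaxEntModel <- function(model, path) {
  fs <- model@featureSet
  jsonlite::write_json(list(
    lambda = model@lambda, beta = model@beta,
    regMultiplier = model@regMultiplier,
    logZ = model@logZ, entropy = model@entropy,
    definitions = fs@definitions,
    varRange = as.data.frame(fs@varRange),
    featRange = as.data.frame(fs@featRange)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a MaxEnt model from JSON
#' @param path .json file written by \code{\link{writeMaxEntModel}}.
#' @return A \linkS4class{MaxEntModel}.
#' @export
readMaxEntModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  defs <- as.data.frame(x$definitions)
  defs$knot <- as.numeric(defs$knot)
  fs <- new("FeatureSet", definitions = defs,
            varRange = as.matrix(x$varRange),
            featRange = as.matrix(x$featRange))
  new("MaxEntModel", lambda = as.numeric(x$lambda), featureSet = fs,
      regMultiplier = x$regMultiplier, beta = as.numeric(x$beta),
      logZ = x$logZ, entropy = x$entropy,
      convergence = list(restored = TRUE))
}

#' Write an evaluation report (JSON + candidate CSV)
#'
#' @param report an \code{EvaluationReport} from \code{\link{tuneModels}}.
#' @param jsonPath path for the JSON summary (selected candidate + table).
#' @param csvPath optional path for the candidate table as CSV.
#' @export
writeEvaluationReport <- function(report, jsonPath, csvPath = NULL) {
  jsonlite::write_json(list(
    selected = report$selected,
    selectedSettings = report$candidates[report$selected,
                                         c("classes", "rm", "k", "AICc")],
    candidates = report$candidates), jsonPath,
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(csvPath))
    write.csv(report$candidates, csvPath, row.names = FALSE)
  invisible(jsonPath)
}
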