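## Occurrence cleaning: spatial thinning to a minimum inter-record distance
## and delimitation of the training background from climate zones.

## exact maximum independent set by branch and bound on the conflict graph;
## adj is a logical adjacency matrix. Returns indices of a maximum subset
## with no adjacent pair. Feasible for n <= ~25 on geometric graphs.
maxIndependentSet <- function(adj) {
  n <- nrow(adj)
  best <- integer(0)
  recurse <- function(chosen, candidates) {
    if (length(chosen) + length(candidates) <= length(best)) return()
    if (!length(candidates)) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    deg <- colSums(adj[candidates, candidates, drop = FALSE])
    if (all(deg == 0)) {
      tot <- c(chosen, candidates)
      if (length(tot) > length(best)) best <<- tot
      return()
    }
    v <- candidates[which.max(deg)]
    ## include v
    recurse(c(chosen, v), setdiff(candidates, c(v, which(adj[v, ]))))
    ## exclude v
    recurse(chosen, setdiff(candidates, v))
  }
  recurse(integer(0), seq_len(n))
  sort(best)
}

## one randomized greedy thinning run: repeatedly delete a record among
## those with the largest number of conflicting neighbours (random tie-break)
## until no pair is closer than the threshold. Returns retained indices.
greedyThinOnce <- function(adj) {
  alive <- rep(TRUE, nrow(adj))
  repeat {
    deg <- colSums(adj & alive) * alive
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    drop <- if (length(worst) == 1L) worst else sample(worst, 1L)
    alive[drop] <- FALSE
  }
  which(alive)
}

#' Spatially thin occurrence records
#'
#' Enforces a minimum great-circle distance between retained records while
#' keeping as many records as possible. Exact duplicate coordinates are
#' removed first (the first is kept). For small sets (n <= \code{exactLimit}
#' after dedup) the maximum-retention subset is found exactly by
#' branch-and-bound; larger sets use a replicated randomized
#' max-conflict-removal heuristic (spThin-style) and the best replicate is
#' returned.
#'
#' @param occ an \linkS4class{OccurrenceSet} with at least one record.
#' @param minDistKm minimum pairwise haversine distance in km (default 20,
#'   Earth radius 6371 km).
#' @param nReplicates number of randomized heuristic runs.
#' @param seed RNG seed for the heuristic.
#' @param exactLimit largest record count solved exactly.
#' @return A thinned \linkS4class{OccurrenceSet}; \code{x@metadata$thinning}
#'   carries a report (input/output counts, method, replicate retention
#'   counts).
#' @export
thinOccurrences <- function(occ, minDistKm = 20, nReplicates = 10, seed = 1,
                            exactLimit = 25) {
  stopifnot(minDistKm > 0, nReplicates >= 1)
  xy <- coords(occ)
  if (nrow(xy) == 0L) stop("cannot thin an empty occurrence set")
  bad <- which(!is.finite(xy[, 1L]) | !is.finite(xy[, 2L]) |
               abs(xy[, 1L]) > 180 | abs(xy[, 2L]) > 90)
  if (length(bad))
    stop("invalid coordinates at record(s): ", paste(bad, collapse = ", "))
  keepFirst <- !duplicated(xy)
  xy <- xy[keepFirst, , drop = FALSE]
  n <- nrow(xy)
  D <- haversineMatrixKm(xy)
  adj <- D < minDistKm
  diag(adj) <- FALSE
  report <- list(nInput = nRecords(occ), nDeduplicated = n,
                 minDistKm = minDistKm, seed = seed)
  if (!any(adj)) {
    keep <- seq_len(n)
    report$method <- "none needed"
  } else if (n <= exactLimit) {
    keep <- maxIndependentSet(adj)
    report$method <- "exact branch-and-bound"
  } else {
    set.seed(seed)
    runs <- lapply(seq_len(nReplicates), function(r) greedyThinOnce(adj))
    sizes <- lengths(runs)
    keep <- runs[[which.max(sizes)]]
    report$method <- "randomized heuristic"
    report$replicateRetention <- sizes
  }
  report$nOutput <- length(keep)
  occurrenceSet(occ@species, xy[keep, 1L], xy[keep, 2L],
                metadata = c(occ@metadata[setdiff(names(occ@metadata), "thinning")],
                             list(thinning = report)))
}

#' Delimit the training background from climate zones
#'
#' The background area is the union of the zones that contain at least one
#' occurrence; background points are sampled uniformly without replacement
#' from the non-nodata cells of those zones.
#'
#' @param occ an \linkS4class{OccurrenceSet}.
#' @param zones a \linkS4class{ZoneRaster} aligned to \code{stack}.
#' @param stack the \linkS4class{ClimateStack} (defines the nodata mask).
#' @param nPoints number of background points (default 10000; capped at the
#'   number of eligible cells with a warning).
#' @param seed RNG seed.
#' @return A \linkS4class{BackgroundDefinition}.
#' @export
selectBackground <- function(occ, zones, stack, nPoints = 10000, seed = 1) {
  stopifnot(identical(gridShape(zones), gridShape(stack)))
  cells <- cellFromXY(zones, coords(occ))
  zl <- as.vector(zones@values)[cells]
  zl <- zl[!is.na(zl)]
  if (!length(zl))
    stop("all occurrences fall on nodata cells of the zone raster")
  zoneIds <- sort(unique(as.integer(zl)))
  d <- gridShape(stack)
  maskVec <- !is.na(as.vector(stack@bands[[1L]])) &
    as.vector(zones@values) %in% zoneIds
  eligible <- which(maskVec)
  if (nPoints > length(eligible)) {
    warning("requested ", nPoints, " background points but only ",
            length(eligible), " eligible cells; capping")
    nPoints <- length(eligible)
  }
  set.seed(seed)
  sel <- sort(eligible[sample.int(length(eligible), nPoints)])
  new("BackgroundDefinition",
      zoneIds = zoneIds, mask = matrix(maskVec, d[1L], d[2L]),
      cells = as.integer(sel), points = cellCenters(stack, sel),
      xmin = stack@xmin, ymin = stack@ymin, cellSize = stack@cellSize)
}
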