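## Shared synthetic-world fixtures, generated in code (small and fast).

tinySpec <- worldSpec(nRows = 30, nCols = 30, nPredictors = 5,
                      collinearPairs = list(c(1, 2, 0.99)),
                      smoothness = 5, seed = 101)
tinyStack <- generateClimateStack(tinySpec)
tinyNiche <- nicheSpec(optimum = rep(0, 5), tolerance = rep(1.5, 5),
                       maxProb = 0.9)
tinySurface <- generateVirtualSpecies(tinyStack, tinyNiche)
tinyOcc <- samplePresences(tinySurface, 50, seed = 7)
tinyZones <- generateZoneRaster(tinyStack, 3, seed = 11)
tinyBackground <- suppressWarnings(
  selectBackground(tinyOcc, tinyZones, tinyStack, nPoints = 600, seed = 5))

tinyPresVals <- stackValues(tinyStack, cellFromXY(tinyStack, coords(tinyOcc)))
tinyBgVals <- stackValues(tinyStack, tinyBackground@cells)

## brute-force maximum "no pair closer than d" subset size, n <= 15
bruteMaxRetention <- function(coordsKm, minDistKm) {
  n <- nrow(coordsKm)
  D <- geosphere::distm(coordsKm, fun = geosphere::distHaversine) *
    (6371 / 6378137)
  best <- 0L
  for (code in 0:(2^n - 1)) {
    sel <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    if (length(sel) < 2L || all(D[sel, sel][upper.tri(D[sel, sel])] >= minDistKm))
      best <- length(sel)
  }
  best
}

## brute-force optimal within-class SSD over all ordered partitions into k
## contiguous non-empty classes (oracle for the Fisher-Jenks DP)
bruteJenksSSD <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- combn(seq_len(n - 1L), k - 1L)
  best <- Inf
  for (c in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, c], n)
    tot <- sum(vapply(seq_len(k), function(i)
      ssd(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1L)))
    best <- min(best, tot)
  }
  best
}

## within-class SSD implied by a break vector (right-closed assignment)
ssdFromBreaks <- function(values, breaks) {
  cls <- 1L + rowSums(outer(values, breaks, ">"))
  sum(vapply(split(values, cls), function(v) sum((v - mean(v))^2), numeric(1L)))
}

## brute-force AUC by enumerating all presence/background pairs
bruteAuc <- function(sp, sb) {
  tot <- 0
  for (p in sp) for (b in sb)
    tot <- tot + if (p > b) 1 else if (p == b) 0.5 else 0
  tot / (length(sp) * length(sb))
}
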