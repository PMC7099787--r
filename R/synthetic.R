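#' Specification of a synthetic study area
#'
#' Describes a fabricated gridded-population world with the spatial
#' structure the frame-construction method assumes: dense, roughly Gaussian
#' settlement clusters on a near-zero background over a vast sparsely
#' populated area, plus matching administrative, urban and IDP boundaries.
#' Defaults emulate a 51 km square at 100 m resolution with a handful of
#' towns of a few thousand to tens of thousands of people — large enough to
#' exercise every splitting rule, small enough to run end-to-end in seconds.
#'
#' @param nRows,nCols grid dimensions in cells.
#' @param cellSize cell side in metres.
#' @param clusters data.frame with columns `x`, `y` (centre coordinates),
#'   `spread_m` (Gaussian sigma) and `total_pop`; `NULL` = generate
#'   `nClusters` clusters at random from `seed`.
#' @param nClusters number of clusters generated when `clusters` is `NULL`.
#' @param backgroundDensity uniform background population per cell
#'   (persons/cell; default 0.02, a near-empty hinterland).
#' @param nRegions number of admin regions tiling the extent.
#' @param urbanRadiusM radius of the urban disk drawn around each cluster
#'   centre.
#' @param seed integer seed making cluster generation deterministic.
#' @return a list of class `"SyntheticSpec"`
#' @export
syntheticSpec <- function(nRows = 512L, nCols = 512L, cellSize = 100,
                          clusters = NULL, nClusters = 8L,
                          backgroundDensity = 0.02, nRegions = 4L,
                          urbanRadiusM = 2000, seed = 1L) {
  extX <- nCols * cellSize
  extY <- nRows * cellSize
  if (is.null(clusters)) {
    clusters <- withr_seed(splitSeed(seed, 17L), {
      data.frame(
        x = stats::runif(nClusters, 0.1 * extX, 0.9 * extX),
        y = stats::runif(nClusters, 0.1 * extY, 0.9 * extY),
        spread_m = stats::runif(nClusters, 400, 1500),
        total_pop = stats::runif(nClusters, 5000, 50000))
    })
  }
  stopifnot(all(clusters$total_pop >= 0), all(clusters$spread_m > 0))
  if (any(clusters$x < 0 | clusters$x > extX |
          clusters$y < 0 | clusters$y > extY))
    stop("cluster centre outside the grid extent")
  structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                 cellSize = cellSize, clusters = clusters,
                 backgroundDensity = backgroundDensity,
                 nRegions = as.integer(nRegions),
                 urbanRadiusM = urbanRadiusM, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Fabricate a population raster from a synthetic specification
#'
#' Each cluster contributes an isotropic Gaussian blob truncated at the grid
#' edge and renormalised so it integrates to exactly its `total_pop`; a
#' uniform background is added on top. The raster total therefore equals
#' `sum(total_pop) + backgroundDensity * n_cells` exactly, making
#' conservation tests sharp. Fully deterministic given the spec.
#'
#' @param spec a [syntheticSpec()]
#' @return a [PopulationGrid-class] with origin (0, nRows * cellSize)
#' @export
makePopulationRaster <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  cs <- spec$cellSize
  xs <- (seq_len(spec$nCols) - 0.5) * cs
  ys <- (spec$nRows - seq_len(spec$nRows) + 0.5) * cs   # row 1 = north
  v <- matrix(spec$backgroundDensity, spec$nRows, spec$nCols)
  cl <- spec$clusters
  for (i in seq_len(nrow(cl))) {
    wy <- stats::dnorm(ys, cl$y[i], cl$spread_m[i])
    wx <- stats::dnorm(xs, cl$x[i], cl$spread_m[i])
    blob <- outer(wy, wx)
    s <- sum(blob)
    if (s > 0) v <- v + blob * (cl$total_pop[i] / s)
  }
  populationGrid(v, cellSize = cs, originX = 0,
                 originY = spec$nRows * cs, crsId = "synthetic-metric")
}

#' Fabricate boundary sets matching a synthetic raster
#'
#' Admin regions tile the extent as a near-square grid of `nRegions` equal
#' rectangles; one urban disk (64-gon of radius `urbanRadiusM`) is drawn
#' around each cluster centre; and one small IDP-camp square (500 m side)
#' is placed adjacent to the first cluster's urban disk. These stand in for
#' administrative boundaries, urban enumeration-area outlines and IDP camp
#' polygons respectively.
#'
#' @param spec a [syntheticSpec()]
#' @return list with [RegionSet-class] elements `admin`, `urban`, `idp`
#' @export
makeBoundaries <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"), spec$nRegions >= 1L)
  extX <- spec$nCols * spec$cellSize
  extY <- spec$nRows * spec$cellSize

  n <- spec$nRegions
  nry <- max(1L, as.integer(floor(sqrt(n))))
  while (n %% nry != 0L) nry <- nry - 1L
  nrx <- n %/% nry
  adminIds <- character(); adminPolys <- list()
  k <- 0L
  for (iy in seq_len(nry)) {
    for (ix in seq_len(nrx)) {
      k <- k + 1L
      adminIds <- c(adminIds, sprintf("R%02d", k))
      adminPolys[[k]] <- rectRing((ix - 1) * extX / nrx, (iy - 1) * extY / nry,
                                  ix * extX / nrx, iy * extY / nry)
    }
  }
  admin <- regionSet(adminIds, adminPolys, "admin")

  cl <- spec$clusters
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  urbanPolys <- lapply(seq_len(nrow(cl)), function(i)
    cbind(cl$x[i] + spec$urbanRadiusM * cos(th),
          cl$y[i] + spec$urbanRadiusM * sin(th)))
  urban <- regionSet(sprintf("U%02d", seq_len(nrow(cl))), urbanPolys, "urban")

  side <- 500
  x0 <- min(max(cl$x[1] + spec$urbanRadiusM + side / 2, side), extX - side)
  y0 <- min(max(cl$y[1], side), extY - side)
  idp <- regionSet("IDP01",
                   list(rectRing(x0 - side / 2, y0 - side / 2,
                                 x0 + side / 2, y0 + side / 2)),
                   "idp")
  list(admin = admin, urban = urban, idp = idp)
}

#' Random clustered rasters with a per-cell population cap
#'
#' Convenience generator for simulation studies: draws a random
#' [syntheticSpec()] from the seed and verifies the stated condition that no
#' single cell reaches `cellCap` persons (cluster spreads and totals are
#' sized so the densest cell of the densest cluster stays under the cap).
#'
#' @param seed integer seed.
#' @param nRows,nCols,cellSize grid geometry.
#' @param cellCap per-cell population ceiling the generated world respects.
#' @return a [PopulationGrid-class]
#' @export
randomClusteredRaster <- function(seed, nRows = 512L, nCols = 512L,
                                  cellSize = 100, cellCap = 3500) {
  spec <- syntheticSpec(nRows = nRows, nCols = nCols, cellSize = cellSize,
                        nClusters = 10L, seed = seed)
  g <- makePopulationRaster(spec)
  mx <- max(g@values)
  if (mx >= cellCap)
    stop("generated raster violates the per-cell cap (max ", mx, ")")
  g
}
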