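## Integral image with a zero top row / left column so block sums are O(1):
## blockSum(S, r0, c0, h, w) over 0-based offsets, clipped to the grid.
integralImage <- function(M) {
  colCum <- function(X) if (nrow(X) == 1L) X else apply(X, 2, cumsum)
  S <- t(colCum(t(colCum(M))))
  rbind(0, cbind(0, S))
}

blockSum <- function(S, r0, c0, h, w) {
  nr <- nrow(S) - 1L; nc <- ncol(S) - 1L
  r1 <- min(r0 + h, nr); c1 <- min(c0 + w, nc)
  r0 <- min(r0, nr); c0 <- min(c0, nc)
  S[r1 + 1L, c1 + 1L] - S[r0 + 1L, c1 + 1L] -
    S[r1 + 1L, c0 + 1L] + S[r0 + 1L, c0 + 1L]
}

#' Quadtree decomposition of a population grid into sampling units
#'
#' Recursively splits the grid into four quadrants until every unit
#' satisfies both constraints: population below `popMax` (default 3500
#' persons) and side at most `sideMaxM` (default 3000 m, i.e. 3 x 3 km at
#' 100 m cells). Dense areas end up as many small units and sparse areas as
#' few large ones, giving a spatially complete frame of approximately
#' population-homogeneous square units.
#'
#' The root square is sized so the area constraint binds at exactly
#' `sideMaxM`: when `floor(sideMaxM / cellSize)` cells exceed the grid's
#' larger dimension the root is the smallest power of two covering the grid
#' (the area rule can never bind); otherwise it is `sideMaxCells * 2^m` for
#' the smallest `m` covering the grid. The grid sits at the root's top-left
#' corner; padding is zero-population, masked-out. Odd sides split at
#' `floor(side/2)`, so units are square up to one cell of floor/ceil
#' asymmetry. Units are emitted in deterministic depth-first NW, NE, SW, SE
#' order; units containing no masked-in cell are dropped, and units that
#' straddle the mask edge are kept whole with population summed over valid
#' cells only. Zero-population units inside the mask are retained. A single
#' cell whose population reaches `popMax` cannot be split and is emitted
#' with `flag_overflow = TRUE`.
#'
#' Splitting decisions use the same (typically smoothed) surface that
#' populates the output units.
#'
#' @param grid a [PopulationGrid-class], usually already masked to one
#'   stratum and smoothed with [gaussianSmooth()].
#' @param popMax maximum unit population (persons); a unit with population
#'   `>= popMax` is split.
#' @param sideMaxM maximum unit side (metres); must be at least one cell.
#' @param minSideCells smallest splittable side in cells (default 1).
#' @param stratumId stratum label stamped on every unit.
#' @return a [Frame-class] with `method = "quadtree"`. Unit populations sum
#'   exactly to [gridTotal()] of the input.
#' @examples
#' g <- populationGrid(matrix(1, 8, 8), cellSize = 100)
#' frameUnits(quadtreePartition(g, popMax = 20, sideMaxM = 10000))
#' @export
quadtreePartition <- function(grid, popMax = 3500, sideMaxM = 3000,
                              minSideCells = 1L, stratumId = "all") {
  stopifnot(popMax > 0, sideMaxM >= grid@cellSize, minSideCells >= 1L)
  cs <- grid@cellSize
  sideMaxCells <- max(1L, as.integer(floor(sideMaxM / cs)))
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  maxDim <- max(nr, nc)

  rootSide <- if (sideMaxCells >= maxDim) {
    as.integer(2^ceiling(log2(max(1L, maxDim))))
  } else {
    s <- sideMaxCells
    while (s < maxDim) s <- s * 2L
    s
  }

  Spop <- integralImage(grid@values * grid@mask)
  Sval <- integralImage(grid@mask * 1)

  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 1024L)
  acc$n <- 0L
  emit <- function(row) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$rows)) acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    acc$rows[[acc$n]] <- row
  }

  recurse <- function(r0, c0, h, w) {
    nValid <- blockSum(Sval, r0, c0, h, w)
    if (nValid == 0) return(invisible())
    pop <- blockSum(Spop, r0, c0, h, w)
    side <- max(h, w)
    splitArea <- side > sideMaxCells
    splitPop <- pop >= popMax && side > minSideCells
    if (splitArea || splitPop) {
      hs <- if (h > 1L) c(h %/% 2L, h - h %/% 2L) else h
      ws <- if (w > 1L) c(w %/% 2L, w - w %/% 2L) else w
      rOff <- cumsum(c(0L, hs))[seq_along(hs)]
      cOff <- cumsum(c(0L, ws))[seq_along(ws)]
      for (i in seq_along(hs))            # rows outer: NW, NE, SW, SE
        for (j in seq_along(ws))
          recurse(r0 + rOff[i], c0 + cOff[j], hs[i], ws[j])
    } else {
      emit(list(
        unit_id = sprintf("q%d_%d_%dx%d", r0, c0, h, w),
        row0 = r0, col0 = c0, h_cells = h, w_cells = w,
        population = pop, n_cells_valid = nValid,
        flag_overflow = pop >= popMax))
    }
    invisible()
  }
  recurse(0L, 0L, rootSide, rootSide)

  rows <- acc$rows[seq_len(acc$n)]
  units <- unitsDataFrame(rows, grid, stratumId)
  new("Frame", units = units, method = "quadtree",
      provenance = list(
        popMax = popMax, sideMaxM = sideMaxM, minSideCells = minSideCells,
        sideMaxCells = sideMaxCells, rootSideCells = rootSide,
        inputChecksum = gridChecksum(grid)))
}

## Assemble the Frame units table from emitted leaf records.
unitsDataFrame <- function(rows, grid, stratumId) {
  cs <- grid@cellSize
  if (!length(rows)) {
    return(data.frame(
      unit_id = character(), stratum_id = character(), x_min = numeric(),
      y_min = numeric(), x_max = numeric(), y_max = numeric(),
      side_m = numeric(), population = numeric(), n_cells_valid = integer(),
      flag_overflow = logical(), row0 = integer(), col0 = integer(),
      h_cells = integer(), w_cells = integer(),
      stringsAsFactors = FALSE))
  }
  g <- function(f, mode) vapply(rows, `[[`, mode, f)
  r0 <- g("row0", integer(1)); c0 <- g("col0", integer(1))
  h <- g("h_cells", integer(1)); w <- g("w_cells", integer(1))
  data.frame(
    unit_id = g("unit_id", character(1)),
    stratum_id = stratumId,
    x_min = grid@originX + c0 * cs,
    y_min = grid@originY - (r0 + h) * cs,
    x_max = grid@originX + (c0 + w) * cs,
    y_max = grid@originY - r0 * cs,
    side_m = pmax(h, w) * cs,
    population = g("population", numeric(1)),
    n_cells_valid = as.integer(g("n_cells_valid", numeric(1))),
    flag_overflow = g("flag_overflow", logical(1)),
    row0 = r0, col0 = c0, h_cells = h, w_cells = w,
    stringsAsFactors = FALSE)
}

gridChecksum <- function(grid) {
  sprintf("%dx%d/%.17g/%.17g/%d", nrow(grid@values), ncol(grid@values),
          sum(grid@values[grid@mask]), grid@cellSize, sum(grid@mask))
}
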