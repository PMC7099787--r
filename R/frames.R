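#' Uniform-grid-cell baseline frame
#'
#' Tiles the grid with fixed-size square units (e.g. 1 x 1 km or 3 x 3 km),
#' anchored at the grid origin — the conventional survey-practitioner
#' baseline the quadtree frame is compared against. Partial tiles at the
#' south/east edges are retained; tiles containing no masked-in cell are
#' dropped; per-tile population is the block sum over masked-in cells, so
#' the tiling conserves the grid total exactly.
#'
#' @param grid a [PopulationGrid-class]
#' @param sideM tile side in metres; must be an integer multiple of the cell
#'   size.
#' @param stratumId stratum label stamped on every unit.
#' @return a [Frame-class] with `method = "ugc"`
#' @export
ugcPartition <- function(grid, sideM, stratumId = "all") {
  cs <- grid@cellSize
  sideCells <- sideM / cs
  if (abs(sideCells - round(sideCells)) > 1e-9)
    stop("sideM (", sideM, ") must be an integer multiple of the cell size (",
         cs, ")")
  sideCells <- as.integer(round(sideCells))
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  Spop <- integralImage(grid@values * grid@mask)
  Sval <- integralImage(grid@mask * 1)
  rows <- list()
  for (r0 in seq(0L, nr - 1L, by = sideCells)) {
    h <- min(sideCells, nr - r0)
    for (c0 in seq(0L, nc - 1L, by = sideCells)) {
      w <- min(sideCells, nc - c0)
      nValid <- blockSum(Sval, r0, c0, h, w)
      if (nValid == 0) next
      rows[[length(rows) + 1L]] <- list(
        unit_id = sprintf("u%d_%d_%dx%d", r0, c0, h, w),
        row0 = r0, col0 = c0, h_cells = h, w_cells = w,
        population = blockSum(Spop, r0, c0, h, w),
        n_cells_valid = nValid, flag_overflow = FALSE)
    }
  }
  new("Frame", units = unitsDataFrame(rows, grid, stratumId), method = "ugc",
      provenance = list(sideM = sideM, inputChecksum = gridChecksum(grid)))
}

#' Population-homogeneity diagnostics of a frame
#'
#' Computes, nationally and (when region boundaries are supplied) per
#' region, the summary the frames are compared on: unit count, minimum,
#' maximum, mean, standard deviation and coefficient of variation of unit
#' populations. A homogeneous frame — the design goal — has small std and cv
#' within each scope.
#'
#' The standard deviation uses the population (`ddof = 0`) denominator and
#' `cv = std / mean`, reported as a ratio (not percent). Units are assigned
#' to regions by their centroid; centroids on a shared boundary go to the
#' lowest region id. Regions containing no unit get a row with `n_units = 0`
#' and `NA` statistics; `cv` is `NA` whenever the scope mean is not positive.
#'
#' @param frame a non-empty [Frame-class]
#' @param regions optionally a [RegionSet-class] of admin regions.
#' @return data.frame with columns `scope_id` ("national" or a region id),
#'   `n_units`, `min`, `max`, `mean`, `std`, `cv`
#' @examples
#' g <- populationGrid(matrix(c(0, 100, 200, 0), 2, 2), cellSize = 100)
#' frameMetrics(ugcPartition(g, 100))
#' @export
frameMetrics <- function(frame, regions = NULL) {
  u <- frame@units
  if (!nrow(u)) stop("frame is empty")
  summarise <- function(pop) {
    n <- length(pop)
    if (n == 0L)
      return(list(n_units = 0L, min = NA_real_, max = NA_real_,
                  mean = NA_real_, std = NA_real_, cv = NA_real_))
    m <- mean(pop)
    s <- sqrt(mean((pop - m)^2))        # ddof = 0
    list(n_units = n, min = min(pop), max = max(pop), mean = m, std = s,
         cv = if (m > 0) s / m else NA_real_)
  }
  out <- list(c(list(scope_id = "national"), summarise(u$population)))
  if (!is.null(regions)) {
    cx <- (u$x_min + u$x_max) / 2
    cy <- (u$y_min + u$y_max) / 2
    assigned <- rep(NA_character_, nrow(u))
    for (id in sort(regions@ids)) {       # ties go to the lowest region id
      hit <- is.na(assigned) & pointInRegion(cbind(cx, cy), regions, id)
      assigned[hit] <- id
    }
    for (id in sort(regions@ids))
      out[[length(out) + 1L]] <-
        c(list(scope_id = id),
          summarise(u$population[!is.na(assigned) & assigned == id]))
  }
  do.call(rbind, lapply(out, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Bind frames from several strata into one
#'
#' @param frames list of [Frame-class] objects sharing a method.
#' @return a single [Frame-class]; unit ids are prefixed with their stratum
#'   to stay unique
#' @export
combineFrames <- function(frames) {
  stopifnot(length(frames) >= 1L)
  method <- unique(vapply(frames, function(f) f@method, character(1)))
  if (length(method) != 1L) stop("frames mix methods: ",
                                 paste(method, collapse = ", "))
  units <- do.call(rbind, lapply(frames, function(f) {
    u <- f@units
    if (nrow(u)) u$unit_id <- paste(u$stratum_id, u$unit_id, sep = ":")
    u
  }))
  rownames(units) <- NULL
  new("Frame", units = units, method = method,
      provenance = list(combined = lapply(frames, function(f) f@provenance)))
}

#' Write a frame as a flat CSV
#'
#' Columns: `unit_id`, `stratum_id`, `x_min`, `y_min`, `x_max`, `y_max`,
#' `side_m`, `population`, plus `n_cells_valid` and `flag_overflow`.
#'
#' @param frame a [Frame-class]
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeFrameCSV <- function(frame, path) {
  cols <- c("unit_id", "stratum_id", "x_min", "y_min", "x_max", "y_max",
            "side_m", "population", "n_cells_valid", "flag_overflow")
  utils::write.csv(frame@units[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a frame's unit extents as GeoJSON polygons
#'
#' @param frame a [Frame-class]
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeFrameGeoJSON <- function(frame, path) {
  u <- frame@units
  feats <- lapply(seq_len(nrow(u)), function(i) {
    ring <- rectRing(u$x_min[i], u$y_min[i], u$x_max[i], u$y_max[i])
    list(type = "Feature",
         properties = list(unit_id = u$unit_id[i],
                           stratum_id = u$stratum_id[i],
                           side_m = u$side_m[i],
                           population = u$population[i]),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(j) c(ring[j, 1], ring[j, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
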