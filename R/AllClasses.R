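#' @import methods
NULL

#' PopulationGrid: a gridded population surface
#'
#' A single-band raster of non-negative population counts in a projected
#' (metre-unit) CRS with square cells, together with a validity mask marking
#' cells inside the study area. The grid origin is the *top-left* corner;
#' row indices increase southward. Cell extents are half-open,
#' `[x_min, x_max) x (y_min, y_max]`, so adjacent units never double-count.
#'
#' @slot values numeric matrix of per-cell population (persons). Masked-out
#'   cells carry 0.
#' @slot mask logical matrix, `TRUE` = cell is inside the study area.
#' @slot cellSize cell side length in metres.
#' @slot originX,originY CRS coordinates of the top-left corner of cell (1,1).
#' @slot crsId free-text identifier of the projected CRS.
#'
#' @seealso [populationGrid()], [loadPopulationGrid()], [gridTotal()],
#'   [maskGrid()]
#' @exportClass PopulationGrid
setClass("PopulationGrid",
  representation(
    values = "matrix",
    mask = "matrix",
    cellSize = "numeric",
    originX = "numeric",
    originY = "numeric",
    crsId = "character"
  )
)

setValidity("PopulationGrid", function(object) {
  msg <- character()
  v <- object@values
  m <- object@mask
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (!is.logical(m)) msg <- c(msg, "mask must be a logical matrix")
  if (!identical(dim(v), dim(m)))
    msg <- c(msg, "values and mask must have identical dimensions")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  vin <- v[m]
  if (length(vin) && (any(!is.finite(vin)) || any(vin < 0)))
    msg <- c(msg, "masked-in values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' RegionSet: a set of boundary polygons
#'
#' Polygons (optionally with holes, even-odd rule) keyed by a unique
#' `region_id`, with a role tag saying what kind of boundary they are:
#' administrative regions, urban enumeration-area outlines, or IDP camps.
#'
#' @slot ids character vector of unique region identifiers.
#' @slot polygons list, one element per region: a list of rings, each ring a
#'   two-column numeric matrix of vertices (closed or open; closure implied).
#' @slot role one of `"admin"`, `"urban"`, `"idp"`.
#'
#' @seealso [regionSet()], [readRegionSet()], [pointInRegion()]
#' @exportClass RegionSet
setClass("RegionSet",
  representation(ids = "character", polygons = "list", role = "character")
)

setValidity("RegionSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "region ids must be unique")
  if (length(object@ids) != length(object@polygons))
    msg <- c(msg, "ids and polygons must have equal length")
  if (length(object@role) != 1L || !object@role %in% c("admin", "urban", "idp"))
    msg <- c(msg, "role must be one of 'admin', 'urban', 'idp'")
  ok <- vapply(object@polygons, function(p) {
    is.list(p) && all(vapply(p, function(r) {
      is.matrix(r) && ncol(r) == 2L && nrow(r) >= 3L && all(is.finite(r))
    }, logical(1)))
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, "each polygon must be a list of >=3-vertex coordinate rings")
  if (length(msg)) msg else TRUE
})

#' Frame: an ordered collection of sampling units
#'
#' The sampling frame is the exhaustive, ordered list of units produced by a
#' partition of a population grid — either the quadtree decomposition or a
#' uniform-grid-cell (UGC) tiling. Units are pairwise non-overlapping squares
#' (up to one cell of floor/ceil asymmetry) that jointly cover every
#' masked-in cell exactly once.
#'
#' @slot units data.frame with one row per unit: `unit_id`, `stratum_id`,
#'   `x_min`, `y_min`, `x_max`, `y_max`, `side_m`, `population`,
#'   `n_cells_valid`, `flag_overflow` (single-cell unit whose population
#'   reaches the split threshold and so could not be split further).
#' @slot method `"quadtree"` or `"ugc"`.
#' @slot provenance list recording the generating parameters and an input
#'   checksum, so selection draws made from the frame are replayable.
#'
#' @seealso [quadtreePartition()], [ugcPartition()], [frameMetrics()]
#' @exportClass Frame
setClass("Frame",
  representation(units = "data.frame", method = "character",
                 provenance = "list")
)

setValidity("Frame", function(object) {
  msg <- character()
  req <- c("unit_id", "stratum_id", "x_min", "y_min", "x_max", "y_max",
           "side_m", "population", "n_cells_valid", "flag_overflow")
  if (!all(req %in% names(object@units)))
    msg <- c(msg, paste("units must contain columns:",
                        paste(setdiff(req, names(object@units)), collapse = ", ")))
  else {
    u <- object@units
    if (anyDuplicated(u$unit_id)) msg <- c(msg, "unit_id must be unique")
    if (nrow(u) && any(u$population < 0)) msg <- c(msg, "population must be >= 0")
    if (nrow(u) && any(u$x_min >= u$x_max | u$y_min >= u$y_max))
      msg <- c(msg, "unit extents must be non-degenerate")
  }
  if (length(object@method) != 1L || !object@method %in% c("quadtree", "ugc"))
    msg <- c(msg, "method must be 'quadtree' or 'ugc'")
  if (length(msg)) msg else TRUE
})

#' StrataSet: design strata as composite geometries
#'
#' Strata are the intersection of administrative regions with population
#' types (urban, rural, IDP). Each stratum is stored as its admin-region
#' polygon plus the urban/IDP polygon sets that carve it up; membership of a
#' point follows the cell-centre rule (IDP wins over urban wins over rural),
#' so strata within a region are pairwise disjoint and union exactly to the
#' region at any raster resolution.
#'
#' @slot table data.frame: `stratum_id`, `region_id`, `pop_type`.
#' @slot geoms list parallel to `table`, each element holding the region
#'   polygon and the urban / idp polygon lists consulted by the membership
#'   predicate.
#'
#' @seealso [stratify()], [stratumMask()]
#' @exportClass StrataSet
setClass("StrataSet",
  representation(table = "data.frame", geoms = "list")
)

setValidity("StrataSet", function(object) {
  msg <- character()
  if (!all(c("stratum_id", "region_id", "pop_type") %in% names(object@table)))
    msg <- c(msg, "table must have stratum_id, region_id, pop_type")
  else if (anyDuplicated(object@table$stratum_id))
    msg <- c(msg, "stratum_id must be unique")
  if (nrow(object@table) != length(object@geoms))
    msg <- c(msg, "geoms must be parallel to table")
  if (length(msg)) msg else TRUE
})
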