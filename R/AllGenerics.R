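#' @rdname PopulationGrid-class
#' @param object,x a `PopulationGrid`
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname PopulationGrid-class
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' @rdname PopulationGrid-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname PopulationGrid-class
#' @export
setGeneric("crsId", function(x) standardGeneric("crsId"))

#' Total masked-in population of a grid
#'
#' Sum of population over masked-in cells only; masked-out cells contribute
#' nothing regardless of their stored value.
#'
#' @param x a [PopulationGrid-class]
#' @return a single number (persons)
#' @examples
#' g <- populationGrid(matrix(1, 10, 10), cellSize = 100)
#' gridTotal(g)  # 100
#' @export
setGeneric("gridTotal", function(x) standardGeneric("gridTotal"))

#' @rdname Frame-class
#' @param x a `Frame`
#' @export
setGeneric("frameUnits", function(x) standardGeneric("frameUnits"))

#' @rdname Frame-class
#' @export
setGeneric("frameMethod", function(x) standardGeneric("frameMethod"))

#' @rdname Frame-class
#' @export
setGeneric("frameProvenance", function(x) standardGeneric("frameProvenance"))

#' @rdname RegionSet-class
#' @param x a `RegionSet`
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname RegionSet-class
#' @export
setGeneric("regionRole", function(x) standardGeneric("regionRole"))

#' @rdname StrataSet-class
#' @param x a `StrataSet`
#' @export
setGeneric("strataTable", function(x) standardGeneric("strataTable"))

setMethod("gridValues", "PopulationGrid", function(x) x@values)
setMethod("gridMask", "PopulationGrid", function(x) x@mask)
setMethod("cellSize", "PopulationGrid", function(x) x@cellSize)
setMethod("crsId", "PopulationGrid", function(x) x@crsId)
setMethod("gridTotal", "PopulationGrid",
          function(x) sum(x@values[x@mask]))

setMethod("frameUnits", "Frame", function(x) x@units)
setMethod("frameMethod", "Frame", function(x) x@method)
setMethod("frameProvenance", "Frame", function(x) x@provenance)

setMethod("regionIds", "RegionSet", function(x) x@ids)
setMethod("regionRole", "RegionSet", function(x) x@role)

setMethod("strataTable", "StrataSet", function(x) x@table)

setMethod("show", "PopulationGrid", function(object) {
  cat(sprintf(
    "PopulationGrid: %d x %d cells of %g m (%s)\n",
    nrow(object@values), ncol(object@values), object@cellSize, object@crsId))
  cat(sprintf("  origin (top-left): %g, %g\n", object@originX, object@originY))
  cat(sprintf("  masked-in cells:   %d / %d\n",
              sum(object@mask), length(object@mask)))
  cat(sprintf("  total population:  %.2f\n", gridTotal(object)))
})

setMethod("show", "Frame", function(object) {
  u <- object@units
  cat(sprintf("Frame (%s): %d units, %d strata\n", object@method, nrow(u),
              length(unique(u$stratum_id))))
  if (nrow(u)) {
    cat(sprintf("  population: total %.2f, range [%.2f, %.2f]\n",
                sum(u$population), min(u$population), max(u$population)))
    cat(sprintf("  side_m:     range [%g, %g]\n", min(u$side_m), max(u$side_m)))
  }
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet (%s): %d regions\n", object@role, length(object@ids)))
})

setMethod("show", "StrataSet", function(object) {
  tab <- object@table
  cat(sprintf("StrataSet: %d strata over %d regions (%s)\n", nrow(tab),
              length(unique(tab$region_id)),
              paste(sort(unique(tab$pop_type)), collapse = "/")))
})
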