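#' Construct a PopulationGrid from a matrix
#'
#' @param values numeric matrix of per-cell population counts (row 1 is the
#'   northernmost row).
#' @param cellSize cell side in metres.
#' @param originX,originY coordinates of the top-left corner.
#' @param crsId projected-CRS identifier (free text).
#' @param mask logical matrix of study-area membership; default all `TRUE`.
#' @return a [PopulationGrid-class]
#' @export
populationGrid <- function(values, cellSize, originX = 0, originY = NULL,
                           crsId = "local-metric", mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(originY)) originY <- nrow(values) * cellSize
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  values[!mask] <- 0
  new("PopulationGrid", values = values, mask = mask,
      cellSize = as.numeric(cellSize), originX = as.numeric(originX),
      originY = as.numeric(originY), crsId = crsId)
}

#' Bounding box of a grid
#'
#' @param grid a [PopulationGrid-class]
#' @return named numeric vector `x_min`, `y_min`, `x_max`, `y_max` (metres)
#' @export
gridExtent <- function(grid) {
  cs <- grid@cellSize
  c(x_min = grid@originX,
    y_min = grid@originY - nrow(grid@values) * cs,
    x_max = grid@originX + ncol(grid@values) * cs,
    y_max = grid@originY)
}

## cell-centre coordinate vectors (x by column, y by row, row 1 = north)
cellCentres <- function(grid) {
  cs <- grid@cellSize
  list(x = grid@originX + (seq_len(ncol(grid@values)) - 0.5) * cs,
       y = grid@originY - (seq_len(nrow(grid@values)) - 0.5) * cs)
}

geographicCrs <- function(crs) {
  crs <- toupper(crs)
  grepl("4326|LONGLAT|LONG/LAT", crs) ||
    (grepl("GEOGCS", crs) && !grepl("PROJCS", crs))
}

#' Read a population grid from an ESRI ASCII grid file
#'
#' Reads the plain-text `.asc` raster format (header lines `ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`, optional
#' `NODATA_value`, then rows north to south). Nodata cells are masked out and
#' their value set to 0. A sidecar `<path>.prj` (or the `.asc` replaced by
#' `.prj`), if present, supplies the CRS string; geographic (degree-unit)
#' CRSs are rejected — reproject to a metre-unit CRS first.
#'
#' @param path path to the `.asc` file.
#' @param crsId override the CRS identifier instead of reading a sidecar.
#' @return a [PopulationGrid-class]
#' @seealso [writePopulationGrid()]
#' @export
loadPopulationGrid <- function(path, crsId = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  nHdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      nHdr <- nHdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header): ", path)
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    stop("non-square cells are not supported")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2
         else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2
         else 0
  vals <- scan(path, what = double(), skip = nHdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("raster body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- if (is.na(nodata)) matrix(TRUE, nr, nc) else m != nodata
  mask[is.na(m)] <- FALSE
  if (any(m[mask] < 0))
    stop("raster contains negative population values")
  if (is.null(crsId)) {
    prj <- c(paste0(path, ".prj"), sub("\\.[^.]+$", ".prj", path))
    prj <- prj[file.exists(prj)]
    crsId <- if (length(prj)) paste(readLines(prj[1], warn = FALSE),
                                    collapse = " ")
             else "unknown-projected"
  }
  if (geographicCrs(crsId))
    stop("grid is in a geographic (degree-unit) CRS; ",
         "project it to a metre-unit CRS before loading")
  m[!mask] <- 0
  populationGrid(m, cellSize = cs, originX = xll, originY = yll + nr * cs,
                 crsId = crsId, mask = mask)
}

#' Write a population grid to an ESRI ASCII grid file
#'
#' Masked-out cells are written as the nodata value; values are printed at
#' full double precision so that load -> write -> load round-trips values,
#' mask and geotransform bit-exactly. The CRS string goes to a `<path>.prj`
#' sidecar.
#'
#' @param grid a [PopulationGrid-class]
#' @param path output `.asc` path.
#' @param nodata nodata sentinel written for masked-out cells.
#' @return `path`, invisibly
#' @export
writePopulationGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  if (any(v[grid@mask] == nodata))
    stop("nodata sentinel collides with a data value; choose another")
  nr <- nrow(v); nc <- ncol(v)
  ext <- gridExtent(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", ext[["x_min"]]),
    sprintf("yllcorner %.17g", ext[["y_min"]]),
    sprintf("cellsize %.17g", grid@cellSize),
    sprintf("NODATA_value %.17g", nodata)), con)
  v[!grid@mask] <- nodata
  for (i in seq_len(nr))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  writeLines(grid@crsId, paste0(path, ".prj"))
  invisible(path)
}

## ---- polygons -------------------------------------------------------------

## Even-odd (ray casting) point-in-polygon over a list of rings; holes work
## automatically. `pts` is an n x 2 matrix; returns logical n.
pointInRings <- function(pts, rings) {
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
    j <- n
    for (i in seq_len(n)) {
      cross <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- xor(inside, cross)
      j <- i
    }
  }
  inside
}

#' Test points against one region of a RegionSet
#'
#' @param pts two-column matrix of x, y coordinates.
#' @param regions a [RegionSet-class]
#' @param id region id to test against.
#' @return logical vector, even-odd rule (holes supported)
#' @export
pointInRegion <- function(pts, regions, id) {
  k <- match(id, regions@ids)
  if (is.na(k)) stop("unknown region id: ", id)
  pointInRings(pts, regions@polygons[[k]])
}

ringsBBox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}

## Logical mask of grid cells whose centre falls inside the rings.
## Restricted to the rings' bounding box for speed.
cellsInRings <- function(grid, rings) {
  cc <- cellCentres(grid)
  bb <- ringsBBox(rings)
  rows <- which(cc$y >= bb[2] & cc$y <= bb[4])
  cols <- which(cc$x >= bb[1] & cc$x <= bb[3])
  out <- matrix(FALSE, nrow(grid@values), ncol(grid@values))
  if (!length(rows) || !length(cols)) return(out)
  pts <- cbind(rep(cc$x[cols], each = length(rows)),
               rep(cc$y[rows], times = length(cols)))
  out[rows, cols] <- pointInRings(pts, rings)
  out
}

#' Restrict a grid to a polygon
#'
#' Cells whose centre falls outside the polygon are masked out (their value
#' is treated as 0 in every downstream sum); the grid extent is unchanged.
#' Masking is idempotent and, for polygons whose boundary crosses no cell
#' centre, masking with a region and its complement splits the total exactly.
#'
#' @param grid a [PopulationGrid-class]
#' @param polygon a list of rings (two-column coordinate matrices), or a
#'   single two-column matrix for a simple ring, in the grid's CRS.
#' @return a [PopulationGrid-class]; all-false mask with a warning when the
#'   polygon misses the grid entirely
#' @export
maskGrid <- function(grid, polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  keep <- grid@mask & cellsInRings(grid, polygon)
  if (!any(keep))
    warning("polygon contains no masked-in cell centres; mask is empty")
  v <- grid@values
  v[!keep] <- 0
  initialize(grid, values = v, mask = keep)
}

#' Build a RegionSet from polygons
#'
#' @param ids character vector of unique region ids.
#' @param polygons list parallel to `ids`; each element either a two-column
#'   vertex matrix (simple ring) or a list of rings.
#' @param role `"admin"`, `"urban"` or `"idp"`.
#' @return a [RegionSet-class]
#' @export
regionSet <- function(ids, polygons, role = "admin") {
  polygons <- lapply(polygons, function(p) if (is.matrix(p)) list(p) else p)
  new("RegionSet", ids = as.character(ids), polygons = polygons, role = role)
}

#' Read a RegionSet from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features, each with
#' a required `region_id` property. All rings of a feature participate in
#' one even-odd membership test, so holes and multipart regions behave as
#' expected.
#'
#' @param path GeoJSON file path.
#' @param role `"admin"`, `"urban"` or `"idp"`.
#' @return a [RegionSet-class]
#' @export
readRegionSet <- function(path, role = "admin") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  ids <- character(); polys <- list()
  for (f in gj$features) {
    id <- f$properties$region_id
    if (is.null(id)) stop("feature lacks the required 'region_id' property")
    geom <- f$geometry
    ringify <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ringify),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(pg) lapply(pg, ringify)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    ids <- c(ids, as.character(id))
    polys <- c(polys, list(rings))
  }
  regionSet(ids, polys, role)
}

#' Write a RegionSet to GeoJSON
#'
#' @param regions a [RegionSet-class]
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeRegionSet <- function(regions, path) {
  feats <- lapply(seq_along(regions@ids), function(k) {
    rings <- lapply(regions@polygons[[k]], function(r) {
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(region_id = regions@ids[k], role = regions@role),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Simple closed rectangle ring (counter-clockwise).
rectRing <- function(xMin, yMin, xMax, yMax) {
  cbind(c(xMin, xMax, xMax, xMin, xMin),
        c(yMin, yMin, yMax, yMax, yMin))
}
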