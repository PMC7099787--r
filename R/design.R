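#' Stratify the study area by admin region and population type
#'
#' Crosses administrative regions with population types to build the survey
#' design strata: within each region, the IDP stratum is the part covered by
#' IDP camp polygons, the urban stratum is the urban-boundary part not in an
#' IDP camp, and the rural stratum is the remainder. Strata within a region
#' are pairwise disjoint and union exactly to the region under the
#' cell-centre membership rule (IDP over urban over rural), which is the
#' rule every raster operation in the package uses.
#'
#' Empty strata (no member cell centre on `grid` when given, otherwise no
#' probe-lattice point) are dropped. Overlapping admin regions are an error.
#'
#' @param admin a [RegionSet-class] of admin regions (role `"admin"`).
#' @param urban optionally a [RegionSet-class] of urban boundaries.
#' @param idp optionally a [RegionSet-class] of IDP camp polygons.
#' @param grid optionally a [PopulationGrid-class]; when supplied, emptiness
#'   and overlap checks are exact at cell-centre resolution.
#' @param probeN probe-lattice resolution per region bounding box used when
#'   no grid is supplied.
#' @return a [StrataSet-class]; stratum ids are `<region_id>_<pop_type>`
#' @seealso [stratumMask()], [neymanAllocate()]
#' @export
stratify <- function(admin, urban = NULL, idp = NULL, grid = NULL,
                     probeN = 96L) {
  stopifnot(is(admin, "RegionSet"))

  probePoints <- function(rings) {
    if (!is.null(grid)) {
      cc <- cellCentres(grid)
      return(cbind(rep(cc$x, each = length(cc$y)),
                   rep(cc$y, times = length(cc$x))))
    }
    bb <- ringsBBox(rings)
    xs <- seq(bb[1], bb[3], length.out = probeN)
    ys <- seq(bb[2], bb[4], length.out = probeN)
    cbind(rep(xs, each = probeN), rep(ys, times = probeN))
  }

  ## overlapping admin regions are a design error
  ids <- admin@ids
  offenders <- character()
  if (length(ids) > 1L) {
    for (a in seq_along(ids)) {
      for (b in seq_len(a - 1L)) {
        bba <- ringsBBox(admin@polygons[[a]])
        bbb <- ringsBBox(admin@polygons[[b]])
        if (bba[1] >= bbb[3] || bbb[1] >= bba[3] ||
            bba[2] >= bbb[4] || bbb[2] >= bba[4]) next
        pts <- probePoints(admin@polygons[[a]])
        both <- pointInRings(pts, admin@polygons[[a]]) &
                pointInRings(pts, admin@polygons[[b]])
        if (any(both))
          offenders <- c(offenders, paste(ids[b], ids[a], sep = " & "))
      }
    }
  }
  if (length(offenders))
    stop("admin regions overlap: ", paste(offenders, collapse = "; "))

  urbanRings <- if (is.null(urban)) list() else urban@polygons
  idpRings <- if (is.null(idp)) list() else idp@polygons
  inAny <- function(pts, ringsList) {
    hit <- rep(FALSE, nrow(pts))
    for (rg in ringsList) hit <- hit | pointInRings(pts, rg)
    hit
  }

  tab <- list(); geoms <- list()
  for (k in seq_along(ids)) {
    region <- admin@polygons[[k]]
    pts <- probePoints(region)
    inR <- pointInRings(pts, region)
    inI <- inR & inAny(pts, idpRings)
    inU <- inR & !inI & inAny(pts, urbanRings)
    inRur <- inR & !inI & !inU
    for (tp in c("urban", "rural", "idp")) {
      nonEmpty <- switch(tp, idp = any(inI), urban = any(inU),
                         rural = any(inRur))
      if (!nonEmpty) next
      tab[[length(tab) + 1L]] <- data.frame(
        stratum_id = paste(ids[k], tp, sep = "_"), region_id = ids[k],
        pop_type = tp, stringsAsFactors = FALSE)
      geoms[[length(geoms) + 1L]] <-
        list(region = region, urban = urbanRings, idp = idpRings,
             pop_type = tp)
    }
  }
  new("StrataSet",
      table = if (length(tab)) do.call(rbind, tab)
              else data.frame(stratum_id = character(),
                              region_id = character(),
                              pop_type = character(),
                              stringsAsFactors = FALSE),
      geoms = geoms)
}

#' Cell membership mask of one stratum
#'
#' Evaluates the stratum's composite geometry at the grid's cell centres.
#'
#' @param grid a [PopulationGrid-class]
#' @param strata a [StrataSet-class]
#' @param stratumId stratum to evaluate.
#' @return logical matrix aligned with the grid
#' @export
stratumMask <- function(grid, strata, stratumId) {
  k <- match(stratumId, strata@table$stratum_id)
  if (is.na(k)) stop("unknown stratum: ", stratumId)
  gm <- strata@geoms[[k]]
  inR <- cellsInRings(grid, gm$region)
  inAnyM <- function(ringsList) {
    hit <- matrix(FALSE, nrow(grid@values), ncol(grid@values))
    for (rg in ringsList) hit <- hit | cellsInRings(grid, rg)
    hit
  }
  inI <- inR & inAnyM(gm$idp)
  switch(gm$pop_type,
         idp = inI,
         urban = inR & !inI & inAnyM(gm$urban),
         rural = inR & !inI & !(inAnyM(gm$urban)))
}

#' Restrict a grid to one stratum
#'
#' Convenience wrapper: masks the grid to the stratum's member cells.
#'
#' @inheritParams stratumMask
#' @return a [PopulationGrid-class]
#' @export
maskGridToStratum <- function(grid, strata, stratumId) {
  keep <- grid@mask & stratumMask(grid, strata, stratumId)
  v <- grid@values
  v[!keep] <- 0
  initialize(grid, values = v, mask = keep)
}

#' Neyman optimal allocation of PSUs across strata
#'
#' Allocates a total sample of `nTotal` PSUs across strata in proportion to
#' `N_h * S_h` (stratum population times within-stratum standard deviation
#' of the survey variable, e.g. consumption), which minimises the variance
#' of the stratified estimator for a fixed total sample size:
#' `n_h = n * N_h S_h / sum_h(N_h S_h)`. Fractional allocations are
#' integerised by largest remainder (ties broken by stratum order), then a
#' minimum of `minPerStratum` PSUs per stratum (default 2, needed for
#' stratum-level variance estimation) is enforced by raising deficient
#' strata to the floor and re-allocating the excess proportionally among the
#' rest. Deliberately oversampled strata are expressed as fixed `override`
#' allocations honoured exactly.
#'
#' @param strata data.frame with columns `stratum_id`, `N_h`, `S_h` and
#'   optionally `override` (`NA` = allocate by Neyman).
#' @param nTotal total number of PSUs to allocate; must cover the overrides
#'   plus the minimum floors.
#' @param minPerStratum minimum PSUs per non-override stratum.
#' @return data.frame `stratum_id`, `n_h` in the input stratum order, with
#'   `sum(n_h) == nTotal`
#' @examples
#' neymanAllocate(data.frame(stratum_id = c("a", "b"),
#'                           N_h = c(100, 300), S_h = c(2, 1)),
#'                nTotal = 10, minPerStratum = 0)
#' @export
neymanAllocate <- function(strata, nTotal, minPerStratum = 2L) {
  stopifnot(all(c("stratum_id", "N_h", "S_h") %in% names(strata)),
            all(strata$N_h >= 0), all(strata$S_h >= 0), nTotal >= 0)
  n <- nrow(strata)
  override <- if ("override" %in% names(strata)) strata$override
              else rep(NA_real_, n)
  fixed <- !is.na(override)
  free <- which(!fixed)
  rem <- nTotal - sum(override[fixed])
  if (rem < minPerStratum * length(free))
    stop("nTotal (", nTotal, ") cannot cover ", minPerStratum,
         " PSUs in each of ", length(free),
         " strata plus the fixed overrides (", sum(override[fixed]), ")")

  largestRemainder <- function(weights, total) {
    if (total == 0L || !length(weights)) return(rep(0L, length(weights)))
    raw <- total * weights / sum(weights)
    base <- floor(raw)
    extra <- as.integer(round(total - sum(base)))
    alloc <- as.integer(base)
    if (extra > 0L) {
      ord <- order(-(raw - base), seq_along(raw))   # ties by stratum order
      alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1L
    }
    alloc
  }

  w <- strata$N_h[free] * strata$S_h[free]
  if (length(free) && all(w == 0)) {
    warning("all N_h * S_h are zero among non-override strata; ",
            "falling back to equal shares")
    w <- rep(1, length(free))
  }
  nh <- rep(0L, n)
  nh[fixed] <- as.integer(round(override[fixed]))

  pool <- free                       # strata still allocated proportionally
  budget <- as.integer(round(rem))
  repeat {
    alloc <- largestRemainder(w[match(pool, free)], budget)
    low <- alloc < minPerStratum
    if (!any(low)) { nh[pool] <- alloc; break }
    floored <- pool[low]
    nh[floored] <- minPerStratum
    budget <- budget - minPerStratum * length(floored)
    pool <- pool[!low]
    if (!length(pool)) break
  }
  stopifnot(sum(nh) == nTotal)
  data.frame(stratum_id = strata$stratum_id, n_h = nh,
             stringsAsFactors = FALSE)
}

#' Read / write a strata specification table
#'
#' CSV columns: `stratum_id`, `region_id`, `pop_type`, `N_h`, `S_h`,
#' `override` (empty = Neyman-allocated).
#'
#' @param path CSV path.
#' @return data.frame
#' @export
readStrataTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum_id", "N_h", "S_h")
  if (!all(need %in% names(tab)))
    stop("strata table must have columns: ", paste(need, collapse = ", "))
  if (!"override" %in% names(tab)) tab$override <- NA_real_
  tab
}
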