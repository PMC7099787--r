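#' Read a flat key:value run configuration
#'
#' One `key: value` pair per line; `#` starts a comment; values are numbers,
#' `true`/`false`, comma-separated numeric lists, or strings. Per-stratum
#' oversampling overrides are written `override.<stratum_id>: <n>`. All of
#' the design parameters default to the values of the Somalia design: 500 m
#' smoothing sigma, population threshold 3500, side cap 3000 m, 20%
#' replacement sample and a minimum of two PSUs per stratum.
#'
#' @param path config file path.
#' @return named list of class `"RunConfig"`
#' @seealso [runPipeline()]
#' @export
readRunConfig <- function(path) {
  defaults <- list(
    synthetic = FALSE, raster = NULL, admin = NULL, urban = NULL, idp = NULL,
    n_rows = 512L, n_cols = 512L, cell_size_m = 100, n_clusters = 8L,
    background_density = 0.02, n_regions = 4L, urban_radius_m = 2000,
    sigma_m = 500, truncation_sigmas = 4, pop_max = 3500, side_max_m = 3000,
    ugc_sides_m = c(1000, 3000), n_total = 6384, min_per_stratum = 2L,
    replacement_rate = 0.2, hh_size = 5.4, seed = 1L, out_dir = "pipeline_out",
    strata_csv = NULL)
  cfg <- defaults
  cfg$overrides <- list()
  for (ln in readLines(path, warn = FALSE)) {
    ln <- sub("#.*$", "", ln)
    if (!nzchar(trimws(ln))) next
    kv <- regmatches(ln, regexec("^\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    key <- kv[2]; val <- kv[3]
    parsed <- if (grepl("^(true|false)$", tolower(val)))
      tolower(val) == "true"
    else if (grepl("^-?[0-9.eE+,-]+$", val) &&
             !anyNA(suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))))
      as.numeric(strsplit(val, ",")[[1]])
    else val
    if (startsWith(key, "override.")) {
      cfg$overrides[[sub("^override\\.", "", key)]] <- parsed
    } else cfg[[key]] <- parsed
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full frame-construction and sample-design pipeline
#'
#' Executes the end-to-end workflow in order: Gaussian smoothing of the
#' population surface, stratification by admin region and population type,
#' quadtree frame construction per stratum, Neyman allocation of PSUs across
#' strata, systematic PPS selection with a replacement list, household
#' design weights, and frame/weight diagnostics. Every intermediate artifact
#' is written to `out_dir` as plain text (ASCII grid, GeoJSON, CSV) together
#' with a JSON manifest recording parameters, seeds, input checksums and row
#' counts; rerunning with the same config reproduces byte-identical CSVs.
#'
#' Inputs come either from files named in the config (`raster`, `admin`,
#' `urban`, `idp`) or, with `synthetic: true`, from the built-in generator.
#' A failure in any stage aborts with the stage name.
#'
#' @param config a [readRunConfig()] list, or a path to a config file.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`)
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- unclass(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = cfg[setdiff(names(cfg), "overrides")],
                   overrides = cfg$overrides, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(stage = stage, status = "complete"),
                                   list(...))
  }
  inStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## inputs -----------------------------------------------------------------
  if (isTRUE(cfg$synthetic)) {
    spec <- syntheticSpec(nRows = cfg$n_rows, nCols = cfg$n_cols,
                          cellSize = cfg$cell_size_m,
                          nClusters = cfg$n_clusters,
                          backgroundDensity = cfg$background_density,
                          nRegions = cfg$n_regions,
                          urbanRadiusM = cfg$urban_radius_m,
                          seed = cfg$seed)
    grid <- makePopulationRaster(spec)
    bnd <- makeBoundaries(spec)
    admin <- bnd$admin; urban <- bnd$urban; idp <- bnd$idp
    manifest$input_checksum <- gridChecksum(grid)
  } else {
    if (is.null(cfg$raster)) stop("config needs 'raster' or 'synthetic: true'")
    grid <- loadPopulationGrid(cfg$raster)
    admin <- if (!is.null(cfg$admin)) readRegionSet(cfg$admin, "admin")
             else regionSet("R01", list(do.call(rectRing,
                            as.list(unname(gridExtent(grid))[c(1, 2, 3, 4)]))),
                            "admin")
    urban <- if (!is.null(cfg$urban)) readRegionSet(cfg$urban, "urban")
    idp <- if (!is.null(cfg$idp)) readRegionSet(cfg$idp, "idp")
    manifest$input_checksum <- unname(tools::md5sum(cfg$raster))
  }

  ## 1. smooth --------------------------------------------------------------
  smoothed <- inStage("smooth",
    gaussianSmooth(grid, sigmaM = cfg$sigma_m,
                   truncationSigmas = cfg$truncation_sigmas))
  writePopulationGrid(smoothed, file.path(cfg$out_dir, "pop_smoothed.asc"))
  note("smooth", sigma_m = cfg$sigma_m, total_population = gridTotal(smoothed))

  ## 2. stratify ------------------------------------------------------------
  strata <- inStage("stratify", stratify(admin, urban, idp, grid = smoothed))
  stab <- strataTable(strata)
  note("stratify", n_strata = nrow(stab))

  ## 3. frame per stratum ---------------------------------------------------
  frames <- inStage("frame", lapply(stab$stratum_id, function(sid)
    quadtreePartition(maskGridToStratum(smoothed, strata, sid),
                      popMax = cfg$pop_max, sideMaxM = cfg$side_max_m,
                      stratumId = sid)))
  frame <- combineFrames(frames)
  writeFrameCSV(frame, file.path(cfg$out_dir, "frame_quadtree.csv"))
  writeFrameGeoJSON(frame, file.path(cfg$out_dir, "frame_quadtree.geojson"))
  note("frame", n_units = nrow(frameUnits(frame)),
       total_population = sum(frameUnits(frame)$population))

  ## 4. allocate ------------------------------------------------------------
  units <- frameUnits(frame)
  Nh <- tapply(units$population, units$stratum_id, sum)[stab$stratum_id]
  Nh[is.na(Nh)] <- 0
  stab$N_h <- as.numeric(Nh)
  stab$S_h <- 1
  stab$override <- NA_real_
  if (!is.null(cfg$strata_csv)) {
    ext <- readStrataTable(cfg$strata_csv)
    i <- match(stab$stratum_id, ext$stratum_id)
    stab$S_h[!is.na(i)] <- ext$S_h[i[!is.na(i)]]
    if ("N_h" %in% names(ext)) stab$N_h[!is.na(i)] <- ext$N_h[i[!is.na(i)]]
    stab$override[!is.na(i)] <- ext$override[i[!is.na(i)]]
  }
  for (sid in names(cfg$overrides))
    stab$override[stab$stratum_id == sid] <- cfg$overrides[[sid]]
  alloc <- inStage("allocate",
    neymanAllocate(stab, nTotal = cfg$n_total,
                   minPerStratum = cfg$min_per_stratum))
  utils::write.csv(stab, file.path(cfg$out_dir, "strata.csv"),
                   row.names = FALSE)
  utils::write.csv(alloc, file.path(cfg$out_dir, "allocation.csv"),
                   row.names = FALSE)
  note("allocate", n_total = sum(alloc$n_h))

  ## 5. sample --------------------------------------------------------------
  selections <- inStage("sample", {
    recs <- lapply(seq_len(nrow(stab)), function(h) {
      sid <- stab$stratum_id[h]
      kh <- alloc$n_h[alloc$stratum_id == sid]
      su <- units[units$stratum_id == sid & units$population > 0, ,
                  drop = FALSE]
      if (kh < 1L || !nrow(su)) return(NULL)
      sf <- new("Frame", units = su, method = frame@method,
                provenance = frame@provenance)
      main <- ppsSystematic(sf, k = kh, seed = splitSeed(cfg$seed, h))
      repl <- replacementSample(sf, k = kh, rate = cfg$replacement_rate,
                                seed = splitSeed(cfg$seed, h))
      rbind(main, repl)
    })
    do.call(rbind, recs)
  })
  writeSelectionCSV(selections, file.path(cfg$out_dir, "selections.csv"))
  note("sample", n_records = nrow(selections),
       n_selections = sum(selections$multiplicity[!selections$is_replacement]))

  ## 6. weights -------------------------------------------------------------
  weightsTab <- inStage("weights", {
    main <- selections[!selections$is_replacement, , drop = FALSE]
    rows <- lapply(seq_len(nrow(main)), function(r) {
      uid <- main$unit_id[r]
      sid <- main$stratum_id[r]
      popI <- units$population[units$unit_id == uid]
      NhS <- stab$N_h[stab$stratum_id == sid]
      kh <- alloc$n_h[alloc$stratum_id == sid]
      p1 <- psuProbability(popI, NhS, kh)
      hh <- max(1L, as.integer(round(popI / cfg$hh_size)))
      plan <- ssuPlan(hh, main$multiplicity[r])
      hhInPsu <- max(hh, plan$n_ssu)
      w <- householdWeight(p1$P1, plan, hhInPsu)
      data.frame(
        household_id = sprintf("%s/hh%02d", uid, seq_len(plan$n_households)),
        unit_id = uid, stratum_id = sid, P1 = w$P1, P2 = w$P2,
        weight = w$weight,
        flag_certainty = p1$certainty, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(weightsTab, file.path(cfg$out_dir, "weights.csv"),
                   row.names = FALSE)
  note("weights", n_households = nrow(weightsTab))

  ## 7. diagnostics ---------------------------------------------------------
  diag <- inStage("diagnostics", {
    qm <- frameMetrics(frame, admin)
    qm$frame <- "quadtree"
    ugcM <- lapply(cfg$ugc_sides_m, function(s) {
      m <- frameMetrics(ugcPartition(smoothed, s), admin)
      m$frame <- sprintf("ugc_%dm", as.integer(s))
      m
    })
    metrics <- rbind(qm, do.call(rbind, ugcM))
    wd <- weightDiagnostics(weightsTab$weight)
    list(metrics = metrics, weight = wd)
  })
  utils::write.csv(diag$metrics, file.path(cfg$out_dir, "frame_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(diag$weight),
                   file.path(cfg$out_dir, "weight_diagnostics.csv"),
                   row.names = FALSE)
  note("diagnostics", deff_w = diag$weight$deff_w,
       quadtree_national_cv = diag$metrics$cv[diag$metrics$scope_id ==
                                              "national" &
                                              diag$metrics$frame ==
                                              "quadtree"][1])

  manifest$stages <- unname(manifest$stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
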