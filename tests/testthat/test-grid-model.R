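test_that("ASCII-grid raster round-trips values, mask and geotransform", {
  set.seed(4)
  v <- matrix(runif(30, 0, 10), 5, 6)
  mask <- matrix(runif(30) < 0.8, 5, 6)
  mask[1, 1] <- TRUE
  g <- populationGrid(v, cellSize = 250, originX = 10000, originY = 99999.5,
                      crsId = "EPSG:32638", mask = mask)
  path <- withr::local_tempfile(fileext = ".asc")
  writePopulationGrid(g, path)
  g2 <- loadPopulationGrid(path)
  expect_identical(gridValues(g2), gridValues(g))
  expect_identical(gridMask(g2), gridMask(g))
  expect_identical(cellSize(g2), cellSize(g))
  expect_identical(gridExtent(g2), gridExtent(g))
  expect_identical(crsId(g2), "EPSG:32638")
})

test_that("loading applies the nodata and non-negativity rules", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 100", "NODATA_value -9999",
               "4 -9999", "0 1"), path)
  g <- loadPopulationGrid(path, crsId = "local")
  expect_equal(gridTotal(g), 5)
  expect_equal(sum(gridMask(g)), 3L)
  expect_equal(gridValues(g)[1, 2], 0)  # nodata stored as 0

  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 100", "1 1", "1 -1"), path)
  expect_error(loadPopulationGrid(path, crsId = "local"), "negative")
})

test_that("geographic CRSs are rejected with a pre-projection message", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 1", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "7"), path)
  expect_error(loadPopulationGrid(path, crsId = "EPSG:4326"),
               "metre-unit CRS")
  expect_equal(gridTotal(loadPopulationGrid(path, crsId = "EPSG:32638")), 7)
})

test_that("maskGrid keeps cells by centre and is idempotent", {
  g <- populationGrid(matrix(1, 4, 4), cellSize = 100)
  left <- rectRing(0, 0, 200, 400)
  gm <- maskGrid(g, left)
  expect_equal(gridTotal(gm), 8)                     # centres of columns 1-2
  expect_identical(gridMask(maskGrid(gm, left)), gridMask(gm))

  expect_equal(gridTotal(maskGrid(g, rectRing(-500, -500, 500, 500))), 16)
  expect_warning(gd <- maskGrid(g, rectRing(9000, 9000, 9100, 9100)),
                 "empty")
  expect_equal(gridTotal(gd), 0)
})

test_that("masking with a region and its complement partitions the total", {
  set.seed(9)
  g <- populationGrid(matrix(rpois(64, 5), 8, 8), cellSize = 100)
  a <- rectRing(0, 0, 300, 800)        # boundary x = 300 hits no centre
  b <- rectRing(300, 0, 800, 800)
  expect_equal(gridTotal(maskGrid(g, a)) + gridTotal(maskGrid(g, b)),
               gridTotal(g))
})

test_that("gridTotal sums masked-in values only", {
  expect_equal(gridTotal(populationGrid(matrix(1, 10, 10), 100)), 100)
  expect_equal(gridTotal(populationGrid(matrix(0, 3, 3), 100)), 0)
  expect_equal(gridTotal(populationGrid(matrix(c(2.5, 7.5), 1, 2), 100)), 10)
  m <- matrix(c(TRUE, FALSE), 1, 2)
  expect_equal(gridTotal(populationGrid(matrix(c(2.5, 7.5), 1, 2), 100,
                                        mask = m)), 2.5)
})

test_that("PopulationGrid validity rejects malformed objects", {
  expect_error(populationGrid(matrix(-1, 2, 2), 100), "finite and >= 0")
  expect_error(populationGrid(matrix(1, 2, 2), -5), "positive")
})

test_that("RegionSets round-trip through GeoJSON with holes intact", {
  outer <- rectRing(0, 0, 1000, 1000)
  hole <- rectRing(400, 400, 600, 600)
  rs <- regionSet(c("A", "B"),
                  list(list(outer, hole), rectRing(2000, 0, 3000, 500)),
                  role = "admin")
  path <- withr::local_tempfile(fileext = ".geojson")
  writeRegionSet(rs, path)
  rs2 <- readRegionSet(path, role = "admin")
  expect_identical(regionIds(rs2), c("A", "B"))
  pts <- rbind(c(500, 500), c(200, 200), c(2500, 250))
  expect_identical(pointInRegion(pts, rs2, "A"), c(FALSE, TRUE, FALSE))
  expect_identical(pointInRegion(pts, rs2, "B"), c(FALSE, FALSE, TRUE))
  expect_error(regionSet(c("A", "A"), list(outer, outer)), "unique")
})
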