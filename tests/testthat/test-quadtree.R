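test_that("an unsplittable overloaded cell is emitted with a flag", {
  g <- populationGrid(matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE), 100)
  f <- quadtreePartition(g, popMax = 5, sideMaxM = 3000)
  u <- frameUnits(f)
  expect_equal(nrow(u), 4L)
  expect_setequal(u$population, c(10, 0, 0, 0))
  expect_identical(u$flag_overflow, u$population >= 5)
  expect_true(all(u$side_m == 100))
})

test_that("a grid already satisfying both constraints is one unit", {
  g <- populationGrid(matrix(1, 2, 2), 100)
  u <- frameUnits(quadtreePartition(g, popMax = 5, sideMaxM = 3000))
  expect_equal(nrow(u), 1L)
  expect_equal(u$population, 4)
})

test_that("population rule splits a uniform 8x8 into four 4x4 quadrants", {
  g <- populationGrid(matrix(1, 8, 8), 100)
  u <- frameUnits(quadtreePartition(g, popMax = 20, sideMaxM = 10000))
  expect_equal(nrow(u), 4L)
  expect_true(all(u$population == 16))
  expect_true(all(u$h_cells == 4 & u$w_cells == 4))
  ## NW, NE, SW, SE emission order
  expect_identical(u$unit_id,
                   c("q0_0_4x4", "q0_4_4x4", "q4_0_4x4", "q4_4_4x4"))
})

test_that("the area rule alone forces splitting of empty space", {
  g <- populationGrid(matrix(0, 4, 4), 100)
  u <- frameUnits(quadtreePartition(g, popMax = 3500, sideMaxM = 200))
  expect_equal(nrow(u), 4L)
  expect_true(all(u$population == 0))
  expect_true(all(u$side_m == 200))
})

test_that("leaf populations sum exactly to the grid total", {
  for (seed in 1:30) {
    g <- randomGrid(seed, maxDim = 48, withMask = TRUE)
    f <- quadtreePartition(g, popMax = sample(c(5, 50, 500), 1),
                           sideMaxM = sample(c(400, 1600, 6400), 1))
    expect_equal(sum(frameUnits(f)$population), gridTotal(g),
                 tolerance = 1e-12)
  }
})

test_that("output matches the independent brute-force recursion", {
  for (seed in 1:20) {
    g <- randomGrid(seed + 500, maxDim = 64, withMask = TRUE)
    popMax <- sample(c(4, 30, 300), 1)
    sideMaxM <- sample(c(300, 1500, 12800), 1)
    f <- frameUnits(quadtreePartition(g, popMax, sideMaxM))
    o <- oracleQuadtree(gridValues(g), gridMask(g), cellSize(g),
                        popMax, sideMaxM)
    cols <- c("row0", "col0", "h_cells", "w_cells", "population",
              "n_cells_valid", "flag_overflow")
    expect_equal(nrow(f), nrow(o))
    for (cl in cols)
      expect_equal(unname(f[[cl]]), unname(o[[cl]]),
                   label = paste("column", cl, "seed", seed))
  }
})

test_that("lowering the population threshold never merges units", {
  for (seed in 1:10) {
    g <- randomGrid(seed + 900, maxDim = 32)
    nHigh <- nrow(frameUnits(quadtreePartition(g, popMax = 100,
                                               sideMaxM = 12800)))
    nLow <- nrow(frameUnits(quadtreePartition(g, popMax = 20,
                                              sideMaxM = 12800)))
    expect_gte(nLow, nHigh)
  }
})

test_that("the decomposition is deterministic", {
  g <- randomGrid(77, maxDim = 40, withMask = TRUE)
  f1 <- quadtreePartition(g, 50, 1600)
  f2 <- quadtreePartition(g, 50, 1600)
  expect_identical(frameUnits(f1), frameUnits(f2))
})

test_that("units never overlap and cover each masked-in cell once", {
  g <- randomGrid(31, maxDim = 20, withMask = TRUE)
  u <- frameUnits(quadtreePartition(g, 30, 800))
  cover <- matrix(0L, nrow(gridValues(g)), ncol(gridValues(g)))
  for (i in seq_len(nrow(u))) {
    rr <- (u$row0[i] + 1):(u$row0[i] + u$h_cells[i])
    cc <- (u$col0[i] + 1):(u$col0[i] + u$w_cells[i])
    rr <- rr[rr <= nrow(cover)]; cc <- cc[cc <= ncol(cover)]
    cover[rr, cc] <- cover[rr, cc] + 1L
  }
  expect_true(all(cover <= 1L))
  expect_true(all(cover[gridMask(g)] == 1L))
})

test_that("an empty mask yields an empty frame", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE
  g <- populationGrid(matrix(0, 4, 4), 100, mask = m)
  g@mask[1, 1] <- FALSE  # fully empty, bypassing the constructor guard
  expect_equal(nrow(frameUnits(quadtreePartition(g, 10, 800))), 0L)
})
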