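mkDisk <- function(cx, cy, r, n = 32) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

test_that("a region with one urban disk splits into two exhaustive strata", {
  g <- populationGrid(matrix(1, 40, 40), 100)   # 4 km square
  admin <- regionSet("R1", list(rectRing(0, 0, 4000, 4000)))
  urban <- regionSet("U1", list(mkDisk(2000, 2000, 800)), "urban")
  st <- stratify(admin, urban, grid = g)
  tab <- strataTable(st)
  expect_setequal(tab$stratum_id, c("R1_urban", "R1_rural"))
  mU <- stratumMask(g, st, "R1_urban")
  mR <- stratumMask(g, st, "R1_rural")
  expect_false(any(mU & mR))                      # disjoint
  expect_equal(sum(mU) + sum(mR), 40 * 40)        # union = region
})

test_that("an urban polygon outside every region leaves only rural strata", {
  g <- populationGrid(matrix(1, 20, 20), 100)
  admin <- regionSet("R1", list(rectRing(0, 0, 2000, 2000)))
  urban <- regionSet("U1", list(mkDisk(9000, 9000, 300)), "urban")
  st <- stratify(admin, urban, grid = g)
  expect_identical(strataTable(st)$stratum_id, "R1_rural")
  expect_equal(sum(stratumMask(g, st, "R1_rural")), 400)
})

test_that("two regions with urban touching only one give three strata", {
  g <- populationGrid(matrix(1, 20, 40), 100)    # 4 km x 2 km
  admin <- regionSet(c("R1", "R2"),
                     list(rectRing(0, 0, 2000, 2000),
                          rectRing(2000, 0, 4000, 2000)))
  urban <- regionSet("U1", list(mkDisk(1000, 1000, 500)), "urban")
  st <- stratify(admin, urban, grid = g)
  expect_setequal(strataTable(st)$stratum_id,
                  c("R1_urban", "R1_rural", "R2_rural"))
})

test_that("IDP camps trump urban boundaries in stratum membership", {
  g <- populationGrid(matrix(1, 40, 40), 100)
  admin <- regionSet("R1", list(rectRing(0, 0, 4000, 4000)))
  urban <- regionSet("U1", list(mkDisk(2000, 2000, 1000)), "urban")
  idp <- regionSet("I1", list(rectRing(1800, 1800, 2200, 2200)), "idp")
  st <- stratify(admin, urban, idp, grid = g)
  expect_setequal(strataTable(st)$pop_type, c("urban", "rural", "idp"))
  masks <- lapply(strataTable(st)$stratum_id,
                  function(s) stratumMask(g, st, s))
  expect_equal(Reduce(`+`, lapply(masks, sum)), 1600)   # exact partition
  expect_true(all(Reduce(`+`, masks) <= 1))
  ## the camp area belongs to the idp stratum, not urban
  mI <- stratumMask(g, st, "R1_idp")
  expect_true(mI[20, 20])
})

test_that("overlapping admin regions are rejected with the offenders named", {
  admin <- regionSet(c("A", "B"),
                     list(rectRing(0, 0, 1000, 1000),
                          rectRing(500, 500, 1500, 1500)))
  expect_error(stratify(admin), "overlap.*A & B")
})

test_that("Neyman allocation shares the sample by N_h * S_h", {
  out <- neymanAllocate(data.frame(stratum_id = c("a", "b"),
                                   N_h = c(100, 300), S_h = c(2, 1)),
                        nTotal = 10, minPerStratum = 0)
  expect_equal(out$n_h, c(4L, 6L))
  one <- neymanAllocate(data.frame(stratum_id = "only", N_h = 50, S_h = 3),
                        nTotal = 7, minPerStratum = 2)
  expect_equal(one$n_h, 7L)
})

test_that("the per-stratum floor lifts zero-variability strata to minimum", {
  out <- neymanAllocate(data.frame(stratum_id = c("a", "b"),
                                   N_h = c(1000, 1000), S_h = c(0, 1)),
                        nTotal = 10, minPerStratum = 2)
  expect_equal(out$n_h, c(2L, 8L))
  expect_equal(sum(out$n_h), 10L)
})

test_that("allocation is invariant to rescaling all S_h", {
  st <- data.frame(stratum_id = letters[1:4], N_h = c(10, 400, 900, 2000),
                   S_h = c(3, 1, 0.5, 2))
  a1 <- neymanAllocate(st, 100, 2)
  st$S_h <- st$S_h * 17
  expect_identical(neymanAllocate(st, 100, 2), a1)
  expect_equal(sum(a1$n_h), 100L)
  expect_true(all(a1$n_h >= 2L))
})

test_that("equal N_h * S_h allocates equally up to integerisation", {
  st <- data.frame(stratum_id = letters[1:3], N_h = c(100, 200, 400),
                   S_h = c(4, 2, 1))
  out <- neymanAllocate(st, 10, 0)
  expect_lte(diff(range(out$n_h)), 1L)
  expect_equal(sum(out$n_h), 10L)
})

test_that("overrides are honoured exactly and degenerate inputs handled", {
  st <- data.frame(stratum_id = c("boost", "x", "y"),
                   N_h = c(10, 500, 500), S_h = c(1, 1, 1),
                   override = c(20, NA, NA))
  out <- neymanAllocate(st, 30, 2)
  expect_equal(out$n_h[out$stratum_id == "boost"], 20L)
  expect_equal(sum(out$n_h), 30L)

  expect_error(neymanAllocate(data.frame(stratum_id = c("a", "b"),
                                         N_h = c(1, 1), S_h = c(1, 1)),
                              nTotal = 3, minPerStratum = 2),
               "cannot cover")
  expect_warning(
    z <- neymanAllocate(data.frame(stratum_id = c("a", "b"),
                                   N_h = c(0, 0), S_h = c(1, 1)),
                        nTotal = 6, minPerStratum = 2),
    "equal shares")
  expect_equal(z$n_h, c(3L, 3L))
})
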