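equalFrame <- function(pops, cellSize = 100) {
  g <- populationGrid(matrix(pops, 1, length(pops)), cellSize)
  ugcPartition(g, cellSize)
}

test_that("systematic PPS walks the cumulative totals from the start", {
  f <- equalFrame(c(10, 10, 10, 10))
  sel <- ppsSystematic(f, k = 2, seed = 1, randomStart = 5)
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$unit_id, frameUnits(f)$unit_id[c(1, 3)])
  expect_true(all(sel$multiplicity == 1L))
  expect_true(all(sel$expected_hits == 0.5))
  expect_equal(sel$random_start, c(5, 5))
})

test_that("a single unit absorbs every hit", {
  f <- equalFrame(42)
  sel <- ppsSystematic(f, k = 3, seed = 9)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$multiplicity, 3L)
})

test_that("multiplicities always sum to k and certainty units always hit", {
  f <- equalFrame(c(5, 120, 8, 3, 60))   # unit 2 exceeds I = 196/4 = 49
  for (seed in 1:50) {
    sel <- ppsSystematic(f, k = 4, seed = seed)
    expect_equal(sum(sel$multiplicity), 4L)
    expect_true(frameUnits(f)$unit_id[2] %in% sel$unit_id)
  }
})

test_that("zero-population units are never selected", {
  f <- equalFrame(c(0, 10, 0, 30))
  for (seed in 1:20) {
    sel <- ppsSystematic(f, k = 3, seed = seed)
    expect_true(all(sel$unit_id %in% frameUnits(f)$unit_id[c(2, 4)]))
  }
})

test_that("selection frequency tracks k * p_i over seeded draws", {
  f <- equalFrame(c(1, 3))
  hits <- vapply(1:2000, function(s) {
    sel <- ppsSystematic(f, k = 1, seed = s)
    as.integer(sel$unit_id == frameUnits(f)$unit_id[1])
  }, integer(1))
  p <- mean(hits)
  se <- sd(hits) / sqrt(length(hits))
  expect_lt(abs(p - 0.25), 3 * se + 1e-12)
})

test_that("the draw is reproducible by seed and varies across seeds", {
  f <- equalFrame(c(7, 1, 9, 2, 6))
  s1 <- ppsSystematic(f, k = 2, seed = 11)
  s2 <- ppsSystematic(f, k = 2, seed = 11)
  expect_identical(s1, s2)
  starts <- vapply(1:30, function(s)
    ppsSystematic(f, k = 2, seed = s)$random_start[1], numeric(1))
  expect_gt(length(unique(starts)), 25)
})

test_that("replacement list sizes follow ceiling(rate * k)", {
  f <- equalFrame(rep(10, 30))
  expect_equal(sum(replacementSample(f, k = 10, rate = 0.2,
                                     seed = 3)$multiplicity), 2L)
  expect_equal(sum(replacementSample(f, k = 3, rate = 0.2,
                                     seed = 3)$multiplicity), 1L)
  expect_equal(nrow(replacementSample(f, k = 5, rate = 0, seed = 3)), 0L)
  expect_true(all(replacementSample(f, k = 10, seed = 3)$is_replacement))
})

test_that("replacement draws come from an independent stream", {
  g <- populationGrid(matrix(runif(100, 1, 20), 10, 10), 100)
  f <- ugcPartition(g, 100)
  differs <- vapply(0:99, function(s) {
    main <- ppsSystematic(f, k = 5, seed = s)
    repl <- replacementSample(f, k = 5, rate = 0.2, seed = s)
    !isTRUE(all.equal(main$random_start[1], repl$random_start[1]))
  }, logical(1))
  expect_gte(sum(differs), 95L)
})

test_that("household selection follows the two-stage uniform tree", {
  one <- selectHousehold(1, list(1), seed = 5)
  expect_equal(one$probability, 1)
  expect_equal(one$structure_index, 1L)

  ## SSU with structures of {1, 3} households: P(hh) = {1/2, 1/6, 1/6, 1/6}
  draws <- t(vapply(1:4000, function(s) {
    r <- selectHousehold(2, list(c(1, 3)), seed = s)
    c(r$structure_index, r$household_index, r$probability)
  }, numeric(3)))
  expect_setequal(unique(draws[, 3]), c(1 / 2, 1 / 6))
  pStr1 <- mean(draws[, 1] == 1)
  expect_lt(abs(pStr1 - 0.5), 4 * sqrt(0.25 / 4000))
  for (h in 1:3) {
    ph <- mean(draws[, 1] == 2 & draws[, 2] == h)
    expect_lt(abs(ph - 1 / 6), 4 * sqrt((1 / 6) * (5 / 6) / 4000))
  }

  twelve <- selectHousehold(rep(10, 12), rep(list(rep(2, 10)), 12), seed = 1)
  expect_equal(nrow(twelve), 12L)

  empty <- selectHousehold(c(0, 3), list(integer(0), c(1, 1, 1)), seed = 2)
  expect_true(empty$needs_replacement[1])
  expect_false(empty$needs_replacement[2])
})
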