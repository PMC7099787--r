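## Independent brute-force reference for the quadtree decomposition: plain
## recursion over the raw matrix with sum() block sums, no integral image,
## no accumulator machinery. Returns leaves in emission order.
oracleQuadtree <- function(values, mask, cellSize, popMax, sideMaxM,
                          minSideCells = 1L) {
  smc <- max(1L, floor(sideMaxM / cellSize))
  nr <- nrow(values); nc <- ncol(values)
  maxDim <- max(nr, nc)
  root <- if (smc >= maxDim) {
    s <- 1L
    while (s < maxDim) s <- s * 2L
    s
  } else {
    s <- smc
    while (s < maxDim) s <- s * 2L
    s
  }
  leaves <- list()
  rec <- function(r0, c0, h, w) {
    rr <- (r0 + 1):(r0 + h); rr <- rr[rr <= nr]
    cc <- (c0 + 1):(c0 + w); cc <- cc[cc <= nc]
    if (!length(rr) || !length(cc)) return()
    mk <- mask[rr, cc, drop = FALSE]
    if (!any(mk)) return()
    pop <- sum(values[rr, cc, drop = FALSE][mk])
    side <- max(h, w)
    if (side > smc || (pop >= popMax && side > minSideCells)) {
      hs <- if (h > 1L) c(h %/% 2L, h - h %/% 2L) else h
      ws <- if (w > 1L) c(w %/% 2L, w - w %/% 2L) else w
      ro <- c(0L, hs[1])[seq_along(hs)]
      co <- c(0L, ws[1])[seq_along(ws)]
      for (i in seq_along(hs))
        for (j in seq_along(ws))
          rec(r0 + ro[i], c0 + co[j], hs[i], ws[j])
    } else {
      leaves[[length(leaves) + 1L]] <<- data.frame(
        row0 = as.integer(r0), col0 = as.integer(c0),
        h_cells = as.integer(h), w_cells = as.integer(w),
        population = pop, n_cells_valid = sum(mk),
        flag_overflow = pop >= popMax)
    }
  }
  rec(0L, 0L, root, root)
  do.call(rbind, leaves)
}

## Hand convolution of a 1-row grid with a truncated Gaussian kernel,
## renormalising each source cell's kernel over in-grid cells (the
## mass-conserving edge rule), for checking gaussianSmooth on tiny inputs.
oracleSmoothRow <- function(v, sigmaCells, trunc = 4) {
  n <- length(v)
  r <- ceiling(trunc * sigmaCells)
  k <- exp(-(seq(-r, r))^2 / (2 * sigmaCells^2))
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1 & idx <= n
    w <- k[ok] / sum(k[ok])
    out[idx[ok]] <- out[idx[ok]] + v[i] * w
  }
  out
}

## Random integer-valued population grid (exact float sums on both the
## integral-image and the sum() route), optionally with a random mask.
randomGrid <- function(seed, maxDim = 32L, cellSize = 100, withMask = FALSE) {
  set.seed(seed)
  nr <- sample(2:maxDim, 1)
  nc <- sample(2:maxDim, 1)
  v <- matrix(rpois(nr * nc, lambda = sample(c(0.5, 3, 20), 1)), nr, nc)
  mask <- if (withMask && runif(1) < 0.7)
    matrix(runif(nr * nc) < 0.85, nr, nc)
  else matrix(TRUE, nr, nc)
  if (!any(mask)) mask[1, 1] <- TRUE
  populationGrid(v, cellSize = cellSize, mask = mask)
}

## Tiny deterministic clustered world shared by several suites.
smallClusteredSpec <- function(seed = 11L, n = 128L)
  syntheticSpec(nRows = n, nCols = n, cellSize = 100, nClusters = 4L,
                nRegions = 4L, seed = seed)
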