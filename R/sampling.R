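## All randomness in the selection stage flows from one user seed through
## this splitting scheme (a Lehmer step, exact in doubles, result < 2^31-1),
## so every draw is replayable from the recorded seed.
splitSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483647)
}

#' Systematic PPS selection of primary sampling units
#'
#' Draws `k` PSUs from a frame with replacement, with selection probability
#' proportional to unit population, by the systematic method: units are
#' cumulated in frame order, the selection interval is `I = total / k`, one
#' uniform start `u` is drawn in `[0, I)`, and the hits `u + j * I`,
#' `j = 0..k-1`, are mapped through the cumulative totals. A unit hit `t`
#' times is returned once with multiplicity `t`; multiplicities always sum
#' to `k`, and a unit whose population exceeds the interval is selected with
#' certainty. Zero-population units have selection probability 0 and are
#' excluded from the cumulation.
#'
#' @param frame a [Frame-class] with positive total population.
#' @param k number of PSU selections (>= 1).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param rate replacement fraction for [replacementSample()].
#' @param randomStart optionally a fixed start in `[0, I)` overriding the
#'   seeded draw (useful for worked examples and audits).
#' @return data.frame of selection records: `unit_id`, `stratum_id`,
#'   `multiplicity`, `expected_hits` (`k * p_i`), `is_replacement`, `seed`,
#'   `random_start`
#' @examples
#' g <- populationGrid(matrix(10, 1, 4), cellSize = 100)
#' f <- ugcPartition(g, 100)
#' ppsSystematic(f, k = 2, seed = 1, randomStart = 5)
#' @export
ppsSystematic <- function(frame, k, seed, randomStart = NULL) {
  stopifnot(k >= 1)
  u0 <- frame@units[frame@units$population > 0, , drop = FALSE]
  total <- sum(u0$population)
  if (!nrow(u0) || total <= 0)
    stop("frame has no units with positive population")
  interval <- total / k
  if (is.null(randomStart)) {
    rs <- withr_seed(seed, stats::runif(1, 0, interval))
  } else {
    stopifnot(randomStart >= 0, randomStart < interval)
    rs <- randomStart
  }
  hits <- rs + (seq_len(k) - 1) * interval
  cum <- cumsum(u0$population)
  idx <- findInterval(hits, cum, left.open = TRUE) + 1L  # cum[idx-1] < h <= cum[idx]
  tab <- table(idx)
  sel <- as.integer(names(tab))
  data.frame(
    unit_id = u0$unit_id[sel],
    stratum_id = u0$stratum_id[sel],
    multiplicity = as.integer(tab),
    expected_hits = k * u0$population[sel] / total,
    is_replacement = FALSE,
    seed = as.integer(seed),
    random_start = rs,
    stringsAsFactors = FALSE)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Replacement PSU sample
#'
#' Draws the additional replacement list — by default 20% of the main
#' sample, the provision for PSUs found without population in the field —
#' by an independent systematic PPS pass under a seed derived from the main
#' seed. `ceiling(rate * k)` records are returned, flagged
#' `is_replacement = TRUE`. When a replacement is substituted for a main
#' PSU it inherits the original's selection probability in the weight
#' calculation (see [householdWeight()]).
#'
#' @inheritParams ppsSystematic
#' @return data.frame of selection records with `is_replacement = TRUE`
#' @export
replacementSample <- function(frame, k, rate = 0.2, seed) {
  stopifnot(rate >= 0)
  kr <- as.integer(ceiling(rate * k))
  if (kr == 0L) {
    out <- ppsSystematic(frame, 1L, seed)[0, ]
    return(out)
  }
  dseed <- splitSeed(seed, 999983L)
  out <- ppsSystematic(frame, kr, dseed)
  out$is_replacement <- TRUE
  out
}

#' Random selection of one household per secondary sampling unit
#'
#' Within each selected PSU, SSUs of roughly 12 structures are delineated;
#' in each SSU one structure is chosen uniformly at random and, within it,
#' one household uniformly at random (the tablet protocol that removes
#' selection decisions from enumerators). The probability of a given
#' household is therefore `1 / (n_structures * n_households_in_its
#' _structure)`. SSUs with no structures are flagged for replacement rather
#' than erroring.
#'
#' @param structuresPerSsu integer vector: number of structures in each SSU.
#' @param householdsPerStructure list parallel to `structuresPerSsu`; element
#'   `i` is the integer vector of household counts per structure in SSU `i`.
#' @param seed integer seed; reproducible given the seed.
#' @return data.frame with one row per SSU: `ssu_index`, `structure_index`,
#'   `household_index`, `probability`, `needs_replacement`
#' @examples
#' selectHousehold(2, list(c(1, 3)), seed = 7)
#' @export
selectHousehold <- function(structuresPerSsu, householdsPerStructure, seed) {
  nSsu <- length(structuresPerSsu)
  stopifnot(length(householdsPerStructure) == nSsu)
  withr_seed(seed, {
    rows <- lapply(seq_len(nSsu), function(i) {
      nStr <- structuresPerSsu[i]
      if (nStr < 1L)
        return(data.frame(ssu_index = i, structure_index = NA_integer_,
                          household_index = NA_integer_,
                          probability = NA_real_, needs_replacement = TRUE))
      hh <- householdsPerStructure[[i]]
      stopifnot(length(hh) == nStr, all(hh >= 1L))
      s <- sample.int(nStr, 1L)
      h <- sample.int(hh[s], 1L)
      data.frame(ssu_index = i, structure_index = s, household_index = h,
                 probability = 1 / (nStr * hh[s]), needs_replacement = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write selection records to CSV
#'
#' @param records data.frame from [ppsSystematic()] / [replacementSample()].
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeSelectionCSV <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
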