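#' First-stage PSU selection probability
#'
#' Under with-replacement systematic PPS with `k` selections in the stratum,
#' the first-stage probability of PSU `i` is `P1 = k * pop_i / N_h` — an
#' expected-hit rate, which can exceed 1 for a unit so large that it is
#' selected with certainty (such units are flagged; their inclusion
#' probability is capped at 1 inside the weight computation).
#'
#' @param popI PSU population (> 0; a zero-population unit cannot have been
#'   selected).
#' @param Nh stratum population total (same units as `popI`).
#' @param k number of PSU selections in the stratum.
#' @return list with `P1` and `certainty` (`TRUE` when `P1 > 1`)
#' @examples
#' psuProbability(500, 10000, k = 2)   # P1 = 0.1
#' @export
psuProbability <- function(popI, Nh, k) {
  stopifnot(k >= 1, Nh > 0, popI <= Nh)
  if (popI <= 0)
    stop("zero-population PSU has selection probability 0 and cannot ",
         "have been selected")
  P1 <- k * popI / Nh
  list(P1 = P1, certainty = P1 > 1)
}

#' SSU delineation plan for a selected PSU
#'
#' Encodes the segmentation protocol: a PSU is manually split into 12
#' approximately equal-sized SSUs of about 12 structures each, with three
#' special cases — (i) PSUs with fewer than 12 structures are not segmented
#' (one SSU), (ii) PSUs with more than 150 structures get
#' `ceiling(n_structures / 12)` SSUs of ~12 buildings each, and (iii) PSUs
#' selected multiple times have their SSU count scaled up proportionately to
#' the multiplicity. One household is interviewed per SSU, so the number of
#' interviews per PSU spans 1 to 36 in the design this implements.
#'
#' @param nStructures structures visible/listed in the PSU (>= 1).
#' @param multiplicity times the PSU was selected (>= 1).
#' @return list: `n_ssu`, `n_households` (interviews, = `n_ssu`),
#'   `segmented`
#' @examples
#' ssuPlan(100, 1)  # 12 SSUs, 12 interviews
#' ssuPlan(8, 1)    # unsegmented: 1 SSU
#' ssuPlan(180, 2)  # ceiling(180/12) * 2 = 30 SSUs
#' @export
ssuPlan <- function(nStructures, multiplicity = 1L) {
  stopifnot(nStructures >= 1, multiplicity >= 1)
  base <- if (nStructures < 12) 1L
          else if (nStructures > 150) as.integer(ceiling(nStructures / 12))
          else 12L
  nSsu <- base * as.integer(multiplicity)
  list(n_ssu = nSsu, n_households = nSsu, segmented = base > 1L)
}

#' Household design weight
#'
#' Composes the two staged probabilities into the design weight
#' `w = 1 / (P1 * P2)`: `P1` is the PSU's first-stage probability (capped at
#' 1 for certainty units) and `P2 = 1 / m` is the within-PSU household
#' probability, where `m = households_in_psu / n_ssu` is the average
#' household count per SSU (one household interviewed per SSU). The special
#' SSU cases enter through the plan's adjusted `n_ssu`. Replacement PSUs
#' should be passed the *original* PSU's `P1`: the replacement is assumed to
#' have the same selection probability as the unit it stands in for.
#'
#' @param P1 first-stage probability from [psuProbability()] (> 0).
#' @param plan SSU plan from [ssuPlan()].
#' @param householdsInPsu households recorded in the PSU (>= `plan$n_ssu`).
#' @return list: `P1` (capped), `P2`, `weight`, `capped`
#' @examples
#' householdWeight(0.1, ssuPlan(100), householdsInPsu = 120)  # weight 100
#' @export
householdWeight <- function(P1, plan, householdsInPsu) {
  if (P1 <= 0) stop("P1 must be positive")
  stopifnot(householdsInPsu >= plan$n_ssu)
  p1 <- min(P1, 1)
  m <- householdsInPsu / plan$n_ssu
  P2 <- 1 / m
  list(P1 = p1, P2 = P2, weight = 1 / (p1 * P2), capped = P1 > 1)
}

#' Dispersion diagnostics of a set of design weights
#'
#' Summarises how unequal the weights are: the max/min ratio, the
#' relvariance `cv^2(w) = n * sum(w^2) / sum(w)^2 - 1`, and the Kish
#' unequal-weighting effect `deff_w = 1 + cv^2(w)` — the factor by which
#' weight variation alone inflates estimator variance relative to a
#' self-weighting design. `deff_w >= 1` always, with equality iff all
#' weights are equal; this is the only component of the design effect the
#' frame construction influences directly.
#'
#' @param weights numeric vector of at least 2 positive weights.
#' @return list: `n`, `ratio_max_min`, `relvariance`, `deff_w`
#' @examples
#' weightDiagnostics(c(1, 3))     # deff_w 1.25, ratio 3
#' weightDiagnostics(c(1, 1, 4))  # deff_w 1.5
#' @export
weightDiagnostics <- function(weights) {
  if (length(weights) < 2L) stop("need at least 2 weights")
  if (any(weights <= 0)) stop("weights must be positive")
  n <- length(weights)
  rel <- n * sum(weights^2) / sum(weights)^2 - 1
  list(n = n,
       ratio_max_min = max(weights) / min(weights),
       relvariance = rel,
       deff_w = 1 + rel)
}
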