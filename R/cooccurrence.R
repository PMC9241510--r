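# Probabilistic pairwise co-occurrence classification. Under independent
# placement of two species with occupancies n_a and n_b over N sites, the
# number of joint-presence sites j follows the hypergeometric law
#   P(j) = C(n_a, j) C(N - n_a, n_b - j) / C(N, n_b)
# on the support max(0, n_a + n_b - N) .. min(n_a, n_b). Pairs are called
# aggregated when the upper closed tail P(J >= j_obs) falls below alpha,
# segregated when the lower closed tail does, random otherwise.

.check_occ <- function(N, n_a, n_b) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (n_a < 0 || n_b < 0 || n_a > N || n_b > N)
    stop("occupancies must lie in [0, N]", call. = FALSE)
}

#' Exact null distribution of the number of co-occurrence sites
#'
#' Computes the probability of each possible number of joint-presence
#' sites for two independently placed species. The law is hypergeometric
#' (drawing species B's `n_b` sites without replacement and counting hits
#' among species A's `n_a`), evaluated with [stats::dhyper()], whose
#' saddle-point implementation is overflow-free and accurate to a few ulp
#' even at N = 10,000.
#'
#' @param N Number of sites.
#' @param n_a,n_b Occupancies of the two species (0 <= n <= N).
#' @return A `data.frame` with columns `j` (support) and `p` (probability,
#'   summing to 1 within 1e-12).
#' @examples
#' d <- cooccurrence_distribution(10, 5, 5)
#' d$p[d$j == 2]  # 100/252
#' @export
cooccurrence_distribution <- function(N, n_a, n_b) {
  .check_occ(N, n_a, n_b)
  j <- seq(max(0, n_a + n_b - N), min(n_a, n_b))
  data.frame(j = j, p = dhyper(j, n_a, N - n_a, n_b))
}

#' Classify one species pair as aggregated, segregated or random
#'
#' Both tails are closed (they include the observed point mass), so
#' `p_lt + p_gt >= 1` always holds; at most one tail can fall below an
#' `alpha <= 0.5`.
#'
#' @param N Number of sites.
#' @param n_a,n_b Occupancies.
#' @param j_obs Observed number of joint-presence sites (within support).
#' @param alpha Per-tail significance level.
#' @return One-row `data.frame`: `N`, `n_a`, `n_b`, `j_obs`, `expected_j`,
#'   `p_lt`, `p_gt`, `classification`.
#' @export
classify_pair <- function(N, n_a, n_b, j_obs, alpha = 0.05) {
  .check_occ(N, n_a, n_b)
  lo <- max(0, n_a + n_b - N)
  hi <- min(n_a, n_b)
  if (j_obs < lo || j_obs > hi)
    stop("j_obs outside the support [", lo, ", ", hi, "]", call. = FALSE)
  d <- cooccurrence_distribution(N, n_a, n_b)
  p_lt <- sum(d$p[d$j <= j_obs])
  p_gt <- sum(d$p[d$j >= j_obs])
  if (p_gt < alpha && p_lt < alpha)
    stop("internal consistency: both tails below alpha", call. = FALSE)
  cls <- if (p_gt < alpha) "aggregated"
         else if (p_lt < alpha) "segregated"
         else "random"
  data.frame(
    N = N, n_a = n_a, n_b = n_b, j_obs = j_obs,
    expected_j = n_a * n_b / N,
    p_lt = min(p_lt, 1), p_gt = min(p_gt, 1),
    classification = cls, stringsAsFactors = FALSE
  )
}

#' Test every unordered taxon pair of an occurrence matrix
#'
#' Vectorized over all `C(S, 2)` pairs using the exact hypergeometric
#' tails ([stats::phyper()]); equivalent to applying [classify_pair()] to
#' each pair. Pairs whose expected number of joint sites falls below
#' `min_expected` are reported but flagged `testable = FALSE` and should
#' be excluded from significant-pair counts.
#'
#' @param occ An [occurrence_matrix()].
#' @param alpha Per-tail significance level.
#' @param min_expected Minimum expected joint-presence count for a pair to
#'   be considered testable.
#' @param p_adjust `"none"` (default) or `"BH"`: Benjamini-Hochberg
#'   adjustment of each tail's p-values across all pairs before
#'   classification.
#' @return A `pair_tests` data.frame: `taxon_a`, `taxon_b`, `N`, `n_a`,
#'   `n_b`, `j_obs`, `expected_j`, `p_lt`, `p_gt`, `classification`,
#'   `testable`; `alpha` is carried as an attribute.
#' @export
test_all_pairs <- function(occ, alpha = 0.05, min_expected = 1,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(occ, "occurrence_matrix"))
  pres <- occ$presence
  if (nrow(pres) < 2) stop("need at least 2 taxa", call. = FALSE)
  N <- ncol(pres)
  n <- rowSums(pres)
  J <- tcrossprod(pres)
  ut <- which(upper.tri(J), arr.ind = TRUE)
  a <- ut[, 1]; b <- ut[, 2]
  j_obs <- J[ut]
  n_a <- n[a]; n_b <- n[b]
  p_lt <- phyper(j_obs, n_a, N - n_a, n_b)
  p_gt <- phyper(j_obs - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
  q_lt <- if (p_adjust == "BH") p.adjust(p_lt, "BH") else p_lt
  q_gt <- if (p_adjust == "BH") p.adjust(p_gt, "BH") else p_gt
  cls <- ifelse(q_gt < alpha, "aggregated",
                ifelse(q_lt < alpha, "segregated", "random"))
  out <- data.frame(
    taxon_a = rownames(pres)[a], taxon_b = rownames(pres)[b],
    N = N, n_a = unname(n_a), n_b = unname(n_b), j_obs = j_obs,
    expected_j = unname(n_a * n_b / N),
    p_lt = pmin(p_lt, 1), p_gt = pmin(p_gt, 1),
    classification = cls,
    testable = unname(n_a * n_b / N) >= min_expected,
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  class(out) <- c("pair_tests", "data.frame")
  out
}

#' Count significant pairs by class
#'
#' @param pairs A `pair_tests` table.
#' @return Named integer vector: aggregated, segregated, random counts
#'   among testable pairs, plus untestable.
#' @export
pair_counts <- function(pairs) {
  ok <- pairs$testable
  c(aggregated = sum(pairs$classification == "aggregated" & ok),
    segregated = sum(pairs$classification == "segregated" & ok),
    random = sum(pairs$classification == "random" & ok),
    untestable = sum(!ok))
}
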