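#' Within-group reproduction probabilities
#'
#' A group holds `K` sites occupied by social individuals (`nA`), asocial
#' individuals (`nB`) or free resources (`K - nA - nB`). Per time step at
#' most one reproduction event occurs:
#' \deqn{p_A = \frac{n_A}{K}\Big(1-\frac{n_A+n_B}{K}\Big), \qquad
#'       p_B = b\,\frac{n_B}{K}\Big(1-\frac{n_A+n_B}{K}\Big),}
#' with `p0 = 1 - pA - pB` the probability of no update. The free-site
#' factor is computed as `(K - nA - nB)/K` in integer arithmetic so the
#' three probabilities sum to 1 exactly. `pA + pB <= 1` for every integer
#' state precisely when `b <= 4` (the sum is maximized at `nA = 0`,
#' `nB = K/2`).
#'
#' @param nA,nB Counts of social / asocial individuals (vectorized).
#' @param K Splitting threshold (sites per group), `K >= 2`.
#' @param b Asocial reproduction scale factor in `[1, 4]`.
#' @return A data frame with columns `pA`, `pB`, `p0` (one row per state).
#' @export
#' @examples
#' reproduction_probs(2, 3, K = 10, b = 2)  # 0.1, 0.3, 0.6
reproduction_probs <- function(nA, nB, K, b = 1) {
  check_group_state(nA, nB, K, b)
  kk <- K * K
  free <- K - nA - nB
  pA <- (nA * free) / kk
  pB <- (b * (nB * free)) / kk
  data.frame(pA = pA, pB = pB, p0 = 1 - pA - pB)
}

check_group_state <- function(nA, nB, K, b) {
  if (K < 2 || K != floor(K)) stop("invalid K: need integer K >= 2")
  if (b < 1 || b > 4) stop("invalid b: need b in [1, 4]")
  if (any(nA < 0) || any(nB < 0)) stop("invalid state: negative counts")
  if (any(nA + nB > K)) stop("invalid state: nA + nB exceeds K")
  invisible(TRUE)
}

#' Advance one group by one reproduction step
#'
#' Draws a single uniform variate and partitions it into
#' `[0, pA)`, `[pA, pA + pB)` and the remainder, so that `nA` increases
#' by one with probability `pA`, `nB` with probability `pB`, and the
#' group is unchanged otherwise. A group at the splitting threshold
#' (`nA + nB = K`) never changes. Counts never decrease (no individual
#' death) and the total changes by exactly 0 or 1.
#'
#' @inheritParams reproduction_probs
#' @return Integer vector `c(nA, nB)` after the step.
#' @export
step_group <- function(nA, nB, K, b = 1) {
  check_group_state(nA, nB, K, b)
  if (nA + nB == K) return(c(nA = nA, nB = nB))
  kk <- K * K
  free <- K - nA - nB
  pA <- (nA * free) / kk
  pB <- (b * (nB * free)) / kk
  u <- runif(1)
  if (u < pA) nA <- nA + 1L
  else if (u < pA + pB) nB <- nB + 1L
  c(nA = nA, nB = nB)
}
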