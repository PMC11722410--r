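#' Per-group death probabilities
#'
#' At most one group dies per time step; `mu` is the probability that any
#' group death occurs. With `f_j = nA_j / (nA_j + nB_j)` the social
#' fraction of group `j`:
#' \describe{
#'   \item{neutral}{every group gets `mu / Ng`; probabilities sum to
#'     `mu` exactly.}
#'   \item{relative}{group `j` gets
#'     \eqn{\mu(1-af_j)/\sum_l (1-af_l)}; probabilities sum to `mu`
#'     exactly regardless of composition (density- and
#'     frequency-dependent selection at the group level). If every weight
#'     vanishes (`a = 1` and all groups purely social) no group can die
#'     and all probabilities are 0.}
#'   \item{absolute}{group `j` gets \eqn{(\mu/N_g)(1-af_j)}; the sum is
#'     at most `mu`, with equality only when no social individuals
#'     exist.}
#' }
#'
#' @param nA,nB Integer vectors of per-group counts (one element per
#'   group); no group may be empty.
#' @param mu Probability that any group death occurs per step.
#' @param a Social trait strength in `[0, 1]`.
#' @param mode One of `"neutral"`, `"relative"`, `"absolute"`.
#' @return Numeric vector of per-group death probabilities.
#' @export
#' @examples
#' death_probabilities(c(10, 0), c(0, 10), mu = 0.7, a = 0.4,
#'                     mode = "relative")
death_probabilities <- function(nA, nB, mu, a = 0,
                                mode = c("neutral", "relative", "absolute")) {
  mode <- match.arg(mode)
  ng <- length(nA)
  if (ng == 0L) stop("empty population")
  if (any(nA + nB == 0)) stop("empty group in population")
  stopifnot(mu >= 0, mu <= 1, a >= 0, a <= 1, length(nB) == ng)
  f <- nA / (nA + nB)
  switch(mode,
    neutral  = rep(mu / ng, ng),
    relative = {
      w <- 1 - a * f
      s <- sum(w)
      if (s == 0) rep(0, ng) else mu * w / s
    },
    absolute = (mu / ng) * (1 - a * f)
  )
}

#' Sample at most one group death
#'
#' Partitions a single uniform variate by the cumulative death
#' probabilities: returns the index of the dying group, or `NA` (no
#' death) with probability `1 - sum(probs)`.
#'
#' @param probs Per-group death probabilities with `sum(probs) <= 1`.
#' @return Integer group index, or `NA_integer_` for no death.
#' @export
sample_death <- function(probs) {
  s <- sum(probs)
  if (s > 1 + 1e-12) stop("death probabilities sum to more than 1")
  u <- runif(1)
  cs <- cumsum(probs)
  j <- which(u < cs)
  if (length(j) == 0L) NA_integer_ else j[1L]
}

#' Select the group that splits this step
#'
#' Splitting occurs with probability 1 whenever at least one group has
#' reached the threshold `K` and the population is below the group
#' carrying capacity `Kg`; the splitter is chosen uniformly among the
#' groups at threshold. Otherwise no group splits.
#'
#' @inheritParams death_probabilities
#' @param K Splitting threshold.
#' @param Kg Group carrying capacity.
#' @return Integer index of the splitting group, or `NA_integer_`.
#' @export
select_splitter <- function(nA, nB, K, Kg) {
  ng <- length(nA)
  if (ng == 0L || ng >= Kg) return(NA_integer_)
  elig <- which(nA + nB == K)
  if (length(elig) == 0L) return(NA_integer_)
  u <- runif(1)
  elig[min(floor(u * length(elig)) + 1L, length(elig))]
}

#' Split a group at threshold into two daughters by random allocation
#'
#' Draws `mA` uniformly on `{0, ..., nA}` and `mB` uniformly on
#' `{0, ..., nB}` (two independent draws, not a hypergeometric partition
#' of the K sites) and forms daughters `(mA, mB)` and
#' `(nA - mA, nB - mB)`. If either daughter is empty it is eliminated
#' immediately: the outcome is flagged `"abortive"` and the surviving
#' daughter equals the parent, which remains at threshold and may split
#' again on a later step. Allocation conserves individuals exactly.
#'
#' @param nA,nB Parent composition with `nA + nB = K`.
#' @param K Splitting threshold (used only to check the precondition).
#' @return List with `kind` (`"two_daughters"` or `"abortive"`) and
#'   `daughters`, a list of one or two `c(nA, nB)` vectors.
#' @export
split_group <- function(nA, nB, K = nA + nB) {
  if (nA + nB != K) stop("split_group called below threshold")
  if (nA < 0 || nB < 0) stop("invalid state")
  mA <- min(floor(runif(1) * (nA + 1)), nA)
  mB <- min(floor(runif(1) * (nB + 1)), nB)
  d1 <- c(nA = mA, nB = mB)
  d2 <- c(nA = nA - mA, nB = nB - mB)
  if (sum(d1) == 0L || sum(d2) == 0L) {
    list(kind = "abortive", daughters = list(c(nA = nA, nB = nB)))
  } else {
    list(kind = "two_daughters", daughters = list(d1, d2))
  }
}
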