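# Independent oracles used across the suite.

# Absorption ("fixation") probabilities of a one-step birth-death chain on
# 0..Kg with absorbing ends, from the transition probabilities of the
# rare-group-death limit. Direct linear solve of the first-step equations;
# independent of the closed-form expression in fixation_probability().
moran_fix_markov <- function(Kg, mu, a, mode) {
  if (Kg == 1) return(c(0, 1))
  m <- Kg - 1
  A <- matrix(0, m, m)
  rhs <- numeric(m)
  for (i in seq_len(m)) {
    tr <- moran_limit_transitions(mode, i, Kg, mu, a)
    td <- tr[["T_down"]]; tu <- tr[["T_up"]]
    A[i, i] <- td + tu
    if (i > 1) A[i, i - 1] <- -td
    if (i < m) A[i, i + 1] <- -tu else rhs[i] <- tu
  }
  c(0, solve(A, rhs), 1)
}

# Random valid population of homogeneous and mixed groups.
random_population <- function(K, max_groups = 40) {
  ng <- sample.int(max_groups, 1)
  nA <- integer(ng); nB <- integer(ng)
  for (j in seq_len(ng)) {
    repeat {
      x <- sample.int(K + 1, 1) - 1L
      y <- sample.int(K + 1 - x, 1) - 1L
      if (x + y > 0) { nA[j] <- x; nB[j] <- y; break }
    }
  }
  list(nA = nA, nB = nB)
}

terminal_row <- function(tr) tr[nrow(tr), , drop = FALSE]
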