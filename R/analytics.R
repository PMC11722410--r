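#' Harmonic number
#'
#' \eqn{H_n = \sum_{i=1}^{n} 1/i}, computed by direct summation. Harmonic
#' numbers enter all high-survival-limit threshold expressions.
#'
#' @param n Non-negative integer (vectorized). `n = 0` gives 0.
#' @return Numeric vector of harmonic numbers.
#' @export
#' @examples
#' harmonic(9)
harmonic <- function(n) {
  stopifnot(all(n >= 0), all(n == floor(n)))
  vapply(n, function(m) if (m == 0L) 0 else sum(1 / seq_len(m)), numeric(1))
}

#' Upward transition probability of the within-group size walk
#'
#' Probability that a group of size `l` (out of `K` sites) gains one
#' individual in a time step, in the neutral single-type case:
#' \eqn{T^+_l = (l/K)(1 - l/K)}. The walk is absorbed at 0 (elimination,
#' via group death handled separately) and at `K` (splitting threshold).
#'
#' @param l Current group size, `0 <= l <= K` (vectorized).
#' @param K Splitting threshold (number of sites per group).
#' @return Probability vector.
#' @export
#' @examples
#' t_up(3, 10)  # 0.21
t_up <- function(l, K) {
  stopifnot(K >= 2, all(l >= 0), all(l <= K))
  (l / K) * (1 - l / K)
}

#' Probability of reaching the splitting threshold before elimination
#'
#' For a single group of current size `n` whose per-step survival
#' probability is `delta` and whose size increases with probability
#' \eqn{b\,T^+_l} while it survives, the probability of reaching the
#' absorbing threshold `K` before the group is eliminated is
#' \deqn{\psi_n = \prod_{l=n}^{K-1}
#'   \frac{\delta b T^+_l}{1-\delta+\delta b T^+_l}.}
#' `psi(K, ...) = 1` (empty product) and `delta = 1` gives 1 for all `n`.
#'
#' [psi_recursion_solve()] solves the defining first-step recursion as a
#' linear system instead, and serves as an independent cross-check.
#'
#' @param n Initial group size(s) in `1..K` (vectorized).
#' @param delta Per-step group survival probability in `[0, 1]`.
#' @param K Splitting threshold.
#' @param b Reproduction scale factor in `[1, 4]` (asocial groups use
#'   `b > 1`; social groups `b = 1`).
#' @return Probability vector, one entry per element of `n`.
#' @export
#' @examples
#' psi(1, delta = 0.8, K = 2)  # 0.5
psi <- function(n, delta, K, b = 1) {
  stopifnot(delta >= 0, delta <= 1, K >= 2, b > 0, b <= 4,
            all(n >= 1), all(n <= K))
  tl <- t_up(seq_len(K - 1), K)
  num <- delta * b * tl
  fac <- num / (1 - delta + num)          # factor for l = 1..K-1
  # psi_n = prod(fac[n..K-1]); cumulative product from the top
  cp <- rev(cumprod(rev(fac)))            # cp[l] = prod_{j=l}^{K-1} fac_j
  cp <- c(cp, 1)                          # psi_K = 1
  cp[n]
}

#' Direct linear-system solution of the threshold-absorption recursion
#'
#' Solves the first-step recursion
#' \eqn{\psi_n = \delta b T^+_n \psi_{n+1} + \delta(1 - bT^+_n)\psi_n}
#' with boundary conditions \eqn{\psi_0 = 0}, \eqn{\psi_K = 1} as an
#' explicit linear system. Used as an oracle for [psi()].
#'
#' @inheritParams psi
#' @return Numeric vector `psi[1..K]` (the value for every initial size).
#' @export
psi_recursion_solve <- function(delta, K, b = 1) {
  stopifnot(delta >= 0, delta <= 1, K >= 2, b > 0, b <= 4)
  if (K == 2) {
    tl <- b * t_up(1, K)
    lhs <- 1 - delta * (1 - tl)
    return(c(delta * tl / lhs, 1))
  }
  m <- K - 1
  A <- matrix(0, m, m)
  rhs <- numeric(m)
  for (n in seq_len(m)) {
    tn <- b * t_up(n, K)
    A[n, n] <- 1 - delta * (1 - tn)
    if (n < m) A[n, n + 1] <- -delta * tn else rhs[n] <- delta * tn
  }
  c(solve(A, rhs), 1)
}

#' Average threshold-absorption probability over random initial sizes
#'
#' Arithmetic mean of [psi()] over initial sizes `1..K-1`, matching groups
#' initialized uniformly on that range. Group proliferation requires, on
#' average, more than one of the two daughters of a split to reach the
#' threshold again, i.e. `psi_avg(...) > 1/2`.
#'
#' @inheritParams psi
#' @return Scalar probability.
#' @export
psi_avg <- function(delta, K, b = 1) {
  mean(psi(seq_len(K - 1), delta, K, b))
}

#' High-survival-limit expansion of the average absorption probability
#'
#' First-order expansion of [psi_avg()] around `delta = 1`:
#' \deqn{\langle\psi\rangle \approx 1 - (1-\delta)\,\frac{H_{K-1}K^2}{b(K-1)}.}
#'
#' @inheritParams psi
#' @return Scalar approximation to `psi_avg(delta, K, b)`.
#' @export
psi_avg_high_delta <- function(delta, K, b = 1) {
  stopifnot(K >= 2, b >= 1, b <= 4)
  1 - (1 - delta) * harmonic(K - 1) * K^2 / (b * (K - 1))
}

#' Survival-probability threshold for group proliferation
#'
#' The value of the per-step survival probability `delta` at which the
#' average absorption probability equals 1/2 in the high-survival limit:
#' \deqn{\delta^* = 1 - \frac{b(K-1)}{2 H_{K-1} K^2}.}
#'
#' @inheritParams psi
#' @return Scalar threshold survival probability.
#' @export
#' @examples
#' delta_star(2)  # 0.875
delta_star <- function(K, b = 1) {
  stopifnot(K >= 2, b >= 1, b <= 4)
  d <- 1 - b * (K - 1) / (2 * harmonic(K - 1) * K^2)
  if (d < 0 || d > 1) {
    stop("delta* = ", format(d), " outside [0,1]: high-survival ",
         "approximation invalid for K = ", K, ", b = ", b)
  }
  d
}

#' Proliferation threshold relating group death probability and group number
#'
#' In the high-survival limit, a population of `Ng` groups with death
#' probability `mu` per step sits on the proliferation boundary when
#' \deqn{\mu/N_g = \frac{b(K-1)}{2 H_{K-1} K^2}.}
#' Supply either `Ng` (solves for the threshold `mu`) or `mu` (solves for
#' the threshold `Ng`).
#'
#' @inheritParams psi
#' @param Ng Initial number of groups (give this to obtain the threshold
#'   death probability).
#' @param mu Group death probability per step (give this to obtain the
#'   threshold number of groups).
#' @return Scalar threshold value (`mu*` or `Ng*`). If a threshold `mu`
#'   exceeds 1 it lies beyond the admissible probability range; the value
#'   is returned with attribute `admissible = FALSE` and a warning.
#' @export
#' @examples
#' neutral_threshold(K = 10, Ng = 50)  # ~0.795
neutral_threshold <- function(K, b = 1, Ng = NULL, mu = NULL) {
  stopifnot(K >= 2, b >= 1, b <= 4, xor(is.null(Ng), is.null(mu)))
  slope <- b * (K - 1) / (2 * harmonic(K - 1) * K^2)  # mu/Ng at threshold
  if (!is.null(Ng)) {
    out <- Ng * slope
    if (out > 1) {
      warning("threshold mu = ", format(out), " exceeds 1")
      attr(out, "admissible") <- FALSE
    }
    out
  } else {
    mu / slope
  }
}

#' Numeric proliferation threshold without the high-survival assumption
#'
#' Finds the group death probability `mu` at which
#' `psi_avg(1 - mu/Ng, K, b) = 1/2` by bracketed root finding, i.e. the
#' proliferation boundary without assuming `delta` close to 1.
#'
#' @inheritParams neutral_threshold
#' @param tol Root-finding tolerance on `mu`.
#' @return Scalar `mu` root in `(0, Ng)`. Attribute `admissible` is FALSE
#'   (with a warning suppressed to a flag) when the root exceeds 1 and is
#'   therefore not a realizable per-step probability.
#' @export
solve_threshold_numeric <- function(K, Ng, b = 1, tol = 1e-8) {
  stopifnot(K >= 2, Ng > 0, b >= 1, b <= 4)
  f <- function(mu) psi_avg(1 - mu / Ng, K, b) - 0.5
  lo <- 0
  hi <- Ng
  if (f(hi) > 0) stop("no root: psi_avg > 1/2 even at delta = 0")
  root <- uniroot(f, c(lo, hi), tol = tol)$root
  if (root > 1) attr(root, "admissible") <- FALSE
  root
}

#' Per-step survival probabilities of homogeneous groups
#'
#' Survival probabilities of all-social (`delta_A`) and all-asocial
#' (`delta_B`) groups in a population of `Ng` homogeneous groups of which
#' `NgA` are all-social, for the two group-fitness regimes:
#' \describe{
#'   \item{relative}{\eqn{\delta_A = 1-\mu(1-a)/(N_g-aN_{g,A})},
#'     \eqn{\delta_B = 1-\mu/(N_g-aN_{g,A})}. Total death probability is
#'     exactly `mu` regardless of composition.}
#'   \item{absolute}{\eqn{\delta_A = 1-\mu(1-a)/N_g},
#'     \eqn{\delta_B = 1-\mu/N_g}; independent of composition.}
#'   \item{neutral}{both \eqn{1-\mu/N_g}.}
#' }
#'
#' @param mode One of `"neutral"`, `"relative"`, `"absolute"`.
#' @param Ng Total number of groups.
#' @param NgA Number of all-social groups (`0 <= NgA <= Ng`).
#' @param mu Group death probability per step.
#' @param a Social trait strength in `[0, 1]`.
#' @return Named vector `c(delta_A, delta_B)`.
#' @export
#' @examples
#' survival_probs("relative", Ng = 20, NgA = 10, mu = 0.7, a = 0.4)
survival_probs <- function(mode = c("neutral", "relative", "absolute"),
                           Ng, NgA = 0, mu, a = 0) {
  mode <- match.arg(mode)
  stopifnot(Ng >= 1, NgA >= 0, NgA <= Ng, mu >= 0, mu <= 1, a >= 0, a <= 1)
  out <- switch(mode,
    neutral  = c(1 - mu / Ng, 1 - mu / Ng),
    relative = {
      denom <- Ng - a * NgA
      if (denom <= 0) stop("relative mode requires Ng - a*NgA > 0")
      c(1 - mu * (1 - a) / denom, 1 - mu / denom)
    },
    absolute = c(1 - mu * (1 - a) / Ng, 1 - mu / Ng)
  )
  names(out) <- c("delta_A", "delta_B")
  if (any(out < 0 | out > 1)) {
    stop("survival probabilities outside [0,1]; parameters out of domain")
  }
  out
}

#' Competition thresholds for the social trait and cheater advantage
#'
#' High-survival-limit threshold values `a*` (social trait strength) and
#' `b*` (asocial reproduction advantage) at which the average absorption
#' probabilities of all-social and all-asocial homogeneous groups equal
#' 1/2 (`psi_A = psi_B = 1/2`).
#'
#' Relative regime:
#' \deqn{a^* = \frac{(K-1)N_g - 2\mu H_{K-1}K^2}{(K-1)N_{g,A} -
#'   2\mu H_{K-1}K^2}, \qquad
#'   b^*(a) = \frac{2\mu H_{K-1}K^2}{(K-1)(N_g - aN_{g,A})}.}
#' Absolute regime:
#' \deqn{a^* = 1 - \frac{(K-1)N_g}{2\mu H_{K-1}K^2}, \qquad
#'   b^* = \frac{2\mu H_{K-1}K^2}{(K-1)N_g}.}
#'
#' Values outside the admissible ranges (`a` in `[0,1]`, `b` in `[1,4]`)
#' indicate the approximation regime does not apply there; they are
#' returned as-is with `in_regime` flags rather than clipped.
#'
#' @inheritParams survival_probs
#' @param K Splitting threshold.
#' @param a Optional social trait strength at which to evaluate `b*(a)`
#'   in the relative regime; defaults to `a*`.
#' @return List with `a_star`, `b_star` (evaluated at `a` or `a*` for the
#'   relative regime; constant for the absolute regime), `b_star_fun`
#'   (function of `a`, relative regime only), and logical flags
#'   `a_in_regime`, `b_in_regime`.
#' @export
#' @examples
#' competition_thresholds("relative", mu = 0.7, K = 10, Ng = 20, NgA = 10)
competition_thresholds <- function(mode = c("relative", "absolute"),
                                   mu, K, Ng, NgA = NULL, a = NULL) {
  mode <- match.arg(mode)
  stopifnot(K >= 2, Ng >= 1, mu >= 0, mu <= 1)
  hk2 <- 2 * mu * harmonic(K - 1) * K^2
  if (mode == "relative") {
    stopifnot(!is.null(NgA), NgA >= 0, NgA <= Ng)
    a_star <- ((K - 1) * Ng - hk2) / ((K - 1) * NgA - hk2)
    b_star_fun <- function(a) hk2 / ((K - 1) * (Ng - a * NgA))
    a_eval <- if (is.null(a)) a_star else a
    b_star <- b_star_fun(a_eval)
  } else {
    a_star <- 1 - (K - 1) * Ng / hk2
    b_star <- hk2 / ((K - 1) * Ng)
    b_star_fun <- function(a) rep(b_star, length(a))
  }
  list(a_star = a_star, b_star = b_star, b_star_fun = b_star_fun,
       a_in_regime = (a_star >= 0 && a_star <= 1),
       b_in_regime = (b_star >= 1 && b_star <= 4))
}

#' Numeric psi = 1/2 curves without the high-survival assumption
#'
#' Locations where the average threshold-absorption probability of
#' homogeneous all-social (`psi_A`, evaluated with `b = 1`) or all-asocial
#' (`psi_B`, evaluated with the supplied `b`) groups equals 1/2, obtained
#' by bracketed root finding on [psi_avg()] with survival probabilities
#' from [survival_probs()].
#'
#' Two sweep geometries are supported:
#' \describe{
#'   \item{`sweep = "ab"`}{Solves for the social-trait threshold `a` on
#'     the `psi_A = 1/2` line (a vertical line in the `(a, b)` plane,
#'     since `delta_A` does not involve `b`), and for each `a` in
#'     `a_grid` the `b` on the `psi_B = 1/2` curve.}
#'   \item{`sweep = "KNg"`}{For each `K` in `K_grid`, solves for the
#'     threshold number of groups `Ng` (with `NgA = frac_A * Ng`, treated
#'     as continuous) on each of the two curves.}
#' }
#'
#' @inheritParams competition_thresholds
#' @param sweep `"ab"` or `"KNg"`.
#' @param b Asocial reproduction advantage used for the `psi_B` curve.
#' @param a Social trait strength (used for `sweep = "KNg"`).
#' @param a_grid Grid of `a` values (`sweep = "ab"`).
#' @param K_grid Grid of `K` values (`sweep = "KNg"`).
#' @param frac_A Initial fraction of all-social groups (`sweep = "KNg"`).
#' @param Ng_max Upper bracket for `Ng` roots.
#' @return For `"ab"`: data frame with columns `a`, `b_half` (`NA` where
#'   no root lies in `(0, 4]`), plus attribute `a_half` (threshold `a`, or
#'   `NA` if `psi_A = 1/2` has no solution in `[0, 1]`). For `"KNg"`: data
#'   frame with columns `K`, `Ng_A_half`, `Ng_B_half` (`NA` where no root
#'   lies below `Ng_max`).
#' @export
psi_half_curves <- function(mode = c("relative", "absolute"),
                            sweep = c("ab", "KNg"),
                            mu, K = NULL, Ng = NULL, NgA = NULL,
                            b = 4, a = NULL,
                            a_grid = NULL, K_grid = NULL,
                            frac_A = 0.5, Ng_max = 1000) {
  mode <- match.arg(mode)
  sweep <- match.arg(sweep)
  half_root <- function(f, lo, hi) {
    # root of f = 0 in [lo, hi]; NA when no sign change
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = 1e-9)$root
  }
  if (sweep == "ab") {
    stopifnot(!is.null(K), !is.null(Ng), !is.null(NgA), !is.null(a_grid))
    fA <- function(av) {
      d <- try(survival_probs(mode, Ng, NgA, mu, av), silent = TRUE)
      if (inherits(d, "try-error")) return(NA_real_)
      psi_avg(d[["delta_A"]], K, b = 1) - 0.5
    }
    a_half <- half_root(fA, 0, 1)
    b_half <- vapply(a_grid, function(av) {
      d <- try(survival_probs(mode, Ng, NgA, mu, av), silent = TRUE)
      if (inherits(d, "try-error")) return(NA_real_)
      fB <- function(bv) psi_avg(d[["delta_B"]], K, b = bv) - 0.5
      half_root(fB, 1e-6, 4)
    }, numeric(1))
    out <- data.frame(a = a_grid, b_half = b_half)
    attr(out, "a_half") <- a_half
    out
  } else {
    stopifnot(!is.null(K_grid), !is.null(a))
    solve_Ng <- function(Kv, which) {
      f <- function(Ngv) {
        d <- try(survival_probs(mode, Ngv, frac_A * Ngv, mu, a),
                 silent = TRUE)
        if (inherits(d, "try-error")) return(NA_real_)
        if (which == "A") psi_avg(d[["delta_A"]], Kv, b = 1) - 0.5
        else psi_avg(d[["delta_B"]], Kv, b = b) - 0.5
      }
      # smallest Ng keeping both survival probabilities in [0, 1]
      lo <- if (mode == "relative") mu / (1 - a * frac_A) else mu
      half_root(f, max(1, lo + 1e-9), Ng_max)
    }
    data.frame(
      K = K_grid,
      Ng_A_half = vapply(K_grid, solve_Ng, numeric(1), which = "A"),
      Ng_B_half = vapply(K_grid, solve_Ng, numeric(1), which = "B")
    )
  }
}

#' Monte-Carlo absorption frequency of a single group
#'
#' Simulates a single group with per-step survival probability `delta`
#' and growth probability \eqn{b T^+_n} directly, and returns the
#' fraction of runs absorbed at the splitting threshold `K` before
#' elimination. An independent simulation-based check of [psi()].
#'
#' @inheritParams psi
#' @param n0 Initial group size.
#' @param reps Number of independent runs.
#' @return Empirical absorption frequency.
#' @export
#' @examples
#' set.seed(1)
#' mc_psi(1, K = 2, delta = 0.8, reps = 1e4)  # ~0.5
mc_psi <- function(n0, K, delta, b = 1, reps = 1e5) {
  stopifnot(n0 >= 1, n0 <= K, K >= 2, delta >= 0, delta <= 1,
            b > 0, b <= 4, reps >= 1)
  cpp_mc_psi(as.integer(n0), as.integer(K), delta, b, as.integer(reps))
}

#' Moran-limit transition probabilities for the number of social groups
#'
#' In the rare-group-death limit (`mu << 1`, population of homogeneous
#' groups at carrying capacity `Kg`, all groups at the splitting
#' threshold) the number of all-social groups `NgA` performs a one-step
#' birth-death chain. Relative regime:
#' \deqn{T^- = \mu\,\frac{K_g-N_{g,A}}{K_g}\,
#'   \frac{N_{g,A}(1-a)}{N_{g,A}(1-a)+K_g-N_{g,A}}, \quad
#'   T^+ = \mu\,\frac{N_{g,A}}{K_g}\,
#'   \frac{K_g-N_{g,A}}{N_{g,A}(1-a)+K_g-N_{g,A}}.}
#' Absolute regime:
#' \deqn{T^- = \mu(1-a)\,\frac{N_{g,A}}{K_g}\,\frac{K_g-N_{g,A}}{K_g},
#'   \quad T^+ = \mu\,\frac{N_{g,A}}{K_g}\,\frac{K_g-N_{g,A}}{K_g}.}
#' In both regimes `T^-/T^+ = 1 - a`, so fixation properties coincide.
#'
#' @inheritParams survival_probs
#' @param Kg Group carrying capacity (chain length).
#' @return Named vector `c(T_down, T_up)`.
#' @export
#' @examples
#' moran_limit_transitions("relative", NgA = 1, Kg = 2, mu = 0.1, a = 0.5)
moran_limit_transitions <- function(mode = c("relative", "absolute"),
                                    NgA, Kg, mu, a) {
  mode <- match.arg(mode)
  stopifnot(NgA > 0, NgA < Kg, mu >= 0, mu <= 1, a >= 0, a <= 1)
  if (mode == "relative") {
    denom <- NgA * (1 - a) + Kg - NgA
    td <- mu * ((Kg - NgA) / Kg) * (NgA * (1 - a) / denom)
    tu <- mu * (NgA / Kg) * ((Kg - NgA) / denom)
  } else {
    td <- mu * (1 - a) * (NgA / Kg) * ((Kg - NgA) / Kg)
    tu <- mu * (NgA / Kg) * ((Kg - NgA) / Kg)
  }
  c(T_down = td, T_up = tu)
}

#' Fixation probability of social groups in the Moran limit
#'
#' Closed-form absorption probability at `NgA = Kg` of the constant-bias
#' birth-death chain defined by [moran_limit_transitions()] (bias ratio
#' `1 - a`):
#' \deqn{\varphi = \frac{1-(1-a)^{N_{g,A}(0)}}{1-(1-a)^{K_g}},}
#' reducing to the neutral value `NgA0/Kg` at `a = 0`. Independent of
#' `mu`, which sets only the time scale.
#'
#' @param NgA0 Initial number of all-social groups, `0 <= NgA0 <= Kg`.
#' @param Kg Group carrying capacity.
#' @param a Social trait strength in `[0, 1]`.
#' @return Fixation probability.
#' @export
#' @examples
#' fixation_probability(1, 3, 0.5)  # ~0.5714
fixation_probability <- function(NgA0, Kg, a) {
  stopifnot(all(NgA0 >= 0), all(NgA0 <= Kg), Kg >= 1, a >= 0, a <= 1)
  if (a == 0) return(NgA0 / Kg)
  if (a == 1) return(as.numeric(NgA0 > 0))
  r <- 1 - a
  (1 - r^NgA0) / (1 - r^Kg)
}
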