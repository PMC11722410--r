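#' Construct a population of groups
#'
#' A population is an ordered collection of non-empty groups, each a pair
#' of counts (social `nA`, asocial `nB`), plus a time index. An empty
#' collection represents extinction, which is absorbing.
#'
#' @param nA,nB Integer vectors of per-group counts; every group must
#'   contain at least one individual.
#' @param t Time step index.
#' @return An object of class `"population"`.
#' @export
population <- function(nA = integer(), nB = integer(), t = 0L) {
  nA <- as.integer(nA); nB <- as.integer(nB)
  stopifnot(length(nA) == length(nB))
  if (any(nA < 0) || any(nB < 0)) stop("negative counts")
  if (any(nA + nB == 0)) stop("empty group not allowed")
  structure(list(nA = nA, nB = nB, t = as.integer(t)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population> t =", x$t, " Ng =", length(x$nA),
      " sum nA =", sum(x$nA), " sum nB =", sum(x$nB), "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles individual-level, group-level and run-control parameters.
#'
#' @param K Splitting threshold (sites per group).
#' @param b Asocial reproduction scale factor in `[1, 4]`.
#' @param mu Probability of any group death per step.
#' @param a Social trait strength in `[0, 1]`.
#' @param Kg Group carrying capacity.
#' @param mode Group-fitness regime: `"neutral"`, `"relative"` or
#'   `"absolute"`.
#' @param init Initialization rule: `"neutral_uniform"` (`Ng` all-asocial
#'   groups with sizes uniform on `1..K-1`), `"homogeneous_mix"` (`NgA`
#'   all-social plus `NgB` all-asocial groups, sizes uniform on
#'   `1..K-1`), `"heterogeneous"` (`Ng` groups with `nA`, `nB` drawn
#'   independently uniform on `0..floor(K/2)`, resampling empty draws),
#'   or `"at_capacity"` (`NgA` all-social plus `NgB` all-asocial groups
#'   all at the splitting threshold; used for rare-death fixation runs).
#' @param Ng Initial number of groups (`neutral_uniform`,
#'   `heterogeneous`).
#' @param NgA,NgB Initial numbers of all-social / all-asocial groups
#'   (`homogeneous_mix`, `at_capacity`).
#' @param T Number of time steps per replicate.
#' @param M Number of replicates.
#' @param seed Root RNG seed; per-replicate streams are derived from it
#'   by a counter scheme (see [run_replicates()]).
#' @param event_order `"reproduction_split_death"` (default: the death
#'   draw sees post-reproduction, post-split compositions) or
#'   `"death_reproduction_split"` (death draw sees the compositions at
#'   the start of the step).
#' @param record_every Record the trajectory every this many steps (0 =
#'   initial and final state only).
#' @param stop_on `"none"`, `"extinct"` or `"homogeneous"` (stop once one
#'   individual type is absent or the population is extinct).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(K = 10, b = 1, mu = 0.1, a = 0, Kg = 70,
                       mode = c("neutral", "relative", "absolute"),
                       init = c("neutral_uniform", "homogeneous_mix",
                                "heterogeneous", "at_capacity"),
                       Ng = NULL, NgA = NULL, NgB = NULL,
                       T = 1000, M = 50, seed = 1L,
                       event_order = c("reproduction_split_death",
                                       "death_reproduction_split"),
                       record_every = 1L,
                       stop_on = c("none", "extinct", "homogeneous")) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  event_order <- match.arg(event_order)
  stop_on <- match.arg(stop_on)
  stopifnot(K >= 2, b >= 1, b <= 4, mu >= 0, mu <= 1, a >= 0, a <= 1,
            Kg >= 1, T >= 1, M >= 1)
  if (init %in% c("neutral_uniform", "heterogeneous")) {
    stopifnot(!is.null(Ng), Ng >= 1)
    if (Ng > Kg) stop("Ng exceeds Kg")
  } else {
    stopifnot(!is.null(NgA), !is.null(NgB), NgA >= 0, NgB >= 0,
              NgA + NgB >= 1)
    if (NgA + NgB > Kg) stop("NgA + NgB exceeds Kg")
  }
  structure(list(K = as.integer(K), b = b, mu = mu, a = a,
                 Kg = as.integer(Kg), mode = mode, init = init,
                 Ng = Ng, NgA = NgA, NgB = NgB,
                 T = as.integer(T), M = as.integer(M),
                 seed = as.integer(seed), event_order = event_order,
                 record_every = as.integer(record_every),
                 stop_on = stop_on),
            class = "sim_config")
}

#' Initialize a population from a configuration
#'
#' @param cfg A [sim_config()].
#' @return A [population()].
#' @export
init_population <- function(cfg) {
  K <- cfg$K
  rsize <- function(n) sample.int(K - 1, n, replace = TRUE)
  switch(cfg$init,
    neutral_uniform = {
      sz <- rsize(cfg$Ng)
      population(nA = rep(0L, cfg$Ng), nB = sz)
    },
    homogeneous_mix = {
      szA <- if (cfg$NgA > 0) rsize(cfg$NgA) else integer()
      szB <- if (cfg$NgB > 0) rsize(cfg$NgB) else integer()
      population(nA = c(szA, rep(0L, cfg$NgB)),
                 nB = c(rep(0L, cfg$NgA), szB))
    },
    heterogeneous = {
      half <- floor(K / 2)
      nA <- integer(cfg$Ng); nB <- integer(cfg$Ng)
      for (i in seq_len(cfg$Ng)) {
        repeat {
          x <- sample.int(half + 1, 1) - 1L
          y <- sample.int(half + 1, 1) - 1L
          if (x + y > 0L) { nA[i] <- x; nB[i] <- y; break }
        }
      }
      population(nA = nA, nB = nB)
    },
    at_capacity = {
      population(nA = c(rep(K, cfg$NgA), rep(0L, cfg$NgB)),
                 nB = c(rep(0L, cfg$NgA), rep(K, cfg$NgB)))
    })
}

#' Advance a population by one time step (reference implementation)
#'
#' Applies, in order: (1) one parallel reproduction draw for every group
#' below the splitting threshold; (2) at most one splitting event
#' ([select_splitter()] / [split_group()]); (3) at most one group death
#' ([death_probabilities()] / [sample_death()]), computed on the
#' post-split population. With
#' `event_order = "death_reproduction_split"` the death draw is taken
#' first instead. Extinct populations pass through unchanged.
#'
#' This pure-R implementation consumes random draws in exactly the same
#' order as the compiled loop used by [run_simulation()]; the two yield
#' identical trajectories from the same RNG state.
#'
#' @param pop A [population()].
#' @param cfg A [sim_config()].
#' @return The updated population, with attribute `"event"` one of
#'   `"none"`, `"split"`, `"abortive"`, `"death"`, or combinations
#'   joined by `"+"`.
#' @export
step_population <- function(pop, cfg) {
  nA <- pop$nA; nB <- pop$nB
  ev <- character()
  do_death <- function() {
    if (length(nA) == 0L) return(FALSE)
    probs <- death_probabilities(nA, nB, cfg$mu, cfg$a, cfg$mode)
    j <- sample_death(probs)
    if (!is.na(j)) {
      nA <<- nA[-j]; nB <<- nB[-j]
      TRUE
    } else FALSE
  }
  if (length(nA) > 0L) {
    death_first <- cfg$event_order == "death_reproduction_split"
    if (death_first && do_death()) ev <- c(ev, "death")
    # parallel reproduction
    if (length(nA) > 0L) {
      kk <- cfg$K * cfg$K
      for (j in seq_along(nA)) {
        n <- nA[j] + nB[j]
        if (n >= cfg$K) next
        free <- cfg$K - n
        pA <- (nA[j] * free) / kk
        pB <- (cfg$b * (nB[j] * free)) / kk
        u <- runif(1)
        if (u < pA) nA[j] <- nA[j] + 1L
        else if (u < pA + pB) nB[j] <- nB[j] + 1L
      }
    }
    # one split
    j <- select_splitter(nA, nB, cfg$K, cfg$Kg)
    if (!is.na(j)) {
      out <- split_group(nA[j], nB[j], cfg$K)
      if (out$kind == "two_daughters") {
        d1 <- out$daughters[[1]]; d2 <- out$daughters[[2]]
        nA[j] <- d1[["nA"]]; nB[j] <- d1[["nB"]]
        nA <- c(nA, d2[["nA"]]); nB <- c(nB, d2[["nB"]])
        ev <- c(ev, "split")
      } else {
        ev <- c(ev, "abortive")
      }
    }
    if (!death_first && do_death()) ev <- c(ev, "death")
  }
  out <- population(nA, nB, pop$t + 1L)
  attr(out, "event") <- if (length(ev)) paste(ev, collapse = "+") else "none"
  out
}

#' Run one replicate with the compiled core
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for this replicate (defaults to `cfg$seed`). Set to
#'   `NULL` to continue from the current RNG state.
#' @param pop Optional starting [population()]; defaults to
#'   [init_population()] under the same RNG stream.
#' @return A data frame of class `"trajectory"` with columns `t`, `Ng`,
#'   `Ng_allA`, `Ng_allB`, `sum_nA`, `sum_nB`, `event`, plus attributes
#'   `final` (the final [population()]) and `stopped`.
#' @export
run_simulation <- function(cfg, seed = cfg$seed, pop = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pop)) pop <- init_population(cfg)
  mode_i <- match(cfg$mode, c("neutral", "relative", "absolute")) - 1L
  stop_i <- match(cfg$stop_on, c("none", "extinct", "homogeneous")) - 1L
  res <- cpp_run_sim(pop$nA, pop$nB, cfg$K, cfg$b, cfg$mu, cfg$a,
                     mode_i, cfg$Kg, cfg$T,
                     cfg$event_order == "death_reproduction_split",
                     cfg$record_every, stop_i)
  traj <- as.data.frame(res$traj)
  traj$event <- c("none", "split", "abortive", "abortive", "death",
                  "split+death", "abortive+death",
                  "abortive+death")[traj$event + 1L]
  attr(traj, "final") <- population(res$nA, res$nB, res$t)
  attr(traj, "stopped") <- res$stopped
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Derive a replicate seed from a root seed and counter
#'
#' Deterministic counter-based derivation kept below 2^31 so the same
#' root seed always reproduces the same replicate streams.
#'
#' @param root Root seed (integer).
#' @param i Counter (replicate or grid-cell index).
#' @return Integer seed.
#' @export
derive_seed <- function(root, i) {
  as.integer((as.double(root) * 69069 + as.double(i) * 104729) %% 2147483629 + 1)
}

#' Run independent replicates
#'
#' Runs `cfg$M` replicates, each on an independent RNG stream derived
#' from `cfg$seed` and the replicate counter via [derive_seed()].
#' Identical configurations reproduce identical trajectories.
#'
#' @param cfg A [sim_config()].
#' @return List of `"trajectory"` data frames (class
#'   `"trajectory_set"`), with the configuration attached as attribute
#'   `"config"`.
#' @export
run_replicates <- function(cfg) {
  out <- lapply(seq_len(cfg$M), function(i) {
    run_simulation(cfg, seed = derive_seed(cfg$seed, i))
  })
  attr(out, "config") <- cfg
  class(out) <- "trajectory_set"
  out
}

traj_state_at <- function(traj, T = NULL) {
  # last recorded row at or before T (final row if T is NULL)
  if (is.null(T)) return(traj[nrow(traj), , drop = FALSE])
  rows <- which(traj$t <= T)
  traj[rows[length(rows)], , drop = FALSE]
}

#' Fraction of replicates surviving to a sampling time
#'
#' The survival indicator averaged over replicates:
#' \eqn{\langle\Theta\rangle = M^{-1}\sum_\alpha 1[N_g^{(\alpha)}(T)>0]}.
#' A value of 1 means extinction was never observed up to `T`.
#'
#' @param trajs A `"trajectory_set"` from [run_replicates()].
#' @param T Sampling time (default: each trajectory's final time).
#' @return Fraction in `[0, 1]`.
#' @export
theta_mean <- function(trajs, T = NULL) {
  mean(vapply(trajs, function(tr) traj_state_at(tr, T)$Ng > 0, logical(1)))
}

#' Group-level outcome statistic
#'
#' \eqn{S = 2 N_{g,A}/N_g - 1} where `Ng_allA` counts groups with no
#' asocial individuals; 0 for an extinct population. `S = 1` when every
#' group is purely social, `-1` when every group is purely asocial.
#'
#' @param x A [population()], or a `"trajectory"` row / data frame (its
#'   last recorded row at or before `T` is used).
#' @param T Optional sampling time for trajectories.
#' @return Value in `[-1, 1]`.
#' @export
s_statistic <- function(x, T = NULL) {
  if (inherits(x, "population")) {
    ng <- length(x$nA)
    if (ng == 0L) return(0)
    return(2 * sum(x$nB == 0L) / ng - 1)
  }
  row <- traj_state_at(x, T)
  if (row$Ng == 0) 0 else 2 * row$Ng_allA / row$Ng - 1
}

#' Individual-level composition statistic
#'
#' \eqn{2\sum n_A / (\sum n_A + \sum n_B) - 1} over all groups; 0 for an
#' extinct population. Used for heterogeneous-group runs where group
#' purity is not informative.
#'
#' @inheritParams s_statistic
#' @return Value in `[-1, 1]`.
#' @export
composition_statistic <- function(x, T = NULL) {
  if (inherits(x, "population")) {
    tot <- sum(x$nA) + sum(x$nB)
    if (tot == 0L) return(0)
    return(2 * sum(x$nA) / tot - 1)
  }
  row <- traj_state_at(x, T)
  tot <- row$sum_nA + row$sum_nB
  if (tot == 0) 0 else 2 * row$sum_nA / tot - 1
}

#' Column average of an outcome heatmap over the social trait
#'
#' Averages the mean outcome statistic over all values of the social
#' trait `a` at each fixed `b`, collapsing a `(a, b)` sweep to a profile
#' in `b`.
#'
#' @param sweep_df Long-format data frame with columns `a`, `b`,
#'   `mean_S` (as returned by [sweep_S()]).
#' @return Data frame with columns `b`, `S_a`.
#' @export
s_mean_over_a <- function(sweep_df) {
  out <- aggregate(mean_S ~ b, data = sweep_df, FUN = mean)
  names(out) <- c("b", "S_a")
  out[order(out$b), , drop = FALSE]
}
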