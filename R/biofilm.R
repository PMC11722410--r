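#' Biofilm model parameters
#'
#' Parameter set for the off-lattice biofilm agent-based model. Cells
#' interact through a pairwise pseudo-force
#' \eqn{H/d^6 - \bar G/d^2} (positive = repulsive) with
#' \eqn{\bar G = (G(p)+G(q))/2}; the attractive constant of asocial
#' (non-producing) cells is fixed by requiring zero net force at the
#' anchor spacing `D` (\eqn{H/D^6 - G/D^2 = 0}, so `G = H/D^4`), and
#' matrix production multiplies it by `G_fold`. Substrate anchors use
#' the same force law with the attraction constant replaced by `G/2`
#' (baseline `G` by default; set `substrate_by_phenotype = TRUE` to use
#' each cell's own `G/2` instead). Division is logistic and Poisson with
#' per-capita rate `r (1 - N/K_BF)`; matrix producers divide `r_fold`
#' times slower. Removal acts only on the predation interface (topmost
#' cell per `D`-sized substrate window) at rate `L` per interface cell.
#'
#' The substrate is a square grid of `n_side^2` anchor points with
#' spacing `D` centred at the origin. The default `n_side` scales with
#' the relaxed biofilm footprint, `20` at the reference carrying
#' capacity of 500 cells (grid side about twice the footprint), shrunk
#' as `sqrt(K_BF/500)` for reduced capacities.
#'
#' @param K_BF Carrying capacity (cells).
#' @param n_side Anchors per grid side (default: footprint scaling rule).
#' @param D Anchor spacing; the length unit and per-step speed.
#' @param H Repulsive force constant.
#' @param G_fold Fold increase of the attractive constant for matrix
#'   producers.
#' @param F Motion randomization weight in `[0, 1]`.
#' @param r_asocial Asocial division rate per unit time (`log(2)`:
#'   doubling time 1 far from capacity).
#' @param r_fold Fold decrease of the division rate for producers.
#' @param L Interface death rate per unit time.
#' @param dt Time step in units of the asocial doubling time.
#' @param jitter Uniqueness displacement magnitude (fraction of `D`,
#'   uniform per axis).
#' @param substrate_by_phenotype Use the cell's own `G/2` for anchors.
#' @param renormalize_direction Rescale the blended direction vector
#'   `(1-F) u_force + F u_rand` to unit length before moving by `D`
#'   (default), so every cell moves at exactly one grid spacing per
#'   step; `FALSE` moves by `D` times the blend length, slowing cells
#'   whose force and random directions disagree.
#' @return List of class `"biofilm_params"` (includes the derived
#'   constants `G_asocial`, `G_social`, `G_substrate`, `r_social` and
#'   the anchor coordinate matrix `anchors`).
#' @export
biofilm_params <- function(K_BF = 500, n_side = NULL, D = 1, H = 1,
                           G_fold = 100, F = 0.5,
                           r_asocial = log(2), r_fold = 5,
                           L = 0.1, dt = 0.01, jitter = 1e-6,
                           substrate_by_phenotype = FALSE,
                           renormalize_direction = TRUE) {
  stopifnot(K_BF >= 1, D > 0, H > 0, F >= 0, F <= 1, dt > 0, L >= 0)
  if (is.null(n_side)) n_side <- max(6L, ceiling(20 * sqrt(K_BF / 500)))
  G_asocial <- H / D^4
  coords <- (seq_len(n_side) - (n_side + 1) / 2) * D
  anchors <- as.matrix(expand.grid(x = coords, y = coords))
  structure(list(K_BF = K_BF, n_side = as.integer(n_side), D = D, H = H,
                 F = F, G_asocial = G_asocial,
                 G_social = G_fold * G_asocial,
                 G_substrate = G_asocial / 2,
                 r_asocial = r_asocial, r_social = r_asocial / r_fold,
                 L = L, dt = dt, jitter = jitter,
                 substrate_by_phenotype = substrate_by_phenotype,
                 renormalize_direction = renormalize_direction,
                 anchors = anchors),
            class = "biofilm_params")
}

#' Pairwise pseudo-force between two cells (reference implementation)
#'
#' Force exerted on cell `p` by cell `q`:
#' \eqn{(H/d^6 - \bar G/d^2)\,\hat r_{pq}} with
#' \eqn{\bar G = (G_p+G_q)/2} and \eqn{\hat r_{pq}} the unit vector from
#' `q` to `p` (positive magnitude = repulsion). Antisymmetric under
#' exchange of `p` and `q`.
#'
#' @param p,q Coordinate vectors (same length).
#' @param Gp,Gq Attractive constants of the two cells.
#' @param H Repulsive constant.
#' @return Force vector acting on `p`.
#' @export
pairwise_force <- function(p, q, Gp, Gq, H = 1) {
  d2 <- sum((p - q)^2)
  if (d2 <= 0) stop("coincident cells")
  f <- H / d2^3 - 0.5 * (Gp + Gq) / d2
  f * (p - q) / sqrt(d2)
}

#' Net substrate pseudo-force on a cell (reference implementation)
#'
#' Sum over all anchors of the pair force law with attraction constant
#' `Gsub` (the baseline `G/2` by default).
#'
#' @param p Cell coordinates (length 3, substrate at `z = 0`).
#' @param anchors Matrix of anchor `(x, y)` coordinates.
#' @param Gsub Substrate attraction constant.
#' @param H Repulsive constant.
#' @return Force vector acting on `p`.
#' @export
substrate_force <- function(p, anchors, Gsub, H = 1) {
  out <- c(0, 0, 0)
  for (k in seq_len(nrow(anchors))) {
    out <- out + pairwise_force(p, c(anchors[k, 1], anchors[k, 2], 0),
                                Gp = Gsub * 2, Gq = 0, H = H)
  }
  out
}

#' Predation interface of a cell configuration
#'
#' Partitions the horizontal plane into `D`-sized windows aligned with
#' the anchor grid and returns, for each occupied window, the index of
#' the cell with the largest vertical coordinate. Only these cells are
#' exposed to removal.
#'
#' @param pos `N x 3` coordinate matrix.
#' @param D Window size (anchor spacing).
#' @return Integer vector of interface cell indices.
#' @export
predation_interface <- function(pos, D = 1) {
  cpp_bf_interface(pos, D)
}

bf_state <- function(pos, social, t = 0L) {
  structure(list(pos = pos, social = as.integer(social), t = as.integer(t)),
            class = "biofilm_state")
}

#' @export
print.biofilm_state <- function(x, ...) {
  cat("<biofilm_state> t =", x$t, " n =", nrow(x$pos),
      " social =", sum(x$social), "\n")
  invisible(x)
}

bf_init_cells <- function(n, par, social = 0L) {
  # uniform positions in a cube over the central square of width 5% of
  # the substrate extent; relaxation settles them onto the substrate
  extent <- (par$n_side - 1) * par$D
  w <- max(0.05 * extent, par$D * 0.5)
  pos <- cbind(runif(n, -w / 2, w / 2), runif(n, -w / 2, w / 2),
               runif(n, 0, w))
  bf_state(pos, rep(social, n))
}

bf_run <- function(state, par, steps, F_weight = par$F,
                   division = TRUE, removal = TRUE,
                   record_every = 100L, stop_mode = 0L, stop_above = 0L) {
  res <- cpp_biofilm_run(state$pos, state$social, par$anchors,
                         unclass(par), as.integer(steps), F_weight,
                         division, removal, as.integer(record_every),
                         as.integer(stop_mode), as.integer(stop_above))
  list(state = bf_state(res$pos, res$social, state$t + res$t),
       series = as.data.frame(res$series),
       stopped = res$stopped)
}

#' Steady-state biofilm simulation
#'
#' Initializes `K_BF` cells of one phenotype in a central column,
#' relaxes positions for `relax_steps` deterministic motion steps
#' (`F = 0`, no division or removal), then runs the full dynamics and
#' records the population size series.
#'
#' @param par A [biofilm_params()].
#' @param phenotype `"asocial"` or `"social"`.
#' @param relax_steps Relaxation steps (motion only).
#' @param steps Full-dynamics steps.
#' @param record_every Series recording stride.
#' @param seed RNG seed (`NULL` to continue the current stream).
#' @return List with `state` (final `"biofilm_state"`), `series` (data
#'   frame `t, n, n_social, n_asocial, interface_size`) and `outcome`
#'   (final cell count).
#' @export
biofilm_steady_state <- function(par, phenotype = c("asocial", "social"),
                                 relax_steps = 1000, steps = 20000,
                                 record_every = 100L, seed = NULL) {
  phenotype <- match.arg(phenotype)
  if (!is.null(seed)) set.seed(seed)
  st <- bf_init_cells(par$K_BF, par, social = (phenotype == "social"))
  relax <- bf_run(st, par, relax_steps, F_weight = 0,
                  division = FALSE, removal = FALSE, record_every = 0L)
  full <- bf_run(relax$state, par, steps, record_every = record_every)
  list(state = full$state, series = full$series,
       outcome = nrow(full$state$pos))
}

#' Biofilm seeding simulation
#'
#' A single founder cell anchors to the substrate (relaxation phase)
#' and the full dynamics run until the colony exceeds `stop_size` cells
#' (`"success"`) or goes extinct (`"extinct"`).
#'
#' @inheritParams biofilm_steady_state
#' @param stop_size Success threshold on the cell count.
#' @param max_steps Safety cap on full-dynamics steps; hitting it yields
#'   outcome `"timeout"`.
#' @return List with `outcome` (`"success"`, `"extinct"` or
#'   `"timeout"`), `series`, and `state`.
#' @export
biofilm_seeding <- function(par, phenotype = c("asocial", "social"),
                            relax_steps = 1000, stop_size = 300,
                            max_steps = 200000, record_every = 100L,
                            seed = NULL) {
  phenotype <- match.arg(phenotype)
  if (!is.null(seed)) set.seed(seed)
  st <- bf_init_cells(1L, par, social = (phenotype == "social"))
  relax <- bf_run(st, par, relax_steps, F_weight = 0,
                  division = FALSE, removal = FALSE, record_every = 0L)
  full <- bf_run(relax$state, par, max_steps, record_every = record_every,
                 stop_mode = 1L, stop_above = stop_size)
  n <- nrow(full$state$pos)
  outcome <- if (n > stop_size) "success"
             else if (n == 0) "extinct" else "timeout"
  list(outcome = outcome, series = full$series, state = full$state)
}

#' Fixation of a matrix-production mutation in an asocial biofilm
#'
#' Starting from an asocial steady-state configuration, one uniformly
#' chosen cell is relabelled as a matrix producer and the dynamics run
#' until the biofilm homogenizes or goes extinct.
#'
#' @inheritParams biofilm_steady_state
#' @param seed_state Optional `"biofilm_state"` to start from (e.g. the
#'   `state` of [biofilm_steady_state()]); by default a fresh asocial
#'   steady state is generated with `prep_relax`/`prep_steps` motion.
#' @param prep_relax,prep_steps Steps used to generate the seed state
#'   when `seed_state` is `NULL`.
#' @param max_steps Safety cap; hitting it yields outcome `"timeout"`.
#' @return List with `outcome` (`"social_fixed"`, `"asocial_fixed"`,
#'   `"extinct"` or `"timeout"`), `series`, and `state`.
#' @export
biofilm_fixation <- function(par, seed_state = NULL,
                             prep_relax = 1000, prep_steps = 20000,
                             max_steps = 2000000, record_every = 200L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(seed_state)) {
    seed_state <- biofilm_steady_state(par, "asocial",
                                       relax_steps = prep_relax,
                                       steps = prep_steps,
                                       record_every = 0L)$state
  }
  st <- seed_state
  st$social <- rep(0L, nrow(st$pos))
  mut <- sample.int(nrow(st$pos), 1L)
  st$social[mut] <- 1L
  full <- bf_run(st, par, max_steps, record_every = record_every,
                 stop_mode = 2L)
  ns <- sum(full$state$social)
  n <- nrow(full$state$pos)
  outcome <- if (n == 0) "extinct"
             else if (ns == n) "social_fixed"
             else if (ns == 0) "asocial_fixed"
             else "timeout"
  list(outcome = outcome, series = full$series, state = full$state)
}
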