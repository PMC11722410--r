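cell_cfg_seed <- function(seed, cell) derive_seed(seed, 1000L + cell)

#' Survival-map sweep over death probability and splitting threshold
#'
#' For every `(mu, K)` grid cell, runs `M` neutral-case replicates of `T`
#' steps from `Ng` single-type groups with sizes uniform on `1..K-1`, and
#' records the surviving fraction [theta_mean()]. Analytic proliferation
#' boundaries (high-survival limit, [neutral_threshold()]; and numeric,
#' [solve_threshold_numeric()]) are attached for overlay.
#'
#' @param mu_grid,K_grid Grid values.
#' @param Ng Initial number of groups.
#' @param b Reproduction scale factor.
#' @param Kg Group carrying capacity.
#' @param M,T Replicates and steps per cell.
#' @param seed Root seed; each cell gets a derived stream.
#' @return Data frame `(mu, K, theta, n_replicates)`; attribute
#'   `"curves"` holds `(K, mu_star_high_delta, mu_star_numeric)`.
#' @export
sweep_theta <- function(mu_grid, K_grid, Ng = 50, b = 1, Kg = 150,
                        M = 50, T = 1000, seed = 1L) {
  grid <- expand.grid(mu = mu_grid, K = K_grid)
  theta <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- sim_config(K = grid$K[i], b = b, mu = grid$mu[i], Kg = Kg,
                      mode = "neutral", init = "neutral_uniform",
                      Ng = Ng, T = T, M = M,
                      seed = cell_cfg_seed(seed, i),
                      record_every = 0L, stop_on = "extinct")
    theta_mean(run_replicates(cfg))
  }, numeric(1))
  out <- data.frame(grid, theta = theta, n_replicates = M)
  curves <- data.frame(
    K = K_grid,
    mu_star_high_delta = vapply(K_grid, function(k) {
      suppressWarnings(as.numeric(neutral_threshold(K = k, b = b, Ng = Ng)))
    }, numeric(1)),
    mu_star_numeric = vapply(K_grid, function(k) {
      as.numeric(solve_threshold_numeric(K = k, Ng = Ng, b = b))
    }, numeric(1)))
  attr(out, "curves") <- curves
  out
}

#' Competition heatmap over social trait strength and cheater advantage
#'
#' For every `(a, b)` cell, runs `M` replicates and records the mean
#' outcome statistic at sampling time `T`: the group-purity statistic
#' [s_statistic()] for homogeneous initialization, or the
#' individual-composition statistic [composition_statistic()] for
#' heterogeneous initialization. Numeric `psi = 1/2` curves and
#' high-survival thresholds are attached for overlay.
#'
#' @param a_grid,b_grid Grid values.
#' @param mode `"relative"` or `"absolute"`.
#' @param init `"homogeneous"` (equal numbers `NgA`, `Ng - NgA` of pure
#'   groups) or `"heterogeneous"`.
#' @param mu Group death probability.
#' @param K Splitting threshold.
#' @param Ng Initial number of groups.
#' @param NgA Initial number of all-social groups (homogeneous init).
#' @param Kg Group carrying capacity.
#' @param M,T Replicates and steps per cell.
#' @param seed Root seed.
#' @return Data frame `(a, b, mean_S, n_replicates)`; attributes
#'   `"curves"` (numeric psi-half curves, see [psi_half_curves()]) and
#'   `"thresholds"` ([competition_thresholds()] output).
#' @export
sweep_S <- function(a_grid, b_grid, mode = c("relative", "absolute"),
                    init = c("homogeneous", "heterogeneous"),
                    mu = 0.7, K = 10, Ng = 20, NgA = 10, Kg = 70,
                    M = 50, T = 3000, seed = 1L) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  grid <- expand.grid(a = a_grid, b = b_grid)
  stat_fun <- if (init == "homogeneous") s_statistic else composition_statistic
  mean_S <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- if (init == "homogeneous") {
      sim_config(K = K, b = grid$b[i], mu = mu, a = grid$a[i], Kg = Kg,
                 mode = mode, init = "homogeneous_mix",
                 NgA = NgA, NgB = Ng - NgA, T = T, M = M,
                 seed = cell_cfg_seed(seed, i),
                 record_every = 0L)
    } else {
      sim_config(K = K, b = grid$b[i], mu = mu, a = grid$a[i], Kg = Kg,
                 mode = mode, init = "heterogeneous",
                 Ng = Ng, T = T, M = M,
                 seed = cell_cfg_seed(seed, i),
                 record_every = 0L)
    }
    mean(vapply(run_replicates(cfg), stat_fun, numeric(1)))
  }, numeric(1))
  out <- data.frame(grid, mean_S = mean_S, n_replicates = M)
  attr(out, "curves") <- psi_half_curves(
    mode, "ab", mu = mu, K = K, Ng = Ng, NgA = NgA,
    a_grid = sort(unique(a_grid)))
  attr(out, "thresholds") <- competition_thresholds(
    mode, mu = mu, K = K, Ng = Ng,
    NgA = if (mode == "relative") NgA else NULL)
  out
}

#' Competition outcome over splitting threshold and initial group number
#'
#' For every `(K, Ng)` cell (with `NgA = floor(frac_A * Ng)` all-social
#' and the rest all-asocial groups), records the mean outcome statistic
#' and the surviving fraction. Numeric and high-survival threshold
#' curves of `Ng` versus `K` are attached.
#'
#' @inheritParams sweep_S
#' @param K_grid,Ng_grid Grid values.
#' @param a,b Social trait strength and cheater advantage (fixed).
#' @param frac_A Initial fraction of all-social groups.
#' @return Data frame `(K, Ng, mean_S, theta, n_replicates)`; attribute
#'   `"curves"` holds the psi-half `Ng(K)` curves (numeric and
#'   high-survival).
#' @export
sweep_KNg <- function(K_grid, Ng_grid, mode = c("relative", "absolute"),
                      mu = 0.7, a = 0.4, b = 4, Kg = 150, frac_A = 0.5,
                      M = 50, T = 5000, seed = 1L) {
  mode <- match.arg(mode)
  grid <- expand.grid(K = K_grid, Ng = Ng_grid)
  res <- t(vapply(seq_len(nrow(grid)), function(i) {
    NgA <- floor(frac_A * grid$Ng[i])
    cfg <- sim_config(K = grid$K[i], b = b, mu = mu, a = a, Kg = Kg,
                      mode = mode, init = "homogeneous_mix",
                      NgA = NgA, NgB = grid$Ng[i] - NgA, T = T, M = M,
                      seed = cell_cfg_seed(seed, i), record_every = 0L)
    trs <- run_replicates(cfg)
    c(mean(vapply(trs, s_statistic, numeric(1))), theta_mean(trs))
  }, numeric(2)))
  out <- data.frame(grid, mean_S = res[, 1], theta = res[, 2],
                    n_replicates = M)
  numeric_curves <- psi_half_curves(mode, "KNg", mu = mu, a = a, b = b,
                                    K_grid = K_grid, frac_A = frac_A)
  hd <- lapply(K_grid, function(k) {
    # high-survival thresholds: Ng solving psi_A = 1/2 (b = 1) and
    # psi_B = 1/2 at the given b, from the linearized expansion
    hk2 <- 2 * mu * harmonic(k - 1) * k^2
    if (mode == "relative") {
      # delta_A = 1 - mu(1-a)/(Ng - a frac_A Ng): 1 - delta_A = (1-deltaA*)
      NgA_half <- hk2 * (1 - a) / ((k - 1) * (1 - a * frac_A))
      NgB_half <- hk2 / (b * (k - 1) * (1 - a * frac_A))
    } else {
      NgA_half <- hk2 * (1 - a) / (k - 1)
      NgB_half <- hk2 / (b * (k - 1))
    }
    c(NgA_half, NgB_half)
  })
  curves <- data.frame(numeric_curves,
                       Ng_A_half_hd = vapply(hd, `[`, numeric(1), 1),
                       Ng_B_half_hd = vapply(hd, `[`, numeric(1), 2))
  attr(out, "curves") <- curves
  out
}

#' Extinction-through-sociality scenario
#'
#' Reproduces the resource-limited regime in which the group carrying
#' capacity supports a homogeneous asocial population
#' (`psi_B(delta(Kg)) > 1/2`) but not a homogeneous social one
#' (`psi_A(delta(Kg)) < 1/2`). Three initializations are run: mixed
#' homogeneous groups (equal all-social and all-asocial counts),
#' all-asocial only, and heterogeneous groups. In the mixed runs the
#' population grows to capacity on the back of the fast-splitting
#' asocial groups, social groups then outcompete them, and the
#' homogenized social population collapses; the all-asocial control
#' persists.
#'
#' @inheritParams sweep_S
#' @param Ng Initial number of groups.
#' @param warn_only If the shipped precondition check fails for
#'   user-supplied parameters, warn and still run (default) or stop.
#' @return List with elements `mixed`, `allB`, `heterogeneous`
#'   (trajectory sets), `precondition` (named logical vector), and
#'   `summary` (per-initialization extinction fraction at `T`).
#' @export
scenario_extinction_by_sociality <- function(mu = 0.5, a = 0.75, b = 4,
                                             K = 20, Ng = 30, Kg = 45,
                                             M = 50, T = 5000, seed = 1L,
                                             warn_only = TRUE) {
  d_cap <- survival_probs("relative", Ng = Kg, NgA = 0, mu = mu, a = a)
  psiA <- psi_avg(1 - mu / Kg, K, b = 1)  # homogeneous all-A population
  psiB <- psi_avg(d_cap[["delta_B"]], K, b = b)
  pre <- c(psi_B_above_half = psiB > 0.5, psi_A_below_half = psiA < 0.5)
  if (!all(pre)) {
    msg <- "parameters do not satisfy psi_B > 1/2 > psi_A at capacity"
    if (warn_only) warning(msg) else stop(msg)
  }
  half <- Ng %/% 2
  run3 <- function(init, off, NgA, NgB) {
    cfg <- if (init == "heterogeneous") {
      sim_config(K = K, b = b, mu = mu, a = a, Kg = Kg, mode = "relative",
                 init = "heterogeneous", Ng = Ng, T = T, M = M,
                 seed = derive_seed(seed, off), record_every = 10L)
    } else {
      sim_config(K = K, b = b, mu = mu, a = a, Kg = Kg, mode = "relative",
                 init = "homogeneous_mix", NgA = NgA, NgB = NgB,
                 T = T, M = M, seed = derive_seed(seed, off),
                 record_every = 10L)
    }
    run_replicates(cfg)
  }
  mixed <- run3("homogeneous_mix", 1L, half, Ng - half)
  allB <- run3("homogeneous_mix", 2L, 0L, Ng)
  het <- run3("heterogeneous", 3L, NULL, NULL)
  summary <- data.frame(
    init = c("mixed", "allB", "heterogeneous"),
    extinct_fraction = c(1 - theta_mean(mixed), 1 - theta_mean(allB),
                         1 - theta_mean(het)))
  list(mixed = mixed, allB = allB, heterogeneous = het,
       precondition = pre, summary = summary)
}

#' Mean asocial-individual fraction over time across replicates
#'
#' Averages `sum_nB / (sum_nA + sum_nB)` over the replicates still alive
#' at each recorded time.
#'
#' @param trajs A `"trajectory_set"`.
#' @return Data frame `(t, B_fraction, n_alive)`.
#' @export
b_fraction_series <- function(trajs) {
  all <- do.call(rbind, lapply(trajs, function(tr) {
    tot <- tr$sum_nA + tr$sum_nB
    data.frame(t = tr$t, frac = ifelse(tot > 0, tr$sum_nB / tot, NA),
               alive = tot > 0)
  }))
  agg <- aggregate(cbind(frac, alive) ~ t, data = all,
                   FUN = function(x) mean(x, na.rm = TRUE),
                   na.action = NULL)
  data.frame(t = agg$t, B_fraction = agg$frac,
             n_alive = agg$alive * length(trajs))
}

#' Write a trajectory set to per-replicate CSV files plus a manifest
#'
#' @param trajs A `"trajectory_set"` from [run_replicates()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_trajectories <- function(trajs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(trajs)) {
    write.csv(trajs[[i]],
              file.path(dir, sprintf("replicate_%03d.csv", i)),
              row.names = FALSE)
  }
  cfg <- attr(trajs, "config")
  manifest <- c(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                list(n_replicates = length(trajs),
                     package_version = as.character(
                       utils::packageVersion("mlscoop"))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
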