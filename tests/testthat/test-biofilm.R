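test_that("pairwise pseudo-force has the right zeros, signs and symmetry", {
  par <- biofilm_params()
  # asocial pair at the anchor spacing: exact force balance
  f <- pairwise_force(c(0, 0, 1), c(1, 0, 1), par$G_asocial, par$G_asocial)
  expect_equal(f, c(0, 0, 0))
  # producer pair at the same distance: net attraction of magnitude 99 G
  f <- pairwise_force(c(0, 0, 1), c(1, 0, 1), par$G_social, par$G_social)
  expect_equal(f, c(99 * par$G_asocial, 0, 0))  # pulls p toward q
  # short range: strong repulsion regardless of phenotype
  f <- pairwise_force(c(0, 0, 0.1), c(0, 0, 0.2), par$G_social, par$G_social)
  expect_lt(f[3], 0)  # pushed away from the cell above
  # antisymmetry
  set.seed(51)
  for (i in 1:20) {
    p <- runif(3); q <- runif(3) + 1
    fpq <- pairwise_force(p, q, par$G_social, par$G_asocial)
    fqp <- pairwise_force(q, p, par$G_asocial, par$G_social)
    expect_equal(fpq, -fqp)
  }
  expect_error(pairwise_force(p, p, 1, 1), "coincident")
})

test_that("substrate force sums the anchor lattice correctly", {
  par <- biofilm_params()
  # single anchor directly below at distance D: repulsive residue G/2
  one <- matrix(c(0, 0), 1)
  f <- substrate_force(c(0, 0, 1), one, Gsub = par$G_substrate)
  expect_equal(f, c(0, 0, par$H - par$G_substrate))  # = +G/2 with H = G
  # symmetric between four anchors: horizontal components cancel
  four <- rbind(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))
  f <- substrate_force(c(0, 0, 0.7), four, Gsub = par$G_substrate)
  expect_lt(max(abs(f[1:2])), 1e-12)
  # far above the lattice: net attraction downward
  f <- substrate_force(c(0.3, -0.2, 8), par$anchors, Gsub = par$G_substrate)
  expect_lt(f[3], 0)
})

test_that("compiled net forces equal the summed reference forces", {
  par <- biofilm_params(K_BF = 20, n_side = 6)
  set.seed(52)
  n <- 12
  pos <- cbind(runif(n, -2, 2), runif(n, -2, 2), runif(n, 0.2, 3))
  soc <- sample(0:1, n, replace = TRUE)
  Gv <- ifelse(soc == 1, par$G_social, par$G_asocial)
  got <- mlscoop:::cpp_bf_forces(pos, soc, par$anchors, unclass(par))
  for (i in seq_len(n)) {
    want <- substrate_force(pos[i, ], par$anchors, par$G_substrate)
    for (j in seq_len(n)[-i]) {
      want <- want + pairwise_force(pos[i, ], pos[j, ], Gv[i], Gv[j])
    }
    expect_lt(max(abs(got[i, ] - want)), 1e-9)
  }
})

test_that("predation interface keeps the topmost cell per window", {
  # vertical stack: only the top cell is exposed
  pos <- rbind(c(0.5, 0.5, 0.3), c(0.52, 0.48, 1.1), c(0.49, 0.51, 2.2))
  expect_equal(predation_interface(pos), 3L)
  # single cell is always the interface
  expect_equal(predation_interface(matrix(c(3.2, -1.1, 0.4), 1)), 1L)
  # one interface cell per occupied window
  set.seed(53)
  pos <- cbind(runif(200, 0, 5), runif(200, 0, 5), runif(200, 0, 3))
  iface <- predation_interface(pos)
  wins <- unique(paste(floor(pos[, 1]), floor(pos[, 2])))
  expect_equal(length(iface), length(wins))
  expect_true(all(pos[iface, 3] >= 0))
})

test_that("motion conserves cells, respects the substrate, breaks ties", {
  par <- biofilm_params(K_BF = 40)
  set.seed(54)
  st <- mlscoop:::bf_init_cells(40, par)
  out <- mlscoop:::bf_run(st, par, 300, division = FALSE, removal = FALSE,
                          record_every = 50)
  expect_equal(nrow(out$state$pos), 40)       # no birth or death
  expect_true(all(out$state$pos[, 3] >= 0))   # reflective boundary
  expect_equal(unique(out$series$n), 40L)
  # uniqueness jitter keeps positions distinct
  expect_equal(nrow(unique(out$state$pos)), 40)
})

test_that("division is logistic, Poisson, and five-fold slower for producers", {
  set.seed(55)
  # at carrying capacity the expected division count is zero
  par <- biofilm_params(K_BF = 30)
  st <- mlscoop:::bf_init_cells(30, par)
  out <- mlscoop:::bf_run(st, par, 200, division = TRUE, removal = FALSE,
                          record_every = 0)
  expect_equal(nrow(out$state$pos), 30)
  # far from capacity an asocial colony doubles once per time unit
  par <- biofilm_params(K_BF = 1e6, n_side = 8)
  st <- mlscoop:::bf_init_cells(50, par)
  out <- mlscoop:::bf_run(st, par, 200, division = TRUE, removal = FALSE,
                          record_every = 0)
  rate <- log(nrow(out$state$pos) / 50) / 2   # 200 steps = 2 time units
  expect_lt(abs(rate - log(2)) / log(2), 0.25)
  # producers divide at a fifth of the rate
  sts <- mlscoop:::bf_init_cells(400, par, social = 1L)
  outs <- mlscoop:::bf_run(sts, par, 500, division = TRUE, removal = FALSE,
                           record_every = 0)
  rate_s <- log(nrow(outs$state$pos) / 400) / 5
  expect_lt(abs(rate_s - log(2) / 5) / (log(2) / 5), 0.3)
})

test_that("removal draws the prescribed Poisson count off the interface", {
  set.seed(56)
  par <- biofilm_params(K_BF = 200, L = 10)  # high rate for signal
  st <- mlscoop:::bf_init_cells(200, par)
  st <- mlscoop:::bf_run(st, par, 300, F_weight = 0, division = FALSE,
                         removal = FALSE, record_every = 0)$state
  out <- mlscoop:::bf_run(st, par, 400, division = FALSE, removal = TRUE,
                          record_every = 1)
  s <- out$series
  removed <- -diff(s$n)
  expect_true(all(removed >= 0))
  expect_true(all(removed <= s$interface_size[-nrow(s)]))
  expected <- sum(s$interface_size[-nrow(s)] * par$L * par$dt)
  total <- sum(removed)
  expect_lt(abs(total - expected), 3 * sqrt(expected))  # Poisson 3 SE
})

test_that("producer colonies expose a smaller fraction of cells to predation", {
  par <- biofilm_params(K_BF = 80)
  frac <- function(ph, seed) {
    ss <- biofilm_steady_state(par, ph, relax_steps = 400, steps = 4000,
                               record_every = 100, seed = seed)
    s <- ss$series
    s <- s[s$t > 2000, ]
    mean(s$interface_size / s$n)
  }
  e_soc <- vapply(1:5, function(i) frac("social", 60 + i), numeric(1))
  e_aso <- vapply(1:5, function(i) frac("asocial", 70 + i), numeric(1))
  expect_lt(mean(e_soc), mean(e_aso))
  expect_gt(mean(e_aso) / mean(e_soc), 1.5)
})

test_that("homogeneous colonies of the two phenotypes reach similar sizes", {
  par <- biofilm_params(K_BF = 80)
  final_n <- function(ph, seed) {
    nrow(biofilm_steady_state(par, ph, relax_steps = 400, steps = 4000,
                              record_every = 0, seed = seed)$state$pos)
  }
  n_soc <- vapply(1:8, function(i) final_n("social", 80 + i), numeric(1))
  n_aso <- vapply(1:8, function(i) final_n("asocial", 90 + i), numeric(1))
  # two-sample test must not separate the distributions at alpha = 0.01
  expect_gt(suppressWarnings(wilcox.test(n_soc, n_aso))$p.value, 0.01)
  expect_lt(abs(mean(n_soc) - mean(n_aso)) / mean(n_aso), 0.15)
})

test_that("seeding and fixation runs stop on their absorbing outcomes", {
  par <- biofilm_params(K_BF = 40, L = 0)
  # without predation a seeding run always succeeds
  r <- biofilm_seeding(par, "asocial", relax_steps = 50, stop_size = 25,
                       max_steps = 50000, seed = 99)
  expect_equal(r$outcome, "success")
  # fixation run terminates at homogenization and reports counts
  par2 <- biofilm_params(K_BF = 40)
  ss <- biofilm_steady_state(par2, "asocial", relax_steps = 300,
                             steps = 2000, record_every = 0, seed = 100)
  fx <- biofilm_fixation(par2, seed_state = ss$state, max_steps = 300000,
                         seed = 101)
  expect_true(fx$outcome %in%
                c("social_fixed", "asocial_fixed", "extinct", "timeout"))
  if (fx$outcome != "timeout") {
    ns <- sum(fx$state$social); n <- nrow(fx$state$pos)
    expect_true(n == 0 || ns == 0 || ns == n)
  }
})
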