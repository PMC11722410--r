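test_that("upward transition probability matches its definition", {
  expect_equal(t_up(0, 10), 0)
  expect_equal(t_up(10, 10), 0)
  expect_equal(t_up(5, 10), 0.25)
  expect_equal(t_up(3, 10), 0.21)
})

test_that("closed-form absorption probability equals the recursion solve", {
  # master oracle: product formula vs direct linear-system solution
  for (K in 2:12) {
    for (delta in c(0.5, 0.9, 0.99)) {
      for (b in c(1, 2, 4)) {
        expect_lt(max(abs(psi(1:K, delta, K, b) -
                          psi_recursion_solve(delta, K, b))), 1e-10)
      }
    }
  }
})

test_that("absorption probability hand cases and limits", {
  expect_equal(psi(1, delta = 0.8, K = 2), 0.5)
  expect_equal(psi(1:7, delta = 1, K = 7), rep(1, 7))
  expect_equal(psi_avg(1, 20), 1)
  expect_equal(psi_avg(0.9, 3), 5 / 9)  # psi_2 = 2/3, psi_1 = 4/9
  # psi_K = 1 by the empty product
  expect_equal(psi(9, 0.3, 9), 1)
})

test_that("absorption probability matches Monte-Carlo group simulations", {
  set.seed(41)
  for (case in list(c(6, 0.9, 1), c(10, 0.99, 4), c(4, 0.5, 2))) {
    K <- case[1]; delta <- case[2]; b <- case[3]
    n0 <- ceiling(K / 2)
    reps <- 4e4
    f <- mc_psi(n0, K, delta, b, reps)
    p <- psi(n0, delta, K, b)
    expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / reps))
  }
})

test_that("high-survival expansion is the true first-order limit", {
  for (K in c(3, 5, 10, 20)) {
    lim <- harmonic(K - 1) * K^2 / (2 * (K - 1))  # b = 2
    eps <- c(1e-4, 1e-5) / lim
    ratio <- (1 - vapply(1 - eps, psi_avg, numeric(1), K = K, b = 2)) / eps
    # slope converges to the limit as delta -> 1
    expect_lt(abs(ratio[2] - lim) / lim, abs(ratio[1] - lim) / lim)
    expect_lt(abs(ratio[2] - lim) / lim, 1e-3)
    expect_equal(psi_avg_high_delta(1, K, 2), 1)
  }
})

test_that("survival threshold delta* matches its closed form and ordering", {
  expect_equal(delta_star(2), 0.875)  # H_1 = 1: 1 - 1/8
  expect_equal(delta_star(10), 1 - 9 / (2 * harmonic(9) * 100))
  expect_lt(delta_star(10, b = 4), delta_star(10, b = 1))
  # the expansion threshold overestimates the true one by a bounded,
  # asymptotically constant margin at the psi = 1/2 level
  v <- psi_avg(delta_star(40), 40)
  expect_gt(v, 0.5)
  expect_lt(v, 0.75)
})

test_that("proliferation threshold relation and its monotonicities", {
  expect_equal(neutral_threshold(K = 10, Ng = 50),
               50 * 9 / (2 * harmonic(9) * 100))
  expect_lt(abs(neutral_threshold(K = 10, Ng = 50) - 0.79534), 1e-4)
  # linear in b
  expect_equal(suppressWarnings(as.numeric(neutral_threshold(K = 10, Ng = 50,
                                                             b = 4))),
               4 * as.numeric(neutral_threshold(K = 10, Ng = 50)))
  # threshold group number increases with K (larger groups need more groups)
  NgStar <- vapply(c(10, 20, 40), function(k) {
    neutral_threshold(K = k, mu = 0.7)
  }, numeric(1))
  expect_true(all(diff(NgStar) > 0))
  expect_warning(neutral_threshold(K = 10, Ng = 100), "exceeds 1")
})

test_that("numeric proliferation threshold self-checks and ordering", {
  for (K in c(2, 10)) {
    mu <- solve_threshold_numeric(K, Ng = 50)
    expect_lt(abs(psi_avg(1 - mu / 50, K) - 0.5), 1e-7)
  }
  roots <- vapply(c(5, 10, 20), solve_threshold_numeric, numeric(1), Ng = 50)
  expect_true(all(diff(roots) < 0))  # harder for larger K
})

test_that("psi_avg is monotone in delta and K", {
  deltas <- seq(0.5, 0.999, length.out = 20)
  vals <- vapply(deltas, psi_avg, numeric(1), K = 10)
  expect_true(all(diff(vals) > 0))
  Ks <- 3:15
  vals <- vapply(Ks, function(k) psi_avg(0.98, k), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("homogeneous survival probabilities and conservation identity", {
  d <- survival_probs("relative", Ng = 20, NgA = 10, mu = 0.7, a = 0.4)
  expect_equal(unname(d), c(0.97375, 0.95625))
  d0 <- survival_probs("relative", Ng = 20, NgA = 10, mu = 0.7, a = 0)
  expect_equal(unname(d0), rep(1 - 0.7 / 20, 2))
  da <- survival_probs("absolute", Ng = 20, NgA = 10, mu = 0.7, a = 0)
  expect_equal(unname(da), rep(1 - 0.7 / 20, 2))
  # total death probability independent of composition (relative regime)
  for (NgA in 0:20) {
    d <- survival_probs("relative", 20, NgA, 0.7, 0.4)
    expect_lt(abs(NgA * (1 - d[["delta_A"]]) +
                  (20 - NgA) * (1 - d[["delta_B"]]) - 0.7), 1e-12)
  }
  expect_error(survival_probs("relative", Ng = 2, NgA = 2, mu = 0.5, a = 1),
               "Ng - a")
})

test_that("competition thresholds reproduce the derived values", {
  th <- competition_thresholds("relative", mu = 0.7, K = 10, Ng = 20,
                               NgA = 10)
  expect_lt(abs(th$a_star - 0.70594), 1e-4)
  expect_lt(abs(th$b_star - 3.4006), 1e-3)
  tha <- competition_thresholds("absolute", mu = 0.7, K = 10, Ng = 20)
  expect_lt(abs(tha$a_star - 0.54552), 1e-4)
  expect_lt(abs(tha$b_star - 2.2003), 1e-3)
  # algebraic round trip: delta_A at a* sits exactly on the expansion's
  # half-absorption threshold
  dA <- survival_probs("relative", 20, 10, 0.7, th$a_star)[["delta_A"]]
  expect_lt(abs(psi_avg_high_delta(dA, 10, 1) - 0.5), 1e-9)
  dB <- survival_probs("relative", 20, 10, 0.7, th$a_star)[["delta_B"]]
  expect_lt(abs(psi_avg_high_delta(dB, 10, th$b_star) - 0.5), 1e-9)
})

test_that("numeric psi-half curves behave like the phase boundaries", {
  # cooperator threshold Ng exceeds the cheater threshold at every K
  cv <- psi_half_curves("relative", "KNg", mu = 0.7, a = 0.4, b = 4,
                        K_grid = seq(10, 30, by = 5))
  expect_true(all(cv$Ng_A_half > cv$Ng_B_half))
  # thresholds grow with K
  expect_true(all(diff(cv$Ng_A_half) > 0))
  expect_true(all(diff(cv$Ng_B_half) > 0))
  # (a, b) sweep: cells with no admissible root are flagged NA
  ab <- psi_half_curves("relative", "ab", mu = 0.7, K = 10, Ng = 20,
                        NgA = 10, a_grid = c(0, 0.5, 1))
  expect_equal(nrow(ab), 3)
  expect_true(is.finite(attr(ab, "a_half")) || is.na(attr(ab, "a_half")))
})

test_that("Moran-limit transitions match hand values and the bias ratio", {
  tr <- moran_limit_transitions("relative", NgA = 1, Kg = 2, mu = 0.1,
                                a = 0.5)
  expect_equal(unname(tr), c(1 / 60, 1 / 30))
  for (mode in c("relative", "absolute")) {
    for (a in c(0, 0.25, 0.8)) {
      tr <- moran_limit_transitions(mode, 7, 20, 0.05, a)
      expect_lt(abs(tr[["T_down"]] / tr[["T_up"]] - (1 - a)), 1e-12)
    }
  }
})

test_that("fixation probability equals the absorbing-chain solution", {
  expect_equal(fixation_probability(3, 10, 0), 0.3)
  expect_equal(fixation_probability(0, 10, 0.4), 0)
  expect_equal(fixation_probability(10, 10, 0.4), 1)
  expect_lt(abs(fixation_probability(1, 3, 0.5) - 0.571429), 1e-6)
  for (mode in c("relative", "absolute")) {
    for (a in c(0.2, 0.6)) {
      for (mu in c(0.01, 0.3)) {
        phi <- moran_fix_markov(12, mu, a, mode)
        expect_lt(max(abs(phi[2:12] -
                          fixation_probability(1:11, 12, a))), 1e-10)
      }
    }
  }
  # independent of mu by construction, monotone in a
  vals <- vapply(seq(0, 0.9, by = 0.1), fixation_probability,
                 numeric(1), NgA0 = 2, Kg = 15)
  expect_true(all(diff(vals) > 0))
})
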