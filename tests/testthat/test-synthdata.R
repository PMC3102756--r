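test_that("sample_chain handles degenerate planted chains exactly", {
  mu <- matrix(0, 2, 7); sd <- matrix(0, 2, 7)
  abs_spec <- planted_chain_spec(diag(2), mu, sd, seed = 1)
  expect_equal(sample_chain(abs_spec, 100, start = 1), rep(1L, 100))

  alt <- planted_chain_spec(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE),
                            mu, sd, seed = 1)
  expect_equal(sample_chain(alt, 4, start = 1), c(1L, 2L, 1L, 2L))
})

test_that("non-stochastic matrices are rejected with the offending row", {
  bad <- matrix(c(0.5, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE)
  expect_error(planted_chain_spec(bad, matrix(0, 2, 7), matrix(0, 2, 7)),
               "row 1")
  expect_error(planted_chain_spec(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                                         byrow = TRUE),
                                  matrix(0, 2, 7), matrix(-1, 2, 7)),
               "nonnegative")
})

test_that("empirical transition frequencies match the planted chain", {
  spec <- two_state_spec(0.1, 0.1, seed = 4)
  n <- 2e5
  l <- sample_chain(spec, n, start = 1)
  from1 <- which(l[-n] == 1)
  phat <- mean(l[from1 + 1] == 2)
  se <- sqrt(0.1 * 0.9 / length(from1))
  expect_lt(abs(phat - 0.1), 4 * se)
})

test_that("stationary occupancy of an ergodic 3-state chain matches theory", {
  P <- matrix(c(0.90, 0.08, 0.02,
                0.05, 0.90, 0.05,
                0.02, 0.03, 0.95), 3, 3, byrow = TRUE)
  spec <- planted_chain_spec(P, matrix(0, 3, 7), matrix(0, 3, 7), seed = 11)
  n <- 2e5
  l <- sample_chain(spec, n, start = 1)
  pi_hat <- tabulate(l, 3) / n
  e <- eigen(t(P)); v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  pi_true <- v / sum(v)
  # correlated samples: inflate the multinomial SE by the slowest
  # correlation time of the chain
  lam2 <- sort(abs(Re(eigen(P)$values)), decreasing = TRUE)[2]
  infl <- sqrt((1 + lam2) / (1 - lam2))
  se <- sqrt(pi_true * (1 - pi_true) / n) * infl
  expect_true(all(abs(pi_hat - pi_true) < 4 * se))
})

test_that("emissions reproduce the planted Gaussians", {
  spec <- two_state_spec(seed = 5)
  # zero-sd emissions are exact
  spec0 <- planted_chain_spec(spec$transition_matrix, spec$emission_means,
                              matrix(0, 2, 7), seed = 2)
  f0 <- emit_features(c(1L, 2L, 1L), spec0)
  expect_equal(f0$opening_deg, spec$emission_means[c(1, 2, 1), 1])
  expect_equal(nrow(f0), 3L)
  # empty label sequence -> empty trajectory
  expect_equal(nrow(emit_features(integer(0), spec)), 0L)
  # out-of-range labels rejected
  expect_error(emit_features(3L, spec), "out of range")
  # CLT: sample mean of a single state within 4 standard errors
  n <- 1e5
  f <- emit_features(rep(1L, n), spec)
  se <- 0.5 / sqrt(n)
  expect_lt(abs(mean(f$twisting_deg) - spec$emission_means[1, 2]), 4 * se)
})

test_that("fixed seeds give bit-identical synthetic data", {
  s1 <- lao_like_spec(seed = 42)
  s2 <- lao_like_spec(seed = 42)
  expect_identical(sample_chain(s1, 1000, 1, traj_index = 3),
                   sample_chain(s2, 1000, 1, traj_index = 3))
  l <- sample_chain(s1, 500, 2)
  expect_identical(emit_features(l, s1, traj_index = 2),
                   emit_features(l, s2, traj_index = 2))
  # different stream indices decorrelate trajectories
  expect_false(identical(sample_chain(s1, 1000, 1, traj_index = 1),
                         sample_chain(s1, 1000, 1, traj_index = 2)))
})

test_that("the LAO-like scenario has the intended architecture", {
  spec <- lao_like_spec()
  P <- spec$transition_matrix
  # encounter is the obligatory gateway: no direct unbound <-> bound edges
  expect_equal(P["unbound", "bound"], 0)
  expect_equal(P["bound", "unbound"], 0)
  expect_equal(P["misbound", "bound"], 0)
  pi <- msmbind:::chain_stationary(P)
  expect_equal(which.max(pi), 3L)  # bound dominates
  expect_gt(pi[3], 0.7)
})

test_that("Metropolis sampling reproduces Boltzmann statistics", {
  # zero steps -> only the start point
  ls <- toy_landscape(list(list(center = c(0, 0, 0), sd = c(1, 1, 1),
                                weight = 1)), step_sd = 0.8, seed = 3)
  tr0 <- simulate_landscape(ls, 0, c(1, 2, 3))
  expect_equal(nrow(tr0), 1L)
  expect_equal(tr0[1, ], c(opening_deg = 1, twisting_deg = 2,
                           site_distance_A = 3))
  # single isotropic well: per-coordinate variance within 10%
  tr <- simulate_landscape(ls, 4e4, c(0, 0, 0))
  v <- apply(tr[-(1:2000), ], 2, stats::var)
  expect_true(all(abs(v - 1) < 0.1))
  # 9:1 two-well occupancy within 20%
  ls2 <- toy_landscape(list(
    list(center = c(0, 0, 0), sd = c(1, 1, 1), weight = 9),
    list(center = c(8, 0, 0), sd = c(1, 1, 1), weight = 1)),
    step_sd = 4, seed = 9)
  tr2 <- simulate_landscape(ls2, 6e4, c(0, 0, 0))
  occ <- mean(tr2[-(1:5000), 1] < 4)
  expect_lt(abs(occ / (1 - occ) - 9) / 9, 0.2)
})

test_that("landscape dynamics are reversible between half-spaces", {
  ls <- toy_landscape(list(list(center = c(0, 0, 0), sd = c(1, 1, 1),
                                weight = 1)), step_sd = 1, seed = 17)
  tr <- simulate_landscape(ls, 2e4, c(0, 0, 0))
  side <- tr[, 1] > 0
  ab <- sum(!side[-length(side)] & side[-1])
  ba <- sum(side[-length(side)] & !side[-1])
  # sequential crossings of a dividing surface alternate, so the counts
  # can differ by at most one; equality up to 1 is the detailed-balance
  # fingerprint for this observable
  expect_lte(abs(ab - ba), 1)
})
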