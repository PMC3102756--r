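test_that("MFPT solves the first-passage linear system", {
  # source inside the target -> 0
  T <- random_stochastic(4, 41)
  expect_equal(mfpt(T, 6, source_set = 2, target_set = c(1, 2))$value, 0)
  # 2-state closed form: lag / p
  T2 <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  expect_equal(mfpt(T2, 6, 1, 2)$value, 60)
  # additivity on a directed chain: a -> b -> c
  T3 <- matrix(c(0.8, 0.2, 0,
                 0, 0.5, 0.5,
                 0.1, 0, 0.9), 3, 3, byrow = TRUE)
  ab <- mfpt(T3, 1, 1, 2)$value
  bc <- mfpt(T3, 1, 2, 3)$value
  ac <- mfpt(T3, 1, 1, 3)$value
  expect_equal(ac, ab + bc, tolerance = 1e-10)
  # unreachable target flagged as infinite
  T4 <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_warning(r4 <- mfpt(T4, 1, 1, 2), "unreachable")
  expect_true(is.infinite(r4$per_source))
})

test_that("MFPT agrees with Monte-Carlo first passage on random chains", {
  for (seed in c(5, 6)) {
    T <- random_stochastic(5, seed)
    want <- oracle_mc_fpt(T, start = 1, target = 5, n_walkers = 2e5,
                          seed = seed)
    got <- mfpt(T, 1, 1, 5)$value
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("bootstrap over trajectories has the expected behaviour", {
  trajs <- as.list(1:20)
  # constant statistic -> sd 0
  b0 <- bootstrap_statistic(trajs, function(x) 42, n_boot = 20, seed = 1)
  expect_equal(b0$mean, 42)
  expect_equal(b0$sd, 0)
  # statistic = trajectory count -> mean = n_draw exactly
  b1 <- bootstrap_statistic(trajs, length, n_boot = 10, n_draw = 7,
                            seed = 2)
  expect_equal(b1$mean, 7)
  # bootstrap sd approximates the analytic standard error of a mean
  set.seed(3)
  vals <- as.list(stats::rnorm(50, sd = 2))
  b2 <- bootstrap_statistic(vals, function(x) mean(unlist(x)),
                            n_boot = 100, seed = 3)
  analytic_se <- stats::sd(unlist(vals)) / sqrt(50)
  expect_lt(abs(b2$sd - analytic_se) / analytic_se, 0.3)
  # failures are skipped and counted
  expect_warning(
    b3 <- bootstrap_statistic(trajs, function(x)
      if (stats::runif(1) < 0.2) stop("boom") else 1,
      n_boot = 30, seed = 4),
    "skipped")
  expect_gt(b3$n_failed, 0)
  expect_equal(b3$mean, 1)
  expect_error(bootstrap_statistic(list(1), length), "at least 2")
})

test_that("population-ratio binding free energy matches closed forms", {
  # ratio = 1 when alpha_free is the golden-ratio root and c0 = 1 M
  a <- (sqrt(5) - 1) / 2
  expect_equal(binding_free_energy(a, 1, 300), 0, tolerance = 1e-10)
  # strictly monotone: lower free fraction -> more negative dG
  dgs <- vapply(c(0.3, 0.1, 0.05, 0.01), binding_free_energy,
                numeric(1), c0_molar = 0.005, T_K = 318)
  expect_true(all(diff(dgs) < 0))
  expect_error(binding_free_energy(0, 0.005, 318), "inside")
  expect_error(binding_free_energy(1, 0.005, 318), "inside")
})

test_that("Kd-referenced free energy follows RT log Kd", {
  expect_equal(dG_from_Kd(1, 277), 0)
  # halving Kd changes dG by exactly -RT log 2
  d1 <- dG_from_Kd(2e-8, 300)
  d2 <- dG_from_Kd(1e-8, 300)
  expect_equal(d2 - d1, -R_KCAL * 300 * log(2), tolerance = 1e-12)
})

test_that("association timescale is the pseudo-first-order half-life", {
  expect_equal(association_timescale(log(2), 1), 1)
  # doubling the concentration halves the timescale
  expect_equal(association_timescale(1e7, 0.0098),
               association_timescale(1e7, 0.0049) / 2)
  expect_equal(association_timescale(1e7, 0.0049), 1.414e-5,
               tolerance = 1e-3)
})

test_that("committor solves the boundary-value problem", {
  # gambler's ruin: symmetric nearest-neighbour chain, q_i = i/N
  N <- 10
  T <- matrix(0, N + 1, N + 1)
  for (i in 2:N) {
    T[i, i - 1] <- 0.5
    T[i, i + 1] <- 0.5
  }
  T[1, 1] <- 1; T[N + 1, N + 1] <- 1
  q <- committor(T, source_set = 1, sink_set = N + 1)
  expect_equal(q, (0:N) / N, tolerance = 1e-10)
  # defining fixed-point property on a random chain
  Tr <- random_stochastic(6, 44)
  qr <- committor(Tr, 1, 6)
  resid <- Tr %*% qr - qr
  expect_lt(max(abs(resid[2:5])), 1e-10)
  expect_equal(qr[1], 0)
  expect_equal(qr[6], 1)
  expect_error(committor(Tr, 1, 1), "disjoint")
})

test_that("net flux is conserved from source to sink", {
  # 4-state linear chain: every edge carries the same net flux
  T <- matrix(0, 4, 4)
  T[1, 1] <- 0.9; T[1, 2] <- 0.1
  T[2, 1] <- 0.2; T[2, 2] <- 0.5; T[2, 3] <- 0.3
  T[3, 2] <- 0.2; T[3, 3] <- 0.5; T[3, 4] <- 0.3
  T[4, 3] <- 0.1; T[4, 4] <- 0.9
  fl <- net_flux(T, 1, 4)
  edges <- c(fl$flux[1, 2], fl$flux[2, 3], fl$flux[3, 4])
  expect_equal(edges[2], edges[1], tolerance = 1e-12)
  expect_equal(edges[3], edges[1], tolerance = 1e-12)
  # conservation and sink absorption
  expect_equal(sum(fl$flux[1, ]), sum(fl$flux[, 4]), tolerance = 1e-10)
  expect_true(all(fl$flux[4, ] == 0))
  # conservation on a random (non-reversible) ergodic chain
  Tr <- random_stochastic(7, 45)
  flr <- net_flux(Tr, c(1, 2), 7)
  F <- flr$flux
  out_src <- sum(F[c(1, 2), ]) - sum(F[, c(1, 2)])
  in_snk <- sum(F[, 7]) - sum(F[7, ])
  expect_equal(out_src, in_snk, tolerance = 1e-10)
  # interior states conserve flux exactly
  for (i in 3:6)
    expect_equal(sum(F[i, ]), sum(F[, i]), tolerance = 1e-10)
})

test_that("widest-path decomposition recovers planted pathway fluxes", {
  # linear chain: one path carrying all flux, then exhaustion
  F1 <- matrix(0, 3, 3)
  F1[1, 2] <- 0.4; F1[2, 3] <- 0.4
  p1 <- suppressMessages(top_flux_paths(F1, 1, 3, n_paths = 3,
                                        total_flux = 0.4))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$path, "1-2-3")
  expect_equal(p1$fraction, 1.0)
  # two parallel branches with planted fluxes 0.7 / 0.3
  F2 <- matrix(0, 4, 4)
  F2[1, 2] <- 0.7; F2[2, 4] <- 0.7
  F2[1, 3] <- 0.3; F2[3, 4] <- 0.3
  p2 <- top_flux_paths(F2, 1, 4, n_paths = 2, total_flux = 1)
  expect_equal(p2$path, c("1-2-4", "1-3-4"))
  expect_equal(p2$flux, c(0.7, 0.3))
  expect_equal(sum(p2$fraction), 1.0, tolerance = 1e-10)
  # path fluxes never exceed the total
  Tr <- random_stochastic(6, 46)
  flr <- net_flux(Tr, 1, 6)
  pr <- suppressMessages(top_flux_paths(flr$flux, 1, 6, n_paths = 10,
                                        total_flux = flr$total_flux))
  expect_lte(sum(pr$flux), flr$total_flux + 1e-10)
})

test_that("transition events respect the residence filter", {
  feats <- data.frame(opening_deg = seq_len(12), twisting_deg = 0)
  # one valid transition (residence 3) and one blip (residence 1)
  l <- c(1L, 1L, 2L, 2L, 2L, 1L, 1L, 2L, 1L, 1L, 1L, 1L)
  ev <- transition_event_features(l, feats, 1L, 2L,
                                  min_residence_frames = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$frame, 2L)
  expect_equal(ev$opening_deg, 2)
  # no matching transitions -> empty
  expect_equal(nrow(transition_event_features(l, feats, 2L, 3L)), 0L)
  # filtered count never exceeds the raw label-change count
  set.seed(47)
  l2 <- sample.int(3, 400, replace = TRUE)
  f2 <- data.frame(v = seq_along(l2))
  raw <- sum(l2[-length(l2)] == 1 & l2[-1] == 2)
  for (m in 1:4)
    expect_lte(nrow(transition_event_features(l2, f2, 1L, 2L, m)), raw)
})

test_that("free-energy surfaces invert Boltzmann statistics", {
  # all samples in one bin -> 0
  g1 <- free_energy_surface(rep(0.1, 50), rep(0.2, 50), 1, 1)
  expect_equal(as.numeric(g1$F[g1$counts > 0]), 0)
  # two bins with counts (e n, n): difference of exactly 1 kT
  n <- 10000
  ne <- round(exp(1) * n)
  x <- c(rep(0.5, ne), rep(1.5, n))
  g2 <- free_energy_surface(x, rep(0.5, length(x)), 1, 1)
  vals <- g2$F[g2$counts > 0]
  expect_equal(max(vals) - min(vals), log(ne / n), tolerance = 1e-12)
  expect_equal(max(vals) - min(vals), 1, tolerance = 1e-3)
  # empty bins are undefined
  g3 <- free_energy_surface(c(0.5, 2.5), c(0.5, 0.5), 1, 1)
  expect_true(anyNA(g3$F))
  expect_error(free_energy_surface(numeric(0), numeric(0), 1, 1), "samples")
  # Boltzmann inversion of an isotropic Gaussian: quadratic radial profile
  set.seed(48)
  n <- 1e6
  gs <- free_energy_surface(stats::rnorm(n), stats::rnorm(n), 0.25, 0.25)
  r2 <- outer(gs$x_mid^2, gs$y_mid^2, "+")
  sel <- r2 > 0.25 & r2 < 4 & gs$counts > 200
  fit <- stats::lm(gs$F[sel] ~ I(r2[sel] / 2))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.05)
})

test_that("medoid selection finds the most central conformations", {
  base <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  # all identical -> first n by index
  coords <- rep(list(base), 6)
  expect_equal(medoid_conformations(coords, 3), 1:3)
  # a gross outlier is never selected
  out <- base; out[1, ] <- c(50, 50, 50)
  coords2 <- c(rep(list(base), 5), list(out))
  expect_false(6 %in% medoid_conformations(coords2, 3))
  # matches an exhaustive pairwise-matrix oracle on random structures
  set.seed(49)
  coords3 <- lapply(1:10, function(i) base + matrix(stats::rnorm(12), 4, 3))
  D <- matrix(0, 10, 10)
  for (i in 1:9) for (j in (i + 1):10)
    D[i, j] <- D[j, i] <- ca_rmsd(coords3[[i]], coords3[[j]])
  want <- order(rowSums(D))[1:3]
  expect_equal(sort(medoid_conformations(coords3, 3)), sort(want))
})

test_that("rate ratios map to kT-scaled barrier differences", {
  expect_equal(rate_ratio_barrier(exp(2)), 2)
  expect_equal(rate_ratio_barrier(8, kT = 0.6), 0.6 * log(8))
})
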