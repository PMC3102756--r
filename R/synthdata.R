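# Synthetic data with planted ground truth.
#
# The study's MD dataset is not deposited, so every downstream stage is
# exercised on synthetic trajectories whose kinetics and geometry are known
# exactly: a discrete Markov chain over a few metastable basins emits
# Gaussian features per state, and a Metropolis Monte Carlo walker explores
# a multi-well toy landscape.

FEATURE_NAMES <- c("opening_deg", "twisting_deg", "site_distance_A",
                   "min_dist_A", "lig_x", "lig_y", "lig_z")

#' Specification of a planted Markov chain with Gaussian emissions
#'
#' Defines the ground truth used by the synthetic generator: a discrete-time
#' Markov chain at fixed frame spacing whose states are metastable basins,
#' each emitting per-frame features from a diagonal Gaussian.
#'
#' @param transition_matrix square row-stochastic matrix (rows sum to 1
#'   within 1e-12); per-frame transition probabilities.
#' @param emission_means numeric matrix, one row per state, columns
#'   `opening_deg`, `twisting_deg`, `site_distance_A`, `min_dist_A`,
#'   `lig_x`, `lig_y`, `lig_z`.
#' @param emission_sds matrix of nonnegative per-state standard deviations,
#'   same shape as `emission_means`.
#' @param dt_ps frame spacing in ps (default 20).
#' @param seed master seed; each trajectory draws its own RNG stream derived
#'   from `(seed, trajectory index)`.
#' @param state_names optional state names.
#' @return object of class `planted_chain_spec`.
#' @export
planted_chain_spec <- function(transition_matrix, emission_means,
                               emission_sds, dt_ps = 20, seed = 1L,
                               state_names = NULL) {
  P <- as.matrix(transition_matrix)
  if (!is_square(P)) stopf("transition matrix must be square")
  n <- nrow(P)
  if (any(P < 0)) stopf("transition matrix has negative entries")
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > 1e-12)
  if (length(bad))
    stopf("transition matrix row %d sums to %.15g, not 1", bad[1], rs[bad[1]])
  mu <- as.matrix(emission_means)
  sd <- as.matrix(emission_sds)
  if (nrow(mu) != n || nrow(sd) != n || ncol(mu) != ncol(sd))
    stopf("emission parameter dimensions do not match n_states = %d", n)
  if (any(sd < 0)) stopf("emission sds must be nonnegative")
  if (is.null(colnames(mu))) colnames(mu) <- FEATURE_NAMES[seq_len(ncol(mu))]
  colnames(sd) <- colnames(mu)
  structure(list(n_states = n, transition_matrix = P, emission_means = mu,
                 emission_sds = sd, dt_ps = dt_ps, seed = as.integer(seed),
                 state_names = state_names %||% rownames(mu) %||%
                   paste0("S", seq_len(n))),
            class = "planted_chain_spec")
}

#' @export
print.planted_chain_spec <- function(x, ...) {
  cat(sprintf("<planted_chain_spec> %d states (%s), dt = %g ps, seed = %d\n",
              x$n_states, paste(x$state_names, collapse = ", "),
              x$dt_ps, x$seed))
  invisible(x)
}

#' Sample a state sequence from a planted chain
#'
#' @param spec a [planted_chain_spec()].
#' @param n_steps number of frames to generate (>= 1).
#' @param start starting state index (1-based).
#' @param traj_index trajectory stream index; the RNG stream is derived from
#'   `(spec$seed, traj_index)` so parallel trajectories are reproducible.
#' @return integer vector of 1-based state labels, length `n_steps`.
#' @export
sample_chain <- function(spec, n_steps, start = 1L, traj_index = 1L) {
  stopifnot(inherits(spec, "planted_chain_spec"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) stopf("n_steps must be >= 1")
  if (start < 1 || start > spec$n_states)
    stopf("start state %d out of range [1, %d]", start, spec$n_states)
  P <- spec$transition_matrix
  cum <- t(apply(P, 1, cumsum))
  with_seed(derive_seed(spec$seed, traj_index), {
    u <- stats::runif(n_steps - 1L)
    out <- integer(n_steps)
    s <- as.integer(start)
    out[1] <- s
    if (n_steps > 1L) {
      for (i in seq_len(n_steps - 1L)) {
        s <- which(u[i] <= cum[s, ])[1]
        out[i + 1L] <- s
      }
    }
    out
  })
}

#' Emit Gaussian features for a planted label sequence
#'
#' @param labels integer state labels (1-based).
#' @param spec a [planted_chain_spec()].
#' @param traj_index RNG stream index (see [sample_chain()]).
#' @return a [feature_trajectory()]; one row per label. Distances are
#'   truncated at zero (state means sit several standard deviations above
#'   zero, so truncation is negligible).
#' @export
emit_features <- function(labels, spec, traj_index = 1L) {
  stopifnot(inherits(spec, "planted_chain_spec"))
  labels <- as.integer(labels)
  if (length(labels) && (min(labels) < 1 || max(labels) > spec$n_states))
    stopf("label out of range [1, %d]", spec$n_states)
  mu <- spec$emission_means
  sd <- spec$emission_sds
  n <- length(labels)
  cols <- colnames(mu)
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  if (n > 0) {
    with_seed(derive_seed(spec$seed, traj_index) + 1L, {
      for (j in seq_along(cols)) {
        out[, j] <- mu[labels, j] + stats::rnorm(n) * sd[labels, j]
      }
    })
    for (j in intersect(c("site_distance_A", "min_dist_A"), cols))
      out[, j] <- pmax(out[, j], 0)
    for (j in intersect(c("opening_deg", "twisting_deg"), cols))
      out[, j] <- wrap_deg(out[, j])
  }
  df <- as.data.frame(out)
  for (j in setdiff(FEATURE_NAMES, cols)) df[[j]] <- numeric(n)
  feature_trajectory(df, dt_ps = spec$dt_ps)
}

#' The default LAO-like synthetic scenario
#'
#' Four metastable basins emulating the architecture of periplasmic
#' binding-protein ligand association: an open unbound basin (ligand
#' diffusing far from the protein), a partially closed encounter complex
#' (ligand weakly associated near the binding site), a closed bound basin
#' (dominant at equilibrium), and an off-pathway mis-bound basin (ligand
#' stuck outside the binding site). The encounter complex is the obligatory
#' gateway between unbound and bound, and the mis-bound basin exchanges only
#' with the unbound basin, so pathway decomposition has a known truth.
#'
#' Per-frame (20 ps) transition probabilities give mean basin dwell times of
#' 1-8 ns and a stationary distribution of (0.0976, 0.0976, 0.7805, 0.0244)
#' over (unbound, encounter, bound, mis-bound); the bound state dominates,
#' as in the real system.
#'
#' @param seed master seed.
#' @param include_misbound drop the mis-bound basin for a clean three-basin
#'   variant (stationary distribution (0.1, 0.1, 0.8)).
#' @return a [planted_chain_spec()].
#' @export
lao_like_spec <- function(seed = 1L, include_misbound = TRUE) {
  states <- c("unbound", "encounter", "bound", "misbound")
  #              open  twist  site  mind  ligx ligy ligz
  mu <- rbind(c(40, -25, 30, 25, 30, 0, 0),     # unbound
              c(25, -15,  4,  2,  4, 0, 0),     # encounter
              c( 0,   0,  1, 0.5, 1, 0, 0),     # bound
              c(35, -20,  6,  1,  0, 6, 0))     # mis-bound (wrong site)
  sd <- rbind(c(2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0),
              c(1.5, 1.5, 0.4, 0.3, 0.4, 0.4, 0.4),
              c(1.5, 1.5, 0.3, 0.15, 0.3, 0.3, 0.3),
              c(1.5, 1.5, 0.4, 0.3, 0.4, 0.4, 0.4))
  colnames(mu) <- colnames(sd) <- FEATURE_NAMES
  rownames(mu) <- rownames(sd) <- states
  P <- matrix(0, 4, 4, dimnames = list(states, states))
  P["unbound", "encounter"] <- 0.010
  P["unbound", "misbound"]  <- 0.0025
  P["encounter", "unbound"] <- 0.010
  P["encounter", "bound"]   <- 0.020
  P["bound", "encounter"]   <- 0.0025
  P["misbound", "unbound"]  <- 0.010
  diag(P) <- 1 - rowSums(P)
  if (!include_misbound) {
    keep <- 1:3
    P <- P[keep, keep]
    diag(P) <- 0
    diag(P) <- 1 - rowSums(P)
    mu <- mu[keep, , drop = FALSE]
    sd <- sd[keep, , drop = FALSE]
  }
  planted_chain_spec(P, mu, sd, dt_ps = 20, seed = seed)
}

#' Generate a set of synthetic trajectories from a planted chain
#'
#' Starting states are drawn from the chain's stationary distribution using
#' a dedicated RNG stream, emulating a dataset begun from scattered
#' conformations.
#'
#' @param spec a [planted_chain_spec()].
#' @param n_traj number of trajectories (default 65).
#' @param n_frames frames per trajectory (default 10000).
#' @return list with `features` (list of [feature_trajectory()]) and
#'   `labels` (list of ground-truth label vectors).
#' @export
generate_dataset <- function(spec, n_traj = 65, n_frames = 10000) {
  pi0 <- chain_stationary(spec$transition_matrix)
  starts <- with_seed(derive_seed(spec$seed, 0L), {
    sample.int(spec$n_states, n_traj, replace = TRUE, prob = pi0)
  })
  labels <- lapply(seq_len(n_traj), function(i)
    sample_chain(spec, n_frames, start = starts[i], traj_index = i))
  feats <- lapply(seq_len(n_traj), function(i)
    emit_features(labels[[i]], spec, traj_index = i))
  list(features = feats, labels = labels)
}

# Analytic stationary distribution of a small row-stochastic matrix.
chain_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Toy free-energy landscape (mixture of Gaussian wells)
#'
#' Potential U(x) = -kT log sum_b w_b N(x; c_b, sd_b), sampled by Metropolis
#' Monte Carlo with isotropic Gaussian proposals.
#'
#' @param basins list of `list(center =, sd =, weight =)`; centers and sds
#'   are vectors in feature space (opening, twisting, site distance).
#' @param kT energy unit (default 1).
#' @param step_sd proposal standard deviation per coordinate.
#' @param seed RNG seed.
#' @return object of class `toy_landscape`.
#' @export
toy_landscape <- function(basins, kT = 1, step_sd = 1, seed = 1L) {
  if (!length(basins)) stopf("at least one basin is required")
  d <- length(basins[[1]]$center)
  for (b in basins) {
    if (length(b$center) != d || length(b$sd) != d)
      stopf("all basin centers/sds must have the same dimension")
    if (any(b$sd <= 0)) stopf("basin sds must be positive")
    if (is.null(b$weight) || b$weight <= 0) stopf("basin weights must be > 0")
  }
  structure(list(basins = basins, kT = kT, step_sd = step_sd,
                 seed = as.integer(seed), dim = d),
            class = "toy_landscape")
}

# Potential energy of the mixture landscape at points (rows of x).
landscape_potential <- function(landscape, x) {
  x <- matrix(x, ncol = landscape$dim)
  dens <- rep(0, nrow(x))
  for (b in landscape$basins) {
    z <- sweep(x, 2, b$center)
    z <- sweep(z, 2, b$sd, "/")
    logn <- -0.5 * rowSums(z^2) - sum(log(b$sd)) -
      0.5 * landscape$dim * log(2 * pi)
    dens <- dens + b$weight * exp(logn)
  }
  -landscape$kT * log(dens)
}

#' Metropolis Monte Carlo walk on a toy landscape
#'
#' @param landscape a [toy_landscape()].
#' @param n_steps number of proposal steps (>= 0); the returned chain has
#'   `n_steps + 1` rows including the start point.
#' @param start_point starting coordinates.
#' @param seed optional seed overriding the landscape's.
#' @return matrix of visited positions (accepted-or-retained), one row per
#'   step including the start.
#' @export
simulate_landscape <- function(landscape, n_steps, start_point,
                               seed = landscape$seed) {
  stopifnot(inherits(landscape, "toy_landscape"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) stopf("n_steps must be >= 0")
  d <- landscape$dim
  x <- as.numeric(start_point)
  if (length(x) != d) stopf("start_point must have dimension %d", d)
  out <- matrix(0, n_steps + 1L, d)
  out[1, ] <- x
  if (n_steps > 0) {
    with_seed(seed, {
      prop <- matrix(stats::rnorm(n_steps * d, sd = landscape$step_sd),
                     n_steps, d)
      u <- stats::runif(n_steps)
      U <- landscape_potential(landscape, x)
      for (i in seq_len(n_steps)) {
        cand <- x + prop[i, ]
        Uc <- landscape_potential(landscape, cand)
        if (u[i] < exp(-(Uc - U) / landscape$kT)) {
          x <- cand
          U <- Uc
        }
        out[i + 1L, ] <- x
      }
    })
  }
  colnames(out) <- FEATURE_NAMES[seq_len(min(d, length(FEATURE_NAMES)))]
  out
}
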