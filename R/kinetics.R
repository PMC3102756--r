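# Kinetic and thermodynamic readouts: mean first passage times, bootstrap
# error bars, binding free energy from bound/free fractions, association
# timescale, committors, transition-path fluxes and top pathways,
# transition-event localization, free-energy surfaces, medoids.

#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.987e-3

# States from which any of `targets` is reachable along nonzero edges.
reachable_set <- function(T, targets) {
  e <- nonzero_edges(T)
  g <- igraph::make_graph(as.vector(t(e)), n = nrow(T), directed = TRUE)
  hit <- unique(unlist(lapply(targets, function(v)
    as.integer(igraph::subcomponent(g, v, mode = "in")))))
  sort(hit)
}

#' Mean first passage time between macrostate sets
#'
#' Solves the linear system X_f = 0 for f in the target set and
#' X_i = lag + sum_j T_ij X_j otherwise, then returns the weighted average
#' over the source set. Sources from which the target is unreachable have
#' infinite MFPT and are flagged.
#'
#' @param T row-stochastic transition matrix.
#' @param lag lag time of `T` (any time unit; the MFPT is returned in the
#'   same unit).
#' @param source_set,target_set nonempty state index sets; overlap is
#'   removed from the source side (a source inside the target has MFPT 0).
#' @param weights source weights (default: stationary populations of the
#'   sources, renormalized).
#' @return object of class `mfpt_result`: list with `value`, `per_source`,
#'   `x` (full MFPT vector), `source_set`, `target_set`, `weights`, `lag`.
#' @export
mfpt <- function(T, lag, source_set, target_set, weights = NULL) {
  T <- as_dense(T)
  K <- nrow(T)
  source_set <- sort(unique(as.integer(source_set)))
  target_set <- sort(unique(as.integer(target_set)))
  if (!length(source_set) || !length(target_set))
    stopf("source and target sets must be nonempty")
  x <- numeric(K)
  interior <- setdiff(seq_len(K), target_set)
  if (length(interior)) {
    can_reach <- reachable_set(T, target_set)
    bad <- setdiff(interior, can_reach)
    if (length(bad)) {
      warnf("target unreachable from %d state(s); their MFPT is infinite",
            length(bad))
      x[bad] <- Inf
    }
    good <- setdiff(interior, bad)
    if (length(good)) {
      A <- diag(length(good)) - T[good, good, drop = FALSE]
      x[good] <- solve(A, rep(lag, length(good)))
    }
  }
  if (is.null(weights)) {
    pi <- stationary_distribution(T)
    weights <- pi[source_set]
    if (sum(weights) == 0) weights <- rep(1, length(source_set))
  }
  weights <- weights / sum(weights)
  per_source <- x[source_set]
  structure(list(value = sum(per_source * weights), per_source = per_source,
                 x = x, source_set = source_set, target_set = target_set,
                 weights = weights, lag = lag),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat(sprintf("<mfpt_result> MFPT = %.6g (lag %.4g) from {%s} to {%s}\n",
              x$value, x$lag, paste(x$source_set, collapse = ","),
              paste(x$target_set, collapse = ",")))
  invisible(x)
}

#' Bootstrap a statistic over trajectories
#'
#' Creates `n_boot` resampled datasets by drawing `n_draw` trajectories
#' with replacement, recomputes the statistic on each, and reports the
#' bootstrap mean and standard deviation. Resamples on which the statistic
#' fails are skipped, counted, and warned about.
#'
#' @param trajectories list (>= 2 elements).
#' @param statistic function taking a list of trajectories and returning a
#'   single numeric.
#' @param n_boot number of resamples (default 100).
#' @param n_draw trajectories drawn per resample (default
#'   `length(trajectories)`).
#' @param seed RNG seed.
#' @return list with `mean`, `sd`, `values`, `n_failed`.
#' @export
bootstrap_statistic <- function(trajectories, statistic, n_boot = 100,
                                n_draw = length(trajectories), seed = 1L) {
  if (length(trajectories) < 2) stopf("need at least 2 trajectories")
  idx <- with_seed(seed, {
    matrix(sample.int(length(trajectories), n_boot * n_draw, replace = TRUE),
           n_boot, n_draw)
  })
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    vals[b] <- tryCatch(statistic(trajectories[idx[b, ]]),
                        error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(vals))
  if (n_failed)
    warnf("statistic failed on %d of %d resamples; skipped", n_failed, n_boot)
  ok <- vals[!is.na(vals)]
  list(mean = mean(ok), sd = stats::sd(ok), values = vals,
       n_failed = n_failed)
}

#' Binding free energy from bound/free fractions
#'
#' Population-ratio estimate for a simulation box containing one protein
#' and one ligand:
#' \deqn{\Delta G = -RT \ln\frac{1 - \alpha_{free}}
#'   {\alpha_{free}^2 \, c_0 / c^\circ}}
#' where `alpha_free` is the fraction of frames with protein and ligand
#' dissociated, `c0` the overall ligand concentration set by the box volume
#' (c0 = 1 / (N_A V_box)), and the standard concentration is 1 mol/L. The
#' quadratic denominator reflects that the dissociated species P and L are
#' at equal concentration `alpha_free * c0`.
#'
#' @param alpha_free free fraction, strictly inside (0, 1).
#' @param c0_molar overall ligand concentration (mol/L).
#' @param T_K temperature (K).
#' @param R gas constant (kcal/(mol K)).
#' @return free energy in kcal/mol.
#' @export
binding_free_energy <- function(alpha_free, c0_molar, T_K, R = R_KCAL) {
  if (alpha_free <= 0 || alpha_free >= 1)
    stopf("alpha_free must lie strictly inside (0, 1)")
  if (c0_molar <= 0 || T_K <= 0) stopf("c0 and T must be positive")
  -R * T_K * log((1 - alpha_free) / (alpha_free^2 * c0_molar / 1))
}

#' Reference free energy from a dissociation constant
#'
#' \deqn{\Delta G = RT \ln (K_d / c^\circ)}, with the standard
#' concentration 1 mol/L.
#'
#' @param Kd_molar dissociation constant (mol/L), > 0.
#' @param T_K temperature (K).
#' @param R gas constant (kcal/(mol K)).
#' @return free energy in kcal/mol.
#' @export
dG_from_Kd <- function(Kd_molar, T_K, R = R_KCAL) {
  if (Kd_molar <= 0) stopf("Kd must be positive")
  R * T_K * log(Kd_molar / 1)
}

#' Association timescale under pseudo-first-order kinetics
#'
#' Half-life of the free protein when the ligand is in excess:
#' \deqn{\tau_{1/2} = \ln 2 / (k_{on} c_0)}.
#'
#' @param k_on association rate constant (1/(M s)).
#' @param c0_molar ligand concentration (mol/L).
#' @return timescale in seconds.
#' @export
association_timescale <- function(k_on, c0_molar) {
  if (k_on <= 0 || c0_molar <= 0) stopf("k_on and c0 must be positive")
  log(2) / (k_on * c0_molar)
}

#' Free-energy barrier difference implied by a rate ratio
#'
#' Rates are proportional to exp(-barrier/kT), so a ratio of rates maps to
#' a barrier-height difference of kT log(ratio) (e.g. an 8-fold rate
#' difference corresponds to about 2 kT).
#'
#' @param ratio ratio of two rates (> 0).
#' @param kT energy unit (default 1, i.e. result in kT).
#' @return barrier difference in units of `kT`.
#' @export
rate_ratio_barrier <- function(ratio, kT = 1) {
  if (ratio <= 0) stopf("ratio must be positive")
  kT * log(ratio)
}

#' Forward committor
#'
#' Probability of reaching the sink set before the source set, from each
#' state: q = 0 on the source, q = 1 on the sink, and
#' q_i = sum_j T_ij q_j elsewhere (linear solve). States from which the
#' sink is unreachable get q = 0 with a warning.
#'
#' @param T row-stochastic matrix.
#' @param source_set,sink_set disjoint nonempty state index sets.
#' @return numeric committor vector in `[0, 1]`.
#' @export
committor <- function(T, source_set, sink_set) {
  T <- as_dense(T)
  K <- nrow(T)
  source_set <- sort(unique(as.integer(source_set)))
  sink_set <- sort(unique(as.integer(sink_set)))
  if (!length(source_set) || !length(sink_set))
    stopf("source and sink sets must be nonempty")
  if (length(intersect(source_set, sink_set)))
    stopf("source and sink sets must be disjoint")
  q <- numeric(K)
  q[sink_set] <- 1
  interior <- setdiff(seq_len(K), c(source_set, sink_set))
  if (length(interior)) {
    can <- reachable_set(T, sink_set)
    bad <- setdiff(interior, can)
    if (length(bad))
      warnf("sink unreachable from %d state(s); committor set to 0 there",
            length(bad))
    good <- setdiff(interior, bad)
    if (length(good)) {
      A <- diag(length(good)) - T[good, good, drop = FALSE]
      b <- T[good, sink_set, drop = FALSE] %*% rep(1, length(sink_set))
      q[good] <- solve(A, as.numeric(b))
    }
  }
  pmin(pmax(q, 0), 1)
}

#' Net transition-path flux between source and sink
#'
#' Gross reactive flux f_ij = pi_i q-_i T_ij q+_j for i != j, where q+ is
#' the forward committor and q- the backward committor of the time-reversed
#' chain (probability of having last come from the source); detailed
#' balance is not assumed, and for reversible chains q- reduces to 1 - q+.
#' Net flux is F_ij = max(0, f_ij - f_ji) and the total flux is the net
#' flux out of the source set. Flux conservation (out of source equals
#' into sink) holds to numerical accuracy.
#'
#' @param T row-stochastic matrix.
#' @param pi stationary distribution (default: computed from `T`).
#' @param q_plus forward committor (default: computed).
#' @param source_set,sink_set disjoint nonempty state sets.
#' @return list with `flux` (net flux matrix, probability mass per lag),
#'   `gross` (gross flux), `total_flux`, `q_plus`, `q_minus`, `pi`.
#' @export
net_flux <- function(T, source_set, sink_set, pi = NULL, q_plus = NULL) {
  T <- as_dense(T)
  pi <- pi %||% stationary_distribution(T)
  q <- q_plus %||% committor(T, source_set, sink_set)
  # backward committor: forward committor of the time-reversed chain with
  # the roles of source and sink exchanged
  pos <- pi > 0
  qm <- numeric(nrow(T))
  if (any(pos)) {
    Trev <- t(T[pos, pos, drop = FALSE] * pi[pos]) / pi[pos]
    # map the boundary sets into the recurrent subspace
    map <- match(seq_len(nrow(T)), which(pos))
    src_r <- stats::na.omit(map[source_set])
    snk_r <- stats::na.omit(map[sink_set])
    qm[pos] <- committor(Trev, source_set = snk_r, sink_set = src_r)
  }
  f <- (pi * qm) * T * rep(q, each = nrow(T))
  diag(f) <- 0
  F <- pmax(f - t(f), 0)
  total <- sum(F[source_set, , drop = FALSE])
  list(flux = F, gross = f, total_flux = total, q_plus = q, q_minus = qm,
       pi = pi)
}

#' Highest-flux pathways by iterative bottleneck decomposition
#'
#' Repeatedly finds the source-to-sink path whose minimum edge flux
#' (bottleneck) is largest — the widest path, by a max-min variant of
#' Dijkstra's algorithm — records it, and subtracts its bottleneck flux
#' from every edge along it. Ties break to the lowest state index. Stops
#' early when the remaining flux is exhausted.
#'
#' @param F net flux matrix (from [net_flux()]).
#' @param source_set,sink_set state sets.
#' @param n_paths number of paths to extract (default 10).
#' @param total_flux total flux used for the reported fractions (default
#'   `sum(F[source_set, ])`).
#' @return data frame with columns `path` (dash-separated state sequence),
#'   `flux`, `fraction`; attribute `paths` holds the integer sequences.
#' @export
top_flux_paths <- function(F, source_set, sink_set, n_paths = 10,
                           total_flux = NULL) {
  F <- as_dense(F)
  K <- nrow(F)
  source_set <- as.integer(source_set); sink_set <- as.integer(sink_set)
  total_flux <- total_flux %||% sum(F[source_set, , drop = FALSE])
  paths <- list(); fluxes <- numeric(0)
  for (p in seq_len(n_paths)) {
    width <- rep(-Inf, K)
    pred <- rep(NA_integer_, K)
    width[source_set] <- Inf
    done <- rep(FALSE, K)
    repeat {
      cand <- which(!done & width > 0)
      if (!length(cand)) break
      i <- cand[which.max(width[cand])]
      done[i] <- TRUE
      relax <- pmin(width[i], F[i, ])
      upd <- which(!done & relax > width)
      width[upd] <- relax[upd]
      pred[upd] <- i
    }
    best <- sink_set[which.max(width[sink_set])]
    bw <- width[best]
    if (!is.finite(bw) || bw <= 1e-15) break
    # backtrack
    seq_rev <- best
    while (!is.na(pred[seq_rev[1]])) seq_rev <- c(pred[seq_rev[1]], seq_rev)
    path <- seq_rev
    idx <- cbind(path[-length(path)], path[-1])
    F[idx] <- F[idx] - bw
    paths[[p]] <- path
    fluxes[p] <- bw
  }
  if (length(fluxes) < n_paths)
    message(sprintf("flux exhausted after %d path(s)", length(fluxes)))
  out <- data.frame(
    path = vapply(paths, function(p) paste(p, collapse = "-"), character(1)),
    flux = fluxes,
    fraction = if (total_flux > 0) fluxes / total_flux else NA_real_)
  attr(out, "paths") <- paths
  out
}

#' Features at transition events between two states
#'
#' Locates frames where the label changes from `from_state` to `to_state`
#' and the destination persists for at least `min_residence_frames`
#' (transitions without recrossing), and returns the feature rows at the
#' last frame in the origin state.
#'
#' @param labels integer label vector.
#' @param features data frame of per-frame features (same length).
#' @param from_state,to_state state indices.
#' @param min_residence_frames minimum residence in the destination
#'   (frames).
#' @return data frame of feature rows at the transition frames (possibly
#'   empty), with a `frame` column.
#' @export
transition_event_features <- function(labels, features, from_state, to_state,
                                      min_residence_frames = 1) {
  labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(nrow(features) == n)
  if (n < 2) return(cbind(frame = integer(0), features[0, , drop = FALSE]))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  run_end <- rep(ends, r$lengths)
  runlen <- run_end - seq_len(n) + 1L
  t <- which(labels[-n] == from_state & labels[-1] == to_state)
  t <- t[runlen[t + 1L] >= min_residence_frames]
  cbind(frame = t, as.data.frame(features)[t, , drop = FALSE])
}

#' Two-dimensional free-energy surface by Boltzmann inversion
#'
#' Histograms the samples and sets F_bin = -kT log(n_bin / n_max), so the
#' deepest bin is at 0 and empty bins are undefined (`NA`).
#'
#' @param x,y equal-length samples.
#' @param bin_x,bin_y bin widths (positive).
#' @param kT energy unit (default 1).
#' @return list with `x_mid`, `y_mid`, `F` (matrix, `NA` for empty bins),
#'   `counts`.
#' @export
free_energy_surface <- function(x, y, bin_x, bin_y, kT = 1) {
  if (!length(x)) stopf("no samples")
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (bin_x <= 0 || bin_y <= 0) stopf("bin sizes must be positive")
  bx <- seq(floor(min(x) / bin_x) * bin_x, max(x) + bin_x, by = bin_x)
  by <- seq(floor(min(y) / bin_y) * bin_y, max(y) + bin_y, by = bin_y)
  ix <- findInterval(x, bx, rightmost.closed = TRUE)
  iy <- findInterval(y, by, rightmost.closed = TRUE)
  nx <- length(bx) - 1L
  ny <- length(by) - 1L
  counts <- matrix(tabulate((iy - 1L) * nx + ix, nbins = nx * ny), nx, ny)
  F <- -kT * log(counts / max(counts))
  F[counts == 0] <- NA
  list(x_mid = bx[-length(bx)] + bin_x / 2, y_mid = by[-length(by)] + bin_y / 2,
       F = F, counts = counts)
}

#' Most central conformations of a set (medoids)
#'
#' Returns the `n` conformations with the smallest mean pairwise
#' superposed Calpha RMSD to all the rest — the most typical members of a
#' state. Exact for up to `max_exact` conformations; larger sets are
#' subsampled deterministically.
#'
#' @param coords list of m x 3 coordinate matrices (matched atoms).
#' @param n number of medoids (default 3).
#' @param max_exact exact-computation cutoff (default 2000).
#' @param seed seed for the subsample above `max_exact`.
#' @return integer indices into `coords`, ordered by centrality.
#' @export
medoid_conformations <- function(coords, n = 3, max_exact = 2000, seed = 1L) {
  N <- length(coords)
  if (N < n) stopf("need at least n = %d conformations", n)
  use <- seq_len(N)
  if (N > max_exact)
    use <- sort(with_seed(seed, sample.int(N, max_exact)))
  m <- length(use)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      D[i, j] <- D[j, i] <- ca_rmsd(coords[[use[i]]], coords[[use[j]]])
    }
  }
  score <- rowMeans(D) * m / (m - 1)   # mean over the *other* members
  use[order(score, use)][seq_len(n)]
}
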