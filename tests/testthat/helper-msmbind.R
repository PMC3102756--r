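# Shared fixtures and independent oracles, built in code.

# A random row-stochastic matrix with strictly positive entries.
random_stochastic <- function(K, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(K * K) + 0.05, K, K)
  m / rowSums(m)
}

# Brute-force sliding-window transition counting oracle: literal double
# loop over window positions, checking the destination-residence rule
# frame by frame.
oracle_count <- function(labels_list, lag, min_res, K) {
  counts <- matrix(0, K, K)
  for (l in labels_list) {
    n <- length(l)
    if (n <= lag) next
    for (t in seq_len(n - lag)) {
      x <- l[t]; y <- l[t + lag]
      if (x == y) {
        counts[x, y] <- counts[x, y] + 1
      } else {
        win <- (t + lag):(t + lag + min_res - 1)
        if (max(win) <= n && all(l[win] == y))
          counts[x, y] <- counts[x, y] + 1
      }
    }
  }
  counts
}

# Independent signed-dihedral oracle: plane normals and a triple-product
# sign, constructed differently from the implementation.
oracle_dihedral <- function(a, h1, h2, b) {
  n1 <- pracma_cross(a - h1, h2 - h1)
  n2 <- pracma_cross(b - h1, h2 - h1)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosang <- min(1, max(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  s <- sum(pracma_cross(n1, n2) * (h2 - h1))
  if (s < 0) ang <- -ang
  ang
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Exhaustive optimal k-centers radius with centers restricted to the data
# points (for small n only).
oracle_kcenters_radius <- function(points, k) {
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  best <- Inf
  for (cmb in utils::combn(n, k, simplify = FALSE)) {
    r <- max(apply(D[, cmb, drop = FALSE], 1, min))
    best <- min(best, r)
  }
  best
}

# Monte-Carlo first-passage-time oracle: simulate `n_walkers` independent
# chains from `start` until they hit `target`, vectorized over walkers.
oracle_mc_fpt <- function(T, start, target, n_walkers, lag = 1,
                          max_steps = 1e5, seed = 1) {
  set.seed(seed)
  K <- nrow(T)
  cum <- t(apply(T, 1, cumsum))
  state <- rep(start, n_walkers)
  steps <- rep(NA_real_, n_walkers)
  active <- rep(TRUE, n_walkers)
  for (s in seq_len(max_steps)) {
    u <- stats::runif(sum(active))
    cur <- state[active]
    nxt <- integer(length(cur))
    for (k in seq_len(K)) {
      sel <- cur == k
      if (any(sel))
        nxt[sel] <- findInterval(u[sel], cum[k, ], left.open = TRUE) + 1L
    }
    state[active] <- nxt
    hit <- nxt %in% target
    idx <- which(active)[hit]
    steps[idx] <- s
    active[idx] <- FALSE
    if (!any(active)) break
  }
  mean(steps, na.rm = TRUE) * lag
}

# Tiny planted 2-state spec used across tests.
two_state_spec <- function(p01 = 0.1, p10 = 0.1, seed = 1) {
  P <- matrix(c(1 - p01, p01, p10, 1 - p10), 2, 2, byrow = TRUE)
  mu <- matrix(c(0, 0, 10, 1, 10, 0, 0,
                 30, -20, 2, 0.5, 2, 0, 0), 2, 7, byrow = TRUE)
  planted_chain_spec(P, mu, matrix(0.5, 2, 7), seed = seed)
}
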