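# Transition counting with a sliding window and a recrossing filter,
# row-normalized transition matrices, stationary distributions, and the
# implied-timescale Markovianity test.

#' Count transitions with a sliding window and recrossing filter
#'
#' For every frame `t` with `t + lag` inside the trajectory, the ordered
#' pair `(x, y) = (labels[t], labels[t + lag])` is counted. Self pairs
#' (`x == y`) are always counted. A cross pair (`x != y`) is accepted only
#' if the destination state persists: frames `t+lag .. t+lag+min_residence-1`
#' must all be `y` (a residence window truncated by the trajectory end
#' rejects the count, since the residence cannot be verified). This
#' suppresses spurious counts from fast recrossing at state boundaries.
#' Trajectories are never concatenated.
#'
#' @param label_trajs list of integer label vectors (1-based), or a single
#'   vector.
#' @param lag_frames lag time in frames (>= 1).
#' @param min_residence_frames minimum destination residence in frames
#'   (>= 1; 1 disables the filter). Default 15 frames (300 ps at 20 ps
#'   spacing).
#' @param K number of states (default: maximum observed label).
#' @return K x K sparse count matrix (`Matrix::dgCMatrix`).
#' @export
count_transitions <- function(label_trajs, lag_frames,
                              min_residence_frames = 15, K = NULL) {
  if (is.numeric(label_trajs)) label_trajs <- list(label_trajs)
  if (!length(label_trajs)) stopf("empty trajectory list")
  lag <- as.integer(lag_frames)
  m <- as.integer(min_residence_frames)
  if (lag < 1) stopf("lag_frames must be >= 1")
  if (m < 1) stopf("min_residence_frames must be >= 1")
  K <- K %||% max(vapply(label_trajs, function(l) if (length(l)) max(l) else 0L,
                         numeric(1)))
  K <- as.integer(K)
  ii <- integer(0); jj <- integer(0)
  for (l in label_trajs) {
    l <- as.integer(l)
    n <- length(l)
    if (n <= lag) next
    x <- l[seq_len(n - lag)]
    y <- l[seq_len(n - lag) + lag]
    keep <- x == y
    if (m == 1L) {
      keep <- rep(TRUE, length(x))
    } else if (any(!keep)) {
      # forward run length of the label starting at each frame
      r <- rle(l)
      ends <- cumsum(r$lengths)
      run_end <- rep(ends, r$lengths)
      runlen <- run_end - seq_len(n) + 1L
      ok <- runlen[seq_len(n - lag) + lag] >= m
      keep <- keep | ok
    }
    ii <- c(ii, x[keep]); jj <- c(jj, y[keep])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(K, K))
}

#' Row-normalize a count matrix into a transition probability matrix
#'
#' Rows with no counts become absorbing self-loops (probability 1 on the
#' diagonal), a conservative convention for unvisited or terminal states.
#'
#' @param counts square nonnegative count matrix (dense or sparse).
#' @return row-stochastic matrix of the same storage class.
#' @export
transition_matrix <- function(counts) {
  if (!is_square(counts)) stopf("count matrix must be square")
  if (any(counts < 0)) stopf("count matrix must be nonnegative")
  rs <- Matrix::rowSums(counts)
  zero <- rs == 0
  rs[zero] <- 1
  if (inherits(counts, "Matrix")) {
    T <- Matrix::Diagonal(x = 1 / rs) %*% counts
    if (any(zero))
      T <- T + Matrix::sparseMatrix(i = which(zero), j = which(zero), x = 1,
                                    dims = dim(counts))
    methods::as(T, "CsparseMatrix")
  } else {
    T <- counts / rs
    if (any(zero)) T[cbind(which(zero), which(zero))] <- 1
    T
  }
}

# Edge list (i, j) of the nonzero entries.
nonzero_edges <- function(M) {
  S <- as_triplets(M)
  cbind(S$i, S$j)
}

# Closed communicating classes of a stochastic matrix (edges where T > 0).
closed_classes <- function(T) {
  K <- nrow(T)
  e <- nonzero_edges(T)
  g <- igraph::make_graph(as.vector(t(e)), n = K, directed = TRUE)
  sc <- igraph::components(g, mode = "strong")
  memb <- sc$membership
  cross <- memb[e[, 1]] != memb[e[, 2]]
  leaves <- unique(memb[e[, 1]][cross])
  closed <- setdiff(seq_len(sc$no), leaves)
  lapply(closed, function(cl) which(memb == cl))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector for eigenvalue 1, computed on the (single) closed
#' communicating class; transient states receive probability 0. Dense
#' eigen-decomposition for small matrices, Krylov iteration
#' ([RSpectra::eigs()]) for large ones, with a power-iteration fallback.
#'
#' @param T row-stochastic matrix.
#' @return nonnegative vector summing to 1 with `pi %*% T = pi`.
#' @export
stationary_distribution <- function(T) {
  check_row_stochastic(T)
  K <- nrow(T)
  cls <- closed_classes(T)
  if (length(cls) > 1)
    stopf("chain is reducible with %d closed classes (e.g. states {%s} and {%s})",
          length(cls), paste(utils::head(cls[[1]], 5), collapse = ","),
          paste(utils::head(cls[[2]], 5), collapse = ","))
  idx <- cls[[1]]
  Tc <- T[idx, idx, drop = FALSE]
  # renormalize (drops of probability to transient states cannot occur for
  # a closed class, but guard against round-off)
  Tc <- Tc / Matrix::rowSums(Tc)
  n <- length(idx)
  v <- NULL
  if (n == 1) {
    v <- 1
  } else if (n <= 500) {
    e <- eigen(t(as_dense(Tc)))
    i <- which.min(abs(e$values - 1))
    v <- abs(Re(e$vectors[, i]))
  } else {
    e <- tryCatch(RSpectra::eigs(Matrix::t(Tc), k = 1, which = "LR"),
                  error = function(e) NULL)
    if (!is.null(e) && length(e$values) == 1 &&
        abs(Re(e$values[1]) - 1) < 1e-6) {
      v <- abs(Re(e$vectors[, 1]))
    } else {
      # power iteration fallback
      v <- rep(1 / n, n)
      for (it in seq_len(10000)) {
        v2 <- as.numeric(Matrix::crossprod(Tc, v))
        v2 <- v2 / sum(v2)
        if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
        v <- v2
      }
    }
  }
  pi <- numeric(K)
  pi[idx] <- v / sum(v)
  pi
}

#' Build a transition model from label trajectories
#'
#' Convenience constructor bundling counts, the row-stochastic matrix and
#' its stationary distribution, with the lag and residence parameters
#' recorded. Populations are taken from the stationary eigenvector (the
#' equilibrium probabilities of the model); raw frame-count populations are
#' also reported for comparison.
#'
#' @inheritParams count_transitions
#' @param dt_ps frame spacing in ps (default 20).
#' @return object of class `transition_model` with elements `counts`, `T`,
#'   `pi`, `pi_raw`, `lag_frames`, `lag_ns`, `min_residence_frames`, `dt_ps`.
#' @export
transition_model <- function(label_trajs, lag_frames,
                             min_residence_frames = 15, dt_ps = 20,
                             K = NULL) {
  if (is.numeric(label_trajs)) label_trajs <- list(label_trajs)
  counts <- count_transitions(label_trajs, lag_frames, min_residence_frames,
                              K = K)
  T <- transition_matrix(counts)
  pi <- stationary_distribution(T)
  tab <- tabulate(unlist(label_trajs), nbins = nrow(T))
  structure(list(counts = counts, T = T, pi = pi, pi_raw = tab / sum(tab),
                 lag_frames = as.integer(lag_frames),
                 lag_ns = lag_frames * dt_ps / 1000,
                 min_residence_frames = as.integer(min_residence_frames),
                 dt_ps = dt_ps),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "<transition_model> %d states, lag = %d frames (%.3g ns), min residence = %d frames, %g total counts\n",
    nrow(x$T), x$lag_frames, x$lag_ns, x$min_residence_frames,
    sum(x$counts)))
  invisible(x)
}

# Leading eigenvalues (by real part, descending) of a stochastic matrix.
leading_eigenvalues <- function(T, m) {
  K <- nrow(T)
  m <- min(m, K)
  if (K <= 500) {
    ev <- eigen(as_dense(T), only.values = TRUE)$values
  } else {
    ev <- tryCatch(RSpectra::eigs(T, k = min(m + 2, K - 1), which = "LR")$values,
                   error = function(e) eigen(as_dense(T),
                                             only.values = TRUE)$values)
  }
  if (any(abs(Im(ev)) > 1e-8))
    warnf("complex transition-matrix eigenvalues (max |Im| = %.3g); using real parts",
          max(abs(Im(ev))))
  ev <- Re(ev)
  sort(ev, decreasing = TRUE)[seq_len(m)]
}

#' Implied timescales as a function of lag time
#'
#' For each lag, estimates a transition matrix and converts its leading
#' eigenvalues below 1 into timescales t_i = -tau / log(lambda_i). A
#' Markovian discretization yields lag-independent timescales; the curves
#' leveling off is the standard model-validation test.
#'
#' @param label_trajs list of integer label vectors.
#' @param lag_frames_list integer vector of lags (frames).
#' @param n_timescales number of timescales per lag (default 5).
#' @param min_residence_frames recrossing filter (frames, default 1).
#' @param dt_ps frame spacing (ps).
#' @return object of class `implied_timescales`: list with `lags_ns` and a
#'   `timescales_ns` matrix (rows = lags). Eigenvalues at or above 1 give
#'   `Inf`; nonpositive eigenvalues give `NA`.
#' @export
implied_timescales <- function(label_trajs, lag_frames_list,
                               n_timescales = 5, min_residence_frames = 1,
                               dt_ps = 20) {
  lag_frames_list <- as.integer(lag_frames_list)
  stopifnot(all(lag_frames_list >= 1))
  ts <- matrix(NA_real_, length(lag_frames_list), n_timescales)
  for (i in seq_along(lag_frames_list)) {
    lag <- lag_frames_list[i]
    counts <- count_transitions(label_trajs, lag, min_residence_frames)
    T <- transition_matrix(counts)
    ev <- leading_eigenvalues(T, n_timescales + 1L)
    ev <- ev[-1]                      # drop the stationary eigenvalue
    tau <- lag * dt_ps / 1000
    t_i <- rep(NA_real_, length(ev))
    t_i[ev >= 1 - 1e-12] <- Inf
    pos <- ev > 0 & ev < 1 - 1e-12
    t_i[pos] <- -tau / log(ev[pos])
    ts[i, seq_along(t_i)] <- t_i
  }
  structure(list(lags_ns = lag_frames_list * dt_ps / 1000,
                 lags_frames = lag_frames_list, timescales_ns = ts),
            class = "implied_timescales")
}

#' @export
print.implied_timescales <- function(x, ...) {
  cat("<implied_timescales>\n")
  print(cbind(lag_ns = x$lags_ns, x$timescales_ns))
  invisible(x)
}

#' Choose a working lag time from an implied-timescale curve
#'
#' Finds the smallest lag after which the slowest implied timescale changes
#' by less than `rel_tol` between successive lags (the plateau), then steps
#' one grid point beyond it, mirroring the practice of building the model
#' slightly past the leveling-off point.
#'
#' @param curve an [implied_timescales()] object with at least 3 lags.
#' @param rel_tol relative change defining the plateau (default 0.1).
#' @return list with `lag_ns`, `lag_frames`, `plateau_index`, and the
#'   successive relative changes (`rel_change`).
#' @export
choose_lag <- function(curve, rel_tol = 0.1) {
  stopifnot(inherits(curve, "implied_timescales"))
  s <- curve$timescales_ns[, 1]
  if (length(s) < 3) stopf("need at least 3 lags")
  if (any(!is.finite(s)))
    stopf("slowest implied timescale is not finite at all lags")
  rel <- abs(diff(s)) / abs(s[-length(s)])
  plateau <- which(rel < rel_tol)
  if (!length(plateau))
    stopf("no plateau found (min relative change %.3g >= %.3g); extend the lag list",
          min(rel), rel_tol)
  i <- plateau[1]
  pick <- min(i + 1L, length(s))
  list(lag_ns = curve$lags_ns[pick], lag_frames = curve$lags_frames[pick],
       plateau_index = i, rel_change = rel)
}
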