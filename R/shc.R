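# Super-level-set hierarchical spectral lumping of microstates into
# macrostates. Macrostates are seeded in the densest regions first (so
# highly populated metastable basins are identified before sparse ones) and
# grown as lower-density microstates enter; high- and low-resolution state
# sets are lumped separately and combined with disjoint label ranges.

#' Default density levels for the hierarchical lumping
#'
#' Cumulative-density fractions at which the hierarchy is cut, for the
#' high-resolution (bound-regime) and low-resolution (diffusing-regime)
#' state sets. The coarse two-level ladder for the diffusing regime
#' reflects that a detailed hierarchy of freely diffusing states carries
#' little information.
#'
#' @return list with `levels_high` and `levels_low`.
#' @export
density_levels <- function() {
  list(levels_high = c(0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85,
                       0.90, 0.95, 0.99),
       levels_low = c(0.4, 0.95))
}

#' Per-microstate densities
#'
#' Fraction of all frames assigned to each microstate. Accepts either label
#' trajectories (frames counted directly) or a transition count matrix
#' (row sums used as frame weights).
#'
#' @param x list of label vectors, a single vector, or a count matrix.
#' @param K number of states (labels input only).
#' @return numeric vector summing to 1.
#' @export
state_densities <- function(x, K = NULL) {
  if (is.list(x) || (is.numeric(x) && is.null(dim(x)))) {
    l <- unlist(x)
    tab <- tabulate(as.integer(l), nbins = K %||% max(l))
    return(tab / sum(tab))
  }
  rs <- Matrix::rowSums(x)
  rs / sum(rs)
}

#' Super level sets of a density vector
#'
#' For each level L, the minimal prefix of states sorted by descending
#' density whose cumulative density reaches L. Sets are nested across
#' increasing levels. Ties in density break to the lowest state index.
#'
#' @param densities nonnegative vector (normalized internally).
#' @param levels increasing fractions in (0, 1].
#' @return list of integer index vectors, one per level.
#' @export
super_level_sets <- function(densities, levels) {
  if (any(diff(levels) <= 0) || any(levels <= 0) || any(levels > 1))
    stopf("levels must be strictly increasing fractions in (0, 1]")
  d <- densities / sum(densities)
  ord <- order(-d, seq_along(d))
  cum <- cumsum(d[ord])
  lapply(levels, function(L) ord[seq_len(which(cum >= L - 1e-12)[1])])
}

#' Spectral split of a microstate subgraph
#'
#' Decides how many kinetic blocks a connected set of microstates contains
#' and partitions it. The coupling matrix is symmetrized, degree-normalized
#' (D^-1/2 W D^-1/2), and its leading eigenvalues examined: the number of
#' clusters is the position of the largest gap among the leading
#' eigenvalues (capped at 5). A strongly mixing component has a large gap
#' after the first eigenvalue and returns a single cluster. Memberships
#' come from a deterministic k-centers-seeded k-means partition of the
#' leading-eigenvector embedding (rows normalized to the unit sphere).
#'
#' @param W square nonnegative coupling matrix (e.g. transition counts or
#'   probabilities restricted to the set); asymmetry is removed by
#'   symmetrization.
#' @param max_clusters cap on the number of clusters (default 5).
#' @return integer cluster membership vector (1-based).
#' @export
spectral_split <- function(W, max_clusters = 5) {
  n <- nrow(W)
  if (n == 0) stopf("empty subgraph")
  if (n == 1) return(1L)
  S <- (W + Matrix::t(W)) / 2
  deg <- Matrix::rowSums(S)
  if (any(deg == 0)) {
    # isolated states cannot be split spectrally; give each its own cluster
    memb <- integer(n)
    iso <- deg == 0
    sub <- which(!iso)
    if (length(sub) > 1) {
      memb[sub] <- spectral_split(S[sub, sub, drop = FALSE], max_clusters)
    } else memb[sub] <- 1L
    memb[iso] <- max(memb, 0L) + seq_len(sum(iso))
    return(memb)
  }
  isq <- 1 / sqrt(deg)
  if (inherits(S, "Matrix")) {
    A <- Matrix::Diagonal(x = isq) %*% S %*% Matrix::Diagonal(x = isq)
  } else {
    A <- S * tcrossprod(isq)
  }
  m <- min(max_clusters + 1L, n)
  if (n <= 400) {
    e <- eigen(as_dense(A), symmetric = TRUE)
    vals <- e$values[seq_len(m)]
    vecs <- e$vectors[, seq_len(m), drop = FALSE]
  } else {
    es <- RSpectra::eigs_sym(A, k = m, which = "LA")
    ordv <- order(es$values, decreasing = TRUE)
    vals <- es$values[ordv]
    vecs <- es$vectors[, ordv, drop = FALSE]
  }
  gaps <- vals[-length(vals)] - vals[-1]
  k <- which.max(gaps[seq_len(min(max_clusters, length(gaps)))])
  if (k == 1) return(rep(1L, n))
  emb <- vecs[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  emb <- emb / nrm
  init <- k_centers(emb, k, auto_shrink = TRUE)
  if (init$k < k) return(init$labels)
  km <- stats::kmeans(emb, centers = emb[init$center_idx, , drop = FALSE],
                      iter.max = 100)
  as.integer(km$cluster)
}

# Connected components (undirected) of a coupling matrix.
coupling_components <- function(S) {
  n <- nrow(S)
  e <- nonzero_edges(S)
  g <- igraph::make_graph(as.vector(t(e)), n = n, directed = FALSE)
  igraph::components(g, mode = "weak")$membership
}

#' Lump microstates into macrostates (super-level-set hierarchy)
#'
#' Within each regime, iterates the density levels from the densest
#' (lowest cumulative fraction) upward. At each level, the coupling graph
#' restricted to the level set is decomposed into connected components and
#' each component is partitioned by [spectral_split()]. A resulting cluster
#' containing no previously assigned microstate seeds a new macrostate;
#' in a cluster that does contain assigned states, each new state joins the
#' macrostate it is most strongly coupled to (largest total symmetrized
#' count into the macrostate's members, applied iteratively so attachments
#' can chain).
#' Macrostates seeded at denser levels are never dissolved later, only
#' grown. After the final level, any remaining unassigned state joins its
#' strongest-coupled neighbour's macrostate; an isolated zero-count state
#' becomes its own macrostate with a warning. The two regimes are lumped
#' separately (their state sizes are not comparable) and combined with
#' disjoint macrostate label ranges.
#'
#' @param counts microstate transition count matrix.
#' @param regime per-microstate regime flags (`"high"`/`"low"`), e.g. from
#'   [two_regime_assign()]; a single-regime model may pass all-`"high"`.
#' @param levels list with `levels_high`, `levels_low` (see
#'   [density_levels()]).
#' @param densities per-microstate densities (default: from `counts` row
#'   sums).
#' @return object of class `macro_mapping`: list with `micro_to_macro`,
#'   `M`, `macro_populations` (aggregated microstate densities),
#'   `level_of_seed`, `macro_regime`.
#' @export
shc_lump <- function(counts, regime = rep("high", nrow(counts)),
                     levels = density_levels(), densities = NULL) {
  K <- nrow(counts)
  stopifnot(length(regime) == K)
  densities <- densities %||% state_densities(counts)
  S <- (counts + Matrix::t(counts)) / 2
  assign_all <- rep(NA_integer_, K)
  seed_level <- numeric(0)
  macro_regime <- character(0)
  n_macro <- 0L

  lump_regime <- function(r, lv) {
    idx <- which(regime == r)
    if (!length(idx)) return(invisible(NULL))
    d_r <- densities[idx]
    if (sum(d_r) == 0) d_r <- rep(1, length(idx))
    sets <- super_level_sets(d_r, lv)
    Sr <- S[idx, idx, drop = FALSE]
    for (li in seq_along(sets)) {
      set <- sets[[li]]
      Ss <- Sr[set, set, drop = FALSE]
      comp <- coupling_components(Ss)
      for (cc in unique(comp)) {
        members <- set[comp == cc]             # regime-local indices
        glob <- idx[members]
        if (!anyNA(assign_all[glob]) ) next    # fully assigned already
        cl <- spectral_split(Sr[members, members, drop = FALSE])
        for (ci in unique(cl)) {
          cmem <- glob[cl == ci]
          have <- cmem[!is.na(assign_all[cmem])]
          need <- cmem[is.na(assign_all[cmem])]
          if (!length(need)) next
          if (!length(have)) {
            n_macro <<- n_macro + 1L
            assign_all[need] <<- n_macro
            seed_level <<- c(seed_level, lv[li])
            macro_regime <<- c(macro_regime, r)
          } else {
            attach_by_coupling(need, cmem)
          }
        }
      }
    }
    # leftover states beyond the last level
    rest <- idx[is.na(assign_all[idx])]
    if (length(rest)) attach_by_coupling(rest, idx, orphan_ok = TRUE, r = r)
    invisible(NULL)
  }

  attach_by_coupling <- function(need, pool, orphan_ok = FALSE, r = NA) {
    # iteratively attach unassigned states to the strongest-coupled
    # assigned neighbour within `pool`; passes repeat so attachments chain
    need <- need[is.na(assign_all[need])]
    repeat {
      if (!length(need)) break
      ap <- pool[!is.na(assign_all[pool])]
      if (!length(ap)) break
      tri <- as_triplets(S[need, ap, drop = FALSE])
      tri <- tri[tri$x > 0, , drop = FALSE]
      if (!nrow(tri)) break
      # per unassigned state: total coupling to each candidate macrostate
      # (the count flux between the state and the macrostate as a whole);
      # ties break to the lowest macrostate id
      macro_of <- assign_all[ap[tri$j]]
      agg <- stats::aggregate(x ~ i + macro_of, data.frame(
        i = tri$i, macro_of = macro_of, x = tri$x), sum)
      ord <- order(agg$i, -agg$x, agg$macro_of)
      agg <- agg[ord, , drop = FALSE]
      first <- !duplicated(agg$i)
      assign_all[need[agg$i[first]]] <<- agg$macro_of[first]
      need <- need[-agg$i[first]]
    }
    if (length(need)) {
      if (!orphan_ok)
        stopf("internal: unattachable states within a spectral cluster")
      for (s in need) {
        warnf("isolated microstate %d becomes its own macrostate", s)
        n_macro <<- n_macro + 1L
        assign_all[s] <<- n_macro
        seed_level <<- c(seed_level, NA_real_)
        macro_regime <<- c(macro_regime, r)
      }
    }
    invisible(NULL)
  }

  lump_regime("high", levels$levels_high)
  lump_regime("low", levels$levels_low)
  if (anyNA(assign_all))
    stopf("internal: %d microstates left unassigned", sum(is.na(assign_all)))
  # densify macro labels in order of first appearance by macro id
  macro_pop <- vapply(seq_len(n_macro),
                      function(m) sum(densities[assign_all == m]), numeric(1))
  structure(list(micro_to_macro = assign_all, M = n_macro,
                 macro_populations = macro_pop / sum(densities),
                 level_of_seed = seed_level, macro_regime = macro_regime),
            class = "macro_mapping")
}

#' @export
print.macro_mapping <- function(x, ...) {
  cat(sprintf("<macro_mapping> %d microstates -> %d macrostates\n",
              length(x$micro_to_macro), x$M))
  invisible(x)
}

#' Aggregate microstate counts into macrostate counts
#'
#' Sums count-matrix blocks over the mapping; total counts are preserved
#' exactly.
#'
#' @param counts microstate count matrix.
#' @param mapping a [shc_lump()] mapping (or an integer micro-to-macro
#'   vector).
#' @return dense M x M macrostate count matrix.
#' @export
macro_counts <- function(counts, mapping) {
  mm <- if (inherits(mapping, "macro_mapping")) mapping$micro_to_macro
        else as.integer(mapping)
  M <- max(mm)
  P <- Matrix::sparseMatrix(i = seq_along(mm), j = mm, x = 1,
                            dims = c(length(mm), M))
  as_dense(Matrix::t(P) %*% counts %*% P)
}

#' Map each macrostate to the planted basin of most of its frames
#'
#' Utility for synthetic-data validation: given ground-truth basin labels
#' and pipeline microstate labels per frame, returns the majority planted
#' basin of each macrostate.
#'
#' @param truth_trajs list of ground-truth basin label vectors.
#' @param micro_trajs list of microstate label vectors (same shapes).
#' @param mapping a [shc_lump()] mapping.
#' @return integer vector of length M: majority basin per macrostate.
#' @export
macro_majority_basin <- function(truth_trajs, micro_trajs, mapping) {
  truth <- unlist(truth_trajs)
  macro <- mapping$micro_to_macro[unlist(micro_trajs)]
  tab <- table(macro, truth)
  basins <- as.integer(colnames(tab))
  out <- integer(mapping$M)
  out[as.integer(rownames(tab))] <- basins[max.col(tab, ties.method = "first")]
  out
}
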