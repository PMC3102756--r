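# Microstate construction: greedy farthest-point (Gonzalez) k-centers
# clustering, product states over independent protein and ligand
# clusterings, and the two-regime bound/diffusing scheme.

#' Greedy farthest-point (k-centers) clustering
#'
#' Gonzalez's algorithm: the first center is `points[seed_index, ]`; each
#' subsequent center is the point farthest from all chosen centers (its
#' covering radius); every point is assigned to its nearest center. The
#' result is a 2-approximation to the optimal covering radius. Ties in both
#' the farthest-point and nearest-center selections break to the lowest
#' index, so the clustering is deterministic.
#'
#' @param points numeric matrix, one row per observation.
#' @param k number of clusters (>= 1, at most the number of distinct rows).
#' @param metric distance identifier (only `"euclidean"` is supported; the
#'   identifier is stored so downstream artifacts are self-describing).
#' @param seed_index row index of the initial center (default 1).
#' @param auto_shrink if `TRUE`, stop early (with a warning) when fewer than
#'   `k` distinct points exist instead of erroring.
#' @return object of class `cluster_model`: list with `centers`,
#'   `center_idx`, `labels`, `radius`, `metric`, `seed_index`, `k`.
#' @export
k_centers <- function(points, k, metric = "euclidean", seed_index = 1L,
                      auto_shrink = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- as.integer(k)
  if (k < 1) stopf("k must be >= 1")
  if (n < 1) stopf("no points to cluster")
  if (!identical(metric, "euclidean"))
    stopf("unsupported metric '%s'", metric)
  if (seed_index < 1 || seed_index > n) stopf("seed_index out of range")
  sq <- rowSums(points^2)
  dist_to <- function(i) {
    # squared distances of all points to point i, clipped at 0
    d <- sq + sq[i] - 2 * drop(points %*% points[i, ])
    d[d < 0] <- 0
    d
  }
  centers <- integer(k)
  centers[1] <- as.integer(seed_index)
  dmin <- dist_to(seed_index)
  labels <- rep(1L, n)
  j <- 1L
  while (j < k) {
    nxt <- which.max(dmin)          # first maximum = lowest index on ties
    if (dmin[nxt] <= 0) {
      if (auto_shrink) {
        warnf("only %d distinct points; returning %d centers instead of %d",
              j, j, k)
        centers <- centers[seq_len(j)]
        k <- j
        break
      }
      stopf("k = %d exceeds the number of distinct points (%d)", k, j)
    }
    j <- j + 1L
    centers[j] <- as.integer(nxt)
    dnew <- dist_to(nxt)
    upd <- dnew < dmin              # strict: ties keep the earlier center
    labels[upd] <- j
    dmin[upd] <- dnew[upd]
  }
  structure(list(centers = points[centers, , drop = FALSE],
                 center_idx = centers, labels = labels,
                 radius = sqrt(max(dmin)), metric = metric,
                 seed_index = as.integer(seed_index), k = k),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, metric = %s, covering radius = %.4g\n",
              x$k, x$metric, x$radius))
  invisible(x)
}

#' Assign points to the nearest center of an existing model
#' @param points numeric matrix.
#' @param model a [k_centers()] model.
#' @return integer labels.
#' @export
assign_to_centers <- function(points, model) {
  points <- as.matrix(points)
  C <- model$centers
  d <- outer(rowSums(points^2), rowSums(C^2), "+") - 2 * points %*% t(C)
  max.col(-d, ties.method = "first")
}

#' Combine independent protein and ligand clusterings into product states
#'
#' M protein clusters and N ligand clusters define up to M x N product
#' states; combinations that occur in no frame are dropped and the
#' remaining labels densified to `1..K`.
#'
#' @param protein_labels,ligand_labels integer label vectors of equal length.
#' @param n_ligand number of ligand clusters N (default `max(ligand_labels)`).
#' @return list with `labels` (dense integer labels), `K`, and `provenance`
#'   (data frame mapping each dense label to its protein/ligand pair).
#' @export
product_assign <- function(protein_labels, ligand_labels,
                           n_ligand = max(ligand_labels)) {
  if (length(protein_labels) != length(ligand_labels))
    stopf("label vectors differ in length (%d vs %d)",
          length(protein_labels), length(ligand_labels))
  if (!length(protein_labels))
    return(list(labels = integer(0), K = 0L,
                provenance = data.frame(micro = integer(0),
                                        protein = integer(0),
                                        ligand = integer(0))))
  raw <- (as.integer(protein_labels) - 1L) * as.integer(n_ligand) +
    as.integer(ligand_labels)
  lev <- sort(unique(raw))
  labels <- match(raw, lev)
  prov <- data.frame(micro = seq_along(lev),
                     protein = (lev - 1L) %/% n_ligand + 1L,
                     ligand = (lev - 1L) %% n_ligand + 1L)
  list(labels = labels, K = length(lev), provenance = prov)
}

#' Two-regime microstate assignment
#'
#' Frames where the ligand is in contact with the protein (minimum
#' heavy-atom distance at most `threshold_A`) are clustered at high
#' resolution: `k_protein_high` clusters on the (opening, twisting) angle
#' pair and `k_ligand_high` clusters on ligand coordinates (all heavy atoms
#' when available, otherwise the centre of mass). Frames where the ligand
#' is freely diffusing (`min_dist > threshold_A`) are clustered at low
#' resolution (`k_protein_low` angle clusters, `k_ligand_low` clusters on
#' the ligand centre of mass), since a detailed model of free diffusion
#' adds states with poor statistics but no insight. The two product-state
#' label spaces are kept disjoint and empty states dropped.
#'
#' Requested cluster counts are capped at the number of distinct points in
#' each regime, so the paper-scale defaults apply safely to small data.
#'
#' @param trajs a [feature_trajectory()] or list of them.
#' @param threshold_A regime split distance (default 5 A).
#' @param k_protein_high,k_ligand_high,k_protein_low,k_ligand_low cluster
#'   counts (defaults 50, 5000, 10, 100).
#' @param ligand_coords optional list (per trajectory) of per-frame ligand
#'   heavy-atom coordinate matrices (frames x 3*n_atoms) for the high-res
#'   ligand clustering; by default the `lig_x/y/z` centre-of-mass columns
#'   are used.
#' @param seed_index initial k-centers center (default 1).
#' @return object of class `microstate_assignment`: list with `labels`
#'   (list of per-trajectory integer vectors in `1..K`), `K`, `regime`
#'   (per-microstate `"high"`/`"low"`), `provenance`, and the fitted
#'   cluster models.
#' @export
two_regime_assign <- function(trajs, threshold_A = 5,
                              k_protein_high = 50, k_ligand_high = 5000,
                              k_protein_low = 10, k_ligand_low = 100,
                              ligand_coords = NULL, seed_index = 1L) {
  if (inherits(trajs, "feature_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  nfr <- vapply(trajs, nrow, integer(1))
  traj_id <- rep(seq_along(trajs), nfr)
  feat <- do.call(rbind, lapply(trajs, as.data.frame))
  ang <- as.matrix(feat[, c("opening_deg", "twisting_deg")])
  com <- as.matrix(feat[, c("lig_x", "lig_y", "lig_z")])
  lig_hi <- if (is.null(ligand_coords)) com else
    do.call(rbind, lapply(ligand_coords, as.matrix))
  if (nrow(lig_hi) != nrow(feat))
    stopf("ligand_coords rows (%d) do not match frames (%d)",
          nrow(lig_hi), nrow(feat))
  hi <- feat$min_dist_A <= threshold_A
  n_hi <- sum(hi); n_lo <- sum(!hi)
  if (n_hi == 0) warnf("no frames in the bound (high-resolution) regime")
  if (n_lo == 0) warnf("no frames in the diffusing (low-resolution) regime")

  cluster_regime <- function(idx, kp, kl, ligmat) {
    if (!length(idx)) return(NULL)
    mp <- k_centers(ang[idx, , drop = FALSE], min(kp, length(idx)),
                    seed_index = min(seed_index, length(idx)),
                    auto_shrink = TRUE)
    ml <- k_centers(ligmat[idx, , drop = FALSE], min(kl, length(idx)),
                    seed_index = min(seed_index, length(idx)),
                    auto_shrink = TRUE)
    pr <- product_assign(mp$labels, ml$labels, n_ligand = ml$k)
    list(protein_model = mp, ligand_model = ml, product = pr)
  }
  hi_res <- cluster_regime(which(hi), k_protein_high, k_ligand_high, lig_hi)
  lo_res <- cluster_regime(which(!hi), k_protein_low, k_ligand_low, com)

  K_hi <- if (is.null(hi_res)) 0L else hi_res$product$K
  K_lo <- if (is.null(lo_res)) 0L else lo_res$product$K
  all_labels <- integer(nrow(feat))
  if (!is.null(hi_res)) all_labels[hi] <- hi_res$product$labels
  if (!is.null(lo_res)) all_labels[!hi] <- lo_res$product$labels + K_hi
  K <- K_hi + K_lo
  regime <- c(rep("high", K_hi), rep("low", K_lo))
  prov <- rbind(
    if (!is.null(hi_res)) cbind(hi_res$product$provenance, regime = "high"),
    if (!is.null(lo_res)) {
      p <- lo_res$product$provenance
      p$micro <- p$micro + K_hi
      cbind(p, regime = "low")
    })
  labels <- split(all_labels, traj_id)
  names(labels) <- NULL
  structure(list(labels = labels, K = K, regime = regime,
                 provenance = prov, threshold_A = threshold_A,
                 high = hi_res, low = lo_res),
            class = "microstate_assignment")
}

#' @export
print.microstate_assignment <- function(x, ...) {
  cat(sprintf(
    "<microstate_assignment> K = %d microstates (%d high-res, %d low-res), %d trajectories\n",
    x$K, sum(x$regime == "high"), sum(x$regime == "low"), length(x$labels)))
  invisible(x)
}

#' Diagnostic: microstates with fewer than a minimum number of transitions
#'
#' Reports states whose total observed transitions to other states fall
#' below `min_transitions` (poor statistics). In the original workflow such
#' states motivated the low-resolution re-clustering of the diffusing
#' regime; here the 5 A rule alone defines the regimes and this check is a
#' diagnostic only.
#'
#' @param counts transition count matrix.
#' @param min_transitions threshold (default 10).
#' @return integer vector of state indices.
#' @export
poorly_sampled_states <- function(counts, min_transitions = 10) {
  off <- Matrix::rowSums(counts) - Matrix::diag(counts)
  which(off < min_transitions)
}
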