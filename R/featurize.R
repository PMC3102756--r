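# Reaction coordinates for two-lobed binding proteins: hinge opening and
# twisting dihedrals between lobe planes, ligand-site distances, and
# related geometric utilities.

#' Default hinge residue groups
#'
#' Residue groups (Calpha only) defining the opening and twisting hinge
#' dihedrals of the LAO protein. Each angle is defined by two planes sharing
#' two hinge centroids: plane A contains the lobe-I centroid and the two
#' hinge centroids; plane B contains the lobe-II centroid and the same
#' hinge centroids.
#'
#' @return named list of residue-id vectors.
#' @export
residue_groups <- function() {
  list(
    opening_outer_A  = c(6:88, 195:227),
    opening_outer_B  = 92:185,
    opening_hinge1   = 162:168,
    opening_hinge2   = 121:127,
    twisting_hinge1  = c(83:88, 194:199),
    twisting_hinge2  = c(92:97, 156:161)
  )
}

#' Binding-site residues (Calpha) used for ligand-site distances
#'
#' Protein Calpha atoms within 8 A of the ligand centre of mass in the
#' closed crystal structure.
#'
#' @return integer vector of residue ids.
#' @export
binding_site_residues <- function() {
  c(9:15, 17:19, 30, 50:53, 55:56, 67:74, 77, 83, 88, 90:92, 117:124,
    141:143, 159:162, 164, 190:191, 194:196)
}

#' Signed hinge dihedral between two planes sharing a hinge axis
#'
#' The angle between the plane through (`p_outer_A`, `p_hinge1`, `p_hinge2`)
#' and the plane through (`p_outer_B`, `p_hinge1`, `p_hinge2`), signed by
#' the scalar triple product with the hinge axis oriented from `p_hinge1`
#' to `p_hinge2`. Equivalent to the torsion angle of the four points, with
#' the coplanar same-side (cis) configuration at 0 degrees.
#'
#' @param p_outer_A,p_hinge1,p_hinge2,p_outer_B 3-vectors.
#' @return signed angle in degrees, in (-180, 180].
#' @export
hinge_dihedral <- function(p_outer_A, p_hinge1, p_hinge2, p_outer_B) {
  u <- p_hinge2 - p_hinge1
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stopf("degenerate geometry: hinge points coincide")
  u <- u / nu
  w1 <- (p_outer_A - p_hinge1)
  w1 <- w1 - sum(w1 * u) * u
  w2 <- (p_outer_B - p_hinge2)
  w2 <- w2 - sum(w2 * u) * u
  if (sqrt(sum(w1^2)) < 1e-12 || sqrt(sum(w2^2)) < 1e-12)
    stopf("degenerate geometry: outer point collinear with the hinge axis")
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- w2 / sqrt(sum(w2^2))
  cr <- c(w1[2] * w2[3] - w1[3] * w2[2],
          w1[3] * w2[1] - w1[1] * w2[3],
          w1[1] * w2[2] - w1[2] * w2[1])
  ang <- atan2(sum(cr * u), sum(w1 * w2)) * 180 / pi
  wrap_deg(ang)
}

#' Opening and twisting angles of a structure relative to a reference
#'
#' Raw hinge dihedrals are computed from residue-group Calpha centroids and
#' referenced against the same dihedrals of `reference` (conventionally the
#' closed holo crystal structure), so the reference itself scores (0, 0).
#' With the default groups and the LAO crystal structures, the open apo
#' form scores an opening angle of about +38 degrees and a twisting angle
#' of about -26 degrees.
#'
#' @param struct,reference [md_structure()] objects.
#' @param groups residue groups, see [residue_groups()].
#' @param strict require every group residue to be present (error listing
#'   missing ones); by default groups only need a nonempty intersection
#'   with the structure, so that reduced toy structures can be featurized.
#' @return named numeric vector `c(opening_deg =, twisting_deg =)`.
#' @export
opening_twisting <- function(struct, groups = residue_groups(), reference,
                             strict = FALSE) {
  raw <- function(s) {
    oa <- ca_centroid(s, groups$opening_outer_A, strict, "opening_outer_A")
    ob <- ca_centroid(s, groups$opening_outer_B, strict, "opening_outer_B")
    oh1 <- ca_centroid(s, groups$opening_hinge1, strict, "opening_hinge1")
    oh2 <- ca_centroid(s, groups$opening_hinge2, strict, "opening_hinge2")
    th1 <- ca_centroid(s, groups$twisting_hinge1, strict, "twisting_hinge1")
    th2 <- ca_centroid(s, groups$twisting_hinge2, strict, "twisting_hinge2")
    c(hinge_dihedral(oa, oh1, oh2, ob), hinge_dihedral(oa, th1, th2, ob))
  }
  a <- raw(struct) - raw(reference)
  out <- wrap_deg(a)
  names(out) <- c("opening_deg", "twisting_deg")
  out
}

#' Distance between the ligand centre of mass and the binding site
#'
#' Euclidean distance between the ligand heavy-atom centroid and the
#' centroid of the binding-site Calpha atoms.
#'
#' @param struct an [md_structure()] with at least one ligand atom.
#' @param site residue ids of the binding site (default
#'   [binding_site_residues()]).
#' @return distance in Angstrom.
#' @export
ligand_site_distance <- function(struct, site = binding_site_residues()) {
  if (!nrow(struct$ligand)) stopf("structure has no ligand heavy atoms")
  lig <- colMeans(as.matrix(struct$ligand))
  sc <- ca_centroid(struct, site, label = "binding site")
  sqrt(sum((lig - sc)^2))
}

#' Minimum protein-ligand heavy-atom distance
#'
#' @param struct an [md_structure()] with protein and ligand atoms.
#' @return minimum over all protein x ligand heavy-atom pair distances (A).
#' @export
min_heavy_distance <- function(struct) {
  if (!nrow(struct$ligand)) stopf("structure has no ligand heavy atoms")
  prot <- struct$protein[!grepl("^H", struct$protein$elety), , drop = FALSE]
  if (!nrow(prot)) stopf("structure has no protein heavy atoms")
  P <- as.matrix(prot[, c("x", "y", "z")])
  L <- as.matrix(struct$ligand)
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  sqrt(max(0, min(d2)))
}

#' Rotational autocorrelation of a unit-vector time series
#'
#' C(t) = mean over s of u(s) . u(s + t), the first-order orientational
#' autocorrelation used to compare ligand tumbling between bound and
#' unbound states.
#'
#' @param orientation_vectors n x 3 matrix of unit vectors (normalized
#'   within 1e-6).
#' @param max_lag_frames maximum lag.
#' @return numeric vector of length `max_lag_frames + 1` (lags 0..max).
#' @export
rotational_acf <- function(orientation_vectors, max_lag_frames) {
  U <- as.matrix(orientation_vectors)
  n <- nrow(U)
  if (n < 2) stopf("need at least 2 frames")
  nrm <- sqrt(rowSums(U^2))
  if (any(abs(nrm - 1) > 1e-6))
    stopf("orientation vectors must be unit length (max deviation %.2g)",
          max(abs(nrm - 1)))
  max_lag_frames <- min(max_lag_frames, n - 1L)
  vapply(0:max_lag_frames, function(t) {
    s <- seq_len(n - t)
    mean(rowSums(U[s, , drop = FALSE] * U[s + t, , drop = FALSE]))
  }, numeric(1))
}

#' Calpha RMSD after optimal rigid superposition
#'
#' Kabsch superposition (rotation + translation, reflections excluded)
#' followed by root-mean-square deviation.
#'
#' @param A,B n x 3 coordinate matrices with matched rows.
#' @return RMSD in the coordinate units (A).
#' @export
ca_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stopf("coordinate sets differ in size")
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B0, A0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Br <- B0 %*% t(R)
  sqrt(mean(rowSums((A0 - Br)^2)))
}

#' Express ligand coordinates in the protein-aligned frame
#'
#' Superposes the frame's protein Calpha atoms onto the reference structure
#' (Kabsch) and applies the same rigid transform to the ligand, so that
#' ligand positions from different frames are comparable.
#'
#' @param struct frame to align.
#' @param reference reference [md_structure()].
#' @return `struct` with protein and ligand coordinates transformed.
#' @export
align_to_reference <- function(struct, reference) {
  A <- ca_coords(reference)
  B <- ca_coords(struct)
  if (nrow(A) != nrow(B))
    stopf("structure and reference have different Calpha counts")
  muA <- colMeans(A); muB <- colMeans(B)
  s <- svd(crossprod(sweep(B, 2, muB), sweep(A, 2, muA)))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tf <- function(M) {
    M <- sweep(as.matrix(M), 2, muB) %*% t(R)
    sweep(M, 2, muA, "+")
  }
  out <- struct
  out$protein[, c("x", "y", "z")] <- tf(struct$protein[, c("x", "y", "z")])
  if (nrow(struct$ligand))
    out$ligand[, c("x", "y", "z")] <- tf(struct$ligand)
  out
}
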