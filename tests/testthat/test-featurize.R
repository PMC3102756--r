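test_that("hinge dihedral matches hand geometry and the vector oracle", {
  h1 <- c(0, 0, 1); h2 <- c(0, 0, -1)
  a <- c(1, 0, 0)
  # coplanar, outer points on the same side -> 0
  expect_equal(hinge_dihedral(a, h1, h2, c(2, 0, 0.5)), 0)
  # outer B rotated 90 degrees about the hinge axis -> |90|
  expect_equal(abs(hinge_dihedral(a, h1, h2, c(0, 1, 0))), 90)
  # antisymmetry: swapping the outer points negates the angle
  set.seed(1)
  for (i in 1:20) {
    p <- lapply(1:4, function(j) stats::rnorm(3))
    d1 <- hinge_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    d2 <- hinge_dihedral(p[[4]], p[[2]], p[[3]], p[[1]])
    expect_equal(d1, -d2, tolerance = 1e-9)
  }
  # 100 random quadruples against an independent normal-vector oracle
  set.seed(2)
  for (i in 1:100) {
    p <- lapply(1:4, function(j) stats::rnorm(3, sd = 3))
    got <- hinge_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    want <- oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(got, want, tolerance = 1e-9)
  }
  # degenerate geometry is rejected
  expect_error(hinge_dihedral(a, h1, h1, c(0, 1, 0)), "degenerate")
  expect_error(hinge_dihedral(c(0, 0, 5), h1, h2, a), "collinear")
})

test_that("opening/twisting angles round-trip through toy structures", {
  ref <- toy_reference_structure()
  expect_identical(unname(opening_twisting(ref, reference = ref)), c(0, 0))
  cases <- list(c(38.2, -26.2), c(90, 0), c(0, 0), c(-45, 30), c(120, -75),
                c(15.5, 88), c(-149, 12))
  for (a in cases) {
    s <- build_toy_structure(a[1], a[2])
    got <- opening_twisting(s, reference = ref)
    expect_equal(unname(got), a, tolerance = 1e-6)
  }
  expect_error(build_toy_structure(160, 0), "opening")
  expect_error(build_toy_structure(0, 95), "twisting")
})

test_that("angles and distances are invariant under rigid motions", {
  ref <- toy_reference_structure()
  s <- build_toy_structure(38.2, -26.2)
  # random rotation + translation applied to all atoms
  set.seed(3)
  th <- stats::runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]),
                 cos(th[1])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rx %*% Rz
  shift <- c(5, -3, 11)
  s2 <- s
  s2$protein[, c("x", "y", "z")] <-
    sweep(as.matrix(s$protein[, c("x", "y", "z")]) %*% t(R), 2, shift, "+")
  s2$ligand[, c("x", "y", "z")] <-
    sweep(as.matrix(s$ligand) %*% t(R), 2, shift, "+")
  expect_equal(opening_twisting(s2, reference = ref),
               opening_twisting(s, reference = ref), tolerance = 1e-9)
  expect_equal(min_heavy_distance(s2), min_heavy_distance(s),
               tolerance = 1e-9)
  A <- ca_coords(s); B <- ca_coords(s2)
  expect_equal(ca_rmsd(A, B), 0, tolerance = 1e-9)
})

test_that("strict featurization reports missing residues", {
  ref <- toy_reference_structure()
  s <- build_toy_structure(10, 5)
  expect_error(opening_twisting(s, reference = ref, strict = TRUE),
               "missing")
})

test_that("ligand-site distance follows two-centroid geometry", {
  s <- toy_reference_structure()
  site <- unique(s$protein$resno)
  sc <- colMeans(as.matrix(
    s$protein[s$protein$elety == "CA", c("x", "y", "z")]))
  s$ligand <- data.frame(x = sc[1], y = sc[2], z = sc[3])
  expect_equal(ligand_site_distance(s, site), 0)
  s$ligand <- data.frame(x = sc[1] + 3, y = sc[2] + 4, z = sc[3])
  expect_equal(ligand_site_distance(s, site), 5)
  # random multi-atom ligands against a direct two-centroid oracle
  set.seed(4)
  for (i in 1:10) {
    L <- matrix(stats::rnorm(9, sd = 5), 3, 3)
    s$ligand <- data.frame(x = L[, 1], y = L[, 2], z = L[, 3])
    want <- sqrt(sum((colMeans(L) - sc)^2))
    expect_equal(ligand_site_distance(s, site), want, tolerance = 1e-9)
  }
  s$ligand <- s$ligand[0, ]
  expect_error(ligand_site_distance(s, site), "ligand")
})

test_that("minimum heavy-atom distance equals the exhaustive pair loop", {
  s <- toy_reference_structure()
  p1 <- as.numeric(s$protein[1, c("x", "y", "z")])
  s$ligand <- data.frame(x = p1[1], y = p1[2], z = p1[3])
  expect_equal(min_heavy_distance(s), 0)
  s$ligand <- data.frame(x = p1[1] + 7.25, y = p1[2], z = p1[3])
  s2 <- s; s2$protein <- s$protein[1, ]
  expect_equal(min_heavy_distance(s2), 7.25)
  set.seed(5)
  for (i in 1:10) {
    L <- matrix(stats::rnorm(12, sd = 8), 4, 3)
    s$ligand <- data.frame(x = L[, 1], y = L[, 2], z = L[, 3])
    P <- as.matrix(s$protein[, c("x", "y", "z")])
    want <- min(apply(L, 1, function(l)
      min(sqrt(rowSums(sweep(P, 2, l)^2)))))
    expect_equal(min_heavy_distance(s), want, tolerance = 1e-9)
  }
})

test_that("rotational autocorrelation behaves as an isotropy probe", {
  U <- matrix(rep(c(0, 0, 1), each = 50), 50, 3)
  expect_equal(rotational_acf(U, 10), rep(1, 11))
  set.seed(6)
  n <- 1e4
  V <- matrix(stats::rnorm(3 * n), n, 3)
  V <- V / sqrt(rowSums(V^2))
  acf <- rotational_acf(V, 5)
  expect_equal(acf[1], 1)
  expect_true(all(abs(acf[-1]) < 0.05))
  expect_error(rotational_acf(V[1, , drop = FALSE], 2), "2 frames")
  expect_error(rotational_acf(V * 2, 2), "unit length")
})

test_that("superposed RMSD matches a brute-force rotation-grid oracle", {
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0), 3, 3, byrow = TRUE)
  expect_equal(ca_rmsd(A, A), 0)
  # rigidly rotated copy superposes exactly
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  expect_equal(ca_rmsd(A, A %*% t(R) + 5), 0, tolerance = 1e-9)
  expect_error(ca_rmsd(A, A[1:2, ]), "size")
  # brute force: scan rotations (coarse Euler grid + refinement)
  set.seed(7)
  B <- A + matrix(stats::rnorm(9, sd = 0.3), 3, 3)
  grid_rmsd <- function(A, B, centers, widths, steps) {
    A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
    best <- Inf
    gr <- lapply(1:3, function(i)
      seq(centers[i] - widths[i], centers[i] + widths[i],
          length.out = steps))
    bestang <- centers
    for (a in gr[[1]]) for (b in gr[[2]]) for (cc in gr[[3]]) {
      Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3)
      Rz2 <- matrix(c(cos(cc), -sin(cc), 0, sin(cc), cos(cc), 0, 0, 0, 1),
                    3, 3)
      R <- Rz1 %*% Ry %*% Rz2
      r <- sqrt(mean(rowSums((A0 - B0 %*% t(R))^2)))
      if (r < best) { best <- r; bestang <- c(a, b, cc) }
    }
    list(rmsd = best, ang = bestang)
  }
  coarse <- grid_rmsd(A, B, c(0, pi / 2, 0), c(pi, pi / 2, pi), 25)
  fine <- grid_rmsd(A, B, coarse$ang, rep(0.15, 3), 21)
  fine2 <- grid_rmsd(A, B, fine$ang, rep(0.02, 3), 21)
  expect_equal(ca_rmsd(A, B), fine2$rmsd, tolerance = 1e-3)
  expect_lte(ca_rmsd(A, B), fine2$rmsd + 1e-9)  # Kabsch is optimal
})

test_that("feature trajectories survive a text round trip", {
  spec <- lao_like_spec(seed = 8)
  f <- emit_features(sample_chain(spec, 50, 1), spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_trajectory(f, path)
  g <- read_feature_trajectory(path)
  expect_equal(as.data.frame(g), as.data.frame(f), tolerance = 1e-12)
  expect_equal(attr(g, "dt_ps"), 20)
})
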