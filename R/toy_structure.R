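# Analytic toy structures with prescribed hinge angles.
#
# A minimal point-set "protein" whose residue-group centroids realize any
# requested (opening, twisting) pair exactly under the default featurizer
# definitions. Used to verify the featurizer by round-trip: build a
# structure at known angles, featurize it, recover the angles.
#
# Geometry: the opening hinge centroids sit on the z axis and the twisting
# hinge centroids on a line parallel to y through x = -2, so the lobe-II
# centroid's azimuth about z sets the opening angle and its height sets the
# twisting angle independently; both equations solve in closed form. The
# lobe-II group necessarily contains the hinge residues (the default group
# definitions overlap), so a ballast residue is placed to keep the lobe-II
# centroid on target.

toy_resids <- list(outer_A = 6L, hinge1_o = 162L, hinge2_o = 121L,
                   hinge1_t = 194L, hinge2_t = 156L, ballast = 100L)

toy_points <- function(phi_deg, cz) {
  phi <- phi_deg * pi / 180
  p <- list()
  p$p6   <- c(1, 0, 0)            # lobe-I centroid (outer A)
  p$p162 <- c(0, 0, 1)            # opening hinge 1
  p$p121 <- c(0, 0, -1)           # opening hinge 2
  p$p194 <- c(-2, 1, 0)           # twisting hinge 1
  p$p156 <- c(-2, -1, 0)          # twisting hinge 2
  b <- c(2 * cos(phi), 2 * sin(phi), cz)   # lobe-II centroid target
  # lobe-II group members present: 162, 121, 156, ballast 100
  p$p100 <- 4 * b - p$p162 - p$p121 - p$p156
  p
}

toy_from_points <- function(p) {
  r <- toy_resids
  prot <- data.frame(
    resno = c(r$outer_A, r$hinge1_o, r$hinge2_o, r$hinge1_t, r$hinge2_t,
              r$ballast),
    elety = "CA",
    rbind(p$p6, p$p162, p$p121, p$p194, p$p156, p$p100))
  names(prot)[3:5] <- c("x", "y", "z")
  md_structure(prot, ligand = data.frame(x = 10, y = 10, z = 10))
}

toy_raw_angles <- function(phi_deg, cz) {
  s <- toy_from_points(toy_points(phi_deg, cz))
  ref <- toy_from_points(toy_points(0, 0))
  opening_twisting(s, reference = ref)
}

#' Build a toy structure with prescribed hinge angles
#'
#' Returns a synthetic point-set structure whose residue-group centroids
#' reproduce the requested opening and twisting dihedrals exactly under
#' [opening_twisting()] with the default groups, relative to the toy
#' reference `build_toy_structure(0, 0)`.
#'
#' @param opening_deg requested opening angle, in (-150, 150).
#' @param twisting_deg requested twisting angle, in (-90, 90).
#' @return an [md_structure()].
#' @export
build_toy_structure <- function(opening_deg, twisting_deg) {
  if (abs(opening_deg) >= 150)
    stopf("toy builder supports opening angles in (-150, 150)")
  if (abs(twisting_deg) >= 90)
    stopf("toy builder supports twisting angles in (-90, 90)")
  # Determine the sign conventions of the featurizer empirically, once.
  probe <- toy_raw_angles(10, 0)
  s1 <- if (probe["opening_deg"] >= 0) 1 else -1
  phi <- s1 * opening_deg
  probe_t <- toy_raw_angles(phi, 0.5)
  s2 <- if (probe_t["twisting_deg"] >= 0) 1 else -1
  cz <- s2 * tan(twisting_deg * pi / 180) * (2 * cos(phi * pi / 180) + 2)
  toy_from_points(toy_points(phi, cz))
}

#' Reference toy structure (both angles zero)
#' @return an [md_structure()].
#' @export
toy_reference_structure <- function() toy_from_points(toy_points(0, 0))
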