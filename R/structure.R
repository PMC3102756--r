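# Lightweight structure container: protein atoms plus a ligand, enough to
# compute hinge angles, distances and RMSDs. Real structures come in through
# bio3d's PDB reader; toy structures are built analytically.

#' Construct a structure object
#'
#' @param protein data frame with columns `resno` (author residue number),
#'   `elety` (atom name, e.g. "CA"), `x`, `y`, `z`.
#' @param ligand data frame of ligand heavy-atom coordinates (`x`, `y`, `z`),
#'   may have zero rows.
#' @return object of class `md_structure`.
#' @export
md_structure <- function(protein, ligand = NULL) {
  stopifnot(all(c("resno", "elety", "x", "y", "z") %in% names(protein)))
  if (is.null(ligand))
    ligand <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))
  structure(list(protein = as.data.frame(protein),
                 ligand = as.data.frame(ligand)[, c("x", "y", "z")]),
            class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("<md_structure> %d protein atoms (%d residues), %d ligand atoms\n",
              nrow(x$protein), length(unique(x$protein$resno)),
              nrow(x$ligand)))
  invisible(x)
}

#' Read a single-model PDB file
#'
#' Wraps [bio3d::read.pdb()]. ATOM records become the protein; non-water
#' HETATM heavy atoms become the ligand. Author residue numbers are used as
#' printed; insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @return an [md_structure()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  if (any(nzchar(trimws(at$insert)) & !is.na(at$insert)))
    stopf("PDB %s contains insertion codes, which are not supported", path)
  prot <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
            drop = FALSE]
  het <- het[!grepl("^H", trimws(het$elety)), , drop = FALSE]  # heavy atoms
  md_structure(
    protein = data.frame(resno = prot$resno, elety = trimws(prot$elety),
                         x = prot$x, y = prot$y, z = prot$z),
    ligand = if (nrow(het)) data.frame(x = het$x, y = het$y, z = het$z)
             else NULL)
}

# Centroid of the Calpha atoms of the given residues. Unit masses: all
# Calpha masses are equal, so mass weighting is moot and the centroid is
# bit-reproducible.
ca_centroid <- function(struct, resids, strict = FALSE, label = "group") {
  ca <- struct$protein[struct$protein$elety == "CA", , drop = FALSE]
  hit <- ca[ca$resno %in% resids, , drop = FALSE]
  if (strict) {
    miss <- setdiff(resids, ca$resno)
    if (length(miss))
      stopf("%s: missing Calpha atoms for residues %s", label,
            paste(miss, collapse = ", "))
  }
  if (!nrow(hit))
    stopf("%s: no Calpha atoms found for the requested residues", label)
  colMeans(as.matrix(hit[, c("x", "y", "z")]))
}

# Calpha coordinate matrix for the given residues (ordered by residue id).
ca_coords <- function(struct, resids = NULL) {
  ca <- struct$protein[struct$protein$elety == "CA", , drop = FALSE]
  if (!is.null(resids)) ca <- ca[ca$resno %in% resids, , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  as.matrix(ca[, c("x", "y", "z")])
}
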