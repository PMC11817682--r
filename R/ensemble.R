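#' Structural ensembles
#'
#' A `structure_ensemble` holds one topology (atom names, residue numbers and
#' types) shared by one or more coordinate frames of a receptor--ligand
#' complex. Coordinates are stored in the flat `x1,y1,z1,x2,...` layout used
#' by bio3d so that frames interoperate directly with its superposition and
#' PDB machinery.
#'
#' @param atoms data.frame with columns `eleno`, `elety` (atom name), `resid`
#'   (3-letter residue code) and `resno` (residue number).
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns,
#'   coordinates in Angstrom.
#' @param ligand_id single string naming the ligand of the complex.
#' @return an object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, xyz, ligand_id = "unknown") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("eleno", "elety", "resid", "resno")
  if (!all(need %in% names(atoms))) {
    stopf("atoms must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stopf("xyz has %d columns; expected %d (3 x %d atoms)",
          ncol(xyz), 3L * nrow(atoms), nrow(atoms))
  }
  if (nrow(xyz) < 1L) stopf("ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stopf("coordinates must be finite")
  structure(
    list(atoms = atoms, xyz = xyz, ligand_id = as.character(ligand_id)),
    class = "structure_ensemble"
  )
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> ligand %s: %d frames, %d atoms, %d residues\n",
              x$ligand_id, nrow(x$xyz), nrow(x$atoms),
              length(unique(x$atoms$resno))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `structure_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Extract one frame's coordinates as an n x 3 matrix
#' @param ensemble a `structure_ensemble`.
#' @param i frame index.
#' @return numeric matrix with one row per atom.
#' @export
frame_coords <- function(ensemble, i = 1L) {
  if (i < 1L || i > nrow(ensemble$xyz)) stopf("frame index %d out of range", i)
  matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Subset an ensemble to selected frames
#' @param ensemble a `structure_ensemble`.
#' @param i integer vector of frame indices.
#' @return a `structure_ensemble` with the selected frames.
#' @export
subset_frames <- function(ensemble, i) {
  structure_ensemble(ensemble$atoms, ensemble$xyz[i, , drop = FALSE],
                     ensemble$ligand_id)
}

#' Read a (possibly multi-model) PDB file as a structure ensemble
#'
#' MODEL/ENDMDL records become frames; a single-model file yields a one-frame
#' ensemble suitable as a reference structure.
#'
#' @param path PDB file path.
#' @param ligand_id ligand label attached to the ensemble; defaults to the
#'   file name without extension.
#' @return a `structure_ensemble`.
#' @export
read_pdb_ensemble <- function(path, ligand_id = NULL) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  keep <- pdb$atom$type == "ATOM"
  atoms <- data.frame(
    eleno = pdb$atom$eleno[keep],
    elety = pdb$atom$elety[keep],
    resid = pdb$atom$resid[keep],
    resno = pdb$atom$resno[keep],
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- as.vector(rbind(3L * which(keep) - 2L, 3L * which(keep) - 1L,
                          3L * which(keep)))
  xyz <- xyz[, cols, drop = FALSE]
  structure_ensemble(atoms, xyz,
                     ligand_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a structure ensemble to a multi-model PDB file
#' @param ensemble a `structure_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  a <- ensemble$atoms
  n <- nrow(a)
  bio3d::write.pdb(
    file = path,
    xyz = ensemble$xyz,
    type = rep("ATOM", n),
    eleno = a$eleno,
    elety = a$elety,
    resid = a$resid,
    resno = a$resno,
    chain = rep("A", n)
  )
  invisible(path)
}

#' Apply a rigid motion (rotation + translation) to every frame
#'
#' Mostly used in tests of rigid-motion invariance of features.
#'
#' @param ensemble a `structure_ensemble`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 shift vector in Angstrom.
#' @return the transformed ensemble.
#' @export
transform_ensemble <- function(ensemble, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  xyz <- ensemble$xyz
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    m <- m %*% t(rotation)
    m <- sweep(m, 2L, translation, "+")
    out[f, ] <- as.vector(t(m))
  }
  structure_ensemble(ensemble$atoms, out, ensemble$ligand_id)
}

# Resolve (resno, elety) to an atom row index; error with a readable name.
atom_index <- function(atoms, resno, elety, what = NULL) {
  i <- which(atoms$resno == resno & atoms$elety == elety)
  if (length(i) == 0L) {
    stopf("atom %s of residue %d%s not found in structure",
          elety, resno, if (is.null(what)) "" else paste0(" (", what, ")"))
  }
  i[1L]
}

#' Dihedral angle of four points
#'
#' Standard signed torsion using the atan2 formulation, wrapped to
#' `[-pi, pi)`. Degenerate (collinear) geometries are rejected.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (Angstrom).
#' @return angle in radians in `[-pi, pi)`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9 || nb2 < 1e-9) {
    stopf("degenerate (collinear) geometry: dihedral undefined")
  }
  m1 <- cross3(n1, b2 / nb2)
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Vectorized dihedrals over rows of four n x 3 matrices.
dihedral_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3_rows(b1, b2); n2 <- cross3_rows(b2, b3)
  nb2 <- row_norms(b2)
  bad <- row_norms(n1) < 1e-9 | row_norms(n2) < 1e-9 | nb2 < 1e-9
  if (any(bad)) {
    stopf("degenerate (collinear) geometry in torsion entries: %s",
          paste(which(bad), collapse = ", "))
  }
  m1 <- cross3_rows(n1, b2 / nb2)
  wrap_angle(atan2(rowSums(m1 * n2), rowSums(n1 * n2)))
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: given three reference positions, a
#' bond length, a bond angle and a dihedral, return the fourth position such
#' that `dihedral_angle(a, b, c, new)` equals `dihedral`.
#'
#' @param a,b,c length-3 reference coordinates.
#' @param bond bond length c--new in Angstrom.
#' @param angle bond angle b-c-new in radians.
#' @param dihedral target torsion a-b-c-new in radians.
#' @return length-3 coordinate vector.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stopf("reference atoms are collinear; placement undefined")
  n <- n / nn
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         -bond * sin(angle) * sin(dihedral))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}
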