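# Featurization: declarative feature specifications and their evaluation on
# structural ensembles. The three feature blocks (torsions, C-alpha pair
# distances, hydrogen-bond donor-acceptor distances) characterize the
# intracellular pocket of a 7TM receptor; residues are addressed both by
# sequence position and by Ballesteros-Weinstein (BW) label.

# --- residue chemistry tables -----------------------------------------------

# fourth atom of chi1 (N-CA-CB-X); residues absent here have no chi1
.chi1_gatom <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1"
)

# third/fourth atoms of chi2 (CA-CB-G-X); for ambiguous terminal atoms
# (Asp, Asn, Phe, Tyr, Trp, Leu, Ile, His) the lower-numbered branch is used
.chi2_datom <- c(
  ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD", GLU = "CD", HIS = "ND1",
  ILE = "CD1", LEU = "CD1", LYS = "CD", MET = "SD", PHE = "CD1", PRO = "CD",
  TRP = "CD1", TYR = "CD1"
)

# heavy-atom hydrogen-bond donors and acceptors per residue type (side chain);
# backbone N (donor) and O (acceptor) apply to every residue
.sc_donors <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH"
)
.sc_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH"
)

# Default intracellular definition for the mu opioid receptor: four residue
# ranges spanning the intracellular halves of the TM bundle plus helix 8,
# and 22 anchor residues (helix midpoints/ends and loop middles) for the
# C-alpha distance block.
.default_ranges <- list(c(84L, 116L), c(156L, 194L), c(246L, 291L),
                        c(328L, 349L))
.default_anchors <- c(84L, 91L, 99L, 102L, 105L, 116L, 156L, 164L, 170L,
                      178L, 183L, 194L, 253L, 260L, 267L, 271L, 283L, 291L,
                      328L, 338L, 343L, 349L)

.angle_names <- c("psi", "phi", "chi1", "chi2")

# atoms defining a named torsion for residue `resno` of type `resid`;
# NULL when the angle does not exist for the residue type
.angle_atoms <- function(resno, resid, angle) {
  switch(angle,
    phi  = data.frame(resno = c(resno - 1L, resno, resno, resno),
                      elety = c("C", "N", "CA", "C")),
    psi  = data.frame(resno = c(resno, resno, resno, resno + 1L),
                      elety = c("N", "CA", "C", "N")),
    chi1 = {
      g <- .chi1_gatom[resid]
      if (is.na(g)) return(NULL)
      data.frame(resno = rep(resno, 4L), elety = c("N", "CA", "CB", g))
    },
    chi2 = {
      d <- .chi2_datom[resid]
      if (is.na(d)) return(NULL)
      g <- .chi1_gatom[resid]
      data.frame(resno = rep(resno, 4L), elety = c("CA", "CB", g, d))
    },
    stopf("unknown angle name '%s'", angle)
  )
}

# --- feature specification ---------------------------------------------------

#' Feature specification
#'
#' Declares which torsions, C-alpha pairs and hydrogen-bond donor--acceptor
#' pairs are extracted from a structure. Usually built by
#' [build_default_spec()] and [derive_hbond_pairs()] rather than by hand.
#'
#' @param torsions data.frame with columns `resno`, `bw`, `resid`, `angle`
#'   (`angle` one of psi, phi, chi1, chi2).
#' @param ca_pairs data.frame with columns `resno_i`, `bw_i`, `resno_j`,
#'   `bw_j`; members must be separated by at least two sequence positions.
#' @param hb_pairs data.frame with columns `don_resno`, `don_bw`, `don_atom`,
#'   `acc_resno`, `acc_bw`, `acc_atom`; may be empty until
#'   [derive_hbond_pairs()] is applied.
#' @param hbond_cutoff donor-acceptor inclusion cutoff in Angstrom (> 0).
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(torsions, ca_pairs,
                         hb_pairs = empty_hb_pairs(), hbond_cutoff = 8.0) {
  torsions <- as.data.frame(torsions, stringsAsFactors = FALSE)
  ca_pairs <- as.data.frame(ca_pairs, stringsAsFactors = FALSE)
  hb_pairs <- as.data.frame(hb_pairs, stringsAsFactors = FALSE)
  if (hbond_cutoff <= 0) stopf("hbond_cutoff must be > 0")
  if (nrow(torsions) < 1L) stopf("torsion selection must be nonempty")
  if (nrow(ca_pairs) < 1L) stopf("ca pair selection must be nonempty")
  if (!all(torsions$angle %in% .angle_names)) {
    stopf("torsion angles must be among: %s", paste(.angle_names, collapse = ", "))
  }
  if (anyDuplicated(torsions[, c("resno", "angle")])) {
    stopf("duplicate entries in torsion selection")
  }
  key <- paste(pmin(ca_pairs$resno_i, ca_pairs$resno_j),
               pmax(ca_pairs$resno_i, ca_pairs$resno_j))
  if (anyDuplicated(key)) stopf("duplicate entries in ca pair selection")
  if (any(abs(ca_pairs$resno_i - ca_pairs$resno_j) < 2L)) {
    stopf("every ca pair must have sequence separation >= 2")
  }
  if (nrow(hb_pairs)) {
    hkey <- paste(hb_pairs$don_resno, hb_pairs$don_atom,
                  hb_pairs$acc_resno, hb_pairs$acc_atom)
    if (anyDuplicated(hkey)) stopf("duplicate entries in hbond pair selection")
  }
  structure(list(torsions = torsions, ca_pairs = ca_pairs,
                 hb_pairs = hb_pairs, hbond_cutoff = hbond_cutoff),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> N_theta=%d, N_C=%d, N_H=%d (hbond cutoff %.1f A)\n",
              nrow(x$torsions), nrow(x$ca_pairs), nrow(x$hb_pairs),
              x$hbond_cutoff))
  invisible(x)
}

#' @rdname feature_spec
#' @export
empty_hb_pairs <- function() {
  data.frame(don_resno = integer(), don_bw = character(),
             don_atom = character(), acc_resno = integer(),
             acc_bw = character(), acc_atom = character(),
             stringsAsFactors = FALSE)
}

#' Read a Ballesteros-Weinstein map from CSV
#'
#' Expects two columns, `seq_position` and `bw_label`.
#'
#' @param path CSV file path.
#' @return named character vector, names are sequence positions.
#' @export
read_bw_map <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("seq_position", "bw_label") %in% names(df))) {
    stopf("BW map must have columns seq_position, bw_label")
  }
  stats::setNames(as.character(df$bw_label), as.character(df$seq_position))
}

bw_of <- function(bw_map, resno) {
  lab <- unname(bw_map[as.character(resno)])
  ifelse(is.na(lab), as.character(resno), lab)
}

#' Build the default intracellular feature specification
#'
#' Torsions (psi, phi, chi1, chi2, omitting angles undefined for the residue
#' type) are taken over four intracellular residue ranges; the C-alpha block
#' is all unordered pairs of the 22 anchor residues with sequence separation
#' at least 2. The hydrogen-bond block is left empty until
#' [derive_hbond_pairs()] is applied to a reference structure.
#'
#' @param structure a `structure_ensemble` whose topology must contain the
#'   selected residues and atoms.
#' @param bw_map named character vector mapping sequence position to BW
#'   label (see [read_bw_map()]).
#' @param ranges list of length-2 integer vectors, the residue ranges
#'   contributing torsions; defaults to the mu-opioid intracellular ranges.
#' @param anchors integer vector of anchor residues for the C-alpha block.
#' @param hbond_cutoff cutoff passed through to the spec (Angstrom).
#' @return a `feature_spec` with an empty hydrogen-bond block.
#' @export
build_default_spec <- function(structure, bw_map,
                               ranges = .default_ranges,
                               anchors = .default_anchors,
                               hbond_cutoff = 8.0) {
  atoms <- structure$atoms
  residues <- sort(unique(unlist(lapply(ranges, function(r) seq(r[1L], r[2L])))))
  for (r in unique(c(residues, anchors))) {
    if (!any(atoms$resno == r)) {
      stopf("residue %d (BW %s) missing from structure", r, bw_of(bw_map, r))
    }
  }
  restype <- function(r) atoms$resid[match(r, atoms$resno)]
  tor <- do.call(rbind, lapply(residues, function(r) {
    rows <- lapply(.angle_names, function(a) {
      at <- .angle_atoms(r, restype(r), a)
      if (is.null(at)) return(NULL)
      # phi/psi need a flanking residue; skip angles whose atoms do not exist
      ok <- all(mapply(function(rn, el) any(atoms$resno == rn & atoms$elety == el),
                       at$resno, at$elety))
      if (!ok) return(NULL)
      data.frame(resno = r, bw = bw_of(bw_map, r), resid = restype(r),
                 angle = a, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (is.null(tor) || nrow(tor) == 0L) stopf("no torsion features resolved")
  cmb <- utils::combn(sort(unique(anchors)), 2L)
  keep <- abs(cmb[1L, ] - cmb[2L, ]) >= 2L
  ca <- data.frame(resno_i = cmb[1L, keep], bw_i = bw_of(bw_map, cmb[1L, keep]),
                   resno_j = cmb[2L, keep], bw_j = bw_of(bw_map, cmb[2L, keep]),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ca))) {
    for (r in c(ca$resno_i[i], ca$resno_j[i])) {
      if (!any(atoms$resno == r & atoms$elety == "CA")) {
        stopf("residue %d (BW %s) has no CA atom", r, bw_of(bw_map, r))
      }
    }
  }
  feature_spec(tor, ca, empty_hb_pairs(), hbond_cutoff)
}

#' Derive hydrogen-bond donor-acceptor pairs from a reference structure
#'
#' Enumerates all heavy-atom donor/acceptor pairs (backbone N and O plus the
#' standard polar side-chain N/O atoms) among the given residues and keeps
#' the pairs whose distance in the reference frame is at most `cutoff`.
#' Pairs within a single residue are excluded, as their near-constant
#' distances carry no conformational signal.
#'
#' @param spec a `feature_spec` (its torsion residues define the candidate
#'   residue set unless `residues` is given).
#' @param reference a single-frame `structure_ensemble`.
#' @param cutoff inclusion cutoff in Angstrom (> 0).
#' @param bw_map named character vector mapping position to BW label.
#' @param residues optional integer vector overriding the candidate residues.
#' @return the `feature_spec` with `hb_pairs` filled.
#' @export
derive_hbond_pairs <- function(spec, reference, cutoff = spec$hbond_cutoff,
                               bw_map = NULL, residues = NULL) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  atoms <- reference$atoms
  co <- frame_coords(reference, 1L)
  residues <- residues %||% sort(unique(spec$torsions$resno))
  bw_map <- bw_map %||% stats::setNames(
    spec$torsions$bw[!duplicated(spec$torsions$resno)],
    as.character(spec$torsions$resno[!duplicated(spec$torsions$resno)]))
  polar <- function(r, role) {
    type <- atoms$resid[match(r, atoms$resno)]
    sc <- if (role == "donor") .sc_donors[[type]] else .sc_acceptors[[type]]
    bb <- if (role == "donor") "N" else "O"
    at <- c(bb, sc)
    at[vapply(at, function(a) any(atoms$resno == r & atoms$elety == a), logical(1))]
  }
  rows <- list()
  for (rd in residues) {
    for (da in polar(rd, "donor")) {
      di <- atom_index(atoms, rd, da)
      for (ra in residues) {
        if (ra == rd) next
        for (aa in polar(ra, "acceptor")) {
          ai <- atom_index(atoms, ra, aa)
          d <- sqrt(sum((co[di, ] - co[ai, ])^2))
          if (d <= cutoff) {
            rows[[length(rows) + 1L]] <- data.frame(
              don_resno = rd, don_bw = bw_of(bw_map, rd), don_atom = da,
              acc_resno = ra, acc_bw = bw_of(bw_map, ra), acc_atom = aa,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  hb <- if (length(rows)) do.call(rbind, rows) else empty_hb_pairs()
  feature_spec(spec$torsions, spec$ca_pairs, hb, cutoff)
}

# --- evaluation --------------------------------------------------------------

# resolve a feature_spec against a topology once; returns atom-index matrices
resolve_spec <- function(spec, atoms) {
  tor_idx <- matrix(0L, nrow(spec$torsions), 4L)
  for (i in seq_len(nrow(spec$torsions))) {
    at <- .angle_atoms(spec$torsions$resno[i], spec$torsions$resid[i],
                       spec$torsions$angle[i])
    if (is.null(at)) {
      stopf("angle %s undefined for residue %d (%s)", spec$torsions$angle[i],
            spec$torsions$resno[i], spec$torsions$resid[i])
    }
    tor_idx[i, ] <- mapply(function(rn, el)
      atom_index(atoms, rn, el,
                 sprintf("torsion %s of %s", spec$torsions$angle[i],
                         spec$torsions$bw[i])),
      at$resno, at$elety)
  }
  ca_idx <- cbind(
    mapply(function(r, b) atom_index(atoms, r, "CA", paste("CA of", b)),
           spec$ca_pairs$resno_i, spec$ca_pairs$bw_i),
    mapply(function(r, b) atom_index(atoms, r, "CA", paste("CA of", b)),
           spec$ca_pairs$resno_j, spec$ca_pairs$bw_j))
  hb_idx <- if (nrow(spec$hb_pairs)) cbind(
    mapply(function(r, a) atom_index(atoms, r, a, "hbond donor"),
           spec$hb_pairs$don_resno, spec$hb_pairs$don_atom),
    mapply(function(r, a) atom_index(atoms, r, a, "hbond acceptor"),
           spec$hb_pairs$acc_resno, spec$hb_pairs$acc_atom))
  else matrix(0L, 0L, 2L)
  list(
    tor = tor_idx, ca = matrix(as.integer(ca_idx), ncol = 2L),
    hb = matrix(as.integer(hb_idx), ncol = 2L),
    tor_names = sprintf("tor:%s:%s", spec$torsions$bw, spec$torsions$angle),
    ca_names = sprintf("ca:%s-%s", spec$ca_pairs$bw_i, spec$ca_pairs$bw_j),
    hb_names = if (nrow(spec$hb_pairs))
      sprintf("hb:%s@%s-%s@%s", spec$hb_pairs$don_bw, spec$hb_pairs$don_atom,
              spec$hb_pairs$acc_bw, spec$hb_pairs$acc_atom)
    else character()
  )
}

featurize_coords <- function(co, res) {
  theta <- if (nrow(res$tor))
    dihedral_rows(co[res$tor[, 1L], , drop = FALSE],
                  co[res$tor[, 2L], , drop = FALSE],
                  co[res$tor[, 3L], , drop = FALSE],
                  co[res$tor[, 4L], , drop = FALSE])
  else numeric()
  pd <- function(idx) {
    if (!nrow(idx)) return(numeric())
    row_norms(co[idx[, 1L], , drop = FALSE] - co[idx[, 2L], , drop = FALSE])
  }
  list(theta = stats::setNames(theta, res$tor_names),
       ca = stats::setNames(pd(res$ca), res$ca_names),
       hb = stats::setNames(pd(res$hb), res$hb_names))
}

#' Featurize a single frame
#'
#' @param ensemble a `structure_ensemble`.
#' @param spec a `feature_spec`.
#' @param frame frame index within the ensemble.
#' @return named list with numeric vectors `theta` (radians in `[-pi, pi)`),
#'   `ca` and `hb` (Angstrom).
#' @export
featurize_frame <- function(ensemble, spec, frame = 1L) {
  res <- resolve_spec(spec, ensemble$atoms)
  featurize_coords(frame_coords(ensemble, frame), res)
}

#' Featurize every frame of an ensemble
#'
#' @param ensemble a `structure_ensemble`.
#' @param spec a `feature_spec`.
#' @return a `feature_table` with one row per frame, in frame order, labeled
#'   with the ensemble's ligand id.
#' @export
featurize_ensemble <- function(ensemble, spec) {
  res <- resolve_spec(spec, ensemble$atoms)
  n <- n_frames(ensemble)
  theta <- matrix(NA_real_, n, nrow(res$tor),
                  dimnames = list(NULL, res$tor_names))
  ca <- matrix(NA_real_, n, nrow(res$ca), dimnames = list(NULL, res$ca_names))
  hb <- matrix(NA_real_, n, nrow(res$hb), dimnames = list(NULL, res$hb_names))
  for (f in seq_len(n)) {
    v <- tryCatch(featurize_coords(frame_coords(ensemble, f), res),
                  error = function(e) stopf("frame %d: %s", f, conditionMessage(e)))
    theta[f, ] <- v$theta; ca[f, ] <- v$ca; hb[f, ] <- v$hb
  }
  feature_table(theta, ca, hb, ligand = ensemble$ligand_id)
}
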