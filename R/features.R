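#' Per-frame feature tables
#'
#' A `feature_table` is the package's central data container: one row per
#' configuration (frame), with three blocks of columns corresponding to the
#' three feature vectors used by the configuration distance --- backbone and
#' side-chain torsions `theta` (radians, wrapped to `[-pi, pi)`), C-alpha
#' pair distances `ca` (Angstrom) and hydrogen-bond donor--acceptor
#' distances `hb` (Angstrom).
#'
#' @param theta numeric matrix of torsions (radians); wrapped on input.
#' @param ca numeric matrix of C-alpha distances (Angstrom, > 0).
#' @param hb numeric matrix of donor-acceptor distances (Angstrom, > 0).
#' @param ligand character vector of per-frame ligand labels (recycled).
#' @param frame integer per-frame indices (default `1:n` within the table).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(theta, ca, hb, ligand = "L1", frame = NULL) {
  theta <- as.matrix(theta); ca <- as.matrix(ca); hb <- as.matrix(hb)
  n <- nrow(theta)
  if (nrow(ca) != n || nrow(hb) != n) {
    stopf("theta, ca and hb must have the same number of rows")
  }
  if (n < 1L) stopf("feature table needs at least one frame")
  if (!all(is.finite(theta)) || !all(is.finite(ca)) || !all(is.finite(hb))) {
    stopf("all feature values must be finite")
  }
  if ((ncol(ca) && any(ca <= 0)) || (ncol(hb) && any(hb <= 0))) {
    stopf("distance features must be strictly positive")
  }
  if (ncol(theta)) theta[] <- wrap_angle(theta)
  ligand <- rep_len(as.character(ligand), n)
  frame <- if (is.null(frame)) seq_len(n) else rep_len(as.integer(frame), n)
  structure(
    list(theta = theta, ca = ca, hb = hb, ligand = ligand, frame = frame),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d frames (%d ligands): N_theta=%d, N_C=%d, N_H=%d\n",
    nrow(x$theta), length(unique(x$ligand)),
    ncol(x$theta), ncol(x$ca), ncol(x$hb)))
  invisible(x)
}

#' Number of frames in a feature table
#' @param ft a `feature_table`.
#' @return integer frame count.
#' @export
n_config <- function(ft) nrow(ft$theta)

#' Subset a feature table by frame index
#' @param ft a `feature_table`.
#' @param i integer frame indices.
#' @return a `feature_table`.
#' @export
subset_config <- function(ft, i) {
  feature_table(ft$theta[i, , drop = FALSE], ft$ca[i, , drop = FALSE],
                ft$hb[i, , drop = FALSE], ft$ligand[i], ft$frame[i])
}

#' Pool several feature tables into one
#'
#' Used to pool replicate runs of one ligand, or all ligands' ensembles,
#' before clustering. Column layouts must match.
#'
#' @param tables list of `feature_table` objects sharing one feature layout.
#' @return a single pooled `feature_table`.
#' @export
bind_feature_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  dims <- vapply(tables, function(t) c(ncol(t$theta), ncol(t$ca), ncol(t$hb)),
                 integer(3))
  if (any(dims != dims[, 1L])) {
    stopf("feature tables have mismatched column layouts; cannot pool")
  }
  feature_table(
    do.call(rbind, lapply(tables, `[[`, "theta")),
    do.call(rbind, lapply(tables, `[[`, "ca")),
    do.call(rbind, lapply(tables, `[[`, "hb")),
    unlist(lapply(tables, `[[`, "ligand")),
    unlist(lapply(tables, `[[`, "frame"))
  )
}

#' Write a feature table to CSV
#'
#' Columns are `frame_index`, `ligand`, then one column per feature named
#' `tor:<label>:<angle>`, `ca:<label_i>-<label_j>` or
#' `hb:<label>@<atom>-<label>@<atom>`; angles in radians, distances in
#' Angstrom. Values round-trip losslessly (shortest exact decimal form).
#'
#' @param ft a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(frame_index = ft$frame, ligand = ft$ligand,
                   check.names = FALSE, stringsAsFactors = FALSE)
  blocks <- list(tor = ft$theta, ca = ft$ca, hb = ft$hb)
  for (kind in names(blocks)) {
    m <- blocks[[kind]]
    if (!ncol(m)) next
    cn <- colnames(m) %||% paste0(kind, ":f", seq_len(ncol(m)))
    if (is.null(colnames(m))) cn <- paste0(kind, ":f", seq_len(ncol(m)))
    colnames(m) <- cn
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_table()]. Feature kinds are recovered from the
#' column-name prefixes (`tor:`, `ca:`, `hb:`).
#'
#' @param path CSV path.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  df <- data.table::fread(path, data.table = FALSE, check.names = FALSE)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, ":"), names(df), value = TRUE)
    m <- as.matrix(df[, cols, drop = FALSE])
    colnames(m) <- cols
    m
  }
  feature_table(pick("tor"), pick("ca"), pick("hb"),
                ligand = if ("ligand" %in% names(df)) df$ligand else "L1",
                frame = if ("frame_index" %in% names(df)) df$frame_index else NULL)
}
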