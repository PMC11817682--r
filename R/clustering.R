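# Two-stage definition of conformations: complete-linkage hierarchical
# clustering of frames into h clusters, medoid extraction, a Gaussian
# similarity over medoid-medoid distances, and deterministic spectral
# grouping of the medoids into c conformations.

#' Complete-linkage hierarchical clustering of a distance matrix
#'
#' @param D symmetric distance matrix (zero diagonal).
#' @param h number of clusters, `2 <= h <= n`.
#' @return list with `h`, integer `labels` in `1..h` (cutree numbering,
#'   deterministic) and `medoid_frames` (one frame index per cluster).
#' @export
hierarchical_cluster <- function(D, h) {
  n <- nrow(D)
  if (h < 2L || h > n) stopf("h must be in [2, %d], got %d", n, h)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  labels <- stats::cutree(hc, k = h)
  list(h = as.integer(h), labels = as.integer(labels),
       medoid_frames = compute_medoids(D, labels))
}

#' Medoid frame of every cluster
#'
#' The medoid of a cluster is the member minimizing the sum of distances to
#' all other members; ties break to the lowest frame index.
#'
#' @param D symmetric distance matrix over all frames.
#' @param labels integer cluster labels in `1..h`.
#' @return integer vector, `medoid[g]` = frame index of cluster g's medoid.
#' @export
compute_medoids <- function(D, labels) {
  ids <- sort(unique(labels))
  vapply(ids, function(g) {
    m <- which(labels == g)
    if (!length(m)) stopf("internal error: empty cluster %d", g)
    if (length(m) == 1L) return(m)
    s <- colSums(D[m, m, drop = FALSE])
    m[which.min(s)]  # which.min takes the first (lowest index) on ties
  }, integer(1))
}

#' Gaussian similarity from a distance matrix
#'
#' `S_ij = exp(-D_ij^2 / (2 * delta^2))`, the radial-basis kernel with
#' bandwidth `delta`.
#'
#' @param D_rmsd symmetric distance matrix with zero diagonal (medoid RMSD
#'   in Angstrom, or feature-space distances for coordinate-free data).
#' @param delta bandwidth, > 0.
#' @return symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @export
similarity_from_rmsd <- function(D_rmsd, delta) {
  if (delta <= 0) stopf("delta must be > 0")
  if (nrow(D_rmsd) != ncol(D_rmsd)) stopf("distance matrix must be square")
  exp(-(D_rmsd^2) / (2 * delta^2))
}

#' Deterministic spectral grouping with pivoted-QR assignment
#'
#' Embeds the h items with the `c` leading eigenvectors of the symmetrically
#' normalized affinity `Dg^{-1/2} S Dg^{-1/2}` (rows rescaled by the inverse
#' square-root degree, the random-walk convention) and assigns labels by the
#' pivoted-QR procedure of Damle, Minden and Ying: column-pivoted QR of the
#' transposed embedding selects c representative rows, and every row is
#' assigned to the representative it aligns with best after an orthogonal
#' (SVD) alignment. No randomized initialization is involved, so the result
#' is fully determined by `S` and `c`.
#'
#' @param S symmetric similarity matrix with positive entries.
#' @param c number of conformations, `2 <= c <= h - 1`.
#' @return integer labels in `1..c` (relabeled in order of first appearance).
#' @export
spectral_conformations <- function(S, c) {
  h <- nrow(S)
  if (c < 2L || c > h - 1L) stopf("c must be in [2, %d], got %d", h - 1L, c)
  deg <- rowSums(S)
  dis <- 1 / sqrt(deg)
  M <- S * (dis %o% dis)
  U <- eigen(M, symmetric = TRUE)$vectors[, seq_len(c), drop = FALSE]
  U <- U * dis
  piv <- qr(t(U), LAPACK = TRUE)$pivot[seq_len(c)]
  sv <- svd(t(U[piv, , drop = FALSE]))
  aligned <- abs(U %*% (sv$u %*% t(sv$v)))
  labels <- max.col(aligned, ties.method = "first")
  labels[piv] <- seq_len(c)  # representatives anchor their own group
  relabel_first_appearance(labels)
}

relabel_first_appearance <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}

#' Fit a conformation model
#'
#' Pipeline composition: hierarchical complete-linkage clustering to `h`
#' clusters, medoid extraction, a medoid-medoid distance matrix, Gaussian
#' similarity with bandwidth `delta`, and spectral grouping into `c`
#' conformations. Frame labels are the hierarchical labels relabeled through
#' the cluster-to-conformation map.
#'
#' The medoid-medoid distances feeding the Gaussian kernel are superposed
#' C-alpha RMSDs when an `ensemble` (with `rmsd_sel`) is supplied
#' (`medoid_metric = "rmsd"`); for coordinate-free feature tables they are
#' the combined feature-space distances between medoid frames
#' (`medoid_metric = "feature"`, the default).
#'
#' @param ft a `feature_table` over all training frames.
#' @param w a `distance_weights` object.
#' @param h hierarchical cluster count.
#' @param delta Gaussian bandwidth (> 0).
#' @param c conformation count, `2 <= c <= h - 1`.
#' @param D optional precomputed combined distance matrix for `ft`.
#' @param medoid_metric `"feature"` or `"rmsd"`.
#' @param ensemble optional `structure_ensemble` aligned with `ft`'s rows,
#'   required for `medoid_metric = "rmsd"`.
#' @param rmsd_sel optional integer atom indices for the RMSD selection
#'   (default: all CA atoms of the ensemble).
#' @return an object of class `conformation_model`.
#' @export
fit_conformation_model <- function(ft, w, h, delta, c, D = NULL,
                                   medoid_metric = c("feature", "rmsd"),
                                   ensemble = NULL, rmsd_sel = NULL) {
  medoid_metric <- match.arg(medoid_metric)
  w <- as_distance_weights(w)
  if (is.null(D)) D <- pairwise_matrix(ft, w)
  hier <- hierarchical_cluster(D, h)
  med <- hier$medoid_frames
  Dm <- medoid_distance_matrix(med, D, medoid_metric, ensemble, rmsd_sel)
  S <- similarity_from_rmsd(Dm, delta)
  # c == h: every hierarchical cluster is its own conformation
  cluster_to_conf <- if (c == h) seq_len(h) else spectral_conformations(S, c)
  frame_labels <- cluster_to_conf[hier$labels]
  conf_medoids <- vapply(seq_len(c), function(k) {
    cand <- med[cluster_to_conf == k]
    # representative frame of the conformation: medoid of its member frames
    members <- which(frame_labels == k)
    if (length(members) == 1L) return(members)
    s <- colSums(D[members, members, drop = FALSE])
    members[which.min(s)]
  }, integer(1))
  structure(list(
    h = hier$h, c = as.integer(c), delta = delta, weights = w,
    hier_labels = hier$labels, cluster_to_conf = as.integer(cluster_to_conf),
    frame_labels = as.integer(frame_labels),
    medoid_frames = med, conformation_medoids = conf_medoids,
    medoid_features = subset_config(ft, med),
    medoid_conf = as.integer(cluster_to_conf),
    ligand = ft$ligand, medoid_metric = medoid_metric
  ), class = "conformation_model")
}

medoid_distance_matrix <- function(med, D, medoid_metric, ensemble, rmsd_sel) {
  if (medoid_metric == "feature") {
    return(D[med, med, drop = FALSE])
  }
  if (is.null(ensemble)) stopf("medoid_metric = 'rmsd' requires an ensemble")
  sel <- rmsd_sel %||% which(ensemble$atoms$elety == "CA")
  h <- length(med)
  Dm <- matrix(0, h, h)
  co <- lapply(med, function(f) frame_coords(ensemble, f)[sel, , drop = FALSE])
  for (i in seq_len(h - 1L)) {
    for (j in (i + 1L):h) {
      Dm[i, j] <- Dm[j, i] <- superpose_rmsd(co[[i]], co[[j]])
    }
  }
  Dm
}

#' @export
print.conformation_model <- function(x, ...) {
  cat(sprintf(
    "<conformation_model> h=%d clusters -> c=%d conformations (delta=%.3g, weights %.3g/%.3g/%.3g, medoid metric %s)\n",
    x$h, x$c, x$delta, x$weights[[1L]], x$weights[[2L]], x$weights[[3L]],
    x$medoid_metric))
  invisible(x)
}

#' Per-ligand conformation occupancy fractions
#'
#' Counts frames of each ligand in each conformation and row-normalizes, so
#' each row sums to one. Replicate runs of one ligand must be pooled (share
#' a ligand label) before this call.
#'
#' @param frame_labels integer conformation labels per frame, or a
#'   `conformation_model`.
#' @param ligand per-frame ligand labels (taken from the model if omitted).
#' @param n_conf number of conformations (columns).
#' @return matrix, rows = ligands (sorted unique labels), columns =
#'   conformations `1..n_conf`; rows sum to 1.
#' @export
conformation_fractions <- function(frame_labels, ligand = NULL, n_conf = NULL) {
  if (inherits(frame_labels, "conformation_model")) {
    model <- frame_labels
    ligand <- ligand %||% model$ligand
    n_conf <- n_conf %||% model$c
    frame_labels <- model$frame_labels
  }
  if (is.null(n_conf)) n_conf <- max(frame_labels)
  if (length(ligand) != length(frame_labels)) {
    stopf("ligand labels and frame labels differ in length")
  }
  ligs <- sort(unique(ligand))
  if (!length(ligs)) stopf("no ligands supplied")
  out <- matrix(0, length(ligs), n_conf,
                dimnames = list(ligs, paste0("conf", seq_len(n_conf))))
  for (i in seq_along(ligs)) {
    lab <- frame_labels[ligand == ligs[i]]
    if (!length(lab)) stopf("ligand %s has zero frames", ligs[i])
    out[i, ] <- tabulate(lab, n_conf) / length(lab)
  }
  out
}

#' Assign new frames to conformations of a fitted model
#'
#' Each frame is labeled with the conformation of its nearest hierarchical
#' cluster medoid under the model's combined distance; exact ties resolve to
#' the lowest conformation id.
#'
#' @param model a `conformation_model`.
#' @param ft_new `feature_table` of held-out frames (same layout as the
#'   training table).
#' @param w optional weights override (defaults to the model's).
#' @return integer conformation labels in `1..model$c`.
#' @export
assign_external_frames <- function(model, ft_new, w = model$weights) {
  cross <- cross_distance_matrix(ft_new, model$medoid_features, w)
  conf <- model$medoid_conf
  vapply(seq_len(nrow(cross)), function(i) {
    row <- cross[i, ]
    min(conf[row <= min(row)])
  }, integer(1))
}

#' Serialize / restore a conformation model as JSON
#'
#' Stores hyperparameters, the cluster-to-conformation map, medoid frame
#' indices and the medoid feature vectors needed for external assignment.
#'
#' @param model a `conformation_model`.
#' @param path JSON file path.
#' @return `path` invisibly (write) or a `conformation_model` (read).
#' @export
write_conformation_model <- function(model, path) {
  mf <- model$medoid_features
  obj <- list(
    h = model$h, c = model$c, delta = model$delta,
    weights = as.list(unclass(model$weights)),
    cluster_to_conf = model$cluster_to_conf,
    frame_labels = model$frame_labels,
    hier_labels = model$hier_labels,
    medoid_frames = model$medoid_frames,
    conformation_medoids = model$conformation_medoids,
    medoid_conf = model$medoid_conf,
    ligand = model$ligand,
    medoid_metric = model$medoid_metric,
    medoid_features = list(
      theta = mf$theta, ca = mf$ca, hb = mf$hb,
      theta_names = colnames(mf$theta), ca_names = colnames(mf$ca),
      hb_names = colnames(mf$hb))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_conformation_model
#' @export
read_conformation_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mf <- o$medoid_features
  dimfix <- function(m, nm) {
    m <- as.matrix(m)
    if (length(nm)) colnames(m) <- nm
    m
  }
  ft <- feature_table(dimfix(mf$theta, mf$theta_names),
                      dimfix(mf$ca, mf$ca_names),
                      dimfix(mf$hb, mf$hb_names))
  structure(list(
    h = o$h, c = o$c, delta = o$delta,
    weights = distance_weights(o$weights$theta, o$weights$ca, o$weights$hb),
    hier_labels = o$hier_labels, cluster_to_conf = o$cluster_to_conf,
    frame_labels = o$frame_labels, medoid_frames = o$medoid_frames,
    conformation_medoids = o$conformation_medoids,
    medoid_features = ft, medoid_conf = o$medoid_conf,
    ligand = o$ligand, medoid_metric = o$medoid_metric
  ), class = "conformation_model")
}
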