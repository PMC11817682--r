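# Weighted configuration-configuration distance. Each feature block yields a
# root-mean-square component (periodic for torsions); the combined distance
# is a convex combination of the three components, so for fixed features it
# is linear in the weights -- a property the cross-validation engine exploits
# by precomputing one matrix per component.

#' Distance weights
#'
#' Nonnegative weights of the torsion, C-alpha and hydrogen-bond components;
#' constrained to sum to one.
#'
#' @param theta,ca,hb component weights.
#' @return object of class `distance_weights` (named numeric of length 3).
#' @export
distance_weights <- function(theta, ca, hb) {
  w <- c(theta = theta, ca = ca, hb = hb)
  if (any(!is.finite(w)) || any(w < 0)) {
    stopf("weights must be finite and nonnegative")
  }
  if (abs(sum(w) - 1) > 1e-12) {
    stopf("weights must sum to 1 (got %.15f)", sum(w))
  }
  structure(w, class = "distance_weights")
}

as_distance_weights <- function(w) {
  if (inherits(w, "distance_weights")) return(w)
  if (length(w) != 3L) stopf("weights must have length 3")
  distance_weights(w[[1L]], w[[2L]], w[[3L]])
}

#' Periodic torsion distance component
#'
#' Root mean square of the smallest angular differences, accounting for
#' periodicity: `sqrt(mean(delta_k^2))` with
#' `delta_k = min(|a_k - b_k|, 2*pi - |a_k - b_k|)`.
#'
#' @param theta_i,theta_j equal-length angle vectors in radians.
#' @return nonnegative scalar.
#' @export
torsion_component <- function(theta_i, theta_j) {
  if (length(theta_i) != length(theta_j)) stopf("torsion vectors differ in length")
  if (length(theta_i) < 1L) stopf("torsion vectors must be nonempty")
  d <- abs(theta_i - theta_j)
  d <- pmin(d, 2 * pi - d)
  sqrt(mean(d * d))
}

#' Euclidean distance component for a distance-feature block
#'
#' Root mean square of per-feature differences; applied identically to the
#' C-alpha and hydrogen-bond blocks.
#'
#' @param x_i,x_j equal-length numeric vectors (Angstrom).
#' @return nonnegative scalar.
#' @export
vector_component <- function(x_i, x_j) {
  if (length(x_i) != length(x_j)) stopf("feature vectors differ in length")
  if (length(x_i) < 1L) stopf("feature vectors must be nonempty")
  sqrt(mean((x_i - x_j)^2))
}

#' Combined weighted configuration distance
#'
#' @param fi,fj per-frame feature lists as returned by [featurize_frame()],
#'   i.e. lists with elements `theta`, `ca`, `hb`.
#' @param w a `distance_weights` object (or length-3 numeric summing to 1).
#' @return nonnegative scalar, the weighted sum of the three components.
#' @export
combined_distance <- function(fi, fj, w) {
  w <- as_distance_weights(w)
  comp <- c(
    if (length(fi$theta)) torsion_component(fi$theta, fj$theta) else 0,
    if (length(fi$ca)) vector_component(fi$ca, fj$ca) else 0,
    if (length(fi$hb)) vector_component(fi$hb, fj$hb) else 0
  )
  sum(unclass(w) * comp)
}

# squared-difference accumulation over torsion columns with periodic wrap
tor_component_matrix <- function(theta) {
  n <- nrow(theta)
  if (!ncol(theta)) return(matrix(0, n, n))
  acc <- matrix(0, n, n)
  for (k in seq_len(ncol(theta))) {
    d <- abs(outer(theta[, k], theta[, k], "-"))
    d <- pmin(d, 2 * pi - d)
    acc <- acc + d * d
  }
  sqrt(acc / ncol(theta))
}

euc_component_matrix <- function(x) {
  n <- nrow(x)
  if (!ncol(x)) return(matrix(0, n, n))
  g <- tcrossprod(x)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  sqrt(d2 / ncol(x))
}

# cross-matrix variants (rows of a vs rows of b)
tor_cross_matrix <- function(a, b) {
  if (!ncol(a)) return(matrix(0, nrow(a), nrow(b)))
  acc <- matrix(0, nrow(a), nrow(b))
  for (k in seq_len(ncol(a))) {
    d <- abs(outer(a[, k], b[, k], "-"))
    d <- pmin(d, 2 * pi - d)
    acc <- acc + d * d
  }
  sqrt(acc / ncol(a))
}

euc_cross_matrix <- function(a, b) {
  if (!ncol(a)) return(matrix(0, nrow(a), nrow(b)))
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2 / ncol(a))
}

#' Per-component pairwise distance matrices
#'
#' Computes the three component matrices once; any weighted combined matrix
#' is then `w_theta * theta + w_ca * ca + w_hb * hb` via
#' [combine_component_matrices()]. This is how grid searches over weight
#' patterns avoid recomputing feature differences.
#'
#' @param ft a `feature_table`.
#' @return list of three symmetric n x n matrices (`theta`, `ca`, `hb`).
#' @export
component_matrices <- function(ft) {
  list(theta = tor_component_matrix(ft$theta),
       ca = euc_component_matrix(ft$ca),
       hb = euc_component_matrix(ft$hb))
}

#' @rdname component_matrices
#' @param cm list as returned by [component_matrices()].
#' @param w a `distance_weights` object.
#' @export
combine_component_matrices <- function(cm, w) {
  w <- unclass(as_distance_weights(w))
  w[["theta"]] * cm$theta + w[["ca"]] * cm$ca + w[["hb"]] * cm$hb
}

#' Pairwise combined-distance matrix
#'
#' @param ft a `feature_table` with at least two frames.
#' @param w a `distance_weights` object.
#' @return symmetric matrix of combined distances with zero diagonal.
#' @export
pairwise_matrix <- function(ft, w) {
  if (n_config(ft) < 2L) stopf("need at least 2 frames")
  combine_component_matrices(component_matrices(ft), w)
}

#' Cross distances between two feature tables
#'
#' Combined distances from every frame of `ft_a` to every frame of `ft_b`;
#' used to assign held-out frames to their nearest cluster medoid.
#'
#' @param ft_a,ft_b `feature_table`s sharing one column layout.
#' @param w a `distance_weights` object.
#' @return matrix with `n_config(ft_a)` rows and `n_config(ft_b)` columns.
#' @export
cross_distance_matrix <- function(ft_a, ft_b, w) {
  if (ncol(ft_a$theta) != ncol(ft_b$theta) || ncol(ft_a$ca) != ncol(ft_b$ca) ||
      ncol(ft_a$hb) != ncol(ft_b$hb)) {
    stopf("feature tables have mismatched layouts")
  }
  w <- unclass(as_distance_weights(w))
  w[["theta"]] * tor_cross_matrix(ft_a$theta, ft_b$theta) +
    w[["ca"]] * euc_cross_matrix(ft_a$ca, ft_b$ca) +
    w[["hb"]] * euc_cross_matrix(ft_a$hb, ft_b$hb)
}

#' C-alpha RMSD after optimal superposition
#'
#' Kabsch least-squares rigid superposition (rotation + translation; the
#' rotation is forced proper, no reflection), then root-mean-square
#' deviation, at full floating-point precision.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices over the same atoms
#'   (n >= 3).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) stopf("atom count mismatch")
  if (nrow(coords_a) < 3L) stopf("need at least 3 atoms for superposition")
  a <- scale(coords_a, scale = FALSE)
  b <- scale(coords_b, scale = FALSE)
  sv <- svd(crossprod(a, b))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((a %*% t(R) - b)^2)))
}

#' Write a distance matrix to square CSV
#' @param D symmetric distance matrix.
#' @param path output path.
#' @param labels optional frame identifiers used as header/rownames.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, labels = NULL) {
  labels <- labels %||% paste0("frame", seq_len(nrow(D)))
  df <- data.frame(frame = labels, D, check.names = FALSE)
  colnames(df) <- c("frame", labels)
  data.table::fwrite(df, path)
  invisible(path)
}
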