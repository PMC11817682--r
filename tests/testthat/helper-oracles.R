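# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (double loops, exhaustive enumeration, numeric
# optimization) and never call the implementation paths they check.

# brute-force combined distance between two frames of a feature table,
# evaluating both wrap branches per torsion feature
bf_combined_distance <- function(ft, i, j, w) {
  dt <- 0
  nt <- ncol(ft$theta)
  if (nt) {
    s <- 0
    for (k in seq_len(nt)) {
      d1 <- abs(ft$theta[i, k] - ft$theta[j, k])
      d2 <- 2 * pi - d1
      s <- s + min(d1, d2)^2
    }
    dt <- sqrt(s / nt)
  }
  dv <- function(m) {
    if (!ncol(m)) return(0)
    s <- 0
    for (k in seq_len(ncol(m))) s <- s + (m[i, k] - m[j, k])^2
    sqrt(s / ncol(m))
  }
  w[[1]] * dt + w[[2]] * dv(ft$ca) + w[[3]] * dv(ft$hb)
}

bf_pairwise_matrix <- function(ft, w) {
  n <- nrow(ft$theta)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- bf_combined_distance(ft, i, j, w)
    }
  }
  D
}

# all partitions of n items into exactly k nonempty blocks, as restricted
# growth strings (matrix, one partition per row)
all_k_partitions <- function(n, k) {
  out <- list()
  recurse <- function(assign, mx) {
    i <- length(assign) + 1L
    if (i > n) {
      if (mx == k) out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    # prune: remaining items must be able to reach k blocks
    if (mx + (n - i + 1L) < k) return(invisible())
    for (lab in seq_len(min(mx + 1L, k))) {
      recurse(c(assign, lab), max(mx, lab))
    }
  }
  recurse(1L, 1L)
  do.call(rbind, out)
}

# maximum within-cluster pairwise distance of a partition (minimax objective)
partition_max_within <- function(D, labels) {
  mx <- 0
  for (g in unique(labels)) {
    m <- which(labels == g)
    if (length(m) > 1) mx <- max(mx, max(D[m, m]))
  }
  mx
}

# total within-group similarity of a partition
partition_within_similarity <- function(S, labels) {
  s <- 0
  for (g in unique(labels)) {
    m <- which(labels == g)
    s <- s + sum(S[m, m])
  }
  s
}

# numeric-optimization superposition oracle: minimize RMSD over rotations
# (Euler angles) after centering both coordinate sets
numeric_superpose_rmsd <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% t(rot(ang)) - b)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(1, 1, 1), c(-1, 2, 0.5), c(2, -1, -2))) {
    r <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}

# adjusted Rand index between two labelings (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# wrapped-histogram oracle for a periodic density: rotate samples so the
# seam moves to the domain center, histogram there, rotate the bins back
wrapped_histogram_oracle <- function(samples, bins = 60L) {
  rot <- pocketsig:::wrap_angle(samples + pi)  # seam now at 0
  width <- 2 * pi / bins
  breaks <- seq(-pi, pi, length.out = bins + 1L)
  counts <- tabulate(findInterval(rot, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  dens_rot <- counts / (sum(counts) * width)
  # undo the rotation: bin j of the rotated histogram covers the original
  # angles in bin j shifted by -pi, i.e. a half-period circular shift
  c(dens_rot[(bins / 2 + 1L):bins], dens_rot[1L:(bins / 2)])
}
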