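# Efficacy response functions: per-conformation densities of a structural
# feature, weighted by mean regression slopes and summed. Sign-gated
# combinations of the two pathways' ERFs and their rectangle-rule integrals
# rank features driving shared (general) vs pathway-specific (selective)
# activation.

ERF_GRID_N <- 1000L

erf_grid <- function(domain, n = ERF_GRID_N) {
  lo <- domain[1L]; hi <- domain[2L]
  spacing <- (hi - lo) / n
  list(x = lo + (seq_len(n) - 0.5) * spacing, spacing = spacing)
}

#' Histogram density of one feature within one conformation
#'
#' Periodic (torsion) features are triplicated at `x + 2*pi` and `x - 2*pi`
#' before binning so the estimate is continuous over the period, then
#' normalized so the numerical integral over `[-pi, pi]` is one.
#' Nonperiodic (distance) features are binned and normalized over `domain`.
#' The density is evaluated at `grid_n` evenly spaced midpoints.
#'
#' @param samples numeric vector of feature values within one conformation.
#' @param periodic logical; torsions are periodic on `[-pi, pi)`.
#' @param domain length-2 numeric; defaults to `c(-pi, pi)` for periodic
#'   features and to the sample range padded by 0.5 Angstrom otherwise.
#' @param bins histogram bin count over the domain. The default (50)
#'   divides the 1000-point evaluation grid evenly, which makes the
#'   rectangle-rule integral of any histogram density exact.
#' @param grid_n evaluation grid size (default 1000).
#' @return object of class `conformation_density`: list with `grid`,
#'   `values`, `domain`, `periodic`, `spacing`.
#' @export
conformation_density <- function(samples, periodic = FALSE, domain = NULL,
                                 bins = 50L, grid_n = ERF_GRID_N) {
  if (!length(samples)) stopf("empty sample set")
  if (periodic) {
    domain <- domain %||% c(-pi, pi)
    samples <- wrap_angle(samples)
    ext <- c(samples, samples + 2 * pi, samples - 2 * pi)
    width <- (domain[2L] - domain[1L]) / bins
    breaks <- seq(domain[1L] - bins * width, domain[2L] + bins * width,
                  by = width)
    counts <- tabulate(findInterval(ext, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE),
                       nbins = length(breaks) - 1L)
    mid <- counts[(bins + 1L):(2L * bins)]
    dens <- mid / (sum(mid) * width)
    inner_breaks <- breaks[(bins + 1L):(2L * bins + 1L)]
  } else {
    domain <- domain %||% (range(samples) + c(-0.5, 0.5))
    if (domain[2L] <= domain[1L]) domain <- domain + c(-0.5, 0.5)
    width <- (domain[2L] - domain[1L]) / bins
    inner_breaks <- seq(domain[1L], domain[2L], length.out = bins + 1L)
    inside <- samples >= domain[1L] & samples <= domain[2L]
    counts <- tabulate(findInterval(samples[inside], inner_breaks,
                                    rightmost.closed = TRUE, all.inside = TRUE),
                       nbins = bins)
    if (!sum(counts)) stopf("no samples inside the density domain")
    dens <- counts / (sum(counts) * width)
  }
  g <- erf_grid(domain, grid_n)
  idx <- findInterval(g$x, inner_breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  structure(list(grid = g$x, values = dens[idx], domain = domain,
                 periodic = periodic, spacing = g$spacing,
                 bin_density = dens, breaks = inner_breaks),
            class = "conformation_density")
}

#' Efficacy response function of one feature
#'
#' `r(x) = sum_c beta_c * p_c(x)`: per-conformation densities weighted by
#' the mean regression slopes of one pathway and summed. ERFs are not
#' probability densities; slopes may be negative, so ERFs may be negative,
#' and they are not normalized.
#'
#' @param densities list of `conformation_density` objects, one per
#'   conformation, on a common grid.
#' @param slopes numeric vector of mean slopes, one per conformation.
#' @param feature_id text identifier of the feature.
#' @param pathway pathway label.
#' @return object of class `erf_curve`: `grid`, `values`, `domain`,
#'   `periodic`, `feature_id`, `pathway`.
#' @export
efficacy_response <- function(densities, slopes, feature_id = "feature",
                              pathway = "Gprotein") {
  if (length(densities) != length(slopes)) {
    stopf("need one slope per conformation density (%d vs %d)",
          length(densities), length(slopes))
  }
  g <- densities[[1L]]$grid
  v <- numeric(length(g))
  for (i in seq_along(densities)) {
    if (length(densities[[i]]$grid) != length(g) ||
        max(abs(densities[[i]]$grid - g)) > 1e-9) {
      stopf("conformation densities are not on a common grid")
    }
    v <- v + slopes[i] * densities[[i]]$values
  }
  structure(list(grid = g, values = v, domain = densities[[1L]]$domain,
                 periodic = densities[[1L]]$periodic,
                 spacing = densities[[1L]]$spacing,
                 feature_id = feature_id, pathway = pathway),
            class = "erf_curve")
}

check_shared_grid <- function(r_G, r_b) {
  if (length(r_G$grid) != length(r_b$grid) ||
      max(abs(r_G$grid - r_b$grid)) > 1e-9) {
    stopf("ERF curves are not on a shared grid")
  }
}

#' General activation function
#'
#' Nonzero exactly where the two pathways' ERFs share a sign:
#' `a(x) = sign(r_G) * min(|r_G|, |r_b|)` there, zero elsewhere. Positive
#' values mark regions favoring activation of both pathways.
#'
#' @param r_G,r_b `erf_curve`s of the two pathways on a shared grid.
#' @return numeric vector `a(x)` on the grid.
#' @export
general_activation <- function(r_G, r_b) {
  check_shared_grid(r_G, r_b)
  g <- r_G$values; b <- r_b$values
  same <- sign(g) == sign(b) & g != 0 & b != 0
  out <- numeric(length(g))
  out[same] <- sign(g[same]) * pmin(abs(g[same]), abs(b[same]))
  out
}

#' Selective activation function
#'
#' Nonzero exactly where the ERFs have opposite signs:
#' `s(x) = sign(r_G) * min(|r_G|, |r_b|)` there, zero elsewhere. Positive
#' values mark G-protein-favoring regions, negative values
#' beta-arrestin-2-favoring regions.
#'
#' @param r_G,r_b `erf_curve`s of the two pathways on a shared grid.
#' @return numeric vector `s(x)` on the grid.
#' @export
selective_activation <- function(r_G, r_b) {
  check_shared_grid(r_G, r_b)
  g <- r_G$values; b <- r_b$values
  opp <- sign(g) == -sign(b) & g != 0 & b != 0
  out <- numeric(length(g))
  out[opp] <- sign(g[opp]) * pmin(abs(g[opp]), abs(b[opp]))
  out
}

#' Rectangle-rule activation score
#'
#' The numerical integral as literally defined: the function summed over the
#' evenly spaced grid and multiplied by the spacing (exact for constants).
#'
#' @param values function values on the evaluation grid.
#' @param domain length-2 numeric domain; spacing is
#'   `(hi - lo) / length(values)`.
#' @param grid optional grid abscissae; if given, checked for uniform
#'   spacing.
#' @return scalar score.
#' @export
activation_score <- function(values, domain, grid = NULL) {
  n <- length(values)
  if (!is.null(grid)) {
    dg <- diff(grid)
    if (max(abs(dg - dg[1L])) > 1e-9 * max(abs(dg))) {
      stopf("grid is not uniformly spaced")
    }
  }
  spacing <- (domain[2L] - domain[1L]) / n
  spacing * sum(values)
}

#' Activation profile of one feature
#'
#' Bundles the two ERFs, the general and selective activation functions and
#' their scores. The two gates are mutually exclusive by construction:
#' `a(x) * s(x) = 0` pointwise.
#'
#' @param r_G,r_b `erf_curve`s of the two pathways.
#' @return object of class `activation_profile`.
#' @export
activation_profile <- function(r_G, r_b) {
  a <- general_activation(r_G, r_b)
  s <- selective_activation(r_G, r_b)
  structure(list(
    feature_id = r_G$feature_id, grid = r_G$grid, domain = r_G$domain,
    periodic = r_G$periodic, r_G = r_G$values, r_b = r_b$values,
    a_values = a, s_values = s,
    general_score = activation_score(a, r_G$domain, r_G$grid),
    selective_score = activation_score(s, r_G$domain, r_G$grid)
  ), class = "activation_profile")
}

#' Rank features by activation score magnitude
#'
#' Stable descending sort by `|general_score|` and `|selective_score|`; ties
#' preserve input order.
#'
#' @param profiles list of `activation_profile` objects.
#' @param top_fraction optional fraction (e.g. 0.02) flagging the
#'   top-scoring features.
#' @return data.frame with one row per feature: scores, per-criterion ranks,
#'   and logical top-percentile flags when `top_fraction` is given.
#' @export
rank_features <- function(profiles, top_fraction = NULL) {
  if (!length(profiles)) stopf("need at least one profile")
  df <- data.frame(
    feature_id = vapply(profiles, `[[`, character(1), "feature_id"),
    general_score = vapply(profiles, `[[`, numeric(1), "general_score"),
    selective_score = vapply(profiles, `[[`, numeric(1), "selective_score"),
    stringsAsFactors = FALSE
  )
  ord_g <- order(-abs(df$general_score))        # order() is a stable sort
  ord_s <- order(-abs(df$selective_score))
  df$general_rank <- match(seq_len(nrow(df)), ord_g)
  df$selective_rank <- match(seq_len(nrow(df)), ord_s)
  if (!is.null(top_fraction)) {
    k <- max(1L, ceiling(top_fraction * nrow(df)))
    df$top_general <- df$general_rank <= k
    df$top_selective <- df$selective_rank <= k
  }
  df[order(df$general_rank), ]
}

#' Compute activation profiles for every feature of a table
#'
#' For each feature column, per-conformation densities (periodic for the
#' torsion block) are combined with the mean slopes of each pathway into
#' ERFs and activation profiles. Any feature table aligned with the frame
#' labels may be supplied, so ERFs can be extended to features (e.g.
#' binding-pocket residues) that did not enter the distance metric.
#'
#' @param ft a `feature_table`.
#' @param frame_labels integer conformation labels per frame of `ft`.
#' @param slope_mean matrix of mean slopes, conformations x pathways
#'   (columns `Gprotein`, `barr2`), as in a `loo_result`.
#' @param bins histogram bins per domain (default 50).
#' @return named list of `activation_profile` objects.
#' @export
compute_erf_profiles <- function(ft, frame_labels, slope_mean, bins = 50L) {
  n_conf <- nrow(slope_mean)
  stopifnot(length(frame_labels) == n_config(ft))
  profiles <- list()
  blocks <- list(theta = ft$theta, ca = ft$ca, hb = ft$hb)
  for (kind in names(blocks)) {
    m <- blocks[[kind]]
    if (!ncol(m)) next
    periodic <- kind == "theta"
    cn <- colnames(m) %||% paste0(kind, ":f", seq_len(ncol(m)))
    for (j in seq_len(ncol(m))) {
      x <- m[, j]
      domain <- if (periodic) c(-pi, pi) else range(x) + c(-0.5, 0.5)
      dens <- lapply(seq_len(n_conf), function(k)
        conformation_density(x[frame_labels == k], periodic = periodic,
                             domain = domain, bins = bins))
      r_G <- efficacy_response(dens, slope_mean[, "Gprotein"], cn[j], "Gprotein")
      r_b <- efficacy_response(dens, slope_mean[, "barr2"], cn[j], "barr2")
      profiles[[cn[j]]] <- activation_profile(r_G, r_b)
    }
  }
  profiles
}

#' Write ERF curves and scores as tidy CSV
#'
#' @param profiles list of `activation_profile`s.
#' @param curves_path output CSV for curves (`feature_id, x, r_G, r_barr2,
#'   a, s`); `NULL` to skip.
#' @param scores_path output CSV for the ranked score table; `NULL` to skip.
#' @param top_fraction passed to [rank_features()].
#' @return the ranked score data.frame, invisibly.
#' @export
write_erf_outputs <- function(profiles, curves_path = NULL,
                              scores_path = NULL, top_fraction = 0.02) {
  if (!is.null(curves_path)) {
    curves <- do.call(rbind, lapply(profiles, function(p)
      data.frame(feature_id = p$feature_id, x = p$grid, r_G = p$r_G,
                 r_barr2 = p$r_b, a = p$a_values, s = p$s_values)))
    data.table::fwrite(curves, curves_path)
  }
  ranked <- rank_features(profiles, top_fraction = top_fraction)
  if (!is.null(scores_path)) data.table::fwrite(ranked, scores_path)
  invisible(ranked)
}

#' Plot one activation profile
#'
#' Convenience ggplot of the two ERFs and the activation gates.
#'
#' @param profile an `activation_profile`.
#' @return a ggplot object.
#' @export
plot_erf <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  df <- data.frame(
    x = rep(profile$grid, 4L),
    value = c(profile$r_G, profile$r_b, profile$a_values, profile$s_values),
    curve = rep(c("ERF G protein", "ERF barr2", "general a(x)",
                  "selective s(x)"), each = length(profile$grid))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = profile$feature_id,
                  x = if (profile$periodic) "angle (rad)" else "distance (A)",
                  y = "response")
}
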