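# Nested leave-one-out training. The outer loop holds one ligand out; the
# inner loop selects hyperparameters by a grid search whose loss is the
# leave-one-out mean squared subtest error summed over both pathways.
#
# The engine exploits two structural facts to stay cheap: the combined
# distance is linear in the weights (so one matrix per component suffices),
# and the dendrogram depends only on (weights, frame subset) -- every
# (h, delta, c) cell reuses it through cutree. Each grid cell is therefore
# exactly the composition hierarchical_cluster -> compute_medoids ->
# similarity -> spectral -> regression, evaluated without redundant work.

#' Hyperparameter set
#'
#' @param weights a `distance_weights` object (or length-3 numeric).
#' @param h hierarchical cluster count (>= 2).
#' @param delta Gaussian bandwidth (> 0).
#' @param c conformation count, `2 <= c <= h - 1`.
#' @return object of class `hyperparameters`.
#' @export
hyperparameters <- function(weights, h, delta, c) {
  weights <- as_distance_weights(weights)
  if (h < 2L) stopf("h must be >= 2")
  if (delta <= 0) stopf("delta must be > 0")
  if (c < 2L || c > h - 1L) stopf("c must satisfy 2 <= c <= h - 1")
  structure(list(weights = weights, h = as.integer(h), delta = delta,
                 c = as.integer(c)), class = "hyperparameters")
}

#' Hyperparameters selected by the original study
#'
#' Distance weights 0.25/0.25/0.5 (torsion/CA/H-bond), 40 hierarchical
#' clusters, bandwidth 2, and 14 conformations; the values every
#' cross-validation fold of the published analysis converged to.
#'
#' @return a `hyperparameters` object.
#' @export
reference_hyperparameters <- function() {
  hyperparameters(distance_weights(0.25, 0.25, 0.5), h = 40L, delta = 2,
                  c = 14L)
}

#' Expand symmetric weight patterns
#'
#' For each `w` in `w_set`, forms the three patterns `(w, w, 1-2w)`,
#' `(w, 1-2w, w)` and `(1-2w, w, w)`. Patterns with a negative entry (e.g.
#' `w = 1`) are skipped with a notice; duplicates are dropped.
#'
#' @param w_set numeric vector of pattern generators.
#' @return list of length-3 weight vectors.
#' @export
weight_patterns <- function(w_set) {
  out <- list()
  for (w in w_set) {
    for (p in list(c(w, w, 1 - 2 * w), c(w, 1 - 2 * w, w),
                   c(1 - 2 * w, w, w))) {
      if (any(p < 0)) {
        message(sprintf("skipping weight pattern (%s): negative entry",
                        paste(format(p), collapse = ", ")))
        next
      }
      key <- paste(format(p, digits = 12), collapse = "_")
      if (!key %in% names(out)) out[[key]] <- p
    }
  }
  if (!length(out)) stopf("no valid weight patterns in grid")
  unname(out)
}

#' Hyperparameter grid
#'
#' @param weights list of length-3 weight vectors (see [weight_patterns()]).
#' @param h integer vector of hierarchical cluster counts.
#' @param delta numeric vector of bandwidths.
#' @param c integer vector of conformation counts, or `NULL` for the full
#'   range `2..h-1` at each `h`.
#' @return object of class `hyper_grid`.
#' @export
hyper_grid <- function(weights, h, delta, c = NULL) {
  weights <- lapply(weights, function(w) unclass(as_distance_weights(w)))
  h <- sort(unique(as.integer(h)))
  if (any(h < 2L)) stopf("h values must be >= 2")
  delta <- sort(unique(as.numeric(delta)))
  if (any(delta <= 0)) stopf("delta values must be > 0")
  if (!is.null(c)) c <- sort(unique(as.integer(c)))
  structure(list(weights = weights, h = h, delta = delta, c = c),
            class = "hyper_grid")
}

#' The grid used by the original study
#'
#' Weight patterns generated from `w` in 0.1, 0.2, 0.25, 0.33 and 1 (the
#' last is dropped by the nonnegativity rule), `h` from 2 to 40, bandwidth 1
#' to 3, and `c` over the full `2..h-1` range. Exhaustive evaluation of this
#' grid is expensive; scaled-down grids are used throughout the tests.
#'
#' @return a `hyper_grid`.
#' @export
default_grid <- function() {
  hyper_grid(weight_patterns(c(0.1, 0.2, 0.25, 0.33, 1)),
             h = 2:40, delta = 1:3, c = NULL)
}

grid_c_values <- function(grid, h) {
  full <- if (h >= 3L) 2:(h - 1L) else integer()
  if (is.null(grid$c)) full else intersect(grid$c, full)
}

# cell table in deterministic tie order: weights, then h, then delta, then c
grid_cells <- function(grid) {
  block <- list()
  for (h in grid$h) {
    for (delta in grid$delta) {
      for (cc in grid_c_values(grid, h)) {
        block[[length(block) + 1L]] <- c(h = h, delta = delta, c = cc)
      }
    }
  }
  if (!length(block)) stopf("empty effective grid")
  block_df <- as.data.frame(do.call(rbind, block))
  cells <- do.call(rbind, lapply(seq_along(grid$weights), function(wi) {
    cbind(wi = wi, block_df)
  }))
  rownames(cells) <- NULL
  cells
}

#' Pipeline data bundle
#'
#' Precomputes the per-component distance matrices and the median efficacy
#' targets for a pooled multi-ligand feature table; the unit of work every
#' cross-validation routine operates on.
#'
#' @param ft pooled `feature_table` with per-frame ligand labels.
#' @param efficacy an `efficacy_table`, or a precomputed median matrix with
#'   ligand rownames and columns `Gprotein`, `barr2`.
#' @return object of class `pipeline_data`.
#' @export
pipeline_data <- function(ft, efficacy) {
  ligs <- sort(unique(ft$ligand))
  eff <- if (inherits(efficacy, "efficacy_table")) {
    median_efficacy(efficacy, ligands = ligs)
  } else {
    as.matrix(efficacy)[ligs, PATHWAYS, drop = FALSE]
  }
  structure(list(ft = ft, ligand = ft$ligand, cm = component_matrices(ft),
                 eff = eff, ligands = ligs),
            class = "pipeline_data")
}

#' @export
print.pipeline_data <- function(x, ...) {
  cat(sprintf("<pipeline_data> %d frames, %d ligands, 2 pathways\n",
              n_config(x$ft), length(x$ligands)))
  invisible(x)
}

# assign held-out frames to conformations given cross distances to medoids
.assign_from_cross <- function(cross, medoid_conf) {
  vapply(seq_len(nrow(cross)), function(i) {
    row <- cross[i, ]
    min(medoid_conf[row <= min(row)])
  }, integer(1))
}

# Evaluate the inner-LOO loss of every grid cell on a training ligand set.
# Returns the cell table augmented with per-pathway and total losses.
eval_grid <- function(pd, train_ligands, grid) {
  train_ligands <- sort(unique(train_ligands))
  if (length(train_ligands) < 3L) {
    stopf("inner leave-one-out needs at least 3 training ligands")
  }
  cells <- grid_cells(grid)
  ncell <- nrow(cells)
  block_n <- ncell / length(grid$weights)
  lossG <- numeric(ncell); lossB <- numeric(ncell)
  for (wi in seq_along(grid$weights)) {
    Dw <- combine_component_matrices(pd$cm, grid$weights[[wi]])
    offset <- (wi - 1L) * block_n
    for (t in train_ligands) {
      sub_lig <- setdiff(train_ligands, t)
      sub_idx <- which(pd$ligand %in% sub_lig)
      t_idx <- which(pd$ligand == t)
      Dsub <- Dw[sub_idx, sub_idx, drop = FALSE]
      hc <- stats::hclust(stats::as.dist(Dsub), method = "complete")
      sub_ligand <- pd$ligand[sub_idx]
      k <- 0L
      for (h in grid$h) {
        cvals <- grid_c_values(grid, h)
        n_h_cells <- length(grid$delta) * length(cvals)
        if (h > length(sub_idx)) { k <- k + n_h_cells; next }
        labs <- stats::cutree(hc, k = h)
        med <- compute_medoids(Dsub, labs)
        Dm <- Dsub[med, med, drop = FALSE]
        crossT <- Dw[t_idx, sub_idx[med], drop = FALSE]
        for (delta in grid$delta) {
          S <- exp(-(Dm^2) / (2 * delta^2))
          for (cc in cvals) {
            k <- k + 1L
            conf <- spectral_conformations(S, cc)
            fl <- conf[labs]
            Fm <- conformation_fractions(fl, sub_ligand, cc)
            beta <- fit_slopes(Fm, pd$eff[rownames(Fm), , drop = FALSE],
                               warn = FALSE)
            t_conf <- .assign_from_cross(crossT, conf)
            f_row <- tabulate(t_conf, cc) / length(t_conf)
            pred <- drop(crossprod(beta, f_row))
            lossG[offset + k] <- lossG[offset + k] +
              (pred[["Gprotein"]] - pd$eff[t, "Gprotein"])^2
            lossB[offset + k] <- lossB[offset + k] +
              (pred[["barr2"]] - pd$eff[t, "barr2"])^2
          }
        }
      }
    }
  }
  nf <- length(train_ligands)
  cells$loss_G <- lossG / nf
  cells$loss_barr2 <- lossB / nf
  cells$loss <- cells$loss_G + cells$loss_barr2
  cells
}

#' Inner leave-one-out loss of one hyperparameter set
#'
#' For each training ligand in turn: the conformation model is fitted on the
#' remaining (subtraining) ligands' frames, the held-out ligand's frames are
#' assigned to the nearest medoid's conformation, slopes are fitted on the
#' subtraining fractions, and the held-out ligand is predicted. The loss is
#' the mean squared held-out error, reported per pathway and summed.
#'
#' @param pd a `pipeline_data`.
#' @param train_ligands character vector of >= 3 training ligands.
#' @param hp a `hyperparameters` object.
#' @return list with `loss_G`, `loss_barr2` and `loss` (their sum).
#' @export
inner_loo_loss <- function(pd, train_ligands, hp) {
  grid <- hyper_grid(list(unclass(hp$weights)), hp$h, hp$delta, hp$c)
  cells <- eval_grid(pd, train_ligands, grid)
  list(loss_G = cells$loss_G[1L], loss_barr2 = cells$loss_barr2[1L],
       loss = cells$loss[1L])
}

#' Grid search over hyperparameters
#'
#' Minimizes the summed per-pathway inner leave-one-out loss over every grid
#' cell. Ties (and a single-cell grid) resolve to the first cell in the
#' deterministic order weights, then h, then delta, then c, all ascending.
#'
#' @param pd a `pipeline_data`.
#' @param train_ligands training ligand labels (>= 3 for a multi-cell grid).
#' @param grid a `hyper_grid`.
#' @return list with `best` (a `hyperparameters`) and `trace` (the cell
#'   table with losses; `NULL` for a single-cell grid, which is returned
#'   without evaluation).
#' @export
grid_search <- function(pd, train_ligands, grid) {
  cells <- grid_cells(grid)
  if (nrow(cells) == 1L) {
    hp <- hyperparameters(grid$weights[[cells$wi[1L]]], cells$h[1L],
                          cells$delta[1L], cells$c[1L])
    return(list(best = hp, trace = NULL))
  }
  cells <- eval_grid(pd, train_ligands, grid)
  i <- which.min(cells$loss)
  hp <- hyperparameters(grid$weights[[cells$wi[i]]], cells$h[i],
                        cells$delta[i], cells$c[i])
  list(best = hp, trace = cells)
}

# most frequent hyperparameter setting across folds; ties -> first fold
modal_hyperparameters <- function(hp_list) {
  keys <- vapply(hp_list, function(hp) {
    paste(paste(format(unclass(hp$weights), digits = 12), collapse = "_"),
          hp$h, format(hp$delta), hp$c, sep = "|")
  }, character(1))
  hp_list[[which.max(tabulate(match(keys, unique(keys))))[1L]]]
  # which.max over counts of first appearances keeps fold order on ties
}

#' Outer leave-one-out cross-validation
#'
#' For each ligand: hyperparameters are selected by [grid_search()] on the
#' remaining ligands, the final conformation model and slopes are fitted on
#' all of them, and the held-out ligand is predicted through external frame
#' assignment. Every ligand is additionally predicted under every fold's
#' model, giving the per-ligand standard deviation across the n
#' cross-validation models.
#'
#' Across-model slope statistics are computed in a single shared conformation
#' space (fitted once on all frames with the modal selected hyperparameters,
#' slopes refitted per fold on that space's training fractions), since
#' conformation indices from different per-fold clusterings do not
#' correspond.
#'
#' @param pd a `pipeline_data` (>= 4 ligands).
#' @param grid a `hyper_grid`; a single-cell grid skips the inner search.
#' @return object of class `loo_result` with elements `predictions`
#'   (data.frame: ligand, pathway, observed, predicted, sd), `metrics`
#'   (per-pathway mae/rmse/r2), `fold_hyperparameters`, `slope_mean`,
#'   `slope_sd`, `slopes` (fold x conformation x pathway array),
#'   `shared_model`, `shared_fractions`, and `prediction_array`.
#' @export
outer_loo_cross_validation <- function(pd, grid) {
  ligs <- pd$ligands
  n <- length(ligs)
  if (n < 4L) stopf("outer leave-one-out needs at least 4 ligands")
  pred_arr <- array(NA_real_, c(n, n, 2L),
                    dimnames = list(model = ligs, ligand = ligs,
                                    pathway = PATHWAYS))
  hp_list <- vector("list", n)
  for (i in seq_len(n)) {
    L <- ligs[i]
    train <- setdiff(ligs, L)
    hp <- grid_search(pd, train, grid)$best
    hp_list[[i]] <- hp
    Dw <- combine_component_matrices(pd$cm, hp$weights)
    tr <- pd$ligand %in% train
    model <- fit_conformation_model(
      subset_config(pd$ft, which(tr)), hp$weights, hp$h, hp$delta, hp$c,
      D = Dw[tr, tr, drop = FALSE])
    Fm <- conformation_fractions(model)
    beta <- fit_slopes(Fm, pd$eff[rownames(Fm), , drop = FALSE], warn = FALSE)
    for (M in train) {
      pred_arr[i, M, ] <- predict_efficacy(Fm[M, ], beta)
    }
    lab_L <- assign_external_frames(model, subset_config(pd$ft, which(pd$ligand == L)))
    f_L <- tabulate(lab_L, model$c) / length(lab_L)
    pred_arr[i, L, ] <- predict_efficacy(f_L, beta)
  }
  heldout <- t(vapply(seq_len(n), function(i) pred_arr[i, i, ], numeric(2)))
  dimnames(heldout) <- list(ligs, PATHWAYS)
  pred_sd <- apply(pred_arr, c(2L, 3L), stats::sd)
  metrics <- lapply(stats::setNames(PATHWAYS, PATHWAYS), function(p)
    evaluate_predictions(heldout[, p], pd$eff[, p]))
  # shared conformation space for slope statistics
  shared_hp <- modal_hyperparameters(hp_list)
  shared_model <- fit_conformation_model(
    pd$ft, shared_hp$weights, shared_hp$h, shared_hp$delta, shared_hp$c,
    D = combine_component_matrices(pd$cm, shared_hp$weights))
  shared_F <- conformation_fractions(shared_model)
  slopes <- array(NA_real_, c(n, shared_hp$c, 2L),
                  dimnames = list(model = ligs,
                                  conformation = paste0("conf", seq_len(shared_hp$c)),
                                  pathway = PATHWAYS))
  for (i in seq_len(n)) {
    train <- setdiff(ligs, ligs[i])
    slopes[i, , ] <- fit_slopes(shared_F[train, , drop = FALSE],
                                pd$eff[train, , drop = FALSE], warn = FALSE)
  }
  predictions <- do.call(rbind, lapply(PATHWAYS, function(p) {
    data.frame(ligand = ligs, pathway = p, observed = pd$eff[, p],
               predicted = heldout[, p], sd = pred_sd[, p],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(
    predictions = predictions, metrics = metrics,
    fold_hyperparameters = hp_list, shared_hyperparameters = shared_hp,
    slopes = slopes,
    slope_mean = apply(slopes, c(2L, 3L), mean),
    slope_sd = apply(slopes, c(2L, 3L), stats::sd),
    shared_model = shared_model, shared_fractions = shared_F,
    prediction_array = pred_arr, efficacy = pd$eff
  ), class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("<loo_result> held-out prediction accuracy:\n")
  for (p in PATHWAYS) {
    m <- x$metrics[[p]]
    cat(sprintf("  %-9s MAE %6.2f%%  RMSE %6.2f%%  R2 %6.3f\n",
                p, m$mae, m$rmse, m$r2))
  }
  invisible(x)
}

#' Order conformations by decreasing average slope
#'
#' Optional relabeling mirroring the reporting convention in which
#' conformation 1 has the largest mean slope averaged over both pathways.
#'
#' @param result a `loo_result`.
#' @return integer permutation `p` such that conformation `p[1]` has the
#'   largest average slope.
#' @export
conformation_order_by_slope <- function(result) {
  order(rowMeans(result$slope_mean), decreasing = TRUE)
}
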