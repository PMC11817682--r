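# Pipeline entry points: one function per subcommand (simulate, featurize,
# cluster, train, predict, erf), each writing its artifacts plus a JSON run
# report. A thin command-line wrapper around these functions ships in
# inst/cli/pocketsig.R. All outputs are regenerable from config + seed; no
# hidden state.

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

write_report <- function(out_dir, subcommand, config) {
  report <- c(list(
    subcommand = subcommand,
    package = "pocketsig",
    version = as.character(utils::packageVersion("pocketsig"))
  ), config)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

as_feature_table <- function(x) {
  if (inherits(x, "feature_table")) x else read_feature_table(x)
}

as_efficacy_table <- function(x) {
  if (inherits(x, "efficacy_table")) x else read_efficacy_table(x)
}

hp_as_list <- function(hp) {
  list(weights = as.list(unclass(hp$weights)), h = hp$h, delta = hp$delta,
       c = hp$c)
}

#' Generate a synthetic scenario's artifacts
#'
#' Samples the scenario, writes the pooled feature table, the ground-truth
#' frame labels (sidecar CSV), the efficacy table, the scenario definition
#' (YAML) and a run report.
#'
#' @param preset preset name (see [preset_scenario()]) or a
#'   `synthetic_scenario`.
#' @param out_dir output directory (created if absent).
#' @param seed sampling seed override.
#' @param records_per_key assay records per (ligand, pathway).
#' @return list with the sampled `features`, `truth` and `efficacy`,
#'   invisibly.
#' @export
run_simulate <- function(preset, out_dir, seed = NULL, records_per_key = 1L) {
  sc <- if (inherits(preset, "synthetic_scenario")) preset
        else preset_scenario(preset, seed = seed)
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  ensure_dir(out_dir)
  sam <- sample_ensembles(sc)
  eff <- make_efficacies(sc, sam$fractions, records_per_key = records_per_key)
  write_feature_table(sam$features, file.path(out_dir, "features.csv"))
  data.table::fwrite(sam$truth, file.path(out_dir, "truth.csv"))
  data.table::fwrite(eff$records, file.path(out_dir, "efficacy.csv"))
  write_scenario_yaml(sc, file.path(out_dir, "scenario.yaml"))
  write_report(out_dir, "simulate", list(
    preset = if (is.character(preset)) preset else "custom",
    seed = sc$seed, n_conformations = sc$n_conformations,
    ligands = rownames(sc$mixtures)))
  invisible(list(features = sam$features, truth = sam$truth, efficacy = eff,
                 scenario = sc))
}

#' Featurize PDB ensembles into feature tables
#'
#' @param pdb_paths named character vector of multi-model PDB files (names =
#'   ligand ids).
#' @param bw_map_path CSV mapping sequence position to BW label.
#' @param reference_path single-model PDB used to derive hydrogen-bond
#'   pairs.
#' @param out_dir output directory.
#' @param hbond_cutoff donor-acceptor cutoff in Angstrom.
#' @param ranges,anchors optional overrides of the intracellular definition.
#' @return the pooled `feature_table`, invisibly.
#' @export
run_featurize <- function(pdb_paths, bw_map_path, reference_path, out_dir,
                          hbond_cutoff = 8.0, ranges = NULL, anchors = NULL) {
  ensure_dir(out_dir)
  bw_map <- read_bw_map(bw_map_path)
  reference <- read_pdb_ensemble(reference_path)
  spec <- build_default_spec(reference, bw_map,
                             ranges = ranges %||% .default_ranges,
                             anchors = anchors %||% .default_anchors,
                             hbond_cutoff = hbond_cutoff)
  spec <- derive_hbond_pairs(spec, reference, cutoff = hbond_cutoff,
                             bw_map = bw_map)
  if (is.null(names(pdb_paths))) {
    names(pdb_paths) <- sub("\\.[^.]*$", "", basename(pdb_paths))
  }
  tabs <- lapply(names(pdb_paths), function(lig) {
    ens <- read_pdb_ensemble(pdb_paths[[lig]], ligand_id = lig)
    featurize_ensemble(ens, spec)
  })
  ft <- bind_feature_tables(tabs)
  write_feature_table(ft, file.path(out_dir, "features.csv"))
  write_report(out_dir, "featurize", list(
    n_theta = nrow(spec$torsions), n_ca = nrow(spec$ca_pairs),
    n_hb = nrow(spec$hb_pairs), hbond_cutoff = hbond_cutoff,
    ligands = names(pdb_paths)))
  invisible(ft)
}

#' Fit and persist a conformation model
#'
#' @param features a `feature_table` or feature-table CSV path.
#' @param out_dir output directory.
#' @param hp a `hyperparameters` object (defaults to the study's selected
#'   values, see [reference_hyperparameters()]).
#' @return the fitted `conformation_model`, invisibly.
#' @export
run_cluster <- function(features, out_dir, hp = reference_hyperparameters()) {
  ensure_dir(out_dir)
  ft <- as_feature_table(features)
  model <- fit_conformation_model(ft, hp$weights, hp$h, hp$delta, hp$c)
  Fm <- conformation_fractions(model)
  write_conformation_model(model, file.path(out_dir, "model.json"))
  data.table::fwrite(data.frame(ligand = rownames(Fm), Fm),
                     file.path(out_dir, "fractions.csv"))
  write_report(out_dir, "cluster", list(hyperparameters = hp_as_list(hp)))
  invisible(model)
}

#' Train the efficacy model with nested leave-one-out cross-validation
#'
#' Runs [outer_loo_cross_validation()] and writes predictions (with
#' per-ligand SDs across the cross-validation models), per-conformation
#' slope means and SDs, the shared-space fraction table, accuracy metrics,
#' the shared conformation model, final all-ligand slopes, and a run
#' report carrying the effective hyperparameters.
#'
#' @param features `feature_table` or CSV path (pooled, multi-ligand).
#' @param efficacy `efficacy_table` or CSV path.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param grid a `hyper_grid`; the default is the single-cell grid at the
#'   study's selected hyperparameters (no inner search).
#' @param seed recorded in the report (the training itself is
#'   deterministic).
#' @return a `loo_result`, invisibly.
#' @export
run_train <- function(features, efficacy, out_dir = NULL, grid = NULL,
                      seed = 0L) {
  ft <- as_feature_table(features)
  eff <- as_efficacy_table(efficacy)
  if (is.null(grid)) {
    hp0 <- reference_hyperparameters()
    grid <- hyper_grid(list(unclass(hp0$weights)), hp0$h, hp0$delta, hp0$c)
  }
  pd <- pipeline_data(ft, eff)
  res <- outer_loo_cross_validation(pd, grid)
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    data.table::fwrite(res$predictions, file.path(out_dir, "predictions.csv"))
    sl <- data.frame(
      conformation = rep(seq_len(nrow(res$slope_mean)), 2L),
      pathway = rep(PATHWAYS, each = nrow(res$slope_mean)),
      slope_mean = c(res$slope_mean[, "Gprotein"], res$slope_mean[, "barr2"]),
      slope_sd = c(res$slope_sd[, "Gprotein"], res$slope_sd[, "barr2"]))
    data.table::fwrite(sl, file.path(out_dir, "slopes.csv"))
    Fm <- res$shared_fractions
    data.table::fwrite(data.frame(ligand = rownames(Fm), Fm),
                       file.path(out_dir, "fractions.csv"))
    met <- do.call(rbind, lapply(PATHWAYS, function(p)
      data.frame(pathway = p, mae = res$metrics[[p]]$mae,
                 rmse = res$metrics[[p]]$rmse, r2 = res$metrics[[p]]$r2)))
    data.table::fwrite(met, file.path(out_dir, "metrics.csv"))
    write_conformation_model(res$shared_model, file.path(out_dir, "model.json"))
    final_slopes <- fit_slopes(res$shared_fractions, res$efficacy, warn = FALSE)
    data.table::fwrite(
      data.frame(conformation = seq_len(nrow(final_slopes)), final_slopes),
      file.path(out_dir, "final_slopes.csv"))
    write_report(out_dir, "train", list(
      seed = seed,
      shared_hyperparameters = hp_as_list(res$shared_hyperparameters),
      fold_hyperparameters = lapply(res$fold_hyperparameters, hp_as_list),
      grid = list(n_weights = length(grid$weights), h = grid$h,
                  delta = grid$delta,
                  c = grid$c %||% "2..h-1"),
      metrics = res$metrics))
  }
  invisible(res)
}

#' Predict efficacy for a new ligand's ensemble against a saved model
#'
#' Frames are assigned to conformations of the saved model by nearest
#' medoid; the occupancy row times the final slopes gives the predicted
#' efficacy per pathway.
#'
#' @param model_path JSON file from [run_train()] / [run_cluster()].
#' @param slopes_path `final_slopes.csv` from [run_train()].
#' @param features `feature_table` or CSV path of the new ensemble (must
#'   match the model's feature layout).
#' @param out_dir optional output directory.
#' @return data.frame with the predicted efficacy per pathway, invisibly.
#' @export
run_predict <- function(model_path, slopes_path, features, out_dir = NULL) {
  model <- read_conformation_model(model_path)
  slopes <- data.table::fread(slopes_path, data.table = FALSE)
  ft <- as_feature_table(features)
  labels <- assign_external_frames(model, ft)
  f_row <- tabulate(labels, model$c) / length(labels)
  beta <- as.matrix(slopes[, PATHWAYS, drop = FALSE])
  pred <- predict_efficacy(f_row, beta)
  out <- data.frame(ligand = ft$ligand[1L], pathway = PATHWAYS,
                    predicted = as.numeric(pred))
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    data.table::fwrite(out, file.path(out_dir, "prediction.csv"))
    data.table::fwrite(data.frame(frame = ft$frame, conformation = labels),
                       file.path(out_dir, "frame_assignments.csv"))
    write_report(out_dir, "predict", list(model = model_path,
                                          n_frames = n_config(ft)))
  }
  invisible(out)
}

#' Compute efficacy response functions and activation rankings
#'
#' @param features `feature_table` or CSV path aligned with the model's
#'   frames (any feature table over the same frames may be supplied, e.g.
#'   binding-pocket features that did not enter the distance metric).
#' @param result a `loo_result` (for its shared model and mean slopes), or
#'   `NULL` if `frame_labels` and `slope_mean` are given directly.
#' @param out_dir output directory.
#' @param frame_labels,slope_mean direct inputs when no `loo_result` is at
#'   hand.
#' @param bins histogram bins per density (default 50).
#' @param top_fraction flagged top fraction in the ranking (default 0.02).
#' @return the ranked score table, invisibly.
#' @export
run_erf <- function(features, result = NULL, out_dir = NULL,
                    frame_labels = NULL, slope_mean = NULL, bins = 50L,
                    top_fraction = 0.02) {
  ft <- as_feature_table(features)
  if (!is.null(result)) {
    frame_labels <- result$shared_model$frame_labels
    slope_mean <- result$slope_mean
  }
  if (is.null(frame_labels) || is.null(slope_mean)) {
    stopf("run_erf needs either a loo_result or frame_labels + slope_mean")
  }
  profiles <- compute_erf_profiles(ft, frame_labels, slope_mean, bins = bins)
  ranked <- if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    r <- write_erf_outputs(profiles, file.path(out_dir, "erf_curves.csv"),
                           file.path(out_dir, "erf_scores.csv"),
                           top_fraction = top_fraction)
    write_report(out_dir, "erf", list(n_features = length(profiles),
                                      bins = bins,
                                      top_fraction = top_fraction))
    r
  } else {
    rank_features(profiles, top_fraction = top_fraction)
  }
  invisible(ranked)
}
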