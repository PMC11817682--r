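# Shared fixture builders (all generated in code at test time).

wrapa <- pocketsig:::wrap_angle

# scenario in which only the torsion block carries the conformation signal:
# distance blocks have identical centers and heavy noise, so only the
# torsion-dominant weight pattern separates the planted conformations, and
# only c = 3 matches their number
grid_identifiability_scenario <- function(seed = 501L) {
  theta <- wrapa(outer(c(-2.0, 0.1, 2.2), 0.2 * (1:6), "+"))
  centers <- list(theta = theta, ca = matrix(9, 3, 6), hb = matrix(6, 3, 6))
  mix <- rbind(L1 = c(1, 0, 0), L2 = c(0, 1, 0), L3 = c(0, 0, 1),
               L4 = c(0.6, 0.2, 0.2), L5 = c(0.2, 0.6, 0.2),
               L6 = c(0.2, 0.2, 0.6))
  slopes <- cbind(Gprotein = c(100, 50, 0), barr2 = c(90, 10, 40))
  synthetic_scenario(centers, mix, slopes,
                     noise_sd = list(theta = 0.05, dist = 2.0),
                     efficacy_noise_sd = 2, frames_per_ligand = 80L,
                     seed = seed)
}

# fabricated receptor-like topology: contiguous residues, each with the
# atom complement of its residue type, for feature-spec construction tests
fabricate_structure <- function(res_from = 83L, res_to = 350L,
                                special = list()) {
  atom_sets <- list(
    LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    GLY = c("N", "CA", "C", "O"),
    ALA = c("N", "CA", "C", "O", "CB"),
    VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
    SER = c("N", "CA", "C", "O", "CB", "OG")
  )
  rows <- list()
  for (r in res_from:res_to) {
    type <- special[[as.character(r)]] %||% "LEU"
    for (a in atom_sets[[type]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        elety = a, resid = type, resno = r, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  # arbitrary non-degenerate coordinates (only topology matters for spec
  # construction; geometry tests use make_toy_structures instead)
  set.seed(4242)
  xyz <- matrix(stats::runif(3L * nrow(atoms), 0, 60), nrow = 1L)
  structure_ensemble(atoms, xyz, "fabricated")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random feature table with given block widths
random_feature_table <- function(n, n_theta, n_ca, n_hb, ligand = "L1",
                                 seed = 7L) {
  set.seed(seed)
  feature_table(
    matrix(stats::runif(n * n_theta, -pi, pi), n, n_theta),
    matrix(stats::runif(n * n_ca, 2, 15), n, n_ca),
    matrix(stats::runif(n * n_hb, 2, 15), n, n_hb),
    ligand = ligand)
}

# small fitted model on a three-conformation planted table, reused by
# several assignment tests
planted_small_fit <- function() {
  sc <- preset_scenario("separable_small")
  sam <- sample_ensembles(sc)
  w <- distance_weights(1 / 3, 1 / 3, 1 / 3)
  model <- fit_conformation_model(sam$features, w, h = 12L, delta = 2, c = 3L)
  list(scenario = sc, sample = sam, model = model, weights = w)
}
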