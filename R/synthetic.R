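# Synthetic scenarios: per-ligand ensembles of feature vectors drawn as
# mixtures over a small set of planted conformations (centers in
# torsion+distance feature space with additive noise, torsions wrapped on
# the circle), and efficacies generated by the linear model the pipeline is
# meant to recover. Ground truth for every downstream stage.

#' Synthetic scenario definition
#'
#' @param centers list with matrices `theta` (radians), `ca`, `hb`
#'   (Angstrom), one row per planted conformation.
#' @param mixtures matrix of per-ligand mixture weights over conformations
#'   (rows = ligands, named; each row sums to 1).
#' @param true_slopes matrix conformations x pathways (`Gprotein`, `barr2`)
#'   of planted regression slopes (percent).
#' @param noise_sd list with `theta` (radians) and `dist` (Angstrom) spreads.
#' @param efficacy_noise_sd observation noise on efficacies (percent).
#' @param frames_per_ligand frames drawn per ligand per replicate.
#' @param replicates replicate runs per ligand (pooled downstream).
#' @param seed integer RNG seed for sampling.
#' @param separable if TRUE, validate that centers are pairwise separated by
#'   more than 4x the noise scale under the equal-weight combined distance.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(centers, mixtures, true_slopes,
                               noise_sd = list(theta = 0.1, dist = 0.15),
                               efficacy_noise_sd = 0,
                               frames_per_ligand = 100L, replicates = 1L,
                               seed = 1L, separable = FALSE) {
  mixtures <- as.matrix(mixtures)
  n_conf <- nrow(centers$theta)
  if (nrow(centers$ca) != n_conf || nrow(centers$hb) != n_conf) {
    stopf("center matrices must agree on the number of conformations")
  }
  if (ncol(mixtures) != n_conf) stopf("mixture columns must match conformations")
  if (is.null(rownames(mixtures))) {
    rownames(mixtures) <- sprintf("L%d", seq_len(nrow(mixtures)))
  }
  if (any(mixtures < 0) || any(abs(rowSums(mixtures) - 1) > 1e-9)) {
    stopf("mixture rows must be nonnegative and sum to 1")
  }
  true_slopes <- as.matrix(true_slopes)
  if (nrow(true_slopes) != n_conf || ncol(true_slopes) != 2L) {
    stopf("true_slopes must be conformations x 2 (Gprotein, barr2)")
  }
  colnames(true_slopes) <- PATHWAYS
  if (noise_sd$theta < 0 || noise_sd$dist < 0 || efficacy_noise_sd < 0) {
    stopf("noise levels must be nonnegative")
  }
  sc <- structure(list(
    n_conformations = n_conf, centers = centers, mixtures = mixtures,
    true_slopes = true_slopes, noise_sd = noise_sd,
    efficacy_noise_sd = efficacy_noise_sd,
    frames_per_ligand = as.integer(frames_per_ligand),
    replicates = as.integer(replicates), seed = as.integer(seed),
    separable = separable
  ), class = "synthetic_scenario")
  if (separable) {
    sep <- scenario_separation(sc)
    if (sep$ratio <= 4) {
      stopf("scenario marked separable but center separation is only %.2fx the noise scale",
            sep$ratio)
    }
  }
  sc
}

#' Center separation relative to noise
#'
#' Minimum pairwise combined distance between planted centers (equal
#' weights) over the expected within-conformation frame-frame distance.
#'
#' @param sc a `synthetic_scenario`.
#' @return list with `min_center_distance`, `noise_scale`, `ratio`.
#' @export
scenario_separation <- function(sc) {
  w <- distance_weights(1 / 3, 1 / 3, 1 / 3)
  ctr <- feature_table(sc$centers$theta, sc$centers$ca, sc$centers$hb)
  D <- pairwise_matrix(ctr, w)
  noise_scale <- sqrt(2) / 3 * (sc$noise_sd$theta + 2 * sc$noise_sd$dist)
  mind <- min(D[upper.tri(D)])
  list(min_center_distance = mind, noise_scale = noise_scale,
       ratio = if (noise_scale > 0) mind / noise_scale else Inf)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scenario> %d conformations, %d ligands x %d replicate(s) x %d frames (seed %d)\n",
    x$n_conformations, nrow(x$mixtures), x$replicates, x$frames_per_ligand,
    x$seed))
  invisible(x)
}

#' Sample per-ligand feature ensembles from a scenario
#'
#' For each ligand and frame, a conformation is drawn from the ligand's
#' mixture, then features are the conformation center plus noise: torsions
#' get wrapped-normal perturbations (so the periodic metric is exercised at
#' the seam) and distances get normal perturbations truncated to stay
#' positive. Reproducible from the scenario seed.
#'
#' @param sc a `synthetic_scenario`.
#' @param seed optional seed override.
#' @return list with `features` (pooled `feature_table` with ligand labels),
#'   `truth` (data.frame ligand, replicate, frame, conformation) and
#'   `fractions` (empirical per-ligand occupancy of the planted labels).
#' @export
sample_ensembles <- function(sc, seed = sc$seed) {
  ligs <- rownames(sc$mixtures)
  n_per <- sc$frames_per_ligand * sc$replicates
  with_seed(seed, {
    tabs <- list(); truth <- list()
    for (l in ligs) {
      z <- sample.int(sc$n_conformations, n_per, replace = TRUE,
                      prob = sc$mixtures[l, ])
      nt <- ncol(sc$centers$theta); nc <- ncol(sc$centers$ca)
      nh <- ncol(sc$centers$hb)
      theta <- wrap_angle(sc$centers$theta[z, , drop = FALSE] +
                            matrix(stats::rnorm(n_per * nt, 0, sc$noise_sd$theta),
                                   n_per, nt))
      ca <- pmax(sc$centers$ca[z, , drop = FALSE] +
                   matrix(stats::rnorm(n_per * nc, 0, sc$noise_sd$dist),
                          n_per, nc), 1e-3)
      hb <- pmax(sc$centers$hb[z, , drop = FALSE] +
                   matrix(stats::rnorm(n_per * nh, 0, sc$noise_sd$dist),
                          n_per, nh), 1e-3)
      colnames(theta) <- sprintf("tor:s%d:ang", seq_len(nt))
      colnames(ca) <- sprintf("ca:s%d-s%d", seq_len(nc), seq_len(nc) + 1L)
      colnames(hb) <- sprintf("hb:s%d@N-s%d@O", seq_len(nh), seq_len(nh) + 2L)
      tabs[[l]] <- feature_table(theta, ca, hb, ligand = l)
      truth[[l]] <- data.frame(
        ligand = l,
        replicate = rep(seq_len(sc$replicates), each = sc$frames_per_ligand),
        frame = seq_len(n_per), conformation = z,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    frac <- conformation_fractions(truth$conformation, truth$ligand,
                                   sc$n_conformations)
    list(features = bind_feature_tables(tabs), truth = truth,
         fractions = frac)
  })
}

#' Generate efficacies from fractions via the planted linear model
#'
#' Per ligand and pathway: `value = sum_c beta*_c f_{l,c} + N(0, sd)`, with
#' `records_per_key` independent assay records so the median target is
#' exercised.
#'
#' @param sc a `synthetic_scenario`.
#' @param fractions per-ligand fraction matrix (e.g. the `fractions` element
#'   of [sample_ensembles()], or the mixture matrix itself).
#' @param records_per_key assay records per (ligand, pathway) key.
#' @param seed optional seed override (defaults to `sc$seed + 1`).
#' @return an `efficacy_table`.
#' @export
make_efficacies <- function(sc, fractions, records_per_key = 1L,
                            seed = sc$seed + 1L) {
  fractions <- as.matrix(fractions)
  if (is.null(rownames(fractions))) {
    rownames(fractions) <- sprintf("L%d", seq_len(nrow(fractions)))
  }
  mu <- fractions %*% sc$true_slopes
  with_seed(seed, {
    rows <- list()
    for (l in rownames(mu)) {
      for (p in PATHWAYS) {
        v <- mu[l, p] + stats::rnorm(records_per_key, 0, sc$efficacy_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          ligand_id = l, pathway = p, value = v,
          assay = sprintf("synthetic_%d", seq_len(records_per_key)),
          stringsAsFactors = FALSE)
      }
    }
    efficacy_table(do.call(rbind, rows))
  })
}

# --- toy structures ----------------------------------------------------------

# fixed local residue geometry (offsets from CA, Angstrom)
.toy_offsets <- list(
  N = c(-1.20, 0.76, 0.00),
  C = c(1.25, 0.60, 0.30),
  O = c(1.70, 1.70, -0.40),
  CB = c(0.45, -1.00, 1.05)
)

#' Build a toy helix-bundle ensemble with prescribed features
#'
#' Constructs leucine-like residues (atoms N, CA, C, O, CB, CG) at given
#' C-alpha positions, with each residue's chi1 torsion (N-CA-CB-CG) placed
#' exactly at the requested value by internal-coordinate construction. The
#' resulting ensemble exercises the featurization path end to end: chi1
#' features reproduce the request and CA distances reproduce the placed
#' coordinates.
#'
#' @param chi1 matrix of requested chi1 angles (radians), frames x residues.
#' @param ca_coords residue CA positions: one n_res x 3 matrix (shared by
#'   all frames) or a list of per-frame matrices.
#' @param ligand_id ligand label of the ensemble.
#' @return list with `ensemble` (a `structure_ensemble`) and `expected`
#'   (list: `chi1` wrapped request, `ca_dist` function(i, j, frame)).
#' @export
make_toy_structures <- function(chi1, ca_coords, ligand_id = "toy") {
  chi1 <- as.matrix(chi1)
  n_frames <- nrow(chi1); n_res <- ncol(chi1)
  if (n_res < 4L) stopf("toy structures need at least 4 residues")
  per_frame_ca <- is.list(ca_coords)
  get_ca <- function(f) {
    m <- if (per_frame_ca) ca_coords[[f]] else ca_coords
    m <- as.matrix(m)
    if (nrow(m) != n_res || ncol(m) != 3L) {
      stopf("ca_coords must be n_res x 3")
    }
    m
  }
  atom_names <- c("N", "CA", "C", "O", "CB", "CG")
  atoms <- data.frame(
    eleno = seq_len(n_res * 6L),
    elety = rep(atom_names, n_res),
    resid = "LEU",
    resno = rep(seq_len(n_res), each = 6L),
    stringsAsFactors = FALSE
  )
  xyz <- matrix(NA_real_, n_frames, n_res * 18L)
  for (f in seq_len(n_frames)) {
    ca <- get_ca(f)
    co <- matrix(NA_real_, n_res * 6L, 3L)
    for (r in seq_len(n_res)) {
      base <- (r - 1L) * 6L
      p_ca <- ca[r, ]
      p_n <- p_ca + .toy_offsets$N
      p_cb <- p_ca + .toy_offsets$CB
      p_cg <- place_atom(p_n, p_ca, p_cb, bond = 1.52,
                         angle = 109.5 * pi / 180, dihedral = chi1[f, r])
      co[base + 1L, ] <- p_n
      co[base + 2L, ] <- p_ca
      co[base + 3L, ] <- p_ca + .toy_offsets$C
      co[base + 4L, ] <- p_ca + .toy_offsets$O
      co[base + 5L, ] <- p_cb
      co[base + 6L, ] <- p_cg
    }
    xyz[f, ] <- as.vector(t(co))
  }
  ens <- structure_ensemble(atoms, xyz, ligand_id)
  list(
    ensemble = ens,
    expected = list(
      chi1 = wrap_angle(chi1),
      ca_dist = function(i, j, frame = 1L) {
        m <- get_ca(frame)
        sqrt(sum((m[i, ] - m[j, ])^2))
      }
    )
  )
}

#' Feature specification for a toy ensemble
#'
#' chi1 of every residue plus all CA pairs with sequence separation >= 2.
#'
#' @param ensemble a toy `structure_ensemble` (see [make_toy_structures()]).
#' @return a `feature_spec`.
#' @export
toy_feature_spec <- function(ensemble) {
  res <- sort(unique(ensemble$atoms$resno))
  tor <- data.frame(resno = res, bw = as.character(res), resid = "LEU",
                    angle = "chi1", stringsAsFactors = FALSE)
  cmb <- utils::combn(res, 2L)
  keep <- abs(cmb[1L, ] - cmb[2L, ]) >= 2L
  ca <- data.frame(resno_i = cmb[1L, keep], bw_i = as.character(cmb[1L, keep]),
                   resno_j = cmb[2L, keep], bw_j = as.character(cmb[2L, keep]),
                   stringsAsFactors = FALSE)
  feature_spec(tor, ca)
}

# --- presets -----------------------------------------------------------------

.preset_names <- c("separable_small", "noisy_medium", "paper_shaped")

# deterministic center/mixture construction; the internal seed is part of
# the scenario definition, independent of the sampling seed
.make_centers <- function(n_conf, n_theta, n_ca, n_hb, internal_seed) {
  with_seed(internal_seed, list(
    theta = matrix(stats::runif(n_conf * n_theta, -pi, pi), n_conf, n_theta),
    ca = matrix(stats::runif(n_conf * n_ca, 6, 14), n_conf, n_ca),
    hb = matrix(stats::runif(n_conf * n_hb, 3, 9), n_conf, n_hb)
  ))
}

#' Named synthetic presets
#'
#' `separable_small`: 3 well-separated conformations, 6 ligands, 200 frames
#' each, noise-free efficacies --- the ground-truth recovery scenario.
#' `noisy_medium`: 4 conformations, 8 ligands, 150 frames, moderate feature
#' noise and 5% efficacy noise. `paper_shaped`: the shape of the original
#' study --- 11 ligands x 3 pooled replicates, 14 planted conformations, two
#' pathways, 5% efficacy noise.
#'
#' @param name one of `"separable_small"`, `"noisy_medium"`,
#'   `"paper_shaped"`.
#' @param seed sampling seed override (the scenario definition itself ---
#'   centers, mixtures, slopes --- is fixed per preset).
#' @param efficacy_noise_sd optional override of the efficacy noise (percent).
#' @return a `synthetic_scenario`.
#' @export
preset_scenario <- function(name, seed = NULL, efficacy_noise_sd = NULL) {
  if (!name %in% .preset_names) {
    stopf("unknown preset '%s'; available: %s", name,
          paste(.preset_names, collapse = ", "))
  }
  sc <- switch(name,
    separable_small = {
      ang0 <- c(-2.8, -0.5, 1.9)
      centers <- list(
        theta = wrap_angle(outer(ang0, 0.35 * (1:8), "+")),
        ca = outer(1.5 * (1:3), 0.3 * (1:5), "+") + 8,
        hb = outer(1.2 * (1:3), 0.25 * (1:5), "+") + 4
      )
      mixtures <- rbind(
        L1 = c(1, 0, 0), L2 = c(0, 1, 0), L3 = c(0, 0, 1),
        L4 = c(0.5, 0.25, 0.25), L5 = c(0.2, 0.6, 0.2),
        L6 = c(0.1, 0.3, 0.6))
      slopes <- cbind(Gprotein = c(100, 35, 5), barr2 = c(80, 10, 45))
      synthetic_scenario(centers, mixtures, slopes,
                         noise_sd = list(theta = 0.12, dist = 0.15),
                         efficacy_noise_sd = 0, frames_per_ligand = 200L,
                         replicates = 1L, seed = 101L, separable = TRUE)
    },
    noisy_medium = {
      centers <- .make_centers(4L, 12L, 8L, 8L, internal_seed = 7701L)
      mixtures <- with_seed(7702L, {
        m <- matrix(stats::runif(8L * 4L), 8L, 4L)^2
        m <- m / rowSums(m)
        rownames(m) <- sprintf("L%d", 1:8)
        m
      })
      slopes <- cbind(Gprotein = c(105, 60, 25, -5), barr2 = c(85, 15, 55, 0))
      synthetic_scenario(centers, mixtures, slopes,
                         noise_sd = list(theta = 0.3, dist = 0.4),
                         efficacy_noise_sd = 5, frames_per_ligand = 150L,
                         replicates = 1L, seed = 202L)
    },
    paper_shaped = {
      n_conf <- 14L
      ligs <- c("DAM", "FEN", "LFT", "MPH", "TRV", "SR", "PZM", "FH",
                "C5", "C6", "MP")
      centers <- .make_centers(n_conf, 24L, 12L, 12L, internal_seed = 8801L)
      # occupancy structure mirroring the study's description: each complex
      # dominated by one conformation, a couple of minor shared states, and
      # three conformations (2, 12, 13) unique to a single ligand
      dominant <- c(4L, 12L, 2L, 9L, 5L, 10L, 7L, 13L, 8L, 14L, 6L)
      secondary <- c(1L, 6L, 6L, 4L, 9L, 14L, 3L, 1L, 11L, 8L, 1L)
      tertiary <- c(6L, 1L, 3L, 14L, 7L, 5L, 11L, 14L, 3L, 11L, 5L)
      # plus a weak uniform thermal occupancy of every state
      mixtures <- matrix(0, length(ligs), n_conf, dimnames = list(ligs, NULL))
      for (i in seq_along(ligs)) {
        mixtures[i, dominant[i]] <- 0.60
        mixtures[i, secondary[i]] <- 0.25
        mixtures[i, tertiary[i]] <- 0.15
      }
      mixtures <- 0.88 * mixtures + 0.12 / n_conf
      # slopes indexed in decreasing average activity; conformations 4 and 9
      # promote G protein and repress barr2, 2/3/5/7 promote barr2 only,
      # the tail represses both
      slopes <- cbind(
        Gprotein = c(110, 5, 10, 95, 15, 75, 20, 40, 60, 30, 50, -10, -5, -20),
        barr2 = c(105, 90, 70, 10, 55, 65, 45, 35, 25, 20, 40, 5, -10, -15))
      synthetic_scenario(centers, mixtures, slopes,
                         noise_sd = list(theta = 0.22, dist = 0.25),
                         efficacy_noise_sd = 5, frames_per_ligand = 40L,
                         replicates = 3L, seed = 303L)
    }
  )
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  if (!is.null(efficacy_noise_sd)) sc$efficacy_noise_sd <- efficacy_noise_sd
  sc
}

#' Read / write scenario definitions as YAML
#'
#' @param sc a `synthetic_scenario`.
#' @param path YAML file path.
#' @return `path` invisibly (write) or a `synthetic_scenario` (read).
#' @export
write_scenario_yaml <- function(sc, path) {
  obj <- list(
    n_conformations = sc$n_conformations,
    centers = lapply(sc$centers, function(m) apply(unname(m), 1L, c,
                                                   simplify = FALSE)),
    mixtures = apply(unname(sc$mixtures), 1L, c, simplify = FALSE),
    ligands = rownames(sc$mixtures),
    true_slopes = apply(unname(sc$true_slopes), 1L, c, simplify = FALSE),
    noise_sd = sc$noise_sd,
    efficacy_noise_sd = sc$efficacy_noise_sd,
    frames_per_ligand = sc$frames_per_ligand,
    replicates = sc$replicates, seed = sc$seed, separable = sc$separable
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  centers <- lapply(o$centers, function(rows) do.call(rbind, rows))
  mixtures <- do.call(rbind, o$mixtures)
  rownames(mixtures) <- o$ligands
  synthetic_scenario(
    centers, mixtures, do.call(rbind, o$true_slopes),
    noise_sd = o$noise_sd, efficacy_noise_sd = o$efficacy_noise_sd,
    frames_per_ligand = o$frames_per_ligand, replicates = o$replicates,
    seed = o$seed, separable = isTRUE(o$separable)
  )
}
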