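test_that("complete-linkage clustering recovers planted block structure", {
  # two zero-diameter groups at distance 1
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0
  hc <- hierarchical_cluster(D, 2L)
  expect_equal(hc$labels[1:3], rep(hc$labels[1L], 3))
  expect_equal(hc$labels[4:6], rep(hc$labels[4L], 3))
  expect_false(hc$labels[1L] == hc$labels[4L])
  # degenerate cut: every frame its own cluster
  expect_equal(sort(hierarchical_cluster(D, 6L)$labels), 1:6)
  expect_error(hierarchical_cluster(D, 1L), "h must be")
  expect_error(hierarchical_cluster(D, 7L), "h must be")
})

test_that("complete linkage matches the exhaustive minimax partition oracle", {
  # 10 frames from 3 planted centers with small noise
  set.seed(55)
  centers <- c(0, 10, 25)
  z <- rep(1:3, c(3, 3, 4))
  x <- centers[z] + runif(10, -0.5, 0.5)
  D <- abs(outer(x, x, "-"))
  got <- hierarchical_cluster(D, 3L)$labels
  parts <- all_k_partitions(10, 3)
  costs <- apply(parts, 1L, function(p) partition_max_within(D, p))
  best <- parts[which.min(costs), ]
  expect_equal(adjusted_rand(got, best), 1)
  expect_equal(adjusted_rand(got, z), 1)
})

test_that("medoids minimize summed within-cluster distance", {
  # 3 collinear points: the middle one is the 1-median
  D <- abs(outer(c(0, 1, 2), c(0, 1, 2), "-"))
  expect_equal(compute_medoids(D, rep(1L, 3)), 2L)
  # singleton cluster is its own medoid
  expect_equal(compute_medoids(D, c(1L, 2L, 2L))[1L], 1L)
  # brute force on a random 20-frame cluster
  set.seed(66)
  x <- matrix(runif(40), 20, 2)
  D20 <- as.matrix(stats::dist(x))
  med <- compute_medoids(D20, rep(1L, 20))
  expect_equal(med, unname(which.min(colSums(D20))))
})

test_that("Gaussian similarity follows the kernel and its monotonicity", {
  D <- matrix(c(0, 2, 5, 2, 0, 1, 5, 1, 0), 3, 3)
  S <- similarity_from_rmsd(D, delta = 2)
  expect_equal(diag(S), rep(1, 3))
  # the study's bandwidth: delta = 2 at D = 2 gives exp(-1/2)
  expect_equal(S[1, 2], exp(-0.5), tolerance = 1e-12)
  expect_equal(S[1, 2], 0.60653, tolerance = 1e-5)
  # larger distances never yield larger similarity
  expect_true(all(order(D[upper.tri(D)]) == order(-S[upper.tri(S)])))
  expect_error(similarity_from_rmsd(D, 0), "delta")
})

test_that("spectral grouping with QR assignment recovers ideal and planted graphs", {
  # three perfect blocks
  S <- matrix(1e-4, 9, 9)
  for (b in list(1:3, 4:6, 7:9)) S[b, b] <- 1
  lab <- spectral_conformations(S, 3L)
  expect_equal(adjusted_rand(lab, rep(1:3, each = 3)), 1)

  # c = h - 1: exactly one pair merged, all other groups singletons
  set.seed(77)
  x <- runif(8, 0, 10)
  S8 <- exp(-abs(outer(x, x, "-"))^2 / 2)
  lab8 <- spectral_conformations(S8, 7L)
  expect_equal(length(unique(lab8)), 7L)
  expect_equal(sort(tabulate(lab8, 7L)), c(rep(1L, 6L), 2L))

  # 8 centroids from 3 planted groups vs the exhaustive similarity oracle
  set.seed(78)
  g <- c(1, 1, 1, 2, 2, 3, 3, 3)
  y <- c(0, 0.2, -0.1, 5, 5.3, 11, 10.8, 11.2) + runif(8, -0.05, 0.05)
  Sg <- exp(-outer(y, y, "-")^2 / 8)
  labg <- spectral_conformations(Sg, 3L)
  parts <- all_k_partitions(8, 3)
  scores <- apply(parts, 1L, function(p) partition_within_similarity(Sg, p))
  expect_equal(adjusted_rand(labg, parts[which.max(scores), ]), 1)
  expect_equal(adjusted_rand(labg, g), 1)
  expect_error(spectral_conformations(Sg, 8L), "c must be")
})

test_that("the fitted conformation model recovers planted conformations exactly", {
  fit <- planted_small_fit()
  truth <- fit$sample$truth$conformation
  expect_equal(adjusted_rand(fit$model$frame_labels, truth), 1)
  # label consistency: frame labels are hierarchical labels relabeled
  expect_equal(fit$model$frame_labels,
               fit$model$cluster_to_conf[fit$model$hier_labels])
  # h = c makes the cluster-to-conformation map a bijection
  ft40 <- subset_config(fit$sample$features, 1:40)
  m_bij <- fit_conformation_model(ft40, fit$weights, h = 5L, delta = 2, c = 5L)
  expect_equal(sort(m_bij$cluster_to_conf), 1:5)
  expect_equal(m_bij$frame_labels, m_bij$hier_labels)
  # determinism: identical inputs give identical models
  m2 <- fit_conformation_model(fit$sample$features, fit$weights, 12L, 2, 3L)
  expect_identical(m2$frame_labels, fit$model$frame_labels)
  expect_identical(m2$medoid_frames, fit$model$medoid_frames)
})

test_that("medoid RMSD metric is available when coordinates exist", {
  set.seed(91)
  ca <- lapply(1:12, function(f)
    matrix(c(0, 0, 0, 5, 0, 0, 9, 3, 0, 12, 7, 2), ncol = 3, byrow = TRUE) +
      matrix(rnorm(12, sd = 0.05), 4, 3) +
      (f > 6) * matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 4, 4, 0), ncol = 3,
                       byrow = TRUE))
  chi1 <- matrix(c(runif(24, -1, -0.5), runif(24, 1, 1.5)), 12, 4,
                 byrow = TRUE)
  toy <- make_toy_structures(chi1, ca)
  ft <- featurize_ensemble(toy$ensemble, toy_feature_spec(toy$ensemble))
  m <- fit_conformation_model(ft, distance_weights(0.5, 0.5, 0),
                              h = 4L, delta = 2, c = 2L,
                              medoid_metric = "rmsd",
                              ensemble = toy$ensemble)
  expect_equal(m$medoid_metric, "rmsd")
  expect_equal(length(unique(m$frame_labels)), 2L)
})

test_that("fractions count frames and rows sum to one", {
  expect_equal(unname(conformation_fractions(c(1L, 1L, 2L, 3L),
                                             rep("A", 4), 3L)),
               matrix(c(0.5, 0.25, 0.25), 1))
  expect_equal(unname(conformation_fractions(rep(2L, 5), rep("A", 5), 3L)),
               matrix(c(0, 1, 0), 1))
  set.seed(101)
  for (rep in 1:5) {
    lab <- sample.int(6, 300, replace = TRUE)
    lig <- sample(c("A", "B", "C"), 300, replace = TRUE)
    Fm <- conformation_fractions(lab, lig, 6L)
    expect_lt(max(abs(rowSums(Fm) - 1)), 1e-12)
  }
  expect_error(conformation_fractions(c(1L, 2L), "A", 2L), "length")
})

test_that("external frames go to the nearest medoid with low-id tie-breaking", {
  fit <- planted_small_fit()
  model <- fit$model
  # a frame identical to a medoid gets that medoid's conformation
  probe <- subset_config(fit$sample$features, model$medoid_frames[1L])
  expect_equal(assign_external_frames(model, probe),
               model$medoid_conf[1L])
  # held-out frames agree with planted truth through label matching
  sc2 <- preset_scenario("separable_small", seed = 777L)
  sam2 <- sample_ensembles(sc2)
  lab2 <- assign_external_frames(model, sam2$features)
  expect_gte(adjusted_rand(lab2, sam2$truth$conformation), 0.95)

  # engineered exact tie between conformations 2 and 1 resolves to 1
  mf <- feature_table(matrix(0, 2, 1), matrix(c(4, 8), 2, 1),
                      matrix(c(4, 8), 2, 1))
  fake <- structure(list(
    medoid_features = mf, medoid_conf = c(2L, 1L), c = 2L,
    weights = distance_weights(0, 0.5, 0.5)), class = "conformation_model")
  midpoint <- feature_table(matrix(0, 1, 1), matrix(6, 1, 1),
                            matrix(6, 1, 1))
  expect_equal(assign_external_frames(fake, midpoint), 1L)
})

test_that("conformation models serialize to JSON and back", {
  fit <- planted_small_fit()
  tmp <- tempfile(fileext = ".json")
  write_conformation_model(fit$model, tmp)
  back <- read_conformation_model(tmp)
  expect_equal(back$frame_labels, fit$model$frame_labels)
  expect_equal(back$cluster_to_conf, fit$model$cluster_to_conf)
  expect_equal(unclass(back$weights), unclass(fit$model$weights))
  probe <- subset_config(fit$sample$features, 1:20)
  expect_equal(assign_external_frames(back, probe),
               assign_external_frames(fit$model, probe))
})
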