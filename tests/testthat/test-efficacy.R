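test_that("median efficacies aggregate assay records per ligand and pathway", {
  tab <- efficacy_table(data.frame(
    ligand_id = c("A", "A", "A", "B", "B", "DAMGO", "DAMGO"),
    pathway = c("Gprotein", "Gprotein", "Gprotein", "Gprotein", "Gprotein",
                "Gprotein", "barr2"),
    value = c(90, 100, 110, 80, 100, 100, 100)))
  # A and B lack barr2 records
  expect_error(median_efficacy(tab), "barr2")
  tab2 <- efficacy_table(rbind(tab$records,
    data.frame(ligand_id = c("A", "B"), pathway = "barr2",
               value = c(50, 60), assay = NA)))
  m <- median_efficacy(tab2, ligands = c("A", "B", "DAMGO"))
  expect_equal(m["A", "Gprotein"], 100)   # odd count
  expect_equal(m["B", "Gprotein"], 90)    # even count: mean of central pair
  # the reference agonist sits at 100% by construction of the scale
  expect_equal(m["DAMGO", "Gprotein"], 100)
  expect_error(efficacy_table(data.frame(ligand_id = "A", pathway = "x",
                                         value = 1)), "pathway")
})

test_that("slope fitting solves intercept-free least squares with min-norm fallback", {
  # identity design returns the targets as slopes
  expect_equal(fit_slopes(diag(2), c(100, 20)), c(100, 20))
  # planted-slope self-consistency on a random full-rank design
  set.seed(7)
  Fm <- matrix(runif(40), 8, 5)
  Fm <- Fm / rowSums(Fm)
  beta_star <- c(110, 60, 20, -10, 45)
  expect_lt(max(abs(fit_slopes(Fm, drop(Fm %*% beta_star)) - beta_star)),
            1e-8)
  # a conformation visited by no ligand gets slope 0 under min-norm
  F0 <- cbind(Fm, 0)
  expect_warning(b0 <- fit_slopes(F0, drop(Fm %*% beta_star)),
                 "minimum-norm")
  expect_equal(b0[6L], 0)
  expect_lt(max(abs(b0[1:5] - beta_star)), 1e-8)
  expect_error(fit_slopes(Fm[1, , drop = FALSE], 1), "at least 2")
})

test_that("prediction is the fraction-slope dot product", {
  expect_equal(predict_efficacy(c(0.5, 0.5), c(100, 20)), 60)
  expect_equal(predict_efficacy(c(0, 1, 0), c(5, 42, 7)), 42)
  # joint permutation invariance and linearity
  set.seed(8)
  f <- runif(6); f <- f / sum(f); b <- rnorm(6, 50, 30)
  p <- sample(6)
  expect_equal(predict_efficacy(f[p], b[p]), predict_efficacy(f, b))
  expect_equal(predict_efficacy(f, 2 * b), 2 * predict_efficacy(f, b))
  expect_error(predict_efficacy(c(1, 0), c(1, 2, 3)), "mismatch")
})

test_that("accuracy metrics follow their definitions", {
  m <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(mae = 0, rmse = 0, r2 = 1))
  # constant prediction at the observed mean has R2 = 0
  obs <- c(10, 20, 30)
  expect_equal(evaluate_predictions(rep(20, 3), obs)$r2, 0)
  # hand-evaluated errors (3, -4)
  m2 <- evaluate_predictions(c(13, 16), c(10, 20))
  expect_equal(m2$mae, 3.5)
  expect_equal(m2$rmse, sqrt(12.5))
  expect_equal(m2$rmse, 3.5355, tolerance = 1e-4)
  expect_warning(z <- evaluate_predictions(c(1, 2), c(5, 5)), "variance")
  expect_true(is.nan(z$r2))
})

test_that("inner LOO loss vanishes on the noise-free planted scenario", {
  fit <- planted_small_fit()
  eff <- make_efficacies(fit$scenario, fit$sample$fractions)
  pd <- pipeline_data(fit$sample$features, eff)
  hp <- hyperparameters(fit$weights, h = 12L, delta = 2, c = 3L)
  loss <- inner_loo_loss(pd, pd$ligands, hp)
  expect_lt(loss$loss, 1e-6)
  # invariant to the order in which training ligands are listed
  loss2 <- inner_loo_loss(pd, rev(pd$ligands), hp)
  expect_equal(loss2$loss, loss$loss)
  expect_equal(loss$loss, loss$loss_G + loss$loss_barr2)
  expect_error(inner_loo_loss(pd, pd$ligands[1:2], hp), "at least 3")
})

test_that("weight patterns exclude negative entries and grids stay valid", {
  expect_message(w <- weight_patterns(c(0.25, 1)), "negative")
  sums <- vapply(w, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(unlist(w) >= 0))
  # w = 1 contributes nothing; w = 0.25 contributes 3 patterns
  expect_equal(length(w), 3L)
  # a 1-point grid is returned without evaluation
  g1 <- hyper_grid(list(c(0.25, 0.25, 0.5)), 40, 2, 14)
  fit <- planted_small_fit()
  eff <- make_efficacies(fit$scenario, fit$sample$fractions)
  pd <- pipeline_data(fit$sample$features, eff)
  gs <- grid_search(pd, pd$ligands, g1)
  expect_equal(gs$best$h, 40L)
  expect_equal(gs$best$c, 14L)
  expect_null(gs$trace)
  # the default grid mirrors the published search space
  dg <- default_grid()
  expect_equal(dg$h, 2:40)
  expect_equal(dg$delta, c(1, 2, 3))
  expect_equal(length(dg$weights), 12L)
  expect_null(dg$c)
})

test_that("outer LOO recovers the planted model exactly without noise", {
  fit <- planted_small_fit()
  eff <- make_efficacies(fit$scenario, fit$sample$fractions)
  pd <- pipeline_data(fit$sample$features, eff)
  grid <- hyper_grid(list(unclass(fit$weights)), 12, 2, 3)
  res <- outer_loo_cross_validation(pd, grid)
  expect_lt(max(abs(res$predictions$predicted - res$predictions$observed)),
            1e-3)
  expect_equal(res$metrics$Gprotein$mae, 0, tolerance = 1e-6)
  # slope stability: SD across models is tiny relative to magnitudes
  expect_lt(max(res$slope_sd), 1e-6)
  # slope recovery in the shared space, up to conformation relabeling
  got <- sort(res$slope_mean[, "Gprotein"])
  expect_equal(got, sort(fit$scenario$true_slopes[, "Gprotein"]),
               tolerance = 1e-6, ignore_attr = TRUE)

  # duplicated ligand: held-out prediction equals the duplicate's fit
  ft <- fit$sample$features
  dup_idx <- which(ft$ligand == "L4")
  dup <- subset_config(ft, dup_idx)
  dup$ligand <- rep("L4copy", length(dup_idx))
  rec_dup <- eff$records[eff$records$ligand_id == "L4", ]
  rec_dup$ligand_id <- "L4copy"
  eff2 <- efficacy_table(rbind(eff$records, rec_dup))
  pd2 <- pipeline_data(bind_feature_tables(list(ft, dup)), eff2)
  res2 <- outer_loo_cross_validation(pd2, grid)
  p4 <- res2$prediction_array[, "L4", ]
  p4c <- res2$prediction_array[, "L4copy", ]
  expect_equal(res2$prediction_array["L4", "L4", ],
               res2$prediction_array["L4", "L4copy", ], tolerance = 1e-6)
  expect_lt(max(abs(p4 - p4c), na.rm = TRUE), 1e-6)
})

test_that("cross-validation outputs are ligand-order invariant", {
  fit <- planted_small_fit()
  eff <- make_efficacies(fit$scenario, fit$sample$fractions)
  ft <- fit$sample$features
  # feed the same frames in a permuted order
  set.seed(31)
  p <- sample(n_config(ft))
  pd_a <- pipeline_data(ft, eff)
  pd_b <- pipeline_data(subset_config(ft, p), eff)
  grid <- hyper_grid(list(unclass(fit$weights)), 12, 2, 3)
  res_a <- outer_loo_cross_validation(pd_a, grid)
  res_b <- outer_loo_cross_validation(pd_b, grid)
  expect_equal(res_b$predictions$predicted, res_a$predictions$predicted,
               tolerance = 1e-9)
})
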