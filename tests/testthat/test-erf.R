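test_that("periodic densities are flat for uniform samples and always normalize", {
  set.seed(12)
  x <- runif(1e5, -pi, pi)
  d <- conformation_density(x, periodic = TRUE)
  expect_lt(max(abs(d$values - 1 / (2 * pi))), 0.02)
  expect_equal(activation_score(d$values, d$domain), 1, tolerance = 1e-3)
  # degenerate distribution: all mass in one bin, integral still one
  d1 <- conformation_density(rep(0.37, 50), periodic = TRUE)
  expect_equal(sum(d1$bin_density > 0), 1L)
  expect_equal(activation_score(d1$values, d1$domain), 1, tolerance = 1e-6)
  # nonperiodic normalization over the padded data range
  y <- rnorm(5e4, 8, 0.7)
  dn <- conformation_density(y, periodic = FALSE)
  expect_equal(activation_score(dn$values, dn$domain), 1, tolerance = 1e-3)
  expect_error(conformation_density(numeric()), "empty")
})

test_that("triplication removes the seam artifact at +/- pi", {
  # samples concentrated just either side of the periodic boundary
  set.seed(13)
  x <- wrapa(pi + rnorm(2e4, 0, 0.25))
  d <- conformation_density(x, periodic = TRUE, bins = 60L)
  oracle <- wrapped_histogram_oracle(x, bins = 60L)
  expect_equal(d$bin_density, oracle, tolerance = 1e-12)
  # the two bins flanking the seam carry comparable, large mass
  expect_gt(d$bin_density[1L], 0.3)
  expect_gt(d$bin_density[60L], 0.3)
  expect_lt(abs(d$bin_density[1L] - d$bin_density[60L]) /
              max(d$bin_density), 0.15)
})

test_that("ERFs are slope-weighted density sums: quadrature, cancellation, linearity", {
  set.seed(14)
  dens <- lapply(c(-1.2, 0.4, 2.0), function(mu)
    conformation_density(wrapa(rnorm(4000, mu, 0.4)), periodic = TRUE))
  # single conformation with slope 1 integrates to one
  r1 <- efficacy_response(dens[1], 1)
  expect_equal(activation_score(r1$values, r1$domain), 1, tolerance = 1e-3)
  # identical densities with slopes summing to zero cancel
  same <- dens[c(1, 1, 1)]
  r0 <- efficacy_response(same, c(2, -0.5, -1.5))
  expect_lt(max(abs(r0$values)), 1e-9)
  # linearity in the slope vector
  ra <- efficacy_response(dens, c(10, 20, 30))
  rb <- efficacy_response(dens, 2 * c(10, 20, 30))
  expect_equal(rb$values, 2 * ra$values, tolerance = 1e-12)
  expect_error(efficacy_response(dens, 1:2), "one slope per")
})

test_that("activation gates fire on sign agreement/opposition and exclude each other", {
  mk <- function(vals) {
    structure(list(grid = seq(0.5, 9.5, by = 1), values = vals,
                   domain = c(0, 10), periodic = FALSE, spacing = 1,
                   feature_id = "f", pathway = "x"), class = "erf_curve")
  }
  ones <- rep(1, 10)
  expect_equal(general_activation(mk(ones), mk(ones)), ones)
  expect_equal(general_activation(mk(ones), mk(-ones)), rep(0, 10))
  expect_equal(selective_activation(mk(ones), mk(-ones)), ones)
  expect_equal(selective_activation(mk(ones), mk(ones)), rep(0, 10))
  # magnitude gate takes the smaller magnitude
  expect_equal(general_activation(mk(2 * ones), mk(0.5 * ones)),
               0.5 * ones)
  # swapping pathways negates the selective function
  set.seed(15)
  va <- rnorm(10); vb <- rnorm(10)
  expect_equal(selective_activation(mk(vb), mk(va)),
               -selective_activation(mk(va), mk(vb)))
  # mixed-sign curves: the gates never fire together
  a <- general_activation(mk(va), mk(vb))
  s <- selective_activation(mk(va), mk(vb))
  expect_true(all(a * s == 0))
})

test_that("the rectangle rule is exact for constants and accurate for sin", {
  expect_equal(activation_score(rep(3.7, 1000), c(-2, 5)), 3.7 * 7,
               tolerance = 1e-9)
  expect_equal(activation_score(rep(0, 1000), c(-2, 5)), 0)
  gg <- pocketsig:::erf_grid(c(-pi, pi))
  expect_lt(abs(activation_score(sin(gg$x), c(-pi, pi))), 1e-4)
  expect_error(activation_score(1:5, c(0, 1), grid = c(0, 0.1, 0.5, 0.6, 1)),
               "uniform")
})

test_that("feature ranking is stable, by magnitude, with top-percent selection", {
  mk_prof <- function(id, gscore, sscore) {
    structure(list(feature_id = id, general_score = gscore,
                   selective_score = sscore), class = "activation_profile")
  }
  profs <- list(mk_prof("a", 3, 1), mk_prof("b", -5, 0), mk_prof("c", 1, -2))
  r <- rank_features(profs)
  expect_equal(r$feature_id, c("b", "a", "c"))
  # a zero-score feature never displaces the others
  r2 <- rank_features(c(profs, list(mk_prof("z", 0, 0))))
  expect_equal(r2$feature_id[1:3], c("b", "a", "c"))
  # top 2% of 100 features selects exactly 2
  many <- lapply(1:100, function(i) mk_prof(paste0("f", i), 101 - i, i))
  r3 <- rank_features(many, top_fraction = 0.02)
  expect_equal(sum(r3$top_general), 2L)
  expect_equal(r3$feature_id[r3$top_general], c("f1", "f2"))
})

test_that("full ERF profiles from a fitted model satisfy the calculus invariants", {
  fit <- planted_small_fit()
  slope_mean <- cbind(Gprotein = c(100, 35, 5), barr2 = c(80, 10, 45))
  profs <- compute_erf_profiles(subset_config(fit$sample$features, 1:600),
                                fit$model$frame_labels[1:600], slope_mean,
                                bins = 40L)
  expect_gt(length(profs), 0L)
  for (p in profs[1:5]) {
    expect_true(all(p$a_values * p$s_values == 0))
    expect_true(all(is.finite(p$r_G)) && all(is.finite(p$r_b)))
  }
  ranked <- rank_features(profs, top_fraction = 0.1)
  expect_equal(nrow(ranked), length(profs))
})
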