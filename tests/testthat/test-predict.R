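# P = 20 keeps the coarse pipeline non-degenerate: at the default 10%
# threshold each parcel row retains its self-correlation plus one real
# connection, whereas P = 10 would keep the self-correlation alone.
small_cohort <- function(n_subjects = 30, seed = 21, sessions = 1,
                         T = 150, rows = 10, cols = 10, P = 20) {
  cortex <- make_toy_cortex(rows, cols)
  parc <- toy_parcellation(cortex, P)
  w <- make_behavior_weights(parc, 3, "parcel_mean", seed = seed)
  w[, 2:3] <- 0
  gt <- synthetic_ground_truth(cortex, m = 3, noise_sd = 0.1,
                               subject_perturbation_sd = 0.3,
                               behavior_weights = w, seed = seed)
  list(cohort = simulate_cohort(gt, n_subjects, sessions, T = T,
                                seed = seed + 1),
       parcellation = parc)
}

test_that("parcel-averaged gradient features follow the arithmetic oracle", {
  coef <- cbind(c(1, 3, 5, 7), c(2, 2, 2, 2))
  gs <- gradient_set(coef, c(0.6, 0.4), provenance = list(aligned = TRUE))
  p <- parcellation_map(c(1, 1, 2, 2))

  feats <- parcel_average_gradients(gs, p, g = 1)
  expect_equal(unname(feats), c(2, 6))

  both <- parcel_average_gradients(gs, p, g = 2)
  expect_equal(unname(both), c(2, 2, 6, 2))  # parcel-major, gradient-minor
  expect_equal(names(both), c("p1_g1", "p1_g2", "p2_g1", "p2_g2"))

  # constant gradient: every parcel mean equals the constant
  expect_equal(unname(both[c(2, 4)]), c(2, 2))

  # identity parcellation: features are the coefficients verbatim
  idp <- identity_parcellation(4)
  expect_equal(unname(parcel_average_gradients(gs, idp, g = 2)),
               as.vector(t(coef)))
})

test_that("parcellated gradients equal the full pipeline under the identity map", {
  ts <- toy_timeseries(6, 6, T = 50)
  idp <- identity_parcellation(36)
  feats <- parcellated_gradients(ts, idp, g = 3)
  full <- full_gradients(ts, n_components = 3)
  expect_identical(attr(feats, "gradients")$coefficients,
                   full$coefficients)

  # determinism
  expect_identical(unname(parcellated_gradients(ts, idp, g = 3)),
                   unname(feats))
  expect_error(parcellated_gradients(ts, parcellation_map(rep(1:3, 12)),
                                     g = 3),
               class = "fcga_argument_error")  # needs P >= g + 1
})

test_that("the two constructions produce different features on coarse parcels", {
  cs <- small_cohort(n_subjects = 4)
  f_g2p <- build_feature_table(cs$cohort, cs$parcellation,
                               "gradients_to_parcellation", g = 3)
  f_p2g <- build_feature_table(cs$cohort, cs$parcellation,
                               "parcellation_to_gradients", g = 3)
  expect_equal(dim(f_g2p$features), dim(f_p2g$features))
  expect_false(isTRUE(all.equal(f_g2p$features, f_p2g$features)))
})

test_that("cross-validation folds partition the subjects", {
  for (seed in 1:5) {
    folds <- make_cv_folds(47, 10, seed = seed)
    expect_length(folds, 47)
    expect_setequal(unique(folds), 1:10)
    expect_true(all(table(folds) %in% c(4, 5)))
  }
  expect_identical(make_cv_folds(30, 10, seed = 3),
                   make_cv_folds(30, 10, seed = 3))
  expect_error(make_cv_folds(5, 10), class = "fcga_argument_error")
})

test_that("a noiseless linear target is predicted almost perfectly", {
  x <- withr::with_seed(31, matrix(rnorm(40 * 5), 40, 5))
  beta <- c(2, -1, 0.5, 1, -2)
  y <- as.vector(x %*% beta)
  rep <- ridge_cv_predict(x, y, n_folds = 10, n_repeats = 2,
                          lambda_grid = c(1, 1e-3, 1e-6), seed = 2)
  expect_true(all(rep$per_repeat$r > 0.99))
})

test_that("prediction reports are a pure function of the seed", {
  x <- withr::with_seed(32, matrix(rnorm(40 * 5), 40, 5))
  y <- withr::with_seed(33, rnorm(40))
  a <- ridge_cv_predict(x, y, n_repeats = 3, seed = 7)
  b <- ridge_cv_predict(x, y, n_repeats = 3, seed = 7)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_identical(a$predictions, b$predictions)
})

test_that("permuted targets yield correlations centered at zero", {
  x <- withr::with_seed(34, matrix(rnorm(300 * 10), 300, 10))
  beta <- withr::with_seed(35, rnorm(10))
  y <- as.vector(x %*% beta) + withr::with_seed(36, rnorm(300, sd = 0.5))
  # each permutation carries its own O(1/sqrt(n)) spurious association, so
  # the centering claim is about the distribution over permutations
  rs <- vapply(37:40, function(ps) {
    y_perm <- withr::with_seed(ps, sample(y))
    mean(ridge_cv_predict(x, y_perm, n_repeats = 2,
                          seed = 4)$per_repeat$r)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("inner model selection never touches outer test subjects", {
  x <- withr::with_seed(38, matrix(rnorm(40 * 5), 40, 5))
  y <- withr::with_seed(39, rnorm(40))
  rep <- ridge_cv_predict(x, y, n_repeats = 2, seed = 11,
                          record_folds = TRUE)
  for (r in rep$folds) {
    test_sets <- lapply(r, `[[`, "test")
    # outer folds partition all subjects
    expect_setequal(unlist(test_sets), 1:40)
    expect_equal(sum(lengths(test_sets)), 40)
    for (f in r) {
      inner_idx <- unlist(f$inner)
      expect_setequal(inner_idx, f$train)         # inner CV covers training
      expect_length(intersect(inner_idx, f$test), 0)  # and never the test
    }
  }
})

test_that("infinite regularization collapses to the training-mean predictor", {
  x <- withr::with_seed(40, matrix(rnorm(40 * 5), 40, 5))
  y <- withr::with_seed(41, rnorm(40, mean = 10))
  rep <- ridge_cv_predict(x, y, n_repeats = 2, lambda_grid = c(1e9, 2e9),
                          seed = 5)
  mean_mae <- mean(abs(y - mean(y)))
  expect_lt(abs(mean(rep$per_repeat$mae) - mean_mae), 0.1 * mean_mae)
})

test_that("ridge input validation catches degenerate setups", {
  x <- matrix(rnorm(40 * 5), 40, 5)
  expect_error(ridge_cv_predict(x, rep(1, 40)),
               class = "fcga_argument_error")
  expect_error(ridge_cv_predict(x, rnorm(40), lambda_grid = numeric(0)),
               class = "fcga_argument_error")
  expect_error(ridge_cv_predict(x[1:20, ], rnorm(20), n_folds = 10),
               class = "fcga_argument_error")
  expect_error(
    permutation_baseline(x, rnorm(40),
                         ridge_cv_predict(x, rnorm(40), n_repeats = 1),
                         n_perm = 0),
    class = "fcga_argument_error")
})

test_that("the shuffled-label baseline brackets strong and absent signal", {
  x <- withr::with_seed(42, matrix(rnorm(40 * 5), 40, 5))
  y_strong <- as.vector(x %*% c(3, -2, 1, 2, -1))
  obs <- ridge_cv_predict(x, y_strong, n_repeats = 2,
                          lambda_grid = c(1, 1e-3, 1e-6), seed = 3)
  perm <- permutation_baseline(x, y_strong, obs, n_perm = 19,
                               lambda_grid = c(1, 1e-3, 1e-6), seed = 3)
  expect_equal(perm$p_value_r, 1 / 20)   # every null beaten
  expect_equal(perm$p_value_mae, 1 / 20)

  y_null <- withr::with_seed(43, rnorm(40))
  obs0 <- ridge_cv_predict(x, y_null, n_repeats = 2, seed = 6)
  perm0 <- permutation_baseline(x, y_null, obs0, n_perm = 19, seed = 6)
  expect_gt(perm0$p_value_r, 0.05)
})

test_that("shared-seed repeats are bit-identical across comparison arms", {
  x <- withr::with_seed(44, matrix(rnorm(40 * 6), 40, 6))
  y <- withr::with_seed(45, rnorm(40))
  a <- ridge_cv_predict(x, y, n_repeats = 3, seed = 13)
  b <- ridge_cv_predict(x, y, n_repeats = 3, seed = 13)
  expect_identical(a$per_repeat$mae, b$per_repeat$mae)
})

test_that("construction comparison reports paired differences and Bonferroni", {
  cs <- small_cohort()
  cmp <- compare_constructions(cs$cohort, cs$parcellation, g = 3,
                               n_repeats = 4, seed = 17, n_comparisons = 1)
  expect_equal(nrow(cmp$paired), 4)
  expect_equal(cmp$paired$mae_diff,
               cmp$paired$mae_p2g - cmp$paired$mae_g2p)
  expect_equal(cmp$wins_g2p, sum(cmp$paired$mae_g2p < cmp$paired$mae_p2g))
  expect_equal(cmp$p_bonferroni, min(1, cmp$p_value * 1))

  cmp3 <- compare_constructions(cs$cohort, cs$parcellation, g = 3,
                                n_repeats = 4, seed = 17, n_comparisons = 3)
  expect_equal(cmp3$p_bonferroni, min(1, cmp3$p_value * 3))

  gl <- glance(cmp)
  expect_named(gl, c("wins_g2p", "n_repeats", "median_mae_g2p",
                     "median_mae_p2g", "p_value", "p_bonferroni"))
})
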