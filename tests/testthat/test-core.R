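test_that("pearson connectivity matches the covariance formula", {
  x <- rbind(c(1, 2, 3), c(1, 2, 4))
  y <- rbind(c(1, 2, 3), c(3, 2, 1), c(1, 3, 2))
  cm <- pearson_connectivity(x, y)
  expect_equal(cm$values[1, 1], 1)
  expect_equal(cm$values[1, 2], -1)

  # hand oracle: r = cov / (sd_x sd_y) computed from first principles
  a <- c(1, 2, 4); b <- c(1, 3, 2)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cm$values[2, 3], r_hand, tolerance = 1e-12)
  expect_equal(round(r_hand, 3), 0.327)
})

test_that("zero-variance rows raise by default and zero out on request", {
  x <- rbind(c(1, 1, 1), c(1, 2, 3))
  y <- rbind(c(1, 2, 3))
  expect_error(pearson_connectivity(x, y), class = "fcga_value_error")
  expect_warning(pearson_connectivity(x, y, zero_variance = "zero"))
  cm <- suppressWarnings(pearson_connectivity(x, y, zero_variance = "zero"))
  expect_equal(cm$values[1, 1], 0)
  expect_equal(cm$values[2, 1], 1)
})

test_that("row thresholding keeps the strongest positive connections only", {
  row <- c(0.5, 0.2, -0.3, 0.1, 0.9, 0.4, -0.1, 0.05, 0.3, 0.7)
  cm <- new_cm_for_test(rbind(row))
  out <- threshold_rows_top_positive(cm, 0.10)   # m = ceil(1) = 1
  expect_equal(out$values[1, ], c(0, 0, 0, 0, 0.9, 0, 0, 0, 0, 0))
  expect_true(out$thresholded)

  allneg <- new_cm_for_test(rbind(c(-0.2, -0.5, -0.1)))
  expect_warning(zeroed <- threshold_rows_top_positive(allneg))
  expect_equal(zeroed$values[1, ], c(0, 0, 0))

  few <- new_cm_for_test(rbind(c(0.2, 0.1)))
  out2 <- threshold_rows_top_positive(few, 0.9)  # m = 2, both positive kept
  expect_equal(out2$values[1, ], c(0.2, 0.1))

  expect_error(threshold_rows_top_positive(cm, 0), class = "fcga_argument_error")
})

test_that("thresholding is idempotent", {
  for (seed in 1:3) {
    vals <- withr::with_seed(seed, matrix(runif(80, -1, 1), 8, 10))
    cm <- new_cm_for_test(vals)
    once <- suppressWarnings(threshold_rows_top_positive(cm))
    twice <- suppressWarnings(threshold_rows_top_positive(once))
    expect_identical(twice$values, once$values)
  }
})

test_that("cosine affinity matches hand-computed similarities", {
  a <- new_cm_for_test(rbind(c(1, 0, 1), c(0, 2, 0), c(0, 1, 1)),
                       thresholded = TRUE)
  b <- new_cm_for_test(rbind(c(1, 0, 1), c(1, 1, 0), c(1, 0, 0)),
                       thresholded = TRUE)
  w <- cosine_affinity(a, b)
  expect_equal(w$values[1, 1], 1)          # identical rows
  expect_equal(w$values[1, 2], 0.5)        # dot 1 / (sqrt2 * sqrt2)
  expect_equal(w$values[2, 3], 0)          # orthogonal supports
})

test_that("cosine affinity requires thresholded inputs and handles zero rows", {
  raw <- new_cm_for_test(matrix(0.5, 2, 3))
  expect_error(cosine_affinity(raw, raw), class = "fcga_argument_error")

  a <- new_cm_for_test(rbind(c(1, 0, 1), c(0, 0, 0)), thresholded = TRUE)
  b <- new_cm_for_test(rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 1)),
                       thresholded = TRUE)
  expect_warning(cosine_affinity(a, b))
  w <- suppressWarnings(cosine_affinity(a, b))
  expect_equal(w$values[2, ], c(0, 0, 0))
  expect_error(cosine_affinity(a, b, zero_rows = "error"),
               class = "fcga_value_error")
})

test_that("self-affinity of the landmark block is symmetric with unit diagonal", {
  inputs <- toy_affinity_inputs()
  w <- suppressWarnings(cosine_affinity(inputs$kk, inputs$kk))
  expect_equal(w$values, t(w$values), tolerance = 1e-12)
  nonzero <- rowSums(inputs$kk$values != 0) > 0
  expect_equal(unname(diag(w$values)[nonzero]),
               rep(1, sum(nonzero)), tolerance = 1e-12)
})

test_that("PCA gradients match a dense eigendecomposition oracle", {
  w <- withr::with_seed(11, matrix(rnorm(24), 6, 4))
  gs <- pca_gradients(w, 3)

  # independent oracle: eigenvectors of the centered covariance matrix
  wc <- scale(w, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(wc) / (nrow(w) - 1), symmetric = TRUE)
  scores <- wc %*% eig$vectors[, 1:3]
  expect_equal(abs(unname(gs$coefficients)), abs(unname(scores)),
               tolerance = 1e-10)
  expect_equal(gs$explained_variance_ratio,
               (eig$values / sum(eig$values))[1:3], tolerance = 1e-10)

  # PCA contract: orthogonal scores, non-increasing variance
  cp <- crossprod(gs$coefficients)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-10 * max(diag(cp)))
  expect_true(all(diff(gs$explained_variance_ratio) <= 1e-12))
})

test_that("PCA sign convention and degenerate inputs behave as documented", {
  w <- cbind(rep(1, 6), c(3, 1, 4, 1, 5, 9), rep(2, 6))
  gs <- pca_gradients(w, 1)
  expect_equal(gs$explained_variance_ratio, 1)

  # sign rule: the largest-|loading| entry of each component is positive,
  # so the first score column must correlate positively with the varying col
  expect_gt(stats::cor(gs$coefficients[, 1], w[, 2]), 0)

  expect_error(pca_gradients(w, 3), class = "fcga_argument_error")
  err <- tryCatch(pca_gradients(w, 3), error = identity)
  expect_match(conditionMessage(err), "rank")
})

test_that("fcga with identity landmarks is bit-identical to the full pipeline", {
  for (n_side in c(6, 8)) {
    ts <- toy_timeseries(n_side, n_side, T = 50, seed = n_side)
    gf <- full_gradients(ts, n_components = 4)
    gid <- fcga(ts, landmarks_from_parcellation(
      identity_parcellation(n_side^2)), n_components = 4)
    expect_identical(gid$coefficients, gf$coefficients)
    expect_identical(gid$explained_variance_ratio,
                     gf$explained_variance_ratio)
  }
})

test_that("fcga is deterministic and records provenance", {
  ts <- toy_timeseries()
  lm <- select_random_vertices(64, 12, seed = 4)
  g1 <- fcga(ts, lm, n_components = 5)
  g2 <- fcga(ts, lm, n_components = 5)
  expect_identical(g1$coefficients, g2$coefficients)
  expect_equal(g1$provenance$method, "random_vertices")
  expect_equal(g1$provenance$k, 12)
  expect_equal(g1$provenance$fraction, 0.10)
  expect_equal(g1$provenance$seed, 4)
})

test_that("the full-pipeline memory guard refuses oversized problems", {
  ts <- toy_timeseries()
  expect_error(full_gradients(ts, n_components = 3, max_vertices = 50),
               class = "fcga_memory_guard")
  err <- tryCatch(full_gradients(ts, n_components = 3, max_vertices = 50),
                  error = identity)
  expect_match(conditionMessage(err), "fcga")
})

test_that("dense-FC landmark averaging matches the arithmetic oracle", {
  fc <- matrix(c(1.0, 0.2, 0.3, 0.4,
                 0.2, 1.0, 0.5, 0.6,
                 0.3, 0.5, 1.0, 0.7,
                 0.4, 0.6, 0.7, 1.0), 4, 4, byrow = TRUE)
  p <- parcellation_map(c(1, 1, 2, 2))
  out <- landmark_connectivity_from_dense_fc(fc, landmarks_from_parcellation(p))
  expect_equal(out$values,
               cbind((fc[, 1] + fc[, 2]) / 2, (fc[, 3] + fc[, 4]) / 2))

  idp <- landmarks_from_parcellation(identity_parcellation(4))
  expect_equal(landmark_connectivity_from_dense_fc(fc, idp)$values, fc,
               ignore_attr = TRUE)

  lmv <- select_random_vertices(4, 2, seed = 1)
  lmv$vertex_indices <- c(1L, 4L)
  expect_equal(landmark_connectivity_from_dense_fc(fc, lmv)$values,
               fc[, c(1, 4)])
})

test_that("the dense-FC gradient variant is deterministic and well-formed", {
  ts <- toy_timeseries(6, 6, T = 50)
  fc <- pearson_connectivity(ts$values, ts$values)
  p <- toy_parcellation(make_toy_cortex(6, 6), 4)
  lm <- landmarks_from_parcellation(p)
  g1 <- fcga_from_dense_fc(fc, lm, n_components = 3)
  g2 <- fcga_from_dense_fc(fc, lm, n_components = 3)
  expect_identical(g1$coefficients, g2$coefficients)
  expect_equal(dim(g1$coefficients), c(36, 3))
  expect_equal(g1$provenance$pipeline, "fcga_dense_fc")
  expect_error(
    fcga_from_dense_fc(pearson_connectivity(ts$values[1:5, ], ts$values),
                       lm, n_components = 2),
    class = "fcga_argument_error")
})

test_that("affinity storage cost is exactly n*k with ratio k/n", {
  cost <- approximation_cost(59412, 3000)
  expect_identical(cost$affinity_entries, 59412 * 3000)
  expect_identical(cost$full_entries, 59412^2)
  expect_identical(cost$ratio, 3000 / 59412)
})
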