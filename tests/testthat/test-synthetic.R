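test_that("the toy cortex is a planar grid with distinct coordinates", {
  cortex <- make_toy_cortex(10, 10)
  expect_equal(cortex$n, 100)
  expect_equal(dim(cortex$coords), c(100, 3))
  expect_equal(nrow(unique(as.data.frame(cortex$coords))), 100)
  expect_error(make_toy_cortex(1, 10), class = "fcga_argument_error")
})

test_that("block parcellations tile the grid exactly", {
  cortex <- make_toy_cortex(10, 10)
  p4 <- toy_parcellation(cortex, 4)
  expect_equal(p4$n_parcels, 4)
  expect_true(all(table(p4$labels) == 25))
  # the block containing vertex (1,1) is contiguous 5x5
  expect_equal(sum(p4$labels == p4$labels[1]), 25)

  expect_error(toy_parcellation(cortex, 3), class = "fcga_argument_error")
})

test_that("latent maps are orthonormal, seeded, and smoothness-ordered", {
  cortex <- make_toy_cortex(12, 12)
  maps <- sample_latent_maps(cortex, 4, smoothness = 2, seed = 5)
  expect_lt(max(abs(crossprod(maps) - diag(4))), 1e-8)
  expect_identical(maps, sample_latent_maps(cortex, 4, smoothness = 2,
                                            seed = 5))
  expect_error(sample_latent_maps(cortex, 144), class = "fcga_argument_error")

  # larger length scale -> higher lag-1 spatial autocorrelation along rows
  lag1 <- function(m) {
    f <- matrix(m[, 1], 12, 12, byrow = TRUE)
    stats::cor(as.vector(f[, -12]), as.vector(f[, -1]))
  }
  rough <- sample_latent_maps(cortex, 1, smoothness = 0.5, seed = 6)
  smooth <- sample_latent_maps(cortex, 1, smoothness = 3, seed = 6)
  expect_gt(lag1(smooth), lag1(rough))
})

test_that("row-norm equalisation keeps orthonormal columns and flat row norms", {
  cortex <- make_toy_cortex(15, 15)
  maps <- sample_latent_maps(cortex, 5, smoothness = 0.5, seed = 7,
                             equal_row_norms = TRUE)
  expect_lt(max(abs(crossprod(maps) - diag(5))), 1e-8)
  rn <- sqrt(rowSums(maps^2))
  expect_lt(stats::sd(rn) / mean(rn), 1e-6)
})

test_that("a rank-1 noiseless model correlates every vertex pair at +/-1", {
  cortex <- make_toy_cortex(5, 5)
  gt <- synthetic_ground_truth(cortex, m = 1, component_scales = 1,
                               noise_sd = 0, seed = 3)
  ts <- simulate_timeseries(gt, T = 30, seed = 4)
  cc <- stats::cor(t(ts$values))
  expect_equal(abs(cc), matrix(1, 25, 25), tolerance = 1e-8)
})

test_that("time-series simulation is deterministic and validates T", {
  cortex <- make_toy_cortex(6, 6)
  gt <- synthetic_ground_truth(cortex, m = 3, seed = 8)
  a <- simulate_timeseries(gt, T = 40, seed = 9)
  b <- simulate_timeseries(gt, T = 40, seed = 9)
  expect_identical(a$values, b$values)
  expect_error(simulate_timeseries(gt, T = 5, seed = 9),
               class = "fcga_argument_error")
})

test_that("ground-truth validation rejects degenerate parameters", {
  cortex <- make_toy_cortex(6, 6)
  expect_error(synthetic_ground_truth(cortex, m = 2,
                                      component_scales = c(1, 2)),
               class = "fcga_validation_error")
  expect_error(synthetic_ground_truth(cortex, m = 2,
                                      component_scales = c(2, -1)),
               class = "fcga_validation_error")
  expect_error(synthetic_ground_truth(cortex, m = 2, noise_sd = -1),
               class = "fcga_validation_error")
  expect_error(synthetic_ground_truth(cortex, m = 2,
                                      latent_maps = matrix(1, 36, 2)),
               class = "fcga_validation_error")
})

test_that("cohorts share subject maps across sessions and are deterministic", {
  cortex <- make_toy_cortex(8, 8)
  gt <- synthetic_ground_truth(cortex, m = 3,
                               subject_perturbation_sd = 0.2, seed = 10)
  a <- simulate_cohort(gt, 4, 2, T = 40, seed = 11)
  b <- simulate_cohort(gt, 4, 2, T = 40, seed = 11)
  expect_identical(a$sessions[[3]]$values, b$sessions[[3]]$values)
  expect_identical(a$subject_maps, b$subject_maps)
  expect_equal(nrow(a$manifest), 8)

  # zero perturbation: all subjects carry the group maps
  gt0 <- synthetic_ground_truth(cortex, m = 3,
                                subject_perturbation_sd = 0, seed = 10)
  c0 <- simulate_cohort(gt0, 3, 1, T = 40, seed = 12)
  expect_identical(c0$subject_maps[[1]], c0$subject_maps[[3]])

  # no behavior weights -> NA target
  expect_true(all(is.na(c0$behavior$behavior)))
})

test_that("subject perturbation is a controlled rotation away from group maps", {
  cortex <- make_toy_cortex(10, 10)
  gt <- synthetic_ground_truth(cortex, m = 4,
                               subject_perturbation_sd = 0.2, seed = 13)
  cohort <- simulate_cohort(gt, 5, 1, T = 40, seed = 14)
  for (L in cohort$subject_maps) {
    cors <- diag(stats::cor(L, gt$latent_maps))
    expect_true(all(cors > 0.9))   # ~11 degrees, orientation preserved
    expect_true(all(cors < 1))
  }
})

test_that("behavior weight maps respect their parcel structure", {
  p <- toy_parcellation(make_toy_cortex(10, 10), 4)
  wc <- make_behavior_weights(p, 3, "within_parcel_contrast", seed = 15)
  sums <- rowsum(wc, p$labels)
  expect_lt(max(abs(sums)), 1e-10)        # contrasts sum to zero per parcel
  expect_equal(sum(wc^2), 1)

  wm <- make_behavior_weights(p, 3, "parcel_mean", seed = 16)
  for (q in 1:4) {
    block <- wm[p$labels == q, ]
    expect_equal(max(apply(block, 2, stats::sd)), 0)  # constant in parcel
  }
})

test_that("planted subspace recovery degrades with sensor noise", {
  cortex <- make_toy_cortex(10, 10)
  recovery_at <- function(noise) {
    maps <- sample_latent_maps(cortex, 3, smoothness = 0.5, seed = 17,
                               equal_row_norms = TRUE)
    gt <- synthetic_ground_truth(
      cortex, latent_maps = maps,
      component_scales = seq(1.05, 1, length.out = 3),
      noise_sd = noise, seed = 17)
    ts <- simulate_timeseries(gt, T = 300, seed = 18)
    gs <- full_gradients(ts, n_components = 6)
    mean(planted_map_recovery(gs, maps)$rho)
  }
  clean <- recovery_at(0)
  expect_gte(clean, recovery_at(0.1))
  expect_gt(clean, recovery_at(2) + 0.3)  # heavy noise destroys the maps
})

test_that("planted-map recovery scores the gradient span, not single axes", {
  cortex <- make_toy_cortex(10, 10)
  gt <- synthetic_ground_truth(cortex, m = 3, noise_sd = 0, seed = 19)
  ts <- simulate_timeseries(gt, T = 100, seed = 20)
  gs <- full_gradients(ts, n_components = 6)
  rec <- planted_map_recovery(gs, gt$latent_maps)
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$rho >= 0 & rec$rho <= 1))

  # a map already inside the span is recovered perfectly
  inside <- gs$coefficients[, 1:2]
  rec2 <- planted_map_recovery(gs, inside, method = "pearson")
  expect_equal(rec2$rho, c(1, 1), tolerance = 1e-10)
})

test_that("moderate perturbation with low noise gives high discriminability", {
  cortex <- make_toy_cortex(10, 10)
  gt <- synthetic_ground_truth(cortex, m = 3, noise_sd = 0.05,
                               subject_perturbation_sd = 0.25, seed = 21)
  cohort <- simulate_cohort(gt, 6, 2, T = 150, seed = 22)
  ref <- NULL
  grads <- lapply(cohort$sessions, function(ts) {
    g <- fcga(ts, select_uniform_vertices(cortex$coords, 20, seed = 23),
              n_components = 3)
    if (is.null(ref)) ref <<- g else g <- procrustes_align(g, ref)$aligned
    g
  })
  panel <- reliability_panel(grads, cohort$manifest$subject,
                             cohort$manifest$session)
  expect_gt(discriminability(panel), 0.95)
})
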