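# Shared fixtures: small seeded synthetic datasets built in code.

toy_timeseries <- function(rows = 8, cols = 8, m = 3, T = 60,
                           noise_sd = 0.1, seed = 42) {
  cortex <- make_toy_cortex(rows, cols)
  gt <- synthetic_ground_truth(cortex, m = m, noise_sd = noise_sd,
                               seed = seed)
  simulate_timeseries(gt, T = T, seed = seed + 1)
}

identity_parcellation <- function(n) parcellation_map(seq_len(n))

new_cm_for_test <- function(values, thresholded = FALSE) {
  fcga:::new_connectivity(values, "vertex", "landmark",
                          thresholded = thresholded,
                          fraction = if (thresholded) 0.10 else NULL)
}

# random thresholded connectivity pair for affinity-stage tests
toy_affinity_inputs <- function(n = 12, k = 5, seed = 7) {
  withr::with_seed(seed, {
    nk <- pearson_connectivity(matrix(rnorm(n * 30), n, 30),
                               matrix(rnorm(k * 30), k, 30))
    kk <- pearson_connectivity(matrix(rnorm(k * 30), k, 30),
                               matrix(rnorm(k * 30), k, 30))
  })
  list(nk = suppressWarnings(threshold_rows_top_positive(nk)),
       kk = suppressWarnings(threshold_rows_top_positive(kk)))
}
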