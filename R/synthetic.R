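# Synthetic cohorts with known ground truth: a planar toy cortex, smooth
# orthonormal latent maps (the planted "gradients"), low-rank time series,
# subject/session repeat structure, and behavioral targets driven by
# vertex-level gradient features. Everything is a pure function of
# (parameters, seed).

#' Build a toy cortex: a regular planar grid embedded in 3-space
#'
#' A stand-in for a cortical surface mesh that keeps smoothness and
#' parcellation structure without any geometry dependencies. Vertices are
#' indexed row-major: vertex `(r, c)` is index `(r - 1) * cols + c`.
#'
#' @param rows,cols Grid dimensions, both >= 2.
#' @return An `fcga_cortex` with `grid_dims`, `coords` (`n x 3`), `n`.
#' @export
make_toy_cortex <- function(rows, cols) {
  if (rows < 2 || cols < 2) {
    abort_fcga("toy cortex needs rows >= 2 and cols >= 2",
               "fcga_argument_error")
  }
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  coords <- cbind(x = grid$col, y = grid$row, z = 0)
  structure(
    list(grid_dims = c(rows = rows, cols = cols), coords = coords,
         n = rows * cols),
    class = "fcga_cortex")
}

#' @exportS3Method base::print
print.fcga_cortex <- function(x, ...) {
  cat(sprintf("<fcga_cortex> %d x %d grid (%d vertices)\n",
              x$grid_dims[1], x$grid_dims[2], x$n))
  invisible(x)
}

#' Block parcellation of a toy cortex
#'
#' Tiles the grid into `P` rectangular parcels of equal size. `P` must
#' factor as `pr * pc` with `pr` dividing the rows and `pc` the columns;
#' among admissible factorizations the one with the most square blocks is
#' chosen.
#'
#' @param cortex An `fcga_cortex`.
#' @param P Number of parcels.
#' @return An [parcellation_map()].
#' @export
toy_parcellation <- function(cortex, P) {
  stopifnot(inherits(cortex, "fcga_cortex"))
  rows <- cortex$grid_dims[["rows"]]
  cols <- cortex$grid_dims[["cols"]]
  divs_r <- which(rows %% seq_len(rows) == 0)
  cand <- lapply(divs_r[P %% divs_r == 0], function(pr) {
    pc <- P / pr
    if (pc <= cols && cols %% pc == 0) c(pr = pr, pc = pc) else NULL
  })
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0) {
    abort_fcga(sprintf("P = %d does not tile the %d x %d grid", P, rows, cols),
               "fcga_argument_error")
  }
  aspect <- vapply(cand, function(d) {
    abs(log((rows / d["pr"]) / (cols / d["pc"])))
  }, numeric(1))
  d <- cand[[which.min(aspect)]]
  block_r <- rows / d[["pr"]]
  block_c <- cols / d[["pc"]]
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  labels <- (ceiling(grid$row / block_r) - 1) * d[["pc"]] +
    ceiling(grid$col / block_c)
  parcellation_map(labels, space_tag = "toy-grid")
}

# Seeded smooth random fields on the grid: white noise low-pass filtered
# with a separable Gaussian kernel. Returns n x m (row-major vertex order).
smooth_fields <- function(cortex, m, smoothness, seed) {
  rows <- cortex$grid_dims[["rows"]]
  cols <- cortex$grid_dims[["cols"]]
  kernel <- function(size) {
    d <- outer(seq_len(size), seq_len(size), "-")
    k <- exp(-d^2 / (2 * smoothness^2))
    k / rowSums(k)
  }
  kr <- kernel(rows)
  kc <- kernel(cols)
  noise <- with_seed(seed, array(stats::rnorm(rows * cols * m),
                                 dim = c(rows, cols, m)))
  vapply(seq_len(m), function(j) {
    f <- kr %*% noise[, , j] %*% t(kc)
    as.vector(t(f))  # row-major, matches vertex indexing
  }, numeric(rows * cols))
}

# Symmetric (polar) orthonormalization: the orthonormal matrix closest to
# `m` in Frobenius norm, so each column stays as close as possible to its
# input — unlike Gram-Schmidt, which mixes later columns into earlier ones,
# and without any sign flip relative to the input.
polar_orthonormalize <- function(m) {
  s <- svd(m)
  s$u %*% t(s$v)
}

orthonormalize <- function(m) {
  q <- polar_orthonormalize(m)
  fix_signs(q, q)$scores
}

#' Sample smooth orthonormal latent maps on a toy cortex
#'
#' Spatially low-pass-filtered seeded noise on the grid, orthonormalized
#' across components; these play the role of the planted connectivity
#' gradients the pipelines are expected to recover.
#'
#' @param cortex An `fcga_cortex`.
#' @param m Number of components, `m < n`.
#' @param smoothness Gaussian smoothing length scale in grid units.
#' @param seed Integer seed.
#' @param equal_row_norms Additionally equalise the per-vertex norms of the
#'   latent coordinate vectors (alternating row normalisation and polar
#'   re-orthonormalisation). With equal row norms every vertex carries a
#'   full-strength connectivity profile, mirroring real functional data
#'   where signal amplitude is roughly homogeneous across cortex; this is
#'   the regime in which the cosine-affinity pipeline can represent all
#'   planted components.
#' @return Numeric `n x m` matrix with orthonormal columns.
#' @export
sample_latent_maps <- function(cortex, m, smoothness = 2, seed = 1,
                               equal_row_norms = FALSE) {
  stopifnot(inherits(cortex, "fcga_cortex"))
  if (m >= cortex$n) {
    abort_fcga("need m < n_vertices latent maps", "fcga_argument_error")
  }
  maps <- orthonormalize(smooth_fields(cortex, m, smoothness, seed))
  if (equal_row_norms) {
    for (i in seq_len(50)) {
      maps <- maps / sqrt(rowSums(maps^2))
      maps <- polar_orthonormalize(maps)
    }
    maps <- fix_signs(maps, maps)$scores
  }
  maps
}

#' Define the ground truth of a synthetic study
#'
#' Bundles the planted latent maps with the generative parameters used by
#' [simulate_timeseries()] and [simulate_cohort()].
#'
#' @param cortex An `fcga_cortex`.
#' @param m Number of latent components.
#' @param latent_maps Optional `n x m` orthonormal matrix; sampled with
#'   [sample_latent_maps()] when omitted.
#' @param component_scales Strictly decreasing positive scales, one per
#'   component (default linearly from 3 to 1): the signal strength of each
#'   planted gradient.
#' @param noise_sd Sensor noise standard deviation (signal units).
#' @param subject_perturbation_sd Standard deviation of the smooth additive
#'   perturbation giving each subject individualized latent maps.
#' @param behavior_weights Optional `n x m` matrix of weights generating
#'   the behavioral target from a subject's latent maps; see
#'   [make_behavior_weights()].
#' @param behavior_noise_sd Noise added to the behavioral target.
#' @param smoothness Length scale for maps and perturbations.
#' @param seed Integer seed used when sampling `latent_maps`.
#' @return An `fcga_ground_truth`.
#' @export
synthetic_ground_truth <- function(cortex, m = 5, latent_maps = NULL,
                                   component_scales = NULL,
                                   noise_sd = 0.1,
                                   subject_perturbation_sd = 0.05,
                                   behavior_weights = NULL,
                                   behavior_noise_sd = 0.1,
                                   smoothness = 2, seed = 1) {
  stopifnot(inherits(cortex, "fcga_cortex"))
  latent_maps <- latent_maps %||%
    sample_latent_maps(cortex, m, smoothness, seed)
  latent_maps <- as.matrix(latent_maps)
  m <- ncol(latent_maps)
  gram <- crossprod(latent_maps)
  if (max(abs(gram - diag(m))) > 1e-8) {
    abort_fcga("latent_maps columns must be orthonormal (within 1e-8)",
               "fcga_validation_error")
  }
  component_scales <- component_scales %||% seq(3, 1, length.out = m)
  if (length(component_scales) != m || any(component_scales <= 0) ||
      (m > 1 && any(diff(component_scales) >= 0))) {
    abort_fcga("component_scales must be strictly decreasing and positive",
               "fcga_validation_error")
  }
  if (noise_sd < 0 || subject_perturbation_sd < 0 || behavior_noise_sd < 0) {
    abort_fcga("standard deviations must be non-negative",
               "fcga_validation_error")
  }
  if (!is.null(behavior_weights)) {
    behavior_weights <- as.matrix(behavior_weights)
    if (!all(dim(behavior_weights) == dim(latent_maps))) {
      abort_fcga("behavior_weights must match latent_maps dimensions",
                 "fcga_validation_error")
    }
  }
  structure(
    list(cortex = cortex, latent_maps = latent_maps,
         component_scales = component_scales, noise_sd = noise_sd,
         subject_perturbation_sd = subject_perturbation_sd,
         behavior_weights = behavior_weights,
         behavior_noise_sd = behavior_noise_sd,
         smoothness = smoothness, seed = seed),
    class = "fcga_ground_truth")
}

#' @exportS3Method base::print
print.fcga_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<fcga_ground_truth> %d vertices, m=%d, noise_sd=%g, subject_sd=%g\n",
    nrow(x$latent_maps), ncol(x$latent_maps), x$noise_sd,
    x$subject_perturbation_sd))
  invisible(x)
}

#' Simulate one functional time-series acquisition
#'
#' `X = L diag(scales) S + E` with `L` the latent maps, `S` an `m x T`
#' matrix of independent unit-variance time courses, and `E` i.i.d. sensor
#' noise at `noise_sd`. Vertex-by-vertex connectivity of `X` is then
#' approximately rank-`m` plus noise, so the planted maps are the gradients
#' the pipelines should recover.
#'
#' @param gt An `fcga_ground_truth` (its `latent_maps` may be subject-
#'   specific, see [simulate_cohort()]).
#' @param T Number of timepoints, `T >= 2 m`.
#' @param seed Integer seed.
#' @return An [time_series_matrix()].
#' @export
simulate_timeseries <- function(gt, T, seed) {
  stopifnot(inherits(gt, "fcga_ground_truth"))
  m <- ncol(gt$latent_maps)
  n <- nrow(gt$latent_maps)
  if (T < 2 * m) {
    abort_fcga(sprintf("need T >= 2m timepoints (T=%d, m=%d)", T, m),
               "fcga_argument_error")
  }
  draws <- with_seed(seed, list(
    s = matrix(stats::rnorm(m * T), m, T),
    e = matrix(stats::rnorm(n * T, sd = gt$noise_sd), n, T)))
  x <- gt$latent_maps %*% (gt$component_scales * draws$s)
  if (gt$noise_sd > 0) x <- x + draws$e
  time_series_matrix(x, space_tag = "toy-grid",
                     allow_constant = gt$noise_sd == 0)
}

#' Behavioral weight maps over (vertex, component) gradient features
#'
#' `within_parcel_contrast` weights are random but sum to zero inside every
#' parcel: the behavioral signal then lives entirely in within-parcel
#' spatial structure of the latent maps, which parcel-averaged *time
#' series* destroy but parcel-averaged *fine-grained gradients* partially
#' retain. `parcel_mean` weights are constant within each parcel, so
#' parcel-level features carry the full signal.
#'
#' @param p An [parcellation_map()].
#' @param m Number of latent components the weights apply to.
#' @param mode `"within_parcel_contrast"` (default) or `"parcel_mean"`.
#' @param seed Integer seed.
#' @param scale Frobenius norm of the returned weight matrix.
#' @return Numeric `n x m` weight matrix (0 on unassigned vertices).
#' @export
make_behavior_weights <- function(p, m,
                                  mode = c("within_parcel_contrast",
                                           "parcel_mean"),
                                  seed = 1, scale = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "fcga_parcellation"))
  n <- length(p$labels)
  w <- with_seed(seed, {
    out <- matrix(0, n, m)
    for (q in seq_len(p$n_parcels)) {
      members <- which(p$labels == q)
      for (j in seq_len(m)) {
        if (mode == "within_parcel_contrast") {
          v <- stats::rnorm(length(members))
          out[members, j] <- v - mean(v)
        } else {
          out[members, j] <- stats::rnorm(1)
        }
      }
    }
    out
  })
  w * (scale / sqrt(sum(w^2)))
}

#' How well does a gradient set recover a known set of planted maps?
#'
#' Projects each planted map onto the span of the gradient coefficients
#' (least squares) and correlates the map with its projection. Working in
#' the span resolves the rotational indeterminacy of PCA: components with
#' near-equal explained variance are only identified up to an orthogonal
#' transform, just as individually computed gradient sets must be aligned
#' before their components can be compared one-to-one.
#'
#' @param gs An `fcga_gradients`; its full component span is used, so a
#'   deeper set (e.g. the conventional 25 gradients) gives a fairer
#'   recovery measure than exactly `m` components.
#' @param maps Numeric `n x m` matrix of planted maps.
#' @param method Correlation type (default `"spearman"`).
#' @return A tibble with columns `map` and `rho` (absolute correlation
#'   between each map and its representation in gradient space).
#' @export
planted_map_recovery <- function(gs, maps, method = "spearman") {
  stopifnot(inherits(gs, "fcga_gradients"))
  maps <- as.matrix(maps)
  if (nrow(maps) != nrow(gs$coefficients)) {
    abort_fcga("maps and gradient set disagree on n_vertices",
               "fcga_argument_error")
  }
  g <- gs$coefficients
  fitted <- g %*% solve(crossprod(g), crossprod(g, maps))
  rho <- vapply(seq_len(ncol(maps)), function(j) {
    abs(stats::cor(maps[, j], fitted[, j], method = method))
  }, numeric(1))
  tibble::tibble(map = seq_len(ncol(maps)), rho = rho)
}

#' Simulate a cohort with subject/session repeat structure and behavior
#'
#' Each subject receives individualized latent maps — the group maps plus a
#' smooth additive perturbation at `subject_perturbation_sd`,
#' re-orthonormalized — shared across that subject's sessions; sessions
#' differ only in their time courses and sensor noise. The behavioral
#' target is `sum(behavior_weights * subject_maps)` plus seeded noise,
#' i.e. a linear readout of vertex-level gradient features.
#'
#' @param gt An `fcga_ground_truth`.
#' @param n_subjects Number of subjects (>= 2).
#' @param n_sessions Sessions per subject.
#' @param T Timepoints per session.
#' @param seed Integer seed.
#' @return An `fcga_cohort`: `sessions` (list of time-series matrices),
#'   `manifest` (tibble: measurement, subject, session), `behavior`
#'   (tibble: subject, behavior), `subject_maps`, `ground_truth`.
#' @export
simulate_cohort <- function(gt, n_subjects, n_sessions = 2, T, seed) {
  stopifnot(inherits(gt, "fcga_ground_truth"))
  if (n_subjects < 2) {
    abort_fcga("a cohort needs at least 2 subjects", "fcga_argument_error")
  }
  seeds <- derive_seeds(seed, 3)
  subj_seeds <- derive_seeds(seeds[1], n_subjects)
  sess_seeds <- matrix(derive_seeds(seeds[2], n_subjects * n_sessions),
                       n_subjects, n_sessions)
  m <- ncol(gt$latent_maps)
  subject_ids <- sprintf("S%03d", seq_len(n_subjects))
  subject_maps <- lapply(seq_len(n_subjects), function(s) {
    if (gt$subject_perturbation_sd == 0) {
      gt$latent_maps
    } else {
      pert <- smooth_fields(gt$cortex, m, gt$smoothness, subj_seeds[s])
      # unit-norm per component, so the sd is the relative deviation of a
      # subject's map from the group map (0.2 ~ an 11 degree rotation)
      pert <- sweep(pert, 2, sqrt(colSums(pert^2)), "/")
      # orientation follows the group maps: no per-subject sign convention
      polar_orthonormalize(gt$latent_maps + gt$subject_perturbation_sd * pert)
    }
  })
  sessions <- list()
  manifest <- list()
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    gt_s <- gt
    gt_s$latent_maps <- subject_maps[[s]]
    for (ses in seq_len(n_sessions)) {
      idx <- idx + 1L
      sessions[[idx]] <- simulate_timeseries(gt_s, T, sess_seeds[s, ses])
      manifest[[idx]] <- tibble::tibble(
        measurement = idx, subject = subject_ids[s], session = ses)
    }
  }
  behavior <- if (is.null(gt$behavior_weights)) {
    rep(NA_real_, n_subjects)
  } else {
    signal <- vapply(subject_maps,
                     function(L) sum(gt$behavior_weights * L), numeric(1))
    signal + gt$behavior_noise_sd *
      with_seed(seeds[3], stats::rnorm(n_subjects))
  }
  structure(
    list(sessions = sessions,
         manifest = dplyr::bind_rows(manifest),
         behavior = tibble::tibble(subject = subject_ids,
                                   behavior = behavior),
         subject_maps = subject_maps,
         ground_truth = gt),
    class = "fcga_cohort")
}

#' @exportS3Method base::print
print.fcga_cohort <- function(x, ...) {
  cat(sprintf("<fcga_cohort> %d subjects x %d sessions, %d vertices\n",
              nrow(x$behavior),
              max(x$manifest$session),
              nrow(x$sessions[[1]]$values)))
  invisible(x)
}
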