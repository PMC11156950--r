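# Brain-behavior prediction benchmark: parcel-level feature tables built by
# the two orderings (fine-grained gradients then parcel-averaging, versus
# gradients computed on parcel-averaged time series), ridge regression with
# nested cross-validation, a shuffled-label baseline, and the paired
# comparison of the two constructions.

#' Parcel-average the coefficients of a gradient set
#'
#' Unweighted mean of each gradient's coefficients within each parcel.
#' Features are ordered parcel-major, gradient-minor and named
#' `p<parcel>_g<gradient>`.
#'
#' @param gs An `fcga_gradients`.
#' @param p An [parcellation_map()] over the same vertices.
#' @param g Number of gradients to use (default 5, keeping the feature
#'   space small).
#' @return Named numeric vector of length `P * g`.
#' @export
parcel_average_gradients <- function(gs, p, g = 5) {
  stopifnot(inherits(gs, "fcga_gradients"), inherits(p, "fcga_parcellation"))
  if (length(p$labels) != nrow(gs$coefficients)) {
    abort_fcga("parcellation and gradient set disagree on n_vertices",
               "fcga_argument_error")
  }
  if (g > ncol(gs$coefficients)) {
    abort_fcga(sprintf("asked for g=%d gradients but the set has %d",
                       g, ncol(gs$coefficients)),
               "fcga_argument_error")
  }
  keep <- p$labels > 0
  coef <- gs$coefficients[keep, seq_len(g), drop = FALSE]
  sums <- rowsum(coef, p$labels[keep])
  counts <- as.vector(table(p$labels[keep]))
  means <- sums / counts  # P x g
  out <- as.vector(t(means))
  names(out) <- paste0("p", rep(seq_len(p$n_parcels), each = g),
                       "_g", rep(seq_len(g), times = p$n_parcels))
  out
}

#' Gradients computed on parcel-averaged time series
#'
#' The coarse-grained construction: average the time series within each
#' parcel, then run the standard connectivity-gradient pipeline on the
#' `P x T` parcel matrix using all parcels as landmarks. Returns the
#' flattened `P * g` feature vector in the same order as
#' [parcel_average_gradients()]; the underlying `P x g` gradient set is
#' attached as attribute `"gradients"`.
#'
#' @param ts An `fcga_timeseries`.
#' @param p An [parcellation_map()] with `P >= g + 1` parcels.
#' @param g Number of gradients (default 5).
#' @param fraction Row-thresholding fraction.
#' @return Named numeric vector of length `P * g`.
#' @export
parcellated_gradients <- function(ts, p, g = 5, fraction = 0.10) {
  stopifnot(inherits(ts, "fcga_timeseries"), inherits(p, "fcga_parcellation"))
  if (p$n_parcels < g + 1) {
    abort_fcga(sprintf("need P >= g + 1 parcels (P=%d, g=%d)",
                       p$n_parcels, g),
               "fcga_argument_error")
  }
  parcel_ts <- extract_landmark_timeseries(ts, landmarks_from_parcellation(p))
  ts_p <- time_series_matrix(parcel_ts, space_tag = ts$space_tag)
  gs <- full_gradients(ts_p, n_components = g, fraction = fraction,
                       zero_variance = "zero")
  gs$provenance$pipeline <- "parcellation_to_gradients"
  out <- as.vector(t(gs$coefficients))
  names(out) <- paste0("p", rep(seq_len(p$n_parcels), each = g),
                       "_g", rep(seq_len(g), times = p$n_parcels))
  attr(out, "gradients") <- gs
  out
}

#' Build a subjects-by-features table from a cohort
#'
#' One row per subject (that subject's chosen session), columns the
#' `P * g` parcel-level gradient features under one of the two
#' constructions:
#' \describe{
#'   \item{gradients_to_parcellation}{fine-grained vertex-level gradients
#'     via [fcga()] (parcel landmarks by default), Procrustes-aligned to
#'     the first subject, then parcel-averaged.}
#'   \item{parcellation_to_gradients}{gradients computed directly on
#'     parcel-averaged time series via [parcellated_gradients()], aligned
#'     likewise.}
#' }
#'
#' @param cohort An `fcga_cohort` (or list of `fcga_timeseries`).
#' @param p An [parcellation_map()].
#' @param construction Which ordering to use.
#' @param g Gradients per parcel (default 5).
#' @param fraction Row-thresholding fraction.
#' @param landmarks Landmark set for the fine-grained construction;
#'   defaults to the parcels of `p`.
#' @param session Which session(s) to use per subject (default 1). With
#'   several sessions the per-session feature vectors are averaged after
#'   alignment, mirroring the common practice of pooling repeated runs.
#' @param reference Optional `fcga_gradients` to Procrustes-align every
#'   subject to. By default a group reference is built by averaging the
#'   subjects' connectivity matrices (the usual role of a group-average
#'   connectome) and running the gradient pipeline on the average; this
#'   keeps the alignment target free of any single subject's noise.
#' @return An `fcga_features`: feature matrix plus construction metadata.
#' @export
build_feature_table <- function(cohort, p,
                                construction = c("gradients_to_parcellation",
                                                 "parcellation_to_gradients"),
                                g = 5, fraction = 0.10, landmarks = NULL,
                                session = 1, reference = NULL) {
  construction <- match.arg(construction)
  stopifnot(inherits(p, "fcga_parcellation"))
  if (length(session) > 1) {
    first <- build_feature_table(cohort, p, construction, g, fraction,
                                 landmarks, session[1], reference)
    rest <- lapply(session[-1], function(s) {
      build_feature_table(cohort, p, construction, g, fraction,
                          landmarks, s, first$reference)$features
    })
    first$features <- Reduce(`+`, c(list(first$features), rest)) /
      length(session)
    return(first)
  }
  ts_list <- cohort_session_list(cohort, session)
  # per-subject vertex-by-landmark and landmark-by-landmark connectivity:
  # fine-grained arm correlates all vertices against the landmarks,
  # coarse-grained arm works entirely at the parcel level
  if (construction == "gradients_to_parcellation") {
    landmarks <- landmarks %||% landmarks_from_parcellation(p)
    cms <- lapply(ts_list, function(ts) {
      lm_ts <- extract_landmark_timeseries(ts, landmarks)
      list(nk = pearson_connectivity(ts$values, lm_ts,
                                     zero_variance = "zero"),
           kk = pearson_connectivity(lm_ts, lm_ts, zero_variance = "zero",
                                     row_role = "landmark"))
    })
  } else {
    if (p$n_parcels < g + 1) {
      abort_fcga(sprintf("need P >= g + 1 parcels (P=%d, g=%d)",
                         p$n_parcels, g),
                 "fcga_argument_error")
    }
    parc_lm <- landmarks_from_parcellation(p)
    cms <- lapply(ts_list, function(ts) {
      pts <- extract_landmark_timeseries(ts, parc_lm)
      cm <- pearson_connectivity(pts, pts, zero_variance = "zero",
                                 row_role = "landmark")
      list(nk = cm, kk = cm)
    })
  }
  gradients_of <- function(nk, kk) {
    w <- suppressWarnings(
      cosine_affinity(threshold_rows_top_positive(nk, fraction),
                      threshold_rows_top_positive(kk, fraction)))
    pca_gradients(w, g)
  }
  if (is.null(reference)) {
    mean_mat <- function(part) {
      Reduce(`+`, lapply(cms, function(x) x[[part]]$values)) / length(cms)
    }
    ref_nk <- new_connectivity(mean_mat("nk"), cms[[1]]$nk$row_role,
                               "landmark")
    ref_kk <- new_connectivity(mean_mat("kk"), "landmark", "landmark")
    reference <- gradients_of(ref_nk, ref_kk)
  }
  rows <- lapply(cms, function(x) {
    gs <- gradients_of(x$nk, x$kk)
    gs <- procrustes_align(gs, reference)$aligned
    if (construction == "gradients_to_parcellation") {
      parcel_average_gradients(gs, p, g)
    } else {
      as.vector(t(gs$coefficients))
    }
  })
  features <- do.call(rbind, lapply(rows, unname))
  colnames(features) <- paste0("p", rep(seq_len(p$n_parcels), each = g),
                               "_g", rep(seq_len(g), times = p$n_parcels))
  structure(
    list(features = features, construction = construction, g = g,
         parcellation = p, reference = reference),
    class = "fcga_features")
}

cohort_session_list <- function(cohort, session = 1) {
  if (inherits(cohort, "fcga_cohort")) {
    man <- cohort$manifest[cohort$manifest$session == session, ]
    man <- man[order(man$subject), ]
    if (nrow(man) == 0) {
      abort_fcga("no measurements for the requested session",
                 "fcga_argument_error")
    }
    cohort$sessions[man$measurement]
  } else {
    cohort
  }
}

#' @exportS3Method base::print
print.fcga_features <- function(x, ...) {
  cat(sprintf("<fcga_features> %d subjects x %d features (%s, g=%d)\n",
              nrow(x$features), ncol(x$features), x$construction, x$g))
  invisible(x)
}

#' Balanced cross-validation fold assignment
#'
#' Random permutation of near-equal fold labels. With `seed = NULL` the
#' draw comes from the current RNG stream (used internally for nested
#' splits); a supplied seed makes the assignment a pure function of
#' `(n, n_folds, seed)`.
#'
#' @param n Number of observations.
#' @param n_folds Number of folds.
#' @param seed Optional integer seed.
#' @return Integer vector of fold labels in `1..n_folds`.
#' @export
make_cv_folds <- function(n, n_folds, seed = NULL) {
  if (n_folds < 2 || n_folds > n) {
    abort_fcga("need 2 <= n_folds <= n", "fcga_argument_error")
  }
  labels <- rep(seq_len(n_folds), length.out = n)
  if (is.null(seed)) sample(labels) else with_seed(seed, sample(labels))
}

default_lambda_grid <- function(x, y, length_out = 30) {
  xz <- scale(x)
  xz[, attr(xz, "scaled:scale") == 0] <- 0
  lam_max <- max(abs(crossprod(xz, y - mean(y)))) / length(y)
  lam_max <- max(lam_max, 1e-6)
  sort(exp(seq(log(1e-3 * lam_max), log(lam_max),
               length.out = length_out)), decreasing = TRUE)
}

zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

zscore_apply <- function(x, fit) {
  sweep(sweep(x, 2, fit$mu, "-"), 2, fit$sd, "/")
}

#' Ridge regression with nested cross-validation, repeated with random splits
#'
#' Per repeat: a seeded outer split into `n_folds` folds; within each outer
#' training fold, an inner `n_folds`-fold cross-validation selects the
#' ridge penalty minimising inner mean absolute error; the model is refit
#' on the full outer training fold at the selected penalty and the held-out
#' fold is predicted. Held-out predictions are aggregated across folds and
#' MAE and Pearson r are computed once per repeat on the aggregated
#' predictions. Features are z-scored inside each training portion (outer
#' and inner separately), so no test statistics leak into the fit.
#'
#' @param features An `fcga_features` or numeric matrix, subjects in rows.
#' @param target Numeric vector (target units), finite and non-constant.
#' @param n_folds Folds for both the outer and inner splits (default 10).
#' @param n_repeats Number of repeated cross-validation runs (default 100).
#' @param lambda_grid Decreasing positive penalty values; default 30
#'   log-spaced values spanning `1e-3 * lambda_max` to `lambda_max`, where
#'   `lambda_max` is the largest absolute feature/centered-target inner
#'   product (per observation).
#' @param seed Integer master seed; repeat `i` uses the `i`-th derived
#'   seed, so two runs with equal seeds are identical.
#' @param record_folds Keep the outer and inner fold assignments of every
#'   repeat in the report (used to audit that inner model selection never
#'   touches outer test subjects).
#' @return An `fcga_prediction`: tibble `per_repeat` (`repeat`, `mae`,
#'   `r`), aggregated `predictions` (subjects x repeats), the grid, seed,
#'   and optionally the recorded `folds`.
#' @export
ridge_cv_predict <- function(features, target, n_folds = 10,
                             n_repeats = 100, lambda_grid = NULL,
                             seed = 1, record_folds = FALSE) {
  x <- if (inherits(features, "fcga_features")) features$features
       else as.matrix(features)
  y <- as.numeric(target)
  n <- nrow(x)
  if (length(y) != n || any(!is.finite(y))) {
    abort_fcga("target must be finite with one value per subject",
               "fcga_argument_error")
  }
  if (stats::sd(y) == 0) {
    abort_fcga("target is constant: nothing to predict", "fcga_argument_error")
  }
  if (n < 3 * n_folds) {
    abort_fcga(sprintf("need at least 3 * n_folds = %d subjects (got %d)",
                       3 * n_folds, n),
               "fcga_argument_error")
  }
  if (!is.null(lambda_grid) && length(lambda_grid) == 0) {
    abort_fcga("lambda_grid is empty", "fcga_argument_error")
  }
  grid <- sort(lambda_grid %||% default_lambda_grid(x, y),
               decreasing = TRUE)
  if (any(grid <= 0)) {
    abort_fcga("lambda_grid must be strictly positive", "fcga_argument_error")
  }
  repeat_seeds <- derive_seeds(seed, n_repeats)
  predictions <- matrix(NA_real_, n, n_repeats)
  fold_log <- if (record_folds) vector("list", n_repeats) else NULL
  for (rep_i in seq_len(n_repeats)) {
    res <- with_seed(repeat_seeds[rep_i], {
      outer <- make_cv_folds(n, n_folds)
      preds <- rep(NA_real_, n)
      inner_log <- vector("list", n_folds)
      for (f in seq_len(n_folds)) {
        train <- which(outer != f)
        test <- which(outer == f)
        inner <- make_cv_folds(length(train), n_folds)
        if (record_folds) {
          inner_log[[f]] <- list(train = train, test = test,
                                 inner = split(train, inner))
        }
        lam <- select_lambda(x[train, , drop = FALSE], y[train], inner, grid)
        zf <- zscore_fit(x[train, , drop = FALSE])
        fit <- glmnet::glmnet(zscore_apply(x[train, , drop = FALSE], zf),
                              y[train], alpha = 0, lambda = grid,
                              standardize = FALSE)
        preds[test] <- as.vector(
          stats::predict(fit, zscore_apply(x[test, , drop = FALSE], zf),
                         s = lam))
      }
      list(preds = preds, inner_log = inner_log)
    })
    predictions[, rep_i] <- res$preds
    if (record_folds) fold_log[[rep_i]] <- res$inner_log
  }
  mae <- colMeans(abs(predictions - y))
  r <- apply(predictions, 2, function(p) {
    if (stats::sd(p) == 0) return(NA_real_)
    stats::cor(p, y)
  })
  structure(
    list(per_repeat = tibble::tibble(repeat_index = seq_len(n_repeats),
                                     mae = mae, r = r),
         predictions = predictions, target = y, lambda_grid = grid,
         n_folds = n_folds, seed = seed, folds = fold_log),
    class = "fcga_prediction")
}

# Inner CV: mean absolute error of held-out predictions, aggregated across
# inner folds, per lambda; ties resolve toward the largest penalty.
select_lambda <- function(x, y, inner, grid) {
  abs_err <- matrix(NA_real_, length(y), length(grid))
  for (f in sort(unique(inner))) {
    tr <- which(inner != f)
    va <- which(inner == f)
    zf <- zscore_fit(x[tr, , drop = FALSE])
    fit <- glmnet::glmnet(zscore_apply(x[tr, , drop = FALSE], zf), y[tr],
                          alpha = 0, lambda = grid, standardize = FALSE)
    pred <- stats::predict(fit, zscore_apply(x[va, , drop = FALSE], zf),
                           s = grid)
    abs_err[va, ] <- abs(pred - y[va])
  }
  grid[which.min(colMeans(abs_err))]
}

#' @exportS3Method base::print
print.fcga_prediction <- function(x, ...) {
  cat(sprintf(
    "<fcga_prediction> %d repeats x %d-fold CV: median MAE %.4g, mean r %.3f\n",
    nrow(x$per_repeat), x$n_folds, stats::median(x$per_repeat$mae),
    mean(x$per_repeat$r, na.rm = TRUE)))
  invisible(x)
}

#' Tidy / summarise a prediction report
#'
#' @param x An `fcga_prediction`.
#' @param ... Unused.
#' @return `tidy()`: the per-repeat tibble; `glance()`: one row with
#'   median/mean MAE and mean r.
#' @export
tidy.fcga_prediction <- function(x, ...) x$per_repeat

#' @rdname tidy.fcga_prediction
#' @export
glance.fcga_prediction <- function(x, ...) {
  tibble::tibble(
    n_repeats = nrow(x$per_repeat),
    n_folds = x$n_folds,
    median_mae = stats::median(x$per_repeat$mae),
    mean_mae = mean(x$per_repeat$mae),
    mean_r = mean(x$per_repeat$r, na.rm = TRUE))
}

#' Shuffled-label permutation baseline for a prediction report
#'
#' Repeats the full nested-CV prediction `n_perm` times with the target
#' randomly permuted, and locates the observed performance in the null
#' distribution with the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_perm)` (for r; the MAE analogue
#' counts `null <= observed`). The observed statistic is the median over
#' the observed report's repeats.
#'
#' @param features,target,n_folds,lambda_grid,seed As in
#'   [ridge_cv_predict()].
#' @param observed An `fcga_prediction` for the unshuffled target.
#' @param n_perm Number of shuffled-label runs (default 100).
#' @return An `fcga_permutation`: tibble `null` (`perm`, `mae`, `r`) plus
#'   `p_value_r` and `p_value_mae`.
#' @export
permutation_baseline <- function(features, target, observed, n_perm = 100,
                                 n_folds = 10, lambda_grid = NULL,
                                 seed = 1) {
  stopifnot(inherits(observed, "fcga_prediction"))
  if (n_perm < 1) {
    abort_fcga("n_perm must be >= 1", "fcga_argument_error")
  }
  perm_seeds <- derive_seeds(seed + 1L, n_perm)
  null_rows <- purrr::map(seq_len(n_perm), function(i) {
    y_perm <- with_seed(perm_seeds[i], sample(as.numeric(target)))
    rep_i <- ridge_cv_predict(features, y_perm, n_folds = n_folds,
                              n_repeats = 1, lambda_grid = lambda_grid,
                              seed = perm_seeds[i])
    tibble::tibble(perm = i, mae = rep_i$per_repeat$mae,
                   r = rep_i$per_repeat$r)
  })
  null <- dplyr::bind_rows(null_rows)
  obs_r <- stats::median(observed$per_repeat$r, na.rm = TRUE)
  obs_mae <- stats::median(observed$per_repeat$mae)
  structure(
    list(null = null,
         observed_r = obs_r, observed_mae = obs_mae,
         p_value_r = (1 + sum(null$r >= obs_r, na.rm = TRUE)) / (1 + n_perm),
         p_value_mae = (1 + sum(null$mae <= obs_mae)) / (1 + n_perm),
         n_perm = n_perm),
    class = "fcga_permutation")
}

#' @exportS3Method base::print
print.fcga_permutation <- function(x, ...) {
  cat(sprintf(
    "<fcga_permutation> %d shuffled-label runs: p(r) = %.4g, p(MAE) = %.4g\n",
    x$n_perm, x$p_value_r, x$p_value_mae))
  invisible(x)
}

#' Paired comparison of the two feature constructions
#'
#' Builds both feature tables from the same cohort and parcellation, runs
#' [ridge_cv_predict()] on each with the same master seed — so every repeat
#' uses identical fold splits in both arms — and reports the paired
#' per-repeat MAE differences, a sign count of wins, and a paired Wilcoxon
#' signed-rank test of the hypothesis that the fine-grained construction
#' (gradients-to-parcellation) attains lower MAE, Bonferroni-adjusted over
#' the caller's family of comparisons.
#'
#' @param cohort An `fcga_cohort`.
#' @param p An [parcellation_map()].
#' @param target Numeric target; defaults to the cohort's behavior column.
#' @param g,fraction,n_folds,n_repeats,lambda_grid,seed,session As in the
#'   underlying functions.
#' @param landmarks Landmark set for the fine-grained arm (default: the
#'   parcels of `p`); a denser vertex landmark set sharpens the
#'   fine-grained gradients without touching the coarse arm.
#' @param n_comparisons Bonferroni family size (default 1: adjusted = raw).
#' @return An `fcga_comparison` with the paired tibble and summary.
#' @export
compare_constructions <- function(cohort, p, target = NULL, g = 5,
                                  fraction = 0.10, n_folds = 10,
                                  n_repeats = 100, lambda_grid = NULL,
                                  seed = 1, n_comparisons = 1, session = 1,
                                  landmarks = NULL) {
  target <- target %||% cohort$behavior$behavior
  if (anyNA(target)) {
    abort_fcga("cohort has no behavioral target; supply `target`",
               "fcga_argument_error")
  }
  f_g2p <- build_feature_table(cohort, p, "gradients_to_parcellation",
                               g = g, fraction = fraction, session = session,
                               landmarks = landmarks)
  f_p2g <- build_feature_table(cohort, p, "parcellation_to_gradients",
                               g = g, fraction = fraction, session = session)
  if (nrow(f_g2p$features) != length(target)) {
    abort_fcga("target length does not match the cohort",
               "fcga_argument_error")
  }
  pred_g2p <- ridge_cv_predict(f_g2p, target, n_folds = n_folds,
                               n_repeats = n_repeats,
                               lambda_grid = lambda_grid, seed = seed)
  pred_p2g <- ridge_cv_predict(f_p2g, target, n_folds = n_folds,
                               n_repeats = n_repeats,
                               lambda_grid = lambda_grid, seed = seed)
  paired <- tibble::tibble(
    repeat_index = pred_g2p$per_repeat$repeat_index,
    mae_g2p = pred_g2p$per_repeat$mae,
    mae_p2g = pred_p2g$per_repeat$mae,
    mae_diff = pred_p2g$per_repeat$mae - pred_g2p$per_repeat$mae,
    r_g2p = pred_g2p$per_repeat$r,
    r_p2g = pred_p2g$per_repeat$r)
  wins <- sum(paired$mae_g2p < paired$mae_p2g)
  p_raw <- if (all(paired$mae_diff == 0)) {
    1
  } else {
    suppressWarnings(
      stats::wilcox.test(paired$mae_p2g, paired$mae_g2p, paired = TRUE,
                         alternative = "greater")$p.value)
  }
  structure(
    list(paired = paired, wins_g2p = wins, n_repeats = n_repeats,
         p_value = p_raw,
         p_bonferroni = min(1, p_raw * n_comparisons),
         prediction_g2p = pred_g2p, prediction_p2g = pred_p2g),
    class = "fcga_comparison")
}

#' @exportS3Method base::print
print.fcga_comparison <- function(x, ...) {
  cat(sprintf(
    "<fcga_comparison> gradients-to-parcellation wins %d/%d repeats (p = %.4g, Bonferroni %.4g)\n",
    x$wins_g2p, x$n_repeats, x$p_value, x$p_bonferroni))
  invisible(x)
}

#' Tidy / summarise a construction comparison
#'
#' @param x An `fcga_comparison`.
#' @param ... Unused.
#' @export
tidy.fcga_comparison <- function(x, ...) x$paired

#' @rdname tidy.fcga_comparison
#' @export
glance.fcga_comparison <- function(x, ...) {
  tibble::tibble(
    wins_g2p = x$wins_g2p,
    n_repeats = x$n_repeats,
    median_mae_g2p = stats::median(x$paired$mae_g2p),
    median_mae_p2g = stats::median(x$paired$mae_p2g),
    p_value = x$p_value,
    p_bonferroni = x$p_bonferroni)
}
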