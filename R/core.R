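# The gradient engine: vertex-to-landmark Pearson connectivity, row-wise
# top-positive thresholding, cosine affinity, and PCA. The full-matrix
# reference pipeline is the same computation with every vertex serving as
# its own landmark, which makes the approximation target exact by
# construction.

#' Pearson connectivity between two sets of time series
#'
#' Entry `(i, j)` is the Pearson correlation of row `i` of `x` with row `j`
#' of `y` across timepoints.
#'
#' @param x Numeric matrix `a x T` (or `fcga_timeseries`).
#' @param y Numeric matrix `b x T` (or `fcga_timeseries`).
#' @param zero_variance `"error"` (default) raises on a zero-variance row;
#'   `"zero"` sets that row's correlations to 0 with a warning.
#' @param row_role,col_role Role tags carried on the result.
#' @return An `fcga_connectivity` of size `a x b`.
#' @export
pearson_connectivity <- function(x, y, zero_variance = c("error", "zero"),
                                 row_role = "vertex", col_role = "landmark") {
  zero_variance <- match.arg(zero_variance)
  x <- if (inherits(x, "fcga_timeseries")) x$values else as.matrix(x)
  y <- if (inherits(y, "fcga_timeseries")) y$values else as.matrix(y)
  if (ncol(x) != ncol(y)) {
    abort_fcga("x and y must share the same number of timepoints",
               "fcga_argument_error")
  }
  if (ncol(x) < 3) {
    abort_fcga("need at least 3 timepoints for correlation",
               "fcga_dimension_error")
  }
  bad_x <- row_sds(x) == 0
  bad_y <- row_sds(y) == 0
  if (any(bad_x) || any(bad_y)) {
    if (zero_variance == "error") {
      abort_fcga(
        sprintf("zero-variance rows: x[%s], y[%s]",
                paste(which(bad_x), collapse = ","),
                paste(which(bad_y), collapse = ",")),
        "fcga_value_error")
    }
    rlang::warn(sprintf(
      "%d zero-variance rows: their correlations set to 0",
      sum(bad_x) + sum(bad_y)))
  }
  r <- suppressWarnings(stats::cor(t(x), t(y)))
  r[bad_x, ] <- 0
  r[, bad_y] <- 0
  r <- pmin(pmax(r, -1), 1)  # guard rounding just past +/-1
  new_connectivity(r, row_role, col_role)
}

#' Keep only the strongest positive connections in each row
#'
#' Per row, the `m = ceiling(fraction * ncol)` largest strictly positive
#' entries are retained and everything else — including all negative
#' values — is set to 0. Rows with fewer than `m` positive entries keep all
#' their positives; a row with none becomes all-zero with a warning (the
#' affinity stage treats such rows explicitly).
#'
#' @param cm An `fcga_connectivity`.
#' @param fraction Proportion of columns to retain, in `(0, 1]`
#'   (default 0.10).
#' @return The thresholded `fcga_connectivity`.
#' @export
threshold_rows_top_positive <- function(cm, fraction = 0.10) {
  stopifnot(inherits(cm, "fcga_connectivity"))
  if (!(fraction > 0 && fraction <= 1)) {
    abort_fcga("fraction must be in (0, 1]", "fcga_argument_error")
  }
  v <- cm$values
  m <- ceiling(fraction * ncol(v))
  out <- matrix(0, nrow(v), ncol(v))
  n_empty <- 0L
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    pos <- which(row > 0)
    if (length(pos) == 0) {
      n_empty <- n_empty + 1L
      next
    }
    keep <- if (length(pos) <= m) {
      pos
    } else {
      pos[order(row[pos], decreasing = TRUE)[seq_len(m)]]
    }
    out[i, keep] <- row[keep]
  }
  if (n_empty > 0) {
    rlang::warn(sprintf(
      "%d row(s) had no positive connections and were zeroed", n_empty))
  }
  new_connectivity(out, cm$row_role, cm$col_role,
                   thresholded = TRUE, fraction = fraction)
}

#' Cosine affinity between vertex and landmark connectivity profiles
#'
#' `W[i, j]` is the cosine similarity between row `i` of the thresholded
#' vertex-by-landmark connectivity and row `j` of the thresholded
#' landmark-by-landmark connectivity: the spatial similarity of their
#' connectivity profiles over the shared landmark axis.
#'
#' @param cm_nk Thresholded `fcga_connectivity`, `n x k`.
#' @param cm_kk Thresholded `fcga_connectivity`, `k x k`.
#' @param zero_rows `"zero"` (default) sets affinities involving an
#'   all-zero profile to 0 with a warning; `"error"` raises.
#' @return An `fcga_affinity` of size `n x k`.
#' @export
cosine_affinity <- function(cm_nk, cm_kk, zero_rows = c("zero", "error")) {
  zero_rows <- match.arg(zero_rows)
  stopifnot(inherits(cm_nk, "fcga_connectivity"),
            inherits(cm_kk, "fcga_connectivity"))
  if (!cm_nk$thresholded || !cm_kk$thresholded) {
    abort_fcga("both connectivity matrices must be thresholded first",
               "fcga_argument_error")
  }
  a <- cm_nk$values
  b <- cm_kk$values
  if (ncol(a) != ncol(b)) {
    abort_fcga("cm_nk and cm_kk must share the landmark axis (equal columns)",
               "fcga_argument_error")
  }
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  za <- na == 0
  zb <- nb == 0
  if (any(za) || any(zb)) {
    if (zero_rows == "error") {
      abort_fcga("all-zero connectivity profile: cosine undefined",
                 "fcga_value_error")
    }
    rlang::warn(sprintf(
      "%d all-zero profile(s): their affinities set to 0", sum(za) + sum(zb)))
  }
  w <- tcrossprod(a, b) / outer(pmax(na, 1e-300), pmax(nb, 1e-300))
  w[za, ] <- 0
  w[, zb] <- 0
  w <- pmin(pmax(w, -1), 1)
  new_affinity(w, provenance = list(fraction = cm_nk$fraction,
                                    k = ncol(a)))
}

#' PCA of the affinity matrix: the connectivity gradients
#'
#' Column-mean-centered PCA of `W` (no variance scaling). Coefficients are
#' the projections of the vertices onto the top components, ordered by
#' decreasing explained variance. Signs are fixed deterministically: each
#' component is flipped, if needed, so that its loading of largest absolute
#' value is positive.
#'
#' @param w An `fcga_affinity` (or plain numeric matrix).
#' @param n_components Number of gradients to retain; must not exceed the
#'   rank of the centered matrix.
#' @return An [gradient_set()].
#' @export
pca_gradients <- function(w, n_components) {
  prov <- list()
  if (inherits(w, "fcga_affinity")) {
    prov <- w$provenance
    w <- w$values
  }
  w <- as.matrix(w)
  if (n_components < 1) {
    abort_fcga("n_components must be >= 1", "fcga_argument_error")
  }
  if (n_components > min(dim(w))) {
    abort_fcga(sprintf("n_components = %d exceeds min(dim(W)) = %d",
                       n_components, min(dim(w))),
               "fcga_argument_error")
  }
  p <- stats::prcomp(w, center = TRUE, scale. = FALSE)
  tol <- max(dim(w)) * .Machine$double.eps * p$sdev[1]
  achievable <- sum(p$sdev > tol)
  if (n_components > achievable) {
    abort_fcga(sprintf(
      "n_components = %d exceeds the achievable rank %d of the centered affinity matrix",
      n_components, achievable),
      "fcga_argument_error")
  }
  idx <- seq_len(n_components)
  fixed <- fix_signs(p$x[, idx, drop = FALSE],
                     p$rotation[, idx, drop = FALSE])
  evr <- p$sdev^2 / sum(p$sdev^2)
  gradient_set(fixed$scores, evr[idx], provenance = prov)
}

#' Fast Connectivity Gradient Approximation
#'
#' The landmark pipeline end to end: extract the `k` landmark time series,
#' correlate all `n` vertices (and the landmarks themselves) against them,
#' threshold each row to its strongest positive connections, form the
#' `n x k` cosine affinity matrix, and reduce it with PCA. Only `n * k`
#' affinity entries are ever stored, against `n^2` for the full
#' vertex-by-vertex pipeline.
#'
#' @param ts An `fcga_timeseries`.
#' @param landmarks An `fcga_landmarks`.
#' @param n_components Number of gradients (default 25, the depth at which
#'   gradient sets are conventionally compared).
#' @param fraction Row-thresholding fraction (default 0.10: the 10%
#'   strongest positive connections are kept).
#' @param zero_variance,zero_rows Degenerate-row policies; see
#'   [pearson_connectivity()] and [cosine_affinity()].
#' @return An [gradient_set()] with full provenance.
#' @export
fcga <- function(ts, landmarks, n_components = 25, fraction = 0.10,
                 zero_variance = c("error", "zero"),
                 zero_rows = c("zero", "error")) {
  stopifnot(inherits(ts, "fcga_timeseries"),
            inherits(landmarks, "fcga_landmarks"))
  lm_ts <- extract_landmark_timeseries(ts, landmarks)
  cm_nk <- pearson_connectivity(ts$values, lm_ts,
                                zero_variance = zero_variance)
  cm_kk <- pearson_connectivity(lm_ts, lm_ts,
                                zero_variance = zero_variance,
                                row_role = "landmark")
  w <- cosine_affinity(threshold_rows_top_positive(cm_nk, fraction),
                       threshold_rows_top_positive(cm_kk, fraction),
                       zero_rows = zero_rows)
  g <- pca_gradients(w, n_components)
  g$provenance <- list(
    pipeline = "fcga", method = landmarks$method, k = landmarks$k,
    fraction = fraction, seed = landmarks$seed,
    n_vertices = nrow(ts$values), space_tag = ts$space_tag)
  g
}

#' Reference gradients from the full vertex-by-vertex pipeline
#'
#' Identical to [fcga()] with every vertex serving as its own landmark:
#' the full `n x n` connectivity matrix is built, thresholded, converted to
#' cosine affinity and reduced by PCA. Serves as the oracle that the
#' landmark approximation is measured against. Guarded by an explicit size
#' check, since the `n x n` stage is exactly what the approximation exists
#' to avoid.
#'
#' @param ts An `fcga_timeseries`.
#' @param n_components Number of gradients.
#' @param fraction Row-thresholding fraction.
#' @param max_vertices Refuse to build the dense matrix beyond this size.
#' @inheritParams fcga
#' @return An [gradient_set()].
#' @export
full_gradients <- function(ts, n_components = 25, fraction = 0.10,
                           max_vertices = 20000,
                           zero_variance = c("error", "zero"),
                           zero_rows = c("zero", "error")) {
  stopifnot(inherits(ts, "fcga_timeseries"))
  n <- nrow(ts$values)
  if (n > max_vertices) {
    abort_fcga(sprintf(
      "n = %d vertices would need a dense %d x %d matrix; use fcga() with landmarks instead",
      n, n, n),
      "fcga_memory_guard")
  }
  identity_lm <- new_landmark_set("identity_vertices", n,
                                  vertex_indices = seq_len(n))
  g <- fcga(ts, identity_lm, n_components = n_components,
            fraction = fraction, zero_variance = zero_variance,
            zero_rows = zero_rows)
  g$provenance$pipeline <- "full"
  g
}

#' Landmark connectivity from a precomputed dense connectome
#'
#' Group-level variant: when a dense `n x n` functional connectivity matrix
#' is already available, the vertex-by-landmark block is obtained by
#' averaging the precomputed connectivity over each landmark's member
#' vertices (parcel landmarks) or by selecting columns (vertex landmarks),
#' instead of recomputing correlations from time series.
#'
#' @param fc Square, unthresholded `fcga_connectivity` (or matrix), `n x n`.
#' @param lm An `fcga_landmarks`.
#' @return An `fcga_connectivity` of size `n x k`.
#' @export
landmark_connectivity_from_dense_fc <- function(fc, lm) {
  v <- if (inherits(fc, "fcga_connectivity")) {
    if (fc$thresholded) {
      abort_fcga("dense FC must be unthresholded", "fcga_argument_error")
    }
    fc$values
  } else {
    as.matrix(fc)
  }
  if (nrow(v) != ncol(v)) {
    abort_fcga("dense FC must be square", "fcga_argument_error")
  }
  stopifnot(inherits(lm, "fcga_landmarks"))
  out <- if (lm$method == "parcellation") {
    labels <- lm$parcellation$labels
    if (length(labels) != ncol(v)) {
      abort_fcga("parcellation does not match the dense FC dimension",
                 "fcga_argument_error")
    }
    keep <- labels > 0
    sums <- t(rowsum(t(v[, keep, drop = FALSE]), labels[keep]))
    counts <- as.vector(table(labels[keep]))
    sweep(sums, 2, counts, "/")
  } else {
    idx <- lm$vertex_indices
    if (any(idx < 1) || any(idx > ncol(v))) {
      abort_fcga("landmark indices outside the dense FC", "fcga_argument_error")
    }
    v[, idx, drop = FALSE]
  }
  dimnames(out) <- NULL
  new_connectivity(out, "vertex", "landmark")
}

#' Gradients from a precomputed dense connectome via landmarks
#'
#' Applies the landmark averaging of
#' [landmark_connectivity_from_dense_fc()] along both axes to obtain the
#' `n x k` and `k x k` connectivity blocks, then runs the standard
#' threshold / cosine / PCA stages.
#'
#' @inheritParams landmark_connectivity_from_dense_fc
#' @inheritParams fcga
#' @return An [gradient_set()].
#' @export
fcga_from_dense_fc <- function(fc, lm, n_components = 25, fraction = 0.10,
                               zero_rows = c("zero", "error")) {
  cm_nk <- landmark_connectivity_from_dense_fc(fc, lm)
  cm_kk_vals <- if (lm$method == "parcellation") {
    labels <- lm$parcellation$labels
    keep <- labels > 0
    sums <- rowsum(cm_nk$values[keep, , drop = FALSE], labels[keep])
    counts <- as.vector(table(labels[keep]))
    sums / counts
  } else {
    cm_nk$values[lm$vertex_indices, , drop = FALSE]
  }
  cm_kk <- new_connectivity(cm_kk_vals, "landmark", "landmark")
  w <- cosine_affinity(threshold_rows_top_positive(cm_nk, fraction),
                       threshold_rows_top_positive(cm_kk, fraction),
                       zero_rows = zero_rows)
  g <- pca_gradients(w, n_components)
  g$provenance <- list(pipeline = "fcga_dense_fc", method = lm$method,
                       k = lm$k, fraction = fraction, seed = lm$seed,
                       n_vertices = nrow(cm_nk$values))
  g
}

#' Storage cost of the landmark approximation versus the full pipeline
#'
#' The affinity stage stores exactly `n * k` entries under the landmark
#' approximation against `n^2` for the full vertex-by-vertex matrix; the
#' ratio `k / n` is the memory (and, to first order, time) fraction that
#' motivates the approximation.
#'
#' @param n_vertices Number of vertices.
#' @param k Number of landmarks.
#' @return A tibble with `affinity_entries`, `full_entries`, and `ratio`.
#' @export
approximation_cost <- function(n_vertices, k) {
  tibble::tibble(
    n_vertices = as.double(n_vertices),
    k = as.double(k),
    affinity_entries = as.double(n_vertices) * k,
    full_entries = as.double(n_vertices)^2,
    ratio = k / n_vertices)
}
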