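#' Construct a vertex-by-timepoint functional time-series matrix
#'
#' The raw input to every gradient computation: one row per cortical vertex
#' (or toy-grid node), one column per timepoint. Vertex indices are 1-based
#' throughout the package; any external 0-based convention is converted at
#' the I/O boundary.
#'
#' @param values Numeric matrix, `n_vertices x n_timepoints`.
#' @param vertex_ids Integer vector of unique vertex identifiers
#'   (default `1:n_vertices`).
#' @param space_tag Free-text label of the spatial reference frame,
#'   e.g. `"fsLR32k"` or `"toy-grid"`.
#' @param allow_constant Permit rows with zero variance. Constant rows have
#'   undefined Pearson correlations, so they are rejected unless explicitly
#'   flagged.
#' @return An object of class `fcga_timeseries`.
#' @export
time_series_matrix <- function(values, vertex_ids = NULL,
                               space_tag = "unspecified",
                               allow_constant = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2) {
    abort_fcga("a time-series matrix needs at least 2 vertices (rows)",
               "fcga_dimension_error")
  }
  if (ncol(values) < 3) {
    abort_fcga("a time-series matrix needs at least 3 timepoints (columns)",
               "fcga_dimension_error")
  }
  if (!all(is.finite(values))) {
    abort_fcga("time-series values must all be finite", "fcga_value_error")
  }
  vertex_ids <- as.integer(vertex_ids %||% seq_len(nrow(values)))
  if (length(vertex_ids) != nrow(values) || anyDuplicated(vertex_ids)) {
    abort_fcga("vertex_ids must be unique and match the number of rows",
               "fcga_value_error")
  }
  if (!allow_constant) {
    sds <- row_sds(values)
    if (any(sds == 0)) {
      abort_fcga(
        sprintf("rows with zero variance: %s (pass allow_constant = TRUE to keep them)",
                paste(utils::head(which(sds == 0), 5), collapse = ", ")),
        "fcga_value_error")
    }
  }
  structure(
    list(values = values, vertex_ids = vertex_ids, space_tag = space_tag),
    class = "fcga_timeseries")
}

row_sds <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

#' @exportS3Method base::print
print.fcga_timeseries <- function(x, ...) {
  cat(sprintf("<fcga_timeseries> %d vertices x %d timepoints [%s]\n",
              nrow(x$values), ncol(x$values), x$space_tag))
  invisible(x)
}

#' @export
dim.fcga_timeseries <- function(x) dim(x$values)

#' Construct a parcellation label map
#'
#' Assigns every vertex an integer parcel label in `1..P`; the label 0 marks
#' unassigned vertices and is excluded from all parcel averaging.
#'
#' @param labels Integer vector, one label per vertex.
#' @param parcel_names Optional character vector of length `P`.
#' @param space_tag Spatial reference label.
#' @return An object of class `fcga_parcellation`.
#' @export
parcellation_map <- function(labels, parcel_names = NULL,
                             space_tag = "unspecified") {
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    abort_fcga("parcel labels must be finite integers", "fcga_format_error")
  }
  labels <- as.integer(labels)
  if (any(labels < 0)) {
    abort_fcga("parcel labels must be >= 0 (0 = unassigned)",
               "fcga_validation_error")
  }
  p <- max(labels)
  if (p < 1) {
    abort_fcga("a parcellation needs at least one assigned parcel",
               "fcga_validation_error")
  }
  missing_ids <- setdiff(seq_len(p), unique(labels))
  if (length(missing_ids) > 0) {
    abort_fcga(
      sprintf("parcel ids with no member vertex: %s",
              paste(missing_ids, collapse = ", ")),
      "fcga_validation_error")
  }
  if (!is.null(parcel_names) && length(parcel_names) != p) {
    abort_fcga("parcel_names must have one entry per parcel",
               "fcga_validation_error")
  }
  structure(
    list(labels = labels, n_parcels = p, parcel_names = parcel_names,
         space_tag = space_tag),
    class = "fcga_parcellation")
}

#' @exportS3Method base::print
print.fcga_parcellation <- function(x, ...) {
  cat(sprintf("<fcga_parcellation> %d vertices, %d parcels (%d unassigned) [%s]\n",
              length(x$labels), x$n_parcels, sum(x$labels == 0), x$space_tag))
  invisible(x)
}

#' Construct a gradient set
#'
#' Holds the `n_vertices x g` matrix of gradient coefficients (embedding
#' coordinates of each vertex along the principal axes of connectivity
#' variation) together with per-component explained-variance ratios and a
#' provenance record of how the set was produced.
#'
#' Coefficient columns of a freshly computed set are mutually orthogonal
#' (they are PCA scores); sets that have been rotated by Procrustes
#' alignment carry `provenance$aligned = TRUE` and are exempt from the
#' orthogonality check, since an orthogonal rotation of scores need not
#' preserve their pairwise orthogonality.
#'
#' @param coefficients Numeric matrix `n_vertices x g`.
#' @param explained_variance_ratio Numeric vector of length `g`, each in
#'   `[0, 1]`, non-increasing.
#' @param provenance Named list (landmark method, `k`, threshold fraction,
#'   seed, ...).
#' @return An object of class `fcga_gradients`.
#' @export
gradient_set <- function(coefficients, explained_variance_ratio,
                         provenance = list()) {
  coefficients <- as.matrix(coefficients)
  storage.mode(coefficients) <- "double"
  g <- ncol(coefficients)
  if (g < 1) abort_fcga("a gradient set needs g >= 1", "fcga_dimension_error")
  evr <- as.numeric(explained_variance_ratio)
  if (length(evr) != g || any(!is.finite(evr)) ||
      any(evr < -1e-12) || any(evr > 1 + 1e-12)) {
    abort_fcga("explained_variance_ratio must be length g with values in [0, 1]",
               "fcga_validation_error")
  }
  if (any(diff(evr) > 1e-12)) {
    abort_fcga("explained_variance_ratio must be non-increasing",
               "fcga_validation_error")
  }
  if (!isTRUE(provenance$aligned) && g > 1) {
    cp <- crossprod(coefficients)
    off <- max(abs(cp[upper.tri(cp)]))
    scale <- max(diag(cp), 1)
    if (off > 1e-6 * scale) {
      abort_fcga("gradient coefficient columns must be mutually orthogonal",
                 "fcga_validation_error")
    }
  }
  structure(
    list(coefficients = coefficients,
         explained_variance_ratio = pmin(pmax(evr, 0), 1),
         provenance = provenance),
    class = "fcga_gradients")
}

#' @exportS3Method base::print
print.fcga_gradients <- function(x, ...) {
  cat(sprintf("<fcga_gradients> %d vertices x %d gradients\n",
              nrow(x$coefficients), ncol(x$coefficients)))
  cat(sprintf("  explained variance: %s%s\n",
              paste(sprintf("%.3f", utils::head(x$explained_variance_ratio, 5)),
                    collapse = " "),
              if (ncol(x$coefficients) > 5) " ..." else ""))
  if (length(x$provenance) > 0) {
    keys <- intersect(c("method", "k", "fraction", "seed", "aligned"),
                      names(x$provenance))
    if (length(keys) > 0) {
      cat("  provenance:",
          paste(sprintf("%s=%s", keys,
                        vapply(x$provenance[keys], format, "")),
                collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @export
dim.fcga_gradients <- function(x) dim(x$coefficients)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gradient set into a long tibble
#'
#' @param x An `fcga_gradients` object.
#' @param ... Unused.
#' @return A tibble with columns `vertex`, `gradient`, `coefficient`.
#' @export
tidy.fcga_gradients <- function(x, ...) {
  g <- ncol(x$coefficients)
  n <- nrow(x$coefficients)
  tibble::tibble(
    vertex = rep(seq_len(n), times = g),
    gradient = rep(seq_len(g), each = n),
    coefficient = as.vector(x$coefficients))
}

#' One-row summary of a gradient set
#'
#' @param x An `fcga_gradients` object.
#' @param ... Unused.
#' @return A tibble with `n_vertices`, `n_gradients`, cumulative explained
#'   variance of the retained components, and the landmark count `k` when
#'   recorded.
#' @export
glance.fcga_gradients <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x$coefficients),
    n_gradients = ncol(x$coefficients),
    explained_variance = sum(x$explained_variance_ratio),
    k = x$provenance$k %||% NA_integer_)
}

# Connectivity matrices (vertex x landmark or landmark x landmark blocks of
# Pearson r). Thresholded matrices keep, per row, only the strongest
# positive entries.
new_connectivity <- function(values, row_role, col_role,
                             thresholded = FALSE, fraction = NULL) {
  structure(
    list(values = values, row_role = row_role, col_role = col_role,
         thresholded = thresholded, fraction = fraction),
    class = "fcga_connectivity")
}

#' @exportS3Method base::print
print.fcga_connectivity <- function(x, ...) {
  cat(sprintf("<fcga_connectivity> %d %s x %d %s%s\n",
              nrow(x$values), x$row_role, ncol(x$values), x$col_role,
              if (x$thresholded)
                sprintf(", row-thresholded (top %g positive)", x$fraction)
              else ""))
  invisible(x)
}

#' @export
dim.fcga_connectivity <- function(x) dim(x$values)

new_affinity <- function(values, provenance = list()) {
  structure(list(values = values, provenance = provenance),
            class = "fcga_affinity")
}

#' @exportS3Method base::print
print.fcga_affinity <- function(x, ...) {
  cat(sprintf("<fcga_affinity> %d vertices x %d landmarks (cosine)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.fcga_affinity <- function(x) dim(x$values)
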