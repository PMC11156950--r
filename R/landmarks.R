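# Landmark construction: the k reference locations against which every
# vertex's connectivity profile is measured. Landmarks are either single
# vertices (random or uniform/farthest-point sampling) or parcel averages.

new_landmark_set <- function(method, k, vertex_indices = NULL,
                             parcellation = NULL, seed = NULL) {
  structure(
    list(method = method, k = as.integer(k),
         vertex_indices = vertex_indices, parcellation = parcellation,
         seed = seed),
    class = "fcga_landmarks")
}

#' @exportS3Method base::print
print.fcga_landmarks <- function(x, ...) {
  cat(sprintf("<fcga_landmarks> method=%s, k=%d%s\n", x$method, x$k,
              if (!is.null(x$seed)) sprintf(", seed=%d", x$seed) else ""))
  invisible(x)
}

#' Select k random vertex landmarks
#'
#' Samples `k` distinct vertex indices uniformly without replacement.
#' Deterministic for a given `(n_vertices, k, seed)`; the stored indices are
#' sorted ascending so downstream matrices have a canonical column order.
#'
#' @param n_vertices Total number of vertices.
#' @param k Number of landmarks, `2 <= k <= n_vertices`.
#' @param seed Integer seed.
#' @return An `fcga_landmarks` object with `method = "random_vertices"`.
#' @export
select_random_vertices <- function(n_vertices, k, seed) {
  check_k(k, n_vertices)
  idx <- sort(with_seed(seed, sample.int(n_vertices, k)))
  new_landmark_set("random_vertices", k, vertex_indices = idx, seed = seed)
}

check_k <- function(k, n_vertices) {
  if (k < 2 || k > n_vertices) {
    abort_fcga(sprintf("k must satisfy 2 <= k <= n_vertices (got k=%d, n=%d)",
                       k, n_vertices),
               "fcga_argument_error")
  }
}

#' Select k spatially uniform vertex landmarks (farthest-point sampling)
#'
#' Greedy farthest-point sampling on Euclidean distance over the vertex
#' coordinates: a seeded random vertex serves as the anchor, the first
#' landmark is the vertex farthest from that anchor, and each subsequent
#' landmark maximises the minimum distance to those already selected (ties
#' broken toward the smallest index). This spreads the landmarks across the
#' surface far more evenly than random sampling; the anchor itself is not
#' retained, so a central vertex never enters the set merely for having
#' been the starting point.
#'
#' @param coords Numeric `n x 3` matrix of vertex coordinates.
#' @param k Number of landmarks.
#' @param seed Integer seed (selects the anchor vertex).
#' @return An `fcga_landmarks` object with `method = "uniform_vertices"`.
#' @export
select_uniform_vertices <- function(coords, k, seed) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) {
    abort_fcga("vertex coordinates must be finite", "fcga_argument_error")
  }
  n <- nrow(coords)
  check_k(k, n)
  if (k == n) {
    return(new_landmark_set("uniform_vertices", k,
                            vertex_indices = seq_len(n), seed = seed))
  }
  anchor <- with_seed(seed, sample.int(n, 1))
  d2 <- function(i) colSums((t(coords) - coords[i, ])^2)
  selected <- integer(k)
  # the anchor only seeds the walk: the first landmark is the vertex
  # farthest from it, and the anchor itself stays eligible thereafter
  selected[1] <- which.max(d2(anchor))
  min_d2 <- d2(selected[1])
  for (j in seq_len(k)[-1]) {
    nxt <- which.max(min_d2)  # ties -> smallest index
    selected[j] <- nxt
    min_d2 <- pmin(min_d2, d2(nxt))
  }
  new_landmark_set("uniform_vertices", k,
                   vertex_indices = sort(selected), seed = seed)
}

#' Use the parcels of a parcellation as landmarks
#'
#' Each parcel contributes one landmark, defined downstream by the
#' unweighted mean time series over its member vertices; `k` equals the
#' number of parcels.
#'
#' @param p An [parcellation_map()].
#' @return An `fcga_landmarks` object with `method = "parcellation"`.
#' @export
landmarks_from_parcellation <- function(p) {
  stopifnot(inherits(p, "fcga_parcellation"))
  if (p$n_parcels < 2) {
    abort_fcga("need at least 2 parcels to serve as landmarks",
               "fcga_argument_error")
  }
  new_landmark_set("parcellation", p$n_parcels, parcellation = p)
}

#' Extract the k landmark time series from a time-series matrix
#'
#' Vertex-based landmarks copy the corresponding rows verbatim; parcel
#' landmarks take the unweighted mean over each parcel's member vertices
#' (unassigned vertices, label 0, are excluded). Rows are ordered by
#' ascending vertex index / parcel id.
#'
#' @param ts An `fcga_timeseries`.
#' @param lm An `fcga_landmarks`.
#' @return Numeric matrix `k x n_timepoints`.
#' @export
extract_landmark_timeseries <- function(ts, lm) {
  stopifnot(inherits(ts, "fcga_timeseries"), inherits(lm, "fcga_landmarks"))
  n <- nrow(ts$values)
  if (lm$method == "parcellation") {
    labels <- lm$parcellation$labels
    if (length(labels) != n) {
      abort_fcga(sprintf("parcellation has %d vertices but time series has %d",
                         length(labels), n),
                 "fcga_argument_error")
    }
    keep <- labels > 0
    sums <- rowsum(ts$values[keep, , drop = FALSE], labels[keep])
    counts <- as.vector(table(labels[keep]))
    sums / counts
  } else {
    idx <- lm$vertex_indices
    if (any(idx < 1) || any(idx > n)) {
      abort_fcga("landmark vertex indices outside the time-series matrix",
                 "fcga_argument_error")
    }
    ts$values[idx, , drop = FALSE]
  }
}
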