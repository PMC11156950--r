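# Comparing gradient sets: orthogonal Procrustes alignment to a reference,
# per-gradient Spearman spatial similarity, and vertex-wise similarity of
# gradient profiles.

#' Orthogonal Procrustes alignment of one gradient set to a reference
#'
#' Finds the orthogonal `g x g` matrix `R` minimising
#' `||source %*% R - reference||_F` (closed form via the SVD of
#' `t(source) %*% reference`) and applies it. Rotation/reflection only: no
#' scaling, no translation. This matches component order and coefficient
#' signs between two gradient sets whose PCA solutions are individually
#' arbitrary in both respects.
#'
#' @param source,reference `fcga_gradients` with equal dimensions.
#' @return An `fcga_alignment`: `aligned` (gradient set), `transform`
#'   (orthogonal matrix), and `residual` (Frobenius norm of
#'   `aligned - reference`).
#' @export
procrustes_align <- function(source, reference) {
  stopifnot(inherits(source, "fcga_gradients"),
            inherits(reference, "fcga_gradients"))
  x <- source$coefficients
  y <- reference$coefficients
  if (!all(dim(x) == dim(y))) {
    abort_fcga("source and reference gradient sets must have equal dimensions",
               "fcga_argument_error")
  }
  s <- svd(crossprod(x, y))
  rot <- s$u %*% t(s$v)
  aligned_coef <- x %*% rot
  prov <- source$provenance
  prov$aligned <- TRUE
  aligned <- gradient_set(aligned_coef, source$explained_variance_ratio,
                          provenance = prov)
  structure(
    list(aligned = aligned, transform = rot,
         residual = sqrt(sum((aligned_coef - y)^2))),
    class = "fcga_alignment")
}

#' @exportS3Method base::print
print.fcga_alignment <- function(x, ...) {
  cat(sprintf("<fcga_alignment> g=%d, residual=%.6g\n",
              ncol(x$transform), x$residual))
  invisible(x)
}

#' @rdname procrustes_align
#' @param x An `fcga_alignment`.
#' @param ... Unused.
#' @export
glance.fcga_alignment <- function(x, ...) {
  tibble::tibble(
    n_gradients = ncol(x$transform),
    residual = x$residual,
    orthogonality_error = max(abs(crossprod(x$transform) -
                                    diag(ncol(x$transform)))))
}

#' Per-gradient Spearman spatial similarity between two gradient sets
#'
#' Component-wise Spearman rank correlation between matching gradient maps.
#' The default `absolute` mode reports `|rho|`: PCA component signs are
#' arbitrary, so without prior alignment only the magnitude of the spatial
#' correspondence is well defined. Use `signed` mode after
#' [procrustes_align()].
#'
#' @param a,b `fcga_gradients` with equal dimensions.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return An `fcga_similarity` report: tibble of per-gradient `rho` plus
#'   `mean_rho`; see [tidy.fcga_similarity()] / [glance.fcga_similarity()].
#' @export
spearman_similarity <- function(a, b, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "fcga_gradients"), inherits(b, "fcga_gradients"))
  if (!all(dim(a$coefficients) == dim(b$coefficients))) {
    abort_fcga("gradient sets must have equal dimensions",
               "fcga_argument_error")
  }
  g <- ncol(a$coefficients)
  rho <- vapply(seq_len(g), function(j) {
    ca <- a$coefficients[, j]
    cb <- b$coefficients[, j]
    if (stats::sd(ca) == 0 || stats::sd(cb) == 0) {
      abort_fcga(sprintf("gradient %d is constant: Spearman undefined", j),
                 "fcga_value_error")
    }
    stats::cor(ca, cb, method = "spearman")
  }, numeric(1))
  if (mode == "absolute") rho <- abs(rho)
  structure(
    list(per_gradient = tibble::tibble(gradient = seq_len(g), rho = rho),
         mean_rho = mean(rho), mode = mode),
    class = "fcga_similarity")
}

#' @exportS3Method base::print
print.fcga_similarity <- function(x, ...) {
  cat(sprintf("<fcga_similarity> %d gradients, mode=%s, mean rho=%.4f\n",
              nrow(x$per_gradient), x$mode, x$mean_rho))
  invisible(x)
}

#' Tidy / summarise a similarity report
#'
#' @param x An `fcga_similarity`.
#' @param ... Unused.
#' @return `tidy()`: tibble with `gradient` and `rho`; `glance()`: one row
#'   with `mean_rho`, `n_gradients`, `mode`.
#' @export
tidy.fcga_similarity <- function(x, ...) x$per_gradient

#' @rdname tidy.fcga_similarity
#' @export
glance.fcga_similarity <- function(x, ...) {
  tibble::tibble(mean_rho = x$mean_rho,
                 n_gradients = nrow(x$per_gradient),
                 mode = x$mode)
}

#' Vertex-wise similarity between gradient profiles
#'
#' For each vertex, correlates its profile across the `g` gradients in `a`
#' with the same profile in `b`. A vertex whose profile is constant in
#' either set has an undefined correlation; it is recorded as `NA` and the
#' count is reported in a warning.
#'
#' @param a,b `fcga_gradients` with equal dimensions (`g >= 3`
#'   recommended).
#' @param metric `"pearson"` (default) or `"spearman"`.
#' @return A tibble with columns `vertex` and `similarity`.
#' @export
vertexwise_profile_similarity <- function(a, b,
                                          metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  stopifnot(inherits(a, "fcga_gradients"), inherits(b, "fcga_gradients"))
  if (!all(dim(a$coefficients) == dim(b$coefficients))) {
    abort_fcga("gradient sets must have equal dimensions",
               "fcga_argument_error")
  }
  ma <- a$coefficients
  mb <- b$coefficients
  n <- nrow(ma)
  sim <- vapply(seq_len(n), function(i) {
    pa <- ma[i, ]
    pb <- mb[i, ]
    if (stats::sd(pa) == 0 || stats::sd(pb) == 0) return(NA_real_)
    stats::cor(pa, pb, method = metric)
  }, numeric(1))
  n_missing <- sum(is.na(sim))
  if (n_missing > 0) {
    rlang::warn(sprintf(
      "%d vertex profile(s) constant: similarity recorded as NA", n_missing))
  }
  tibble::tibble(vertex = seq_len(n), similarity = sim)
}
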