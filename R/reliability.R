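# Test-retest reliability of gradient measurements: vertex-wise intraclass
# correlation (two-way random effects, absolute agreement, single measure)
# and the discriminability statistic.

#' Bundle repeated gradient measurements into a reliability panel
#'
#' @param measurements List of `fcga_gradients` (or numeric matrices of
#'   identical dimension), one per acquisition.
#' @param subject_id Vector of subject labels, one per measurement.
#' @param session_id Vector of session labels, one per measurement.
#' @return An `fcga_panel`: the measurement list plus a tibble manifest.
#' @export
reliability_panel <- function(measurements, subject_id, session_id = NULL) {
  mats <- lapply(measurements, function(m) {
    if (inherits(m, "fcga_gradients")) m$coefficients else as.matrix(m)
  })
  if (length(mats) < 2) {
    abort_fcga("a reliability panel needs at least 2 measurements",
               "fcga_argument_error")
  }
  d0 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d0), logical(1)))) {
    abort_fcga("all measurements must share the same dimensions",
               "fcga_argument_error")
  }
  if (length(subject_id) != length(mats)) {
    abort_fcga("subject_id must have one entry per measurement",
               "fcga_argument_error")
  }
  if (length(unique(subject_id)) < 2) {
    abort_fcga("a reliability panel needs at least 2 subjects",
               "fcga_argument_error")
  }
  session_id <- session_id %||% stats::ave(seq_along(subject_id), subject_id,
                                           FUN = seq_along)
  structure(
    list(measurements = mats,
         manifest = tibble::tibble(
           measurement = seq_along(mats),
           subject = as.character(subject_id),
           session = as.character(session_id))),
    class = "fcga_panel")
}

#' @exportS3Method base::print
print.fcga_panel <- function(x, ...) {
  cat(sprintf("<fcga_panel> %d measurements, %d subjects, %d x %d each\n",
              length(x$measurements),
              length(unique(x$manifest$subject)),
              nrow(x$measurements[[1]]), ncol(x$measurements[[1]])))
  invisible(x)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) from the two-way ANOVA decomposition of a subjects-by-repeats
#' table:
#' `(MS_rows - MS_err) / (MS_rows + (r - 1) MS_err + (r / s)(MS_cols - MS_err))`
#' with `s` subjects and `r` repeats. Quantifies the degree of absolute
#' agreement between single measurements.
#'
#' @param table Numeric matrix, subjects in rows, repeated measurements in
#'   columns; no missing cells.
#' @return An `fcga_icc`: `icc` plus the model tag.
#' @export
icc_absolute_agreement <- function(table) {
  x <- as.matrix(table)
  s <- nrow(x)
  r <- ncol(x)
  if (s < 2 || r < 2) {
    abort_fcga("ICC needs at least 2 subjects and 2 repeats",
               "fcga_argument_error")
  }
  if (anyNA(x)) abort_fcga("ICC table has missing cells", "fcga_value_error")
  grand <- mean(x)
  if (all(x == grand)) {
    abort_fcga("zero total variance: ICC undefined", "fcga_value_error")
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ms_rows <- r * sum((row_m - grand)^2) / (s - 1)
  ms_cols <- s * sum((col_m - grand)^2) / (r - 1)
  resid <- x - outer(row_m, rep(1, r)) - outer(rep(1, s), col_m) + grand
  ms_err <- sum(resid^2) / ((s - 1) * (r - 1))
  icc <- (ms_rows - ms_err) /
    (ms_rows + (r - 1) * ms_err + (r / s) * (ms_cols - ms_err))
  structure(
    list(icc = icc,
         model_tag = "two-way random effects, absolute agreement, single measure",
         n_subjects = s, n_repeats = r),
    class = "fcga_icc")
}

#' @exportS3Method base::print
print.fcga_icc <- function(x, ...) {
  cat(sprintf("<fcga_icc> ICC = %.4f (%s; %d subjects x %d repeats)\n",
              x$icc, x$model_tag, x$n_subjects, x$n_repeats))
  invisible(x)
}

#' @rdname icc_absolute_agreement
#' @param x An `fcga_icc`.
#' @param ... Unused.
#' @export
glance.fcga_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, n_subjects = x$n_subjects,
                 n_repeats = x$n_repeats, model = x$model_tag)
}

#' Vertex-wise ICC of one gradient across a balanced panel
#'
#' Builds the subjects-by-repeats table of coefficients at each vertex for
#' the chosen gradient and computes [icc_absolute_agreement()] per vertex.
#' Requires a balanced panel (equal repeats per subject); no imputation is
#' attempted.
#'
#' @param panel An `fcga_panel`.
#' @param gradient_index Which gradient column to evaluate.
#' @return A tibble with columns `vertex` and `icc`; the mean over
#'   vertices is attached as attribute `mean_icc`.
#' @export
vertexwise_icc <- function(panel, gradient_index = 1) {
  stopifnot(inherits(panel, "fcga_panel"))
  man <- panel$manifest
  reps <- table(man$subject)
  if (length(unique(as.vector(reps))) != 1 || reps[1] < 2) {
    abort_fcga("vertexwise ICC needs a balanced panel with >= 2 repeats per subject",
               "fcga_argument_error")
  }
  if (gradient_index > ncol(panel$measurements[[1]])) {
    abort_fcga("gradient_index exceeds the panel's gradient count",
               "fcga_argument_error")
  }
  subjects <- sort(unique(man$subject))
  r <- as.vector(reps)[1]
  n <- nrow(panel$measurements[[1]])
  # per subject, repeats ordered by session label for a reproducible table
  cols <- lapply(subjects, function(s) {
    rows <- man[man$subject == s, ]
    rows <- rows[order(rows$session), ]
    vapply(rows$measurement,
           function(i) panel$measurements[[i]][, gradient_index],
           numeric(n))
  })
  icc <- vapply(seq_len(n), function(v) {
    tab <- do.call(rbind, lapply(cols, function(m) m[v, ]))
    icc_absolute_agreement(tab)$icc
  }, numeric(1))
  out <- tibble::tibble(vertex = seq_len(n), icc = icc)
  attr(out, "mean_icc") <- mean(icc)
  attr(out, "gradient_index") <- gradient_index
  out
}

#' Discriminability of repeated measurements
#'
#' Nonparametric multivariate statistic of how reliably repeated
#' measurements of the same subject resemble each other more than
#' measurements of other subjects: for every ordered pair `(i, j)` of
#' same-subject measurements, the fraction of other-subject measurements
#' `w` with `d(i, w) > d(i, j)` (ties count one half); the statistic is the
#' mean over all such pairs. 1 means perfect identifiability, 0.5 is
#' chance.
#'
#' @param panel An `fcga_panel`; at least one subject needs >= 2
#'   measurements.
#' @param distance Distance between flattened measurements; only
#'   `"euclidean"` is implemented.
#' @return A single value in `[0, 1]`.
#' @export
discriminability <- function(panel, distance = "euclidean") {
  stopifnot(inherits(panel, "fcga_panel"))
  distance <- match.arg(distance, "euclidean")
  man <- panel$manifest
  if (max(table(man$subject)) < 2) {
    abort_fcga("discriminability needs a subject with >= 2 measurements",
               "fcga_argument_error")
  }
  flat <- do.call(rbind, lapply(panel$measurements, as.vector))
  d <- as.matrix(stats::dist(flat, method = "euclidean"))
  subj <- man$subject
  n <- nrow(d)
  fracs <- c()
  for (i in seq_len(n)) {
    same <- which(subj == subj[i] & seq_len(n) != i)
    other <- which(subj != subj[i])
    if (length(same) == 0 || length(other) == 0) next
    for (j in same) {
      gt <- sum(d[i, other] > d[i, j])
      ties <- sum(d[i, other] == d[i, j])
      fracs <- c(fracs, (gt + 0.5 * ties) / length(other))
    }
  }
  mean(fracs)
}
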