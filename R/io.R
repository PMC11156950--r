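# Readers and writers for the canonical plain-text formats, plus an adapter
# registry so neuroimaging formats (CIFTI-2 / GIFTI) can be plugged in
# behind the same interface without making them a hard dependency.

.fcga_adapters <- new.env(parent = emptyenv())

#' Register a reader adapter for an additional file format
#'
#' The canonical formats are plain delimited text (and, for time series, a
#' raw float64 binary with a JSON sidecar). Surface neuroimaging formats
#' can be attached here: an adapter is a function `(path) -> matrix` (time
#' series, vertices in rows) or `(path) -> integer vector` (parcellations),
#' keyed by file extension.
#'
#' @param kind `"timeseries"` or `"parcellation"`.
#' @param extension File extension without the dot, e.g. `"dtseries.nii"`.
#' @param reader Function taking a path and returning the raw data.
#' @export
register_reader_adapter <- function(kind = c("timeseries", "parcellation"),
                                    extension, reader) {
  kind <- match.arg(kind)
  stopifnot(is.function(reader))
  assign(paste(kind, tolower(extension), sep = "."), reader,
         envir = .fcga_adapters)
  invisible(NULL)
}

find_adapter <- function(kind, path) {
  exts <- tolower(sub("^[^.]*\\.", "", basename(path)))
  key <- paste(kind, exts, sep = ".")
  if (exists(key, envir = .fcga_adapters)) {
    get(key, envir = .fcga_adapters)
  } else {
    NULL
  }
}

read_delim_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  m <- tryCatch(
    as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                comment.char = "#",
                                colClasses = "numeric")),
    error = function(e) {
      abort_fcga(
        sprintf("'%s' is not a numeric delimited matrix: %s",
                path, conditionMessage(e)),
        "fcga_format_error")
    })
  dimnames(m) <- NULL
  m
}

write_delim_matrix <- function(m, path, col_names = NULL, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  if (!is.null(col_names)) writeLines(paste(col_names, collapse = "\t"), con)
  # %.17g keeps doubles bit-exact through the round-trip
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
}

#' Read a dense functional time-series matrix
#'
#' Canonical formats: tab/comma/space delimited text (`.tsv`, `.csv`,
#' `.txt`) and a raw little-endian float64 binary (`.bin`) with a JSON
#' sidecar (`<path>.json` holding `n_vertices`, `n_timepoints`). Other
#' extensions are dispatched to adapters registered with
#' [register_reader_adapter()].
#'
#' Rows are vertices, columns timepoints. For a non-square matrix stored
#' the other way round, pass `format_hint = "timepoints-by-vertices"`. A
#' square matrix is orientation-ambiguous and requires an explicit hint —
#' the reader never silently transposes.
#'
#' @param path File to read.
#' @param format_hint `"vertices-by-timepoints"` (default) or
#'   `"timepoints-by-vertices"`.
#' @param space_tag Spatial reference label attached to the result.
#' @return An [time_series_matrix()] object.
#' @export
read_timeseries <- function(path, format_hint = NULL,
                            space_tag = "unspecified") {
  if (!file.exists(path)) {
    abort_fcga(sprintf("file not found: %s", path), "fcga_io_error")
  }
  adapter <- find_adapter("timeseries", path)
  m <- if (!is.null(adapter)) {
    as.matrix(adapter(path))
  } else if (grepl("\\.bin$", path)) {
    read_binary_matrix(path)
  } else {
    read_delim_matrix(path)
  }
  if (ncol(m) == nrow(m) && is.null(format_hint)) {
    abort_fcga(
      "square matrix: orientation is ambiguous, pass format_hint explicitly",
      "fcga_format_error")
  }
  hint <- format_hint %||% "vertices-by-timepoints"
  hint <- match.arg(hint, c("vertices-by-timepoints", "timepoints-by-vertices"))
  if (hint == "timepoints-by-vertices") m <- t(m)
  if (ncol(m) < 3) {
    abort_fcga(sprintf("time series has %d timepoints, need >= 3", ncol(m)),
               "fcga_dimension_error")
  }
  time_series_matrix(m, space_tag = space_tag)
}

read_binary_matrix <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort_fcga(sprintf("binary matrix needs a JSON sidecar at %s", sidecar),
               "fcga_format_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- as.integer(meta$n_vertices)
  t <- as.integer(meta$n_timepoints)
  v <- readBin(path, what = "double", n = n * t, size = 8, endian = "little")
  # vertex-major: one vertex's full time course is contiguous
  matrix(v, nrow = n, ncol = t, byrow = TRUE)
}

#' Write a time-series matrix (delimited text or binary + sidecar)
#'
#' @param ts An `fcga_timeseries`.
#' @param path Destination; `.bin` selects the binary format.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "fcga_timeseries"))
  if (grepl("\\.bin$", path)) {
    writeBin(as.vector(t(ts$values)), path, size = 8, endian = "little")
    jsonlite::write_json(
      list(n_vertices = nrow(ts$values), n_timepoints = ncol(ts$values),
           dtype = "float64", order = "vertex-major",
           space_tag = ts$space_tag),
      paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    write_delim_matrix(ts$values, path)
  }
  invisible(path)
}

#' Read a parcellation label map (integer labels, one per vertex)
#'
#' @param path A one-column (or one-row) integer text file; other
#'   extensions dispatch to registered adapters.
#' @param space_tag Spatial reference label.
#' @return An [parcellation_map()] object.
#' @export
read_parcellation <- function(path, space_tag = "unspecified") {
  if (!file.exists(path)) {
    abort_fcga(sprintf("file not found: %s", path), "fcga_io_error")
  }
  adapter <- find_adapter("parcellation", path)
  labels <- if (!is.null(adapter)) {
    adapter(path)
  } else {
    m <- read_delim_matrix(path)
    if (nrow(m) == 1) m <- t(m)
    if (ncol(m) != 1) {
      abort_fcga("a parcellation file must hold a single label vector",
                 "fcga_format_error")
    }
    m[, 1]
  }
  parcellation_map(labels, space_tag = space_tag)
}

#' Write a parcellation label map as integer text
#'
#' @param p An `fcga_parcellation`.
#' @param path Destination file.
#' @export
write_parcellation <- function(p, path) {
  stopifnot(inherits(p, "fcga_parcellation"))
  writeLines(as.character(p$labels), path)
  invisible(path)
}

#' Write a gradient set to the canonical TSV format
#'
#' Coefficients are stored as a TSV with header `gradient_1..gradient_g`;
#' explained variance and the provenance record travel in `#` comment lines
#' so that the file round-trips through [read_gradients()] bit-exactly.
#'
#' @param g An `fcga_gradients` object.
#' @param path Destination file.
#' @param format_hint Unused for the canonical format; reserved for
#'   adapters.
#' @export
write_gradients <- function(g, path, format_hint = NULL) {
  stopifnot(inherits(g, "fcga_gradients"))
  meta <- c(
    paste0("explained_variance_ratio\t",
           paste(sprintf("%.17g", g$explained_variance_ratio),
                 collapse = "\t")),
    paste0("provenance\t",
           jsonlite::toJSON(g$provenance, auto_unbox = TRUE, digits = NA)))
  write_delim_matrix(
    g$coefficients, path,
    col_names = paste0("gradient_", seq_len(ncol(g$coefficients))),
    comments = meta)
  invisible(path)
}

#' Read a gradient set written by [write_gradients()]
#'
#' @param path File to read.
#' @return An `fcga_gradients` object.
#' @export
read_gradients <- function(path) {
  if (!file.exists(path)) {
    abort_fcga(sprintf("file not found: %s", path), "fcga_io_error")
  }
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  if (length(body) < 2 || !grepl("^gradient_1(\t|$)", body[1])) {
    abort_fcga(sprintf("'%s' is not a gradient TSV (missing header)", path),
               "fcga_format_error")
  }
  coef <- do.call(rbind, lapply(body[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  evr_line <- grep("^# explained_variance_ratio\t", lines, value = TRUE)
  evr <- if (length(evr_line) == 1) {
    as.numeric(strsplit(sub("^# explained_variance_ratio\t", "", evr_line),
                        "\t", fixed = TRUE)[[1]])
  } else {
    rep(NA_real_, ncol(coef))
  }
  prov_line <- grep("^# provenance\t", lines, value = TRUE)
  prov <- if (length(prov_line) == 1) {
    jsonlite::fromJSON(sub("^# provenance\t", "", prov_line),
                       simplifyVector = TRUE)
  } else {
    list()
  }
  gradient_set(coef, evr, provenance = as.list(prov))
}
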