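#' Coerce a data frame to the canonical marker-matrix layout
#'
#' The canonical layout used throughout the package is a tibble with a
#' character `sample_id` column, a `class` factor with levels
#' `c("control", "case")`, and one numeric column per marker (log10
#' fluorescence units). `as_marker_matrix()` maps arbitrary column names and
#' class tokens onto that layout.
#'
#' @param x A data frame with one row per sample.
#' @param sample_col Name of the sample-identifier column. `NULL` generates
#'   ids `S1, S2, ...`.
#' @param label_col Name of the class-label column.
#' @param case,control Tokens in `label_col` denoting cases and controls.
#' @return A tibble in canonical layout: `sample_id`, `class`, then one
#'   numeric column per marker.
#' @examples
#' df <- data.frame(id = c("a", "b"), grp = c("PC", "healthy"),
#'                  M1 = c(2.5, 1.8), M2 = c(3.0, 2.1))
#' as_marker_matrix(df, sample_col = "id", label_col = "grp",
#'                  case = "PC", control = "healthy")
#' @export
as_marker_matrix <- function(x, sample_col = "sample_id",
                             label_col = "class",
                             case = "case", control = "control") {
  x <- tibble::as_tibble(x)
  if (!label_col %in% names(x)) {
    abort(paste0("label column '", label_col, "' not found"))
  }
  lab <- as.character(x[[label_col]])
  bad <- !lab %in% c(case, control)
  if (any(bad)) {
    abort(paste0("labels other than '", case, "'/'", control, "' found: ",
                 paste(unique(lab[bad]), collapse = ", ")))
  }
  cls <- factor(ifelse(lab == case, "case", "control"),
                levels = c("control", "case"))
  if (all(table(cls) == 0) || length(unique(cls)) < 2L) {
    abort("both classes must be present")
  }
  if (is.null(sample_col)) {
    sid <- paste0("S", seq_len(nrow(x)))
    drop <- label_col
  } else {
    if (!sample_col %in% names(x)) {
      abort(paste0("sample column '", sample_col, "' not found"))
    }
    sid <- as.character(x[[sample_col]])
    drop <- c(sample_col, label_col)
  }
  if (anyDuplicated(sid)) abort("sample ids must be unique")
  vals <- x[setdiff(names(x), drop)]
  if (ncol(vals) < 1L) abort("no marker columns found")
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("all marker columns must be numeric")
  }
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1)))) {
    abort("marker values must be finite")
  }
  dplyr::bind_cols(tibble::tibble(sample_id = sid, class = cls), vals)
}

#' Marker column names of a canonical marker matrix
#' @param data A canonical marker matrix (see [as_marker_matrix()]).
#' @return Character vector of marker column names.
#' @export
marker_cols <- function(data) {
  setdiff(names(data), c("sample_id", "class"))
}

#' Read / write a marker matrix as delimited text
#'
#' Files are tab-delimited by default (comma accepted on read via `delim`),
#' with one row per sample: a sample-id column, a class-label column, and
#' one column per marker.
#'
#' @inheritParams as_marker_matrix
#' @param path File path.
#' @param delim Field delimiter.
#' @return `read_marker_matrix()` returns a canonical marker matrix tibble;
#'   `write_marker_matrix()` returns `path` invisibly.
#' @export
read_marker_matrix <- function(path, sample_col = "sample_id",
                               label_col = "class", case = "case",
                               control = "control", delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  as_marker_matrix(x, sample_col = sample_col, label_col = label_col,
                   case = case, control = control)
}

#' @rdname read_marker_matrix
#' @param data A canonical marker matrix.
#' @export
write_marker_matrix <- function(data, path, delim = "\t") {
  out <- data
  out$class <- as.character(out$class)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
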