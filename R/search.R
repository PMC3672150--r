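#' Enumerate marker combinations for panels of size n
#'
#' @param marker_ids Character vector of available markers.
#' @param n Panel size.
#' @return Character matrix with one row per unordered combination, columns
#'   `marker_1..marker_n`, in deterministic (combinatorial) order.
#' @examples
#' enumerate_panels(c("A", "B", "C", "D"), 2)  # 6 combinations
#' @export
enumerate_panels <- function(marker_ids, n) {
  if (n < 1 || n > length(marker_ids)) {
    abort("panel size must be between 1 and the number of markers")
  }
  out <- t(combn(marker_ids, n))
  colnames(out) <- paste0("marker_", seq_len(n))
  out
}

#' Exhaustive full-train search over panels and thresholds
#'
#' For every combination of `panel_size` markers and every element of the
#' Cartesian product of the per-marker threshold grids, state rules are
#' learned on all samples by per-state majority vote and the panel is
#' scored; panels meeting both performance cutoffs are retained. The best
#' combination overall (by correct calls, ties broken toward specificity,
#' then earliest in lexicographic grid order) is tracked regardless of the
#' cutoffs.
#'
#' @inheritParams assign_states
#' @param step Threshold spacing (log10 units).
#' @param panel_size Number of markers per panel.
#' @param min_sensitivity,min_specificity Retention cutoffs in `[0, 1]`.
#' @param range,global_range Grid construction mode, see
#'   [threshold_grids()].
#' @param grids Optional pre-built named list of grids (overrides `step`
#'   and `range`); must cover every marker column used.
#' @param markers Markers to search over (default: all marker columns).
#' @return An object of class `mss_fit`: a list with `panels` (tibble of
#'   retained panels, sorted lexicographically by marker ids then
#'   thresholds), `best` (one-row tibble), `grids`, and `config`.
#' @examples
#' sim <- simulate_markers(n_case = 40, n_control = 40, n_markers = 4,
#'                         seed = 1)
#' fit <- full_train(sim$data, step = 0.5, panel_size = 3,
#'                   min_sensitivity = 0.9, min_specificity = 0.9)
#' glance(fit)
#' @export
full_train <- function(data, step = 0.2, panel_size = 3,
                       min_sensitivity = 0.8, min_specificity = 0.8,
                       range = c("per_marker", "global"),
                       global_range = NULL, grids = NULL,
                       markers = marker_cols(data)) {
  range <- match.arg(range)
  if (length(markers) < 2L) abort("at least two markers required")
  if (min_sensitivity < 0 || min_sensitivity > 1 ||
      min_specificity < 0 || min_specificity > 1) {
    abort("cutoffs must lie in [0, 1]")
  }
  cls <- as.character(data$class)
  if (!any(cls == "case") || !any(cls == "control")) {
    abort("both classes must be present")
  }
  if (is.null(grids)) {
    grids <- threshold_grids(data, step, markers = markers, range = range,
                             global_range = global_range)
  }
  is_case <- as.integer(cls == "case")
  bits_all <- lapply(markers, function(m) {
    g <- grids[[m]]
    matrix(as.integer(outer(data[[m]], g, ">")), nrow = nrow(data))
  })
  names(bits_all) <- markers
  combos <- enumerate_panels(markers, panel_size)
  acc <- vector("list", nrow(combos))
  best <- NULL
  best_key <- c(-1L, -1L)
  for (ci in seq_len(nrow(combos))) {
    mk <- combos[ci, ]
    res <- cpp_scan_combo(bits_all[mk], is_case, min_sensitivity,
                          min_specificity)
    if (nrow(res$retained) > 0L) {
      thr <- vapply(seq_along(mk), function(j) {
        grids[[mk[j]]][res$retained[, j]]
      }, numeric(nrow(res$retained)))
      thr <- matrix(thr, nrow = nrow(res$retained))
      row <- tibble::as_tibble(
        setNames(as.data.frame(matrix(rep(mk, each = nrow(thr)),
                                      ncol = length(mk)),
                 stringsAsFactors = FALSE),
                 paste0("marker_", seq_along(mk))))
      for (j in seq_along(mk)) row[[paste0("threshold_", j)]] <- thr[, j]
      cnt <- res$counts
      row <- dplyr::bind_cols(row, performance_record(
        tp = cnt[, 1], fp = cnt[, 2], tn = cnt[, 3], fn = cnt[, 4]))
      acc[[ci]] <- row
    }
    bc <- res$best_counts
    key <- c(bc[1] + bc[3], bc[3])
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best_key <- key
      bthr <- vapply(seq_along(mk), function(j) grids[[mk[j]]][res$best_idx[j]],
                     numeric(1))
      best <- dplyr::bind_cols(
        tibble::as_tibble(as.list(setNames(mk, paste0("marker_",
                                                      seq_along(mk))))),
        tibble::as_tibble(as.list(setNames(bthr, paste0("threshold_",
                                                        seq_along(mk))))),
        performance_record(bc[1], bc[2], bc[3], bc[4]))
    }
  }
  panels <- dplyr::bind_rows(acc)
  if (nrow(panels) > 0L) {
    ord <- do.call(order, as.list(panels[, c(paste0("marker_",
                                                    seq_len(panel_size)),
                                             paste0("threshold_",
                                                    seq_len(panel_size)))]))
    panels <- panels[ord, ]
  }
  structure(
    list(panels = panels, best = best, grids = grids,
         config = list(step = step, panel_size = panel_size,
                       min_sensitivity = min_sensitivity,
                       min_specificity = min_specificity,
                       range = range, markers = markers),
         n_samples = nrow(data), n_case = sum(is_case)),
    class = "mss_fit")
}

#' @export
print.mss_fit <- function(x, ...) {
  cat("MSS full train:", nrow(x$panels), "panel(s) retained at cutoffs",
      "sens >=", x$config$min_sensitivity,
      "/ spec >=", x$config$min_specificity, "\n")
  cat("Searched", choose(length(x$config$markers), x$config$panel_size),
      "marker combinations of size", x$config$panel_size,
      "at step", x$config$step, "\n")
  if (!is.null(x$best)) {
    cat("Best combination: accuracy",
        sprintf("%.1f%%", 100 * x$best$accuracy), "\n")
  }
  invisible(x)
}

#' @describeIn full_train Retained panels as a tibble.
#' @param x An `mss_fit`.
#' @param ... Unused.
#' @export
tidy.mss_fit <- function(x, ...) x$panels

#' @describeIn full_train One-row summary (panels retained, combinations
#'   searched, best accuracy).
#' @export
glance.mss_fit <- function(x, ...) {
  tibble::tibble(
    n_panels = nrow(x$panels),
    n_combinations = choose(length(x$config$markers), x$config$panel_size),
    panel_size = x$config$panel_size,
    step = x$config$step,
    best_accuracy = if (is.null(x$best)) NA_real_ else x$best$accuracy,
    best_sensitivity = if (is.null(x$best)) NA_real_ else x$best$sensitivity,
    best_specificity = if (is.null(x$best)) NA_real_ else x$best$specificity)
}
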