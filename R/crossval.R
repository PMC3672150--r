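#' Randomly divide samples into k cross-validation splits
#'
#' Samples are shuffled under the given seed and dealt into `k` groups whose
#' sizes differ by at most one. With `stratified = TRUE` the dealing is done
#' within each class, keeping class proportions as equal as possible per
#' split; the default is plain random division.
#'
#' @inheritParams assign_states
#' @param k Number of splits (default 10).
#' @param seed Integer seed; required so plans are reproducible.
#' @param stratified Stratify the division by class?
#' @return A tibble with `sample_id` and `split` columns (attributes `k`,
#'   `seed`, `stratified`).
#' @export
make_splits <- function(data, k = 10, seed, stratified = FALSE) {
  if (k > nrow(data)) abort("k must not exceed the number of samples")
  if (missing(seed) || is.null(seed)) abort("a seed is required")
  assignment <- withr::with_seed(as.integer(seed), {
    if (stratified) {
      split_idx <- integer(nrow(data))
      for (cl in levels(data$class)) {
        rows <- which(data$class == cl)
        split_idx[sample(rows)] <- rep_len(seq_len(k), length(rows))
      }
      split_idx
    } else {
      sizes <- rep(nrow(data) %/% k, k) +
        as.integer(seq_len(k) <= nrow(data) %% k)
      rep(seq_len(k), times = sizes)[order(sample.int(nrow(data)))]
    }
  })
  structure(tibble::tibble(sample_id = data$sample_id, split = assignment),
            k = as.integer(k), seed = as.integer(seed),
            stratified = stratified)
}

#' Cross-validate the retained panels of a full train
#'
#' For each split, rules for every retained panel are re-learned on the
#' other k-1 splits (at the panel's own thresholds, which come from the
#' full-train grids); panels whose training-portion sensitivity and
#' specificity meet the full-train cutoffs are applied to the held-out
#' split and the held-out accuracy recorded, otherwise the split cell is
#' missing (reported as `N/A` in the final report). Averages are taken over
#' non-missing splits only.
#'
#' With `headline = TRUE`, an exhaustive scan is additionally run on each
#' split's training portion (same grids) and the best training panel (ties
#' broken toward specificity, then lexicographic thresholds) is applied to
#' the held-out split; the mean of those ten held-out accuracies is the
#' single cross-validation accuracy quoted for the method.
#'
#' @inheritParams assign_states
#' @param fit An `mss_fit` from [full_train()] on the same data.
#' @param plan A split plan from [make_splits()].
#' @param headline Also compute the per-split best-panel held-out accuracy?
#' @return An object of class `mss_cv`: list with `results` (retained
#'   panels plus `split_1..split_k` accuracy columns and `avg_accuracy`),
#'   `headline` (per-split tibble or `NULL`), `plan`, `config`.
#' @export
cv_run <- function(data, fit, plan, headline = TRUE) {
  k <- attr(plan, "k")
  if (!identical(sort(plan$sample_id), sort(data$sample_id))) {
    abort("split plan does not cover the data's samples")
  }
  split_of <- plan$split[match(data$sample_id, plan$sample_id)]
  is_case <- as.integer(as.character(data$class) == "case")
  # flag degenerate splits (a class absent from the training portion)
  degenerate <- vapply(seq_len(k), function(f) {
    tr <- split_of != f
    sum(is_case[tr]) == 0L || sum(1L - is_case[tr]) == 0L
  }, logical(1))
  if (any(degenerate)) {
    warning("split(s) ", paste(which(degenerate), collapse = ", "),
            " have a class absent from the training portion; reported as ",
            "missing", call. = FALSE)
  }
  n <- fit$config$panel_size
  panels <- fit$panels
  mk_cols <- paste0("marker_", seq_len(n))
  th_cols <- paste0("threshold_", seq_len(n))
  split_cols <- paste0("split_", seq_len(k))
  if (nrow(panels) > 0L) {
    accs <- matrix(NA_real_, nrow(panels), k)
    for (p in seq_len(nrow(panels))) {
      mk <- unlist(panels[p, mk_cols], use.names = FALSE)
      th <- unlist(panels[p, th_cols], use.names = FALSE)
      bits <- vapply(seq_len(n), function(j) {
        as.integer(data[[mk[j]]] > th[j])
      }, integer(nrow(data)))
      st <- encode_state(matrix(bits, nrow = nrow(data))) - 1L
      a <- cpp_panel_cv(st, is_case, split_of, k, n,
                        fit$config$min_sensitivity,
                        fit$config$min_specificity)
      a[degenerate] <- NA_real_
      accs[p, ] <- a
    }
    colnames(accs) <- split_cols
    results <- dplyr::bind_cols(panels, tibble::as_tibble(accs))
    results$avg_accuracy <- rowMeans(accs, na.rm = TRUE)
    results$avg_accuracy[is.nan(results$avg_accuracy)] <- NA_real_
    results$n_splits_present <- rowSums(!is.na(accs))
  } else {
    results <- panels
  }
  head_tbl <- NULL
  if (headline) {
    markers <- fit$config$markers
    bits_all <- lapply(markers, function(m) {
      g <- fit$grids[[m]]
      matrix(as.integer(outer(data[[m]], g, ">")), nrow = nrow(data))
    })
    names(bits_all) <- markers
    combos <- enumerate_panels(markers, n)
    rows <- purrr::map(seq_len(k), function(f) {
      if (degenerate[f]) {
        return(tibble::tibble(split = f, train_accuracy = NA_real_,
                              test_accuracy = NA_real_))
      }
      tr <- which(split_of != f)
      te <- which(split_of == f)
      best <- NULL
      best_key <- c(-1L, -1L)
      for (ci in seq_len(nrow(combos))) {
        mk <- combos[ci, ]
        res <- cpp_scan_combo(lapply(bits_all[mk], function(b) {
          b[tr, , drop = FALSE]
        }), is_case[tr], 2, 2)  # cutoffs > 1: track the best only
        bc <- res$best_counts
        key <- c(bc[1] + bc[3], bc[3])
        if (key[1] > best_key[1] ||
            (key[1] == best_key[1] && key[2] > best_key[2])) {
          best_key <- key
          best <- list(mk = mk, thr = vapply(seq_len(n), function(j) {
            fit$grids[[mk[j]]][res$best_idx[j]]
          }, numeric(1)), counts = bc)
        }
      }
      rules <- learn_state_rules(data[tr, ], best$mk, best$thr)
      pred <- classify_samples(data[te, ], rules)
      out <- tibble::tibble(split = f)
      for (j in seq_len(n)) out[[mk_cols[j]]] <- best$mk[j]
      for (j in seq_len(n)) out[[th_cols[j]]] <- best$thr[j]
      out$train_accuracy <- (best$counts[1] + best$counts[3]) / length(tr)
      out$test_accuracy <-
        mean(as.character(pred$class) == pred$.class_pred)
      out
    })
    head_tbl <- dplyr::bind_rows(rows)
  }
  structure(list(results = results, headline = head_tbl, plan = plan,
                 config = fit$config, k = k),
            class = "mss_cv")
}

#' @export
print.mss_cv <- function(x, ...) {
  cat("MSS", x$k, "fold cross-validation:", nrow(x$results),
      "retained panel(s)\n")
  if (!is.null(x$headline)) {
    cat("Cross-validation accuracy (best training panel per split):",
        sprintf("%.1f%%", 100 * mean(x$headline$test_accuracy, na.rm = TRUE)),
        "\n")
  }
  invisible(x)
}

#' @describeIn cv_run Per-panel per-split accuracies in long format
#'   (`NA` = the panel missed the cutoffs in that split).
#' @param x An `mss_cv`.
#' @param ... Unused.
#' @export
tidy.mss_cv <- function(x, ...) {
  if (nrow(x$results) == 0L) return(x$results)
  tidyr::pivot_longer(x$results, dplyr::starts_with("split_"),
                      names_to = "split", names_prefix = "split_",
                      names_transform = as.integer,
                      values_to = "split_accuracy")
}

#' @describeIn cv_run One-row summary including the headline
#'   cross-validation accuracy (when computed).
#' @export
glance.mss_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_panels = nrow(x$results),
    cv_accuracy = if (is.null(x$headline)) NA_real_ else
      mean(x$headline$test_accuracy, na.rm = TRUE),
    mean_avg_accuracy = if (nrow(x$results) > 0L)
      mean(x$results$avg_accuracy, na.rm = TRUE) else NA_real_)
}

#' Trim a cross-validation report to the top panels of any split
#'
#' Keeps every panel whose held-out accuracy reaches the best or
#' second-best distinct accuracy value attained in at least one split.
#' Reading "first or second best" as distinct accuracy levels keeps the
#' trim well defined when many panels tie on a coarse grid.
#'
#' @param cv An `mss_cv` from [cv_run()].
#' @return The subset of `cv$results` rows that qualify.
#' @export
trim_top_panels <- function(cv) {
  results <- cv$results
  if (nrow(results) == 0L) abort("no retained panels to trim")
  split_cols <- paste0("split_", seq_len(cv$k))
  keep <- rep(FALSE, nrow(results))
  for (sc in split_cols) {
    a <- results[[sc]]
    lv <- sort(unique(a[!is.na(a)]), decreasing = TRUE)
    if (length(lv) == 0L) next
    top2 <- lv[seq_len(min(2L, length(lv)))]
    keep <- keep | (!is.na(a) & a %in% top2)
  }
  results[keep, ]
}

panel_combo_key <- function(df, n) {
  mk <- as.matrix(df[paste0("marker_", seq_len(n))])
  apply(mk, 1, function(r) paste(sort(r), collapse = " + "))
}

#' Robustness summary of the trimmed top-panel list
#'
#' Groups the trimmed panels by unordered marker combination. The number of
#' distinct threshold settings at which a combination appears
#' (`variant_count`) measures insensitivity to threshold placement; the
#' mean over variants of each variant's average split accuracy
#' (`mean_split_accuracy`) measures held-out performance.
#'
#' @param trimmed Output of [trim_top_panels()].
#' @return A tibble with `combo`, `variant_count`, `mean_split_accuracy`,
#'   sorted by the selection order (count, then accuracy, then combo).
#' @export
summarize_robustness <- function(trimmed) {
  if (nrow(trimmed) == 0L) abort("empty trimmed list")
  n <- sum(grepl("^marker_", names(trimmed)))
  trimmed |>
    dplyr::mutate(combo = panel_combo_key(trimmed, n)) |>
    dplyr::group_by(.data$combo) |>
    dplyr::summarise(variant_count = dplyr::n(),
                     mean_split_accuracy = mean(.data$avg_accuracy,
                                                na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$variant_count),
                   dplyr::desc(.data$mean_split_accuracy), .data$combo)
}

#' Select the most robust marker combination
#'
#' Ranks combinations by `variant_count` (descending), breaking ties by
#' `mean_split_accuracy` (descending) and then lexicographically by marker
#' ids, and returns the winner's markers.
#'
#' @param summary Output of [summarize_robustness()].
#' @return Character vector of the selected combination's marker ids.
#' @export
select_robust_panel <- function(summary) {
  if (nrow(summary) == 0L) abort("empty robustness summary")
  strsplit(summary$combo[1], " \\+ ")[[1]]
}

#' Finalize a marker combination on the full data
#'
#' Re-scans every threshold combination for the fixed markers on all
#' samples and returns the best panel by accuracy, ties broken by higher
#' specificity and then lexicographically earlier thresholds, together with
#' its learned state rules and performance.
#'
#' @inheritParams full_train
#' @param markers The marker combination to finalize.
#' @param fit Optional `mss_fit` whose grids and cutoff configuration are
#'   reused; otherwise grids are built from `step`/`range`.
#' @return An object of class `mss_panel`: list with `markers`,
#'   `thresholds`, `rules`, `performance`.
#' @export
finalize_panel <- function(data, markers, fit = NULL, step = 0.2,
                           range = c("per_marker", "global"),
                           global_range = NULL) {
  range <- match.arg(range)
  grids <- if (!is.null(fit)) fit$grids else
    threshold_grids(data, step, markers = markers, range = range,
                    global_range = global_range)
  is_case <- as.integer(as.character(data$class) == "case")
  bits <- lapply(markers, function(m) {
    matrix(as.integer(outer(data[[m]], grids[[m]], ">")), nrow = nrow(data))
  })
  res <- cpp_scan_combo(bits, is_case, 2, 2)  # track the best only
  thr <- vapply(seq_along(markers), function(j) {
    grids[[markers[j]]][res$best_idx[j]]
  }, numeric(1))
  rules <- learn_state_rules(data, markers, thr)
  structure(list(markers = markers, thresholds = setNames(thr, markers),
                 rules = rules,
                 performance = evaluate_panel(data, rules)),
            class = "mss_panel")
}

#' @export
print.mss_panel <- function(x, ...) {
  cat("MSS panel:", paste(x$markers, collapse = ", "), "\n")
  cat("Thresholds:", paste(format(x$thresholds), collapse = ", "), "\n")
  p <- x$performance
  cat(sprintf("Sensitivity %.1f%% / specificity %.1f%% / accuracy %.1f%%\n",
              100 * p$sensitivity, 100 * p$specificity, 100 * p$accuracy))
  invisible(x)
}

#' @describeIn finalize_panel The panel's state rules as a tibble.
#' @param x An `mss_panel`.
#' @param ... Unused.
#' @export
tidy.mss_panel <- function(x, ...) tibble::as_tibble(x$rules)

#' @describeIn finalize_panel One-row performance summary.
#' @export
glance.mss_panel <- function(x, ...) x$performance
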