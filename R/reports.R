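fmt_pct <- function(x) ifelse(is.na(x), "N/A", sprintf("%.1f", 100 * x))

#' Write / read the final cross-validation report
#'
#' One row per retained panel: markers, thresholds, full-train sensitivity
#' and specificity, held-out accuracy in each split (`N/A` where the panel
#' missed the cutoffs in that split's training portion), and the average
#' accuracy over non-missing splits. Performance is printed as percentages
#' at one decimal; rows are sorted by average accuracy (descending), ties
#' broken lexicographically by markers then thresholds, so re-running on
#' identical inputs yields a byte-identical file.
#'
#' @param cv An `mss_cv` from [cv_run()].
#' @param path Output file path.
#' @return `write_final_report()` returns `path` invisibly;
#'   `read_final_report()` returns a tibble with accuracies back on the
#'   `[0, 1]` scale (`NA` for `N/A` cells).
#' @export
write_final_report <- function(cv, path) {
  k <- cv$k
  n <- cv$config$panel_size
  mk_cols <- paste0("marker_", seq_len(n))
  th_cols <- paste0("threshold_", seq_len(n))
  split_cols <- paste0("split_", seq_len(k))
  res <- cv$results
  lines <- c("# mss final report v1",
             paste(c(mk_cols, th_cols, "sensitivity", "specificity",
                     split_cols, "avg_accuracy"), collapse = "\t"))
  if (nrow(res) > 0L) {
    ord <- do.call(order, c(list(-res$avg_accuracy),
                            as.list(res[c(mk_cols, th_cols)])))
    res <- res[ord, ]
    body <- vapply(seq_len(nrow(res)), function(i) {
      paste(c(unlist(res[i, mk_cols], use.names = FALSE),
              format_threshold(unlist(res[i, th_cols], use.names = FALSE)),
              fmt_pct(res$sensitivity[i]), fmt_pct(res$specificity[i]),
              fmt_pct(unlist(res[i, split_cols], use.names = FALSE)),
              fmt_pct(res$avg_accuracy[i])),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

format_threshold <- function(x) {
  s <- sub("0+$", "", sprintf("%.6f", x))
  ifelse(grepl("\\.$", s), paste0(s, "0"), s)
}

#' @rdname write_final_report
#' @export
read_final_report <- function(path) {
  x <- readr::read_tsv(path, comment = "#", na = "N/A",
                       show_col_types = FALSE, progress = FALSE)
  for (nm in grep("^(split_|sensitivity|specificity|avg_accuracy)",
                  names(x), value = TRUE)) {
    x[[nm]] <- as.numeric(x[[nm]]) / 100
  }
  x
}

#' Write / read the detailed rules report
#'
#' For each panel, one block of 2^n state rows in state-index order: bit
#' pattern, assigned class, case/control occupancy counts, and the ids of
#' the samples populating the state (unoccupied states appear with zero
#' counts and their inferred class).
#'
#' @param data A canonical marker matrix (used to list state members).
#' @param panels A list of `mss_panel` objects (see [finalize_panel()]), or
#'   a single `mss_panel`.
#' @param path Output file path.
#' @return `write_detailed_report()` returns `path` invisibly;
#'   `read_detailed_report()` returns a tibble with one row per panel ×
#'   state.
#' @export
write_detailed_report <- function(data, panels, path) {
  if (inherits(panels, "mss_panel")) panels <- list(panels)
  lines <- c("# mss detailed report v1")
  for (p in panels) {
    st <- assign_states(data, p$markers, unname(p$thresholds))
    lines <- c(lines,
               paste0("## panel\t", paste(p$markers, collapse = "\t"),
                      "\t", paste(format_threshold(unname(p$thresholds)),
                                  collapse = "\t")),
               paste(c("state", "pattern", "class", "case_n", "control_n",
                       "samples"), collapse = "\t"))
    for (s in seq_len(nrow(p$rules))) {
      members <- st$sample_id[st$state == s]
      lines <- c(lines, paste(c(
        s, p$rules$pattern[s], p$rules$class[s],
        sum(st$state == s & as.character(st$class) == "case"),
        sum(st$state == s & as.character(st$class) == "control"),
        paste(members, collapse = ",")), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_detailed_report
#' @export
read_detailed_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines)]
  starts <- grep("^## panel\t", lines)
  out <- purrr::map(seq_along(starts), function(b) {
    head_parts <- strsplit(lines[starts[b]], "\t")[[1]][-1]
    n <- length(head_parts) / 2
    mk <- head_parts[seq_len(n)]
    th <- as.numeric(head_parts[n + seq_len(n)])
    end <- if (b < length(starts)) starts[b + 1] - 1L else length(lines)
    body <- lines[(starts[b] + 2L):end]
    rows <- strsplit(body, "\t")
    tibble::tibble(
      block = b,
      panel = paste(mk, collapse = " + "),
      markers = list(mk), thresholds = list(th),
      state = vapply(rows, function(r) as.integer(r[1]), integer(1)),
      pattern = vapply(rows, function(r) r[2], character(1)),
      class = vapply(rows, function(r) r[3], character(1)),
      case_n = vapply(rows, function(r) as.integer(r[4]), integer(1)),
      control_n = vapply(rows, function(r) as.integer(r[5]), integer(1)),
      samples = lapply(rows, function(r) {
        if (length(r) < 6L || r[6] == "") character(0)
        else strsplit(r[6], ",")[[1]]
      }))
  })
  dplyr::bind_rows(out)
}

#' State-occupancy summary by class (and optional subgroup)
#'
#' For each class, the percentage of that class's samples occupying each
#' state — the tabular form of the training/test occupancy bar charts. When
#' a subgroup column is supplied (e.g. healthy / pancreatitis within
#' controls, early / late stage within cases), rows are further broken down
#' by subgroup, still as percentages of the class, so each class's rows sum
#' to 100.
#'
#' @inheritParams assign_states
#' @param subgroup Optional name of a column in `data` giving a per-sample
#'   subgroup.
#' @return A tibble with `class`, `state`, `pattern`, optionally
#'   `subgroup`, `n` and `pct` columns; every state appears for every class
#'   (zero-occupancy rows included).
#' @export
summarize_occupancy <- function(data, markers, thresholds, subgroup = NULL) {
  st <- assign_states(data, markers, thresholds)
  n <- length(markers)
  n_states <- as.integer(state_space_size(n))
  if (!is.null(subgroup)) st$subgroup <- as.character(data[[subgroup]])
  grp <- c("class", "state", if (!is.null(subgroup)) "subgroup")
  counts <- st |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), name = "n")
  full <- tidyr::expand_grid(class = levels(st$class),
                             state = seq_len(n_states))
  counts <- dplyr::left_join(full, counts, by = c("class", "state"))
  counts$n[is.na(counts$n)] <- 0L
  class_tot <- table(st$class)
  counts$pct <- 100 * counts$n / as.numeric(class_tot[counts$class])
  counts$pattern <- state_pattern(counts$state, n)
  cols <- c("class", "state", "pattern", if (!is.null(subgroup)) "subgroup",
            "n", "pct")
  tibble::as_tibble(counts[cols])
}

#' Save / load a panel as structured text
#'
#' Serializes a panel (markers, thresholds and full rule set) so that new
#' samples can be classified later without retraining.
#'
#' @param panel An `mss_panel`.
#' @param path File path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   an `mss_panel`.
#' @export
write_panel <- function(panel, path) {
  lines <- c("# mss panel v1",
             paste0("markers\t", paste(panel$markers, collapse = "\t")),
             paste0("thresholds\t",
                    paste(format_threshold(unname(panel$thresholds)),
                          collapse = "\t")),
             "state\tpattern\tcase_n\tcontrol_n\tclass\tsource")
  r <- panel$rules
  lines <- c(lines, vapply(seq_len(nrow(r)), function(s) {
    paste(c(r$state[s], r$pattern[s], r$case_n[s], r$control_n[s],
            r$class[s], r$source[s]), collapse = "\t")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines)]
  markers <- strsplit(lines[1], "\t")[[1]][-1]
  thresholds <- as.numeric(strsplit(lines[2], "\t")[[1]][-1])
  rows <- strsplit(lines[-(1:3)], "\t")
  rules <- new_mss_rules(tibble::tibble(
    state = vapply(rows, function(r) as.integer(r[1]), integer(1)),
    pattern = vapply(rows, function(r) r[2], character(1)),
    case_n = vapply(rows, function(r) as.integer(r[3]), integer(1)),
    control_n = vapply(rows, function(r) as.integer(r[4]), integer(1)),
    class = vapply(rows, function(r) r[5], character(1)),
    source = vapply(rows, function(r) r[6], character(1))),
    markers = markers, thresholds = setNames(thresholds, markers))
  structure(list(markers = markers,
                 thresholds = setNames(thresholds, markers),
                 rules = rules, performance = NULL),
            class = "mss_panel")
}
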