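#' Net spot signal after local-background subtraction
#'
#' Convenience operation for pre-quantified array data: the median local
#' background around a spot is subtracted from the spot's median intensity.
#' The result may be negative; negative net signals are resolved later by
#' the positive floor applied before averaging / log transform.
#'
#' @param spot_median,local_background_median Non-negative finite numerics
#'   (vectorized).
#' @return Numeric net signal.
#' @export
net_signal <- function(spot_median, local_background_median) {
  if (!all(is.finite(spot_median)) || !all(is.finite(local_background_median))) {
    abort("net_signal() requires finite inputs")
  }
  if (any(spot_median < 0) || any(local_background_median < 0)) {
    abort("intensities must be non-negative")
  }
  spot_median - local_background_median
}

#' Geometric mean of replicate intensities
#'
#' Replicate measurements of the same marker within an array are combined by
#' geometric mean. Values are clipped to a positive floor first so that zero
#' or negative net signals do not annihilate the mean; the same floor is
#' used by [log_transform()], making "geometric mean then log" identical to
#' "log then arithmetic mean".
#'
#' @param replicates Non-empty numeric vector of replicate net intensities.
#' @param floor Positive clipping floor in raw fluorescence units.
#' @return The geometric mean of the floored replicates.
#' @examples
#' average_replicates(c(10, 1000))        # 100
#' average_replicates(c(0, 100))          # sqrt(10 * 100)
#' @export
average_replicates <- function(replicates, floor = 10) {
  if (length(replicates) == 0L) abort("no replicates supplied")
  if (!all(is.finite(replicates))) abort("replicates must be finite")
  exp(mean(log(pmax(replicates, floor))))
}

#' Log10 transform with a positive floor
#'
#' Raw 16-bit fluorescence values (0 to 65535) are floored at 10 raw units
#' and log10-transformed, mapping the full scale onto roughly 1 to 4.82.
#' The floor resolves zero and negative net signals and pins the lower end
#' of the transformed range at exactly 1.
#'
#' @param raw Finite numeric vector of raw intensities.
#' @param floor Positive clipping floor (raw units).
#' @return `log10(pmax(raw, floor))`.
#' @examples
#' log_transform(c(0, 100, 65535))  # 1, 2, 4.816...
#' @export
log_transform <- function(raw, floor = 10) {
  if (!all(is.finite(raw))) abort("raw values must be finite")
  log10(pmax(raw, floor))
}

#' Filter markers with low signal relative to the negative control
#'
#' A marker is dropped when fewer than `min_fraction` of samples give a
#' signal at least `fold` times the marker's signal on the negative-control
#' (buffer-only) array. The comparison is inclusive (`signal >= fold *
#' control`) and the fraction cutoff strict (`< min_fraction` removes), so a
#' marker passing in exactly 10% of samples is retained at the defaults.
#'
#' @param signals Data frame or matrix of raw signals, samples in rows,
#'   markers in columns (non-marker columns such as `sample_id` are
#'   ignored).
#' @param controls Named numeric vector of negative-control signals, one
#'   per marker.
#' @param min_fraction Minimum passing fraction of samples (default 0.10).
#' @param fold Fold-change over control counted as signal (default 2).
#' @param missing_control `"error"` (default) or `"keep"`: what to do with a
#'   marker that has no negative-control value (`"keep"` retains it with a
#'   warning).
#' @return A tibble with one row per marker: `marker`, `n_pass`, `fraction`,
#'   `retained`.
#' @export
filter_low_signal <- function(signals, controls, min_fraction = 0.10,
                              fold = 2, missing_control = c("error", "keep")) {
  missing_control <- match.arg(missing_control)
  signals <- tibble::as_tibble(as.data.frame(signals))
  keep_cols <- names(signals)[vapply(signals, is.numeric, logical(1))]
  keep_cols <- setdiff(keep_cols, c("sample_id"))
  rows <- purrr::map(keep_cols, function(m) {
    if (!m %in% names(controls) || !is.finite(controls[[m]])) {
      if (missing_control == "error") {
        abort(paste0("no negative-control signal for marker '", m, "'"))
      }
      warning("no negative control for marker '", m, "'; retained unfiltered",
              call. = FALSE)
      return(tibble::tibble(marker = m, n_pass = NA_integer_,
                            fraction = NA_real_, retained = TRUE))
    }
    pass <- signals[[m]] >= fold * controls[[m]]
    frac <- mean(pass)
    tibble::tibble(marker = m, n_pass = sum(pass), fraction = frac,
                   retained = !(frac < min_fraction))
  })
  dplyr::bind_rows(rows)
}

#' Build an analysis-ready marker matrix from replicate-level intensities
#'
#' Runs the standard preprocessing chain on a long replicate table:
#' background subtraction (when a `background` column is present), clipping
#' to a positive floor, geometric-mean averaging of within-array replicates,
#' low-signal marker filtering against the negative control, and log10
#' transformation.
#'
#' @param replicates Long-format data frame with columns `sample_id`,
#'   `marker`, `intensity`, optionally `background`, one row per replicate
#'   spot.
#' @param labels Data frame with `sample_id` and `class` columns, or `NULL`
#'   to emit an unlabeled matrix.
#' @param controls Named numeric vector of per-marker negative-control
#'   signals, or `NULL` to skip the low-signal filter.
#' @param floor Positive clipping floor (raw units).
#' @inheritParams filter_low_signal
#' @return A list with `data` (the marker matrix tibble, log10 units) and
#'   `filter` (the [filter_low_signal()] report, or `NULL`).
#' @export
preprocess_replicates <- function(replicates, labels = NULL, controls = NULL,
                                  floor = 10, min_fraction = 0.10, fold = 2) {
  req <- c("sample_id", "marker", "intensity")
  missing <- setdiff(req, names(replicates))
  if (length(missing) > 0L) {
    abort(paste0("replicate table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  net <- if ("background" %in% names(replicates)) {
    net_signal(replicates$intensity, replicates$background)
  } else {
    replicates$intensity
  }
  avg <- replicates |>
    dplyr::mutate(net = net) |>
    dplyr::group_by(.data$sample_id, .data$marker) |>
    dplyr::summarise(signal = average_replicates(.data$net, floor = floor),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(avg, names_from = "marker",
                             values_from = "signal")
  report <- NULL
  if (!is.null(controls)) {
    report <- filter_low_signal(wide, controls, min_fraction = min_fraction,
                                fold = fold)
    drop <- report$marker[!report$retained]
    wide <- wide[setdiff(names(wide), drop)]
  }
  for (m in setdiff(names(wide), "sample_id")) {
    wide[[m]] <- log_transform(wide[[m]], floor = floor)
  }
  if (!is.null(labels)) {
    wide <- dplyr::inner_join(
      tibble::tibble(sample_id = as.character(labels$sample_id),
                     class = labels$class),
      wide, by = "sample_id")
    wide <- as_marker_matrix(wide, sample_col = "sample_id",
                             label_col = "class")
  }
  list(data = wide, filter = report)
}
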