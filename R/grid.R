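#' Candidate thresholds for one marker
#'
#' Thresholds are consecutive integer multiples of `step` spanning the
#' marker's value range: from the largest multiple at or below the minimum
#' to the smallest multiple at or above the maximum. A marker ranging from
#' 1.25 to 3.25 scanned at step 0.5 is therefore tested at 1, 1.5, 2, 2.5,
#' 3 and 3.5. Anchoring at step multiples (rather than at the data minimum)
#' keeps grids comparable across markers and immune to float accumulation:
#' thresholds are carried internally as integer multiples of `step`.
#'
#' @param min_value,max_value Range of the marker's (log10) values.
#' @param step Positive threshold spacing, in the same units.
#' @return Numeric vector of thresholds, with attributes `step` and
#'   `multiples` (the integer multiples of `step`).
#' @examples
#' build_threshold_grid(1.25, 3.25, 0.5)
#' @export
build_threshold_grid <- function(min_value, max_value, step) {
  if (!is.finite(step) || step <= 0) abort("step must be positive")
  if (!is.finite(min_value) || !is.finite(max_value) || min_value > max_value) {
    abort("invalid value range")
  }
  lo <- grid_multiple(min_value, step, floor)
  hi <- grid_multiple(max_value, step, ceiling)
  mult <- lo:hi
  structure(mult * step, step = step, multiples = mult)
}

# nearest integer multiple with a relative guard against float representation
# of values sitting exactly on a grid point
grid_multiple <- function(x, step, round_fn) {
  r <- x / step
  nearest <- round(r)
  if (abs(r - nearest) < 1e-9 * max(1, abs(r))) nearest else round_fn(r)
}

#' Per-marker threshold grids for a marker matrix
#'
#' @inheritParams assign_states
#' @param step Positive threshold spacing (log10 units).
#' @param markers Markers to build grids for (default: all marker columns).
#' @param range `"per_marker"` (default) spans each marker's own value
#'   range; `"global"` spans the range of `global_range` for every marker.
#' @param global_range Length-2 numeric used when `range = "global"`;
#'   `NULL` uses the pooled range of all selected markers.
#' @return Named list of [build_threshold_grid()] vectors.
#' @export
threshold_grids <- function(data, step, markers = marker_cols(data),
                            range = c("per_marker", "global"),
                            global_range = NULL) {
  range <- match.arg(range)
  if (range == "global") {
    if (is.null(global_range)) {
      pool <- unlist(data[markers], use.names = FALSE)
      global_range <- c(min(pool), max(pool))
    }
    g <- build_threshold_grid(global_range[1], global_range[2], step)
    return(setNames(rep(list(g), length(markers)), markers))
  }
  setNames(lapply(markers, function(m) {
    build_threshold_grid(min(data[[m]]), max(data[[m]]), step)
  }), markers)
}
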