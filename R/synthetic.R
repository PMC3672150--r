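#' Simulate marker data with planted patient subclasses
#'
#' Generates a samples-by-markers matrix on the log10 scale (i.e. log-normal
#' raw intensities) with the structure the marker-state model assumes: the
#' case population is a mixture of subclasses, each elevated in a distinct
#' subset of the planted panel markers, and the control population a mixture
#' of mostly-low states. A marker whose subclass state bit is 1 is shifted
#' up by `effect_size`; decoy markers carry no class signal. The ground
#' truth (planted markers, separating thresholds at `baseline_mean +
#' effect_size / 2`, per-sample subclass states) is returned alongside.
#'
#' The default mixtures put most cases in the all-elevated and
#' first-and-third-elevated states with smaller fractions in the remaining
#' two-elevated states, and most controls in the all-low state with smaller
#' single-elevated fractions — the occupancy picture typical of a
#' CA 19-9-anchored pancreatic-cancer panel.
#'
#' @param n_case,n_control Samples per class.
#' @param n_markers Total markers; the first `length(panel_markers)` to
#'   `max(panel_markers)` must fit, the rest are decoys.
#' @param panel_markers Indices of the planted panel markers.
#' @param case_states,control_states Named numeric vectors: names are bit
#'   patterns over the panel markers (e.g. `"101"`), values are mixing
#'   proportions summing to 1 within each class.
#' @param baseline_mean Baseline log10 level shared by all markers.
#' @param sd Per-measurement Gaussian noise sd (log10 units).
#' @param effect_size Log10 shift added when a subclass state bit is 1.
#' @param marker_baseline_sd Optional sd of per-marker baseline offsets
#'   (default 0: common baseline, so the true thresholds are exactly
#'   `baseline_mean + effect_size / 2`).
#' @param label_noise Probability that a sample's recorded class label is
#'   flipped after generation.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return A list with `data` (canonical marker matrix tibble) and `truth`
#'   (list: `markers`, `thresholds`, `case_states`, `control_states`,
#'   `states` per-sample tibble, `flipped` sample ids).
#' @examples
#' sim <- simulate_markers(n_case = 50, n_control = 50, seed = 7)
#' head(sim$data)
#' sim$truth$thresholds
#' @export
simulate_markers <- function(n_case = 100, n_control = 100, n_markers = 13,
                             panel_markers = 1:3,
                             case_states = c("111" = 0.45, "101" = 0.30,
                                             "110" = 0.15, "011" = 0.10),
                             control_states = c("000" = 0.60, "010" = 0.30,
                                                "100" = 0.10),
                             baseline_mean = 2.0, sd = 0.25,
                             effect_size = 1.0, marker_baseline_sd = 0,
                             label_noise = 0, seed) {
  if (missing(seed) || is.null(seed)) abort("a seed is required")
  np <- length(panel_markers)
  check_mix <- function(x, what) {
    if (abs(sum(x) - 1) > 1e-8) abort(paste(what, "proportions must sum to 1"))
    if (any(x < 0)) abort(paste(what, "proportions must be non-negative"))
    if (any(nchar(names(x)) != np)) {
      abort(paste(what, "state patterns must have one bit per panel marker"))
    }
  }
  check_mix(case_states, "case")
  check_mix(control_states, "control")
  if (max(panel_markers) > n_markers) {
    abort("panel_markers must index existing markers")
  }
  if (label_noise < 0 || label_noise >= 1) abort("label_noise must be in [0,1)")
  marker_ids <- sprintf("M%02d", seq_len(n_markers))
  n <- n_case + n_control
  withr::with_seed(as.integer(seed), {
    offsets <- rnorm(n_markers, 0, marker_baseline_sd)
    draw_class <- function(n_s, mix) {
      pats <- sample(names(mix), n_s, replace = TRUE, prob = mix)
      t(vapply(strsplit(pats, ""), as.integer, integer(np)))
    }
    bits_case <- draw_class(n_case, case_states)
    bits_ctrl <- draw_class(n_control, control_states)
    bits <- rbind(bits_case, bits_ctrl)
    values <- matrix(rnorm(n * n_markers, baseline_mean, sd), n, n_markers)
    values <- sweep(values, 2, offsets, "+")
    for (j in seq_len(np)) {
      values[, panel_markers[j]] <-
        values[, panel_markers[j]] + effect_size * bits[, j]
    }
    cls_true <- c(rep("case", n_case), rep("control", n_control))
    cls <- cls_true
    flipped <- character(0)
    if (label_noise > 0) {
      flip <- stats::runif(n) < label_noise
      cls[flip] <- ifelse(cls[flip] == "case", "control", "case")
      flipped <- sprintf("S%03d", which(flip))
    }
    sid <- sprintf("S%03d", seq_len(n))
    df <- tibble::as_tibble(as.data.frame(values))
    names(df) <- marker_ids
    data <- dplyr::bind_cols(
      tibble::tibble(sample_id = sid,
                     class = factor(cls, levels = c("control", "case"))),
      df)
    truth <- list(
      markers = marker_ids[panel_markers],
      thresholds = setNames(rep(baseline_mean + effect_size / 2, np) +
                              offsets[panel_markers],
                            marker_ids[panel_markers]),
      case_states = case_states,
      control_states = control_states,
      states = tibble::tibble(sample_id = sid,
                              class = factor(cls_true,
                                             levels = c("control", "case")),
                              state = encode_state(bits)),
      flipped = flipped)
    list(data = data, truth = truth)
  })
}

#' Write a simulated data set and its ground truth to disk
#'
#' Emits the marker matrix in the standard tab-delimited layout plus a
#' ground-truth sidecar (planted markers and thresholds, one per line).
#'
#' @param sim Output of [simulate_markers()].
#' @param path Path for the marker matrix TSV; the sidecar is written to
#'   `paste0(path, ".truth.tsv")`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  write_marker_matrix(sim$data, path)
  truth <- tibble::tibble(marker = sim$truth$markers,
                          threshold = unname(sim$truth$thresholds))
  readr::write_tsv(truth, paste0(path, ".truth.tsv"))
  invisible(path)
}
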