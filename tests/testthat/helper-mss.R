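# Shared fixtures and an independent brute-force oracle for the exhaustive
# search. The oracle deliberately shares no code with the package's scan:
# states are string keys, grids are built with seq(), and the per-state
# optimum uses max(case, control) counts (equivalent to majority voting
# under any tie rule, since ties contribute equally either way).

oracle_best_accuracy <- function(data, step, panel_size) {
  markers <- setdiff(names(data), c("sample_id", "class"))
  labs <- as.character(data$class)
  n <- nrow(data)
  best <- -1
  for (combo in utils::combn(markers, panel_size, simplify = FALSE)) {
    grids <- lapply(combo, function(m) {
      v <- data[[m]]
      seq(floor(min(v) / step) * step,
          ceiling(max(v) / step) * step + step / 4, by = step)
    })
    thr_grid <- expand.grid(grids)
    for (r in seq_len(nrow(thr_grid))) {
      bits <- sapply(seq_along(combo), function(j) {
        ifelse(data[[combo[j]]] > thr_grid[r, j], "1", "0")
      })
      key <- apply(matrix(bits, nrow = n), 1, paste, collapse = "")
      correct <- 0
      for (s in unique(key)) {
        nc <- sum(key == s & labs == "case")
        nk <- sum(key == s & labs == "control")
        correct <- correct + max(nc, nk)
      }
      best <- max(best, correct / n)
    }
  }
  best
}

# small random labeled instance with both classes guaranteed
random_instance <- function(n_samples, n_markers, seed) {
  withr::with_seed(seed, {
    labs <- c("case", "control",
              sample(c("case", "control"), n_samples - 2L, replace = TRUE))
    vals <- matrix(round(stats::runif(n_samples * n_markers, 1, 4), 2),
                   n_samples, n_markers)
    df <- tibble::as_tibble(as.data.frame(vals))
    names(df) <- sprintf("V%02d", seq_len(n_markers))
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s%03d", seq_len(n_samples)),
                     class = factor(sample(labs),
                                    levels = c("control", "case"))),
      df)
  })
}

# tiny deterministic two-class matrix used across unit tests
toy_matrix <- function() {
  tibble::tibble(
    sample_id = sprintf("t%d", 1:8),
    class = factor(rep(c("case", "control"), each = 4),
                   levels = c("control", "case")),
    A = c(3.1, 3.4, 2.9, 3.2, 1.2, 1.5, 1.1, 1.4),
    B = c(2.8, 3.0, 3.1, 1.1, 1.3, 1.2, 1.6, 1.0),
    C = c(1.9, 2.2, 2.0, 2.1, 2.0, 1.8, 2.1, 2.2))
}
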