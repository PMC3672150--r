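cv_fixture <- function() {
  sim <- simulate_markers(n_case = 30, n_control = 30, n_markers = 4,
                          effect_size = 1.5, seed = 14)
  fit <- full_train(sim$data, step = 0.5, panel_size = 3,
                    min_sensitivity = 0.85, min_specificity = 0.85)
  plan <- make_splits(sim$data, k = 5, seed = 6)
  list(sim = sim, fit = fit,
       cv = cv_run(sim$data, fit, plan, headline = FALSE))
}

test_that("the final report is deterministic with N/A for missing splits", {
  fx <- cv_fixture()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_final_report(fx$cv, p1)
  write_final_report(fx$cv, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical re-run
  lines <- readLines(p1)
  expect_match(lines[1], "^# mss")
  expect_equal(length(lines) - 2L, nrow(fx$cv$results))
  if (any(is.na(as.matrix(fx$cv$results[paste0("split_", 1:5)])))) {
    expect_true(any(grepl("\tN/A", lines)))
  }
  # panels are sorted by average accuracy, best first
  back <- read_final_report(p1)
  expect_false(is.unsorted(rev(back$avg_accuracy), na.rm = TRUE))
})

test_that("final report values round-trip at the printed precision", {
  fx <- cv_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_final_report(fx$cv, path)
  back <- read_final_report(path)
  ord <- order(-fx$cv$results$avg_accuracy, fx$cv$results$marker_1,
               fx$cv$results$marker_2, fx$cv$results$marker_3,
               fx$cv$results$threshold_1, fx$cv$results$threshold_2,
               fx$cv$results$threshold_3)
  orig <- fx$cv$results[ord, ]
  expect_equal(back$marker_1, orig$marker_1)
  expect_equal(back$threshold_1, orig$threshold_1)
  expect_equal(back$sensitivity, orig$sensitivity, tolerance = 6e-4)
  expect_equal(is.na(back$split_1), is.na(orig$split_1))
  expect_equal(back$split_3, orig$split_3, tolerance = 6e-4)
  expect_equal(back$avg_accuracy, orig$avg_accuracy, tolerance = 6e-4)
})

test_that("an empty retained set writes a header-only final report", {
  d <- random_instance(20, 3, seed = 3)
  fit <- full_train(d, step = 0.5, panel_size = 2, min_sensitivity = 1,
                    min_specificity = 1)
  plan <- make_splits(d, k = 5, seed = 1)
  cv <- cv_run(d, fit, plan, headline = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_final_report(cv, path)
  expect_length(readLines(path), 2L)
})

test_that("the detailed report lists all states with member samples", {
  fx <- cv_fixture()
  panels <- panels_from_fit(fx$sim$data, fx$fit, rows = 1:2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_detailed_report(fx$sim$data, panels, path)
  back <- read_detailed_report(path)
  expect_equal(nrow(back), 2L * 8L)  # 2^3 state rows per panel
  per_panel <- dplyr::count(back, block, wt = case_n + control_n)
  expect_true(all(per_panel$n == nrow(fx$sim$data)))
  # unoccupied states still appear, with zero counts and a class
  first <- back[back$block == 1L, ]
  expect_equal(first$state, 1:8)
  expect_true(all(first$class %in% c("case", "control")))
  # member ids reconstruct the occupancy counts exactly
  expect_equal(vapply(first$samples, length, integer(1)),
               first$case_n + first$control_n)
  # and agree with the panel's rule table
  expect_equal(first$case_n, panels[[1]]$rules$case_n)
  expect_equal(first$control_n, panels[[1]]$rules$control_n)
  expect_equal(first$class, panels[[1]]$rules$class)
})

test_that("final report numbers are recomputable from the detailed file", {
  fx <- cv_fixture()
  final_path <- withr::local_tempfile(fileext = ".tsv")
  det_path <- withr::local_tempfile(fileext = ".tsv")
  write_final_report(fx$cv, final_path)
  write_detailed_report(fx$sim$data,
                        panels_from_fit(fx$sim$data, fx$fit), det_path)
  final <- read_final_report(final_path)
  det <- read_detailed_report(det_path)
  for (i in head(seq_len(nrow(final)), 10)) {
    mk <- unname(unlist(final[i, paste0("marker_", 1:3)]))
    th <- unname(unlist(final[i, paste0("threshold_", 1:3)]))
    block <- det[vapply(seq_len(nrow(det)), function(r) {
      identical(det$markers[[r]], mk) &&
        isTRUE(all.equal(det$thresholds[[r]], th))
    }, logical(1)), ]
    expect_equal(nrow(block), 8L)
    tp <- sum(block$case_n[block$class == "case"])
    fn <- sum(block$case_n[block$class == "control"])
    tn <- sum(block$control_n[block$class == "control"])
    fp <- sum(block$control_n[block$class == "case"])
    expect_equal(tp / (tp + fn), final$sensitivity[i], tolerance = 6e-4)
    expect_equal(tn / (tn + fp), final$specificity[i], tolerance = 6e-4)
  }
})

test_that("occupancy summaries are class percentages summing to 100", {
  d <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    class = factor(c(rep("case", 4), rep("control", 4)),
                   levels = c("control", "case")),
    M = c(3, 3, 3, 3, 1, 1, 2.5, 2.5))
  occ <- summarize_occupancy(d, "M", 2)
  expect_equal(occ$pct[occ$class == "control" & occ$state == 1], 50)
  expect_equal(occ$pct[occ$class == "control" & occ$state == 2], 50)
  expect_equal(occ$pct[occ$class == "case" & occ$state == 2], 100)
  expect_equal(occ$pct[occ$class == "case" & occ$state == 1], 0)
  agg <- tapply(occ$pct, occ$class, sum)
  expect_equal(as.numeric(agg), c(100, 100))
  # subgroup breakdown preserves the per-class total
  d$stage <- c("early", "early", "late", "late", rep("healthy", 4))
  occ2 <- summarize_occupancy(d, "M", 2, subgroup = "stage")
  agg2 <- tapply(occ2$pct, occ2$class, sum)
  expect_equal(as.numeric(agg2), c(100, 100))
  expect_equal(occ2$pct[occ2$class == "case" & occ2$state == 2 &
                          occ2$subgroup == "late"], 50)
})

test_that("training and test occupancy agree on planted data", {
  sim <- simulate_markers(n_case = 400, n_control = 400, n_markers = 3,
                          seed = 58)
  idx <- rep(c(TRUE, FALSE), 400)  # alternate into two halves
  train <- sim$data[idx, ]
  test <- sim$data[!idx, ]
  occ_tr <- summarize_occupancy(train, sim$truth$markers,
                                unname(sim$truth$thresholds))
  occ_te <- summarize_occupancy(test, sim$truth$markers,
                                unname(sim$truth$thresholds))
  # per-state class proportions differ by no more than ~4 binomial SEs
  for (i in seq_len(nrow(occ_tr))) {
    p <- (occ_tr$pct[i] + occ_te$pct[i]) / 200
    se <- sqrt(p * (1 - p) / 400)
    expect_lt(abs(occ_tr$pct[i] - occ_te$pct[i]), 4 * 100 * se + 1)
  }
})

test_that("panels round-trip through their text serialization", {
  sim <- simulate_markers(n_case = 20, n_control = 20, n_markers = 3,
                          seed = 71)
  pan <- finalize_panel(sim$data, sim$truth$markers, step = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(pan, path)
  back <- read_panel(path)
  expect_equal(back$markers, pan$markers)
  expect_equal(back$thresholds, pan$thresholds)
  for (col in c("state", "pattern", "case_n", "control_n", "class",
                "source")) {
    expect_equal(back$rules[[col]], pan$rules[[col]])
  }
  # a reloaded panel classifies new data identically
  new <- simulate_markers(n_case = 10, n_control = 10, n_markers = 3,
                          seed = 72)$data
  expect_equal(classify_samples(new, back)$.class_pred,
               classify_samples(new, pan)$.class_pred)
})
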