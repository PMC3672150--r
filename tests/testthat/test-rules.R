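two_state_data <- function(case_high = 2L, ctrl_high = 6L,
                           case_low = 5L, ctrl_low = 1L) {
  # one-marker data set with a chosen occupancy of the two states
  tibble::tibble(
    sample_id = sprintf("s%02d",
                        seq_len(case_high + ctrl_high + case_low + ctrl_low)),
    class = factor(c(rep("case", case_high), rep("control", ctrl_high),
                     rep("case", case_low), rep("control", ctrl_low)),
                   levels = c("control", "case")),
    M = c(rep(3, case_high + ctrl_high), rep(1, case_low + ctrl_low)))
}

test_that("occupied states take the class with more occurrences", {
  # high state: 2 cases vs 6 controls -> control despite being 'elevated'
  d <- two_state_data(case_high = 2, ctrl_high = 6, case_low = 5, ctrl_low = 1)
  r <- learn_state_rules(d, "M", 2)
  expect_equal(r$class[r$pattern == "1"], "control")
  expect_equal(r$source[r$pattern == "1"], "majority")
  expect_equal(r$case_n[r$pattern == "1"], 2L)
  expect_equal(r$control_n[r$pattern == "1"], 6L)
})

test_that("tied states fall to control by default, to case on request", {
  d <- two_state_data(case_high = 3, ctrl_high = 3, case_low = 1, ctrl_low = 4)
  r <- learn_state_rules(d, "M", 2)
  expect_equal(r$class[r$pattern == "1"], "control")
  expect_equal(r$source[r$pattern == "1"], "tie_rule")
  r2 <- learn_state_rules(d, "M", 2, tie = "case")
  expect_equal(r2$class[r2$pattern == "1"], "case")
})

test_that("unoccupied states inherit the nearest occupied states' majority", {
  # occupy 000 (controls), 010 (controls), 111 (cases); 001's nearest
  # occupied neighbours at Hamming distance 1 are 000 -> control
  d <- tibble::tibble(
    sample_id = sprintf("s%d", 1:9),
    class = factor(c(rep("control", 6), rep("case", 3)),
                   levels = c("control", "case")),
    A = c(rep(1, 6), rep(3, 3)),
    B = c(rep(1, 3), rep(3, 3), rep(3, 3)),
    C = c(rep(1, 6), rep(3, 3)))
  r <- learn_state_rules(d, c("A", "B", "C"), c(2, 2, 2))
  expect_equal(r$class[r$pattern == "000"], "control")
  expect_equal(r$class[r$pattern == "010"], "control")
  expect_equal(r$class[r$pattern == "111"], "case")
  # 001 neighbours: 000 (occupied control) at distance 1
  expect_equal(r$class[r$pattern == "001"], "control")
  expect_equal(r$source[r$pattern == "001"], "unoccupied_rule")
  # 110 is at distance 1 from both 010 (control) and 111 (case): tie -> control
  expect_equal(r$class[r$pattern == "110"], "control")
  # 101 is at distance 1 from 111 only among occupied -> case
  expect_equal(r$class[r$pattern == "101"], "case")
  # every state got exactly one class
  expect_equal(nrow(r), 8L)
  expect_true(all(r$class %in% c("case", "control")))
})

test_that("samples are classified by their state's assignment", {
  rules <- manual_state_rules(3, c(4, 6, 7, 8))
  d <- tibble::tibble(sample_id = c("x", "y"),
                      A = c(3, 1), B = c(3, 1), C = c(3, 1))
  pred <- classify_samples(d, rules, markers = c("A", "B", "C"),
                           thresholds = c(2, 2, 2))
  expect_equal(pred$.class_pred, c("case", "control"))  # states 8 and 1
  all_ctrl <- manual_state_rules(3, integer(0))
  pred2 <- classify_samples(d, all_ctrl, markers = c("A", "B", "C"),
                            thresholds = c(2, 2, 2))
  expect_true(all(pred2$.class_pred == "control"))
  expect_error(classify_samples(d, rules, markers = c("A", "B"),
                                thresholds = c(2, 2)), "panel size")
})

test_that("performance metrics follow the confusion-matrix definitions", {
  # 121 cases (108 above threshold), 76 controls (69 below): the classic
  # 89.3% / 90.8% / 89.9% operating point
  d <- tibble::tibble(
    sample_id = sprintf("p%03d", 1:197),
    class = factor(c(rep("case", 121), rep("control", 76)),
                   levels = c("control", "case")),
    M = c(rep(3, 108), rep(1, 13), rep(1, 69), rep(3, 7)))
  rules <- manual_state_rules(1, 2L)  # state 2 (high) = case
  perf <- evaluate_panel(d, rules, markers = "M", thresholds = 2)
  expect_equal(perf$tp, 108L)
  expect_equal(perf$fn, 13L)
  expect_equal(round(perf$sensitivity, 3), 0.893)
  expect_equal(round(perf$specificity, 3), 0.908)
  expect_equal(perf$accuracy, 177 / 197)
  # internal consistency: accuracy is the prevalence-weighted mean of
  # sensitivity and specificity, and reconstructing it from the one-decimal
  # percentages gives 89.9%
  expect_equal(perf$accuracy,
               (perf$sensitivity * 121 + perf$specificity * 76) / 197)
  expect_equal(round((0.893 * 121 + 0.908 * 76) / 197, 3), 0.899)
})

test_that("perfect separation yields unit metrics and counts sum to n", {
  d <- two_state_data(case_high = 5, ctrl_high = 0, case_low = 0,
                      ctrl_low = 5)
  r <- learn_state_rules(d, "M", 2)
  perf <- evaluate_panel(d, r)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$tp + perf$fp + perf$tn + perf$fn, nrow(d))
})

test_that("metrics agree with an independent confusion oracle", {
  withr::with_seed(21, {
    for (i in 1:10) {
      d <- random_instance(25, 2, seed = 100 + i)
      r <- learn_state_rules(d, c("V01", "V02"), stats::runif(2, 1.5, 3.5))
      perf <- evaluate_panel(d, r)
      pred <- classify_samples(d, r)
      tab <- table(truth = as.character(pred$class), pred = pred$.class_pred)
      get <- function(a, b) if (a %in% rownames(tab) && b %in% colnames(tab))
        tab[a, b] else 0L
      expect_equal(perf$tp, unname(get("case", "case")))
      expect_equal(perf$tn, unname(get("control", "control")))
      expect_equal(perf$accuracy,
                   mean(as.character(pred$class) == pred$.class_pred))
    }
  })
})

test_that("rule condensation finds the minimal wildcard cover", {
  rules <- manual_state_rules(3, c("011", "101", "110", "111"))
  cond <- condense_rules(rules)
  expect_setequal(cond$pattern[cond$class == "case"],
                  c("X11", "1X1", "11X"))
  expect_setequal(cond$pattern[cond$class == "control"],
                  c("00X", "0X0", "X00"))
  expect_equal(nrow(cond), 6L)  # 8 states condense to 6
  # nothing to merge for a singleton class
  single <- condense_rules(manual_state_rules(3, "111"))
  expect_equal(single$pattern[single$class == "case"], "111")
  # empty case class: control condenses to the universal pattern
  none <- condense_rules(manual_state_rules(3, integer(0)))
  expect_equal(none$pattern[none$class == "control"], "XXX")
  expect_equal(sum(none$class == "case"), 0L)
})

test_that("condensed patterns round-trip to the exact class partition", {
  for (n in 2:4) {
    n_states <- 2^n
    withr::with_seed(33 + n, {
      for (i in 1:15) {
        case_states <- which(stats::runif(n_states) < 0.4)
        rules <- manual_state_rules(n, case_states)
        cond <- condense_rules(rules)
        for (cl in c("case", "control")) {
          covered <- as.integer(sort(unique(unlist(
            lapply(cond$pattern[cond$class == cl], expand_pattern)))))
          expect_equal(covered, rules$state[rules$class == cl])
        }
        # classification via patterns matches the full rule set everywhere
        for (s in seq_len(n_states)) {
          via_pat <- cond$class[vapply(cond$pattern, function(p) {
            s %in% expand_pattern(p)
          }, logical(1))]
          expect_equal(unique(via_pat), rules$class[s])
        }
      }
    })
  }
})
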