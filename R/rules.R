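new_mss_rules <- function(df, markers = NULL, thresholds = NULL) {
  structure(df, class = c("mss_rules", class(tibble::tibble()))) |>
    `attr<-`("markers", markers) |>
    `attr<-`("thresholds", thresholds)
}

rules_n <- function(rules) as.integer(round(log2(nrow(rules))))

#' Learn case/control state rules from labeled samples
#'
#' Every sample is assigned its marker state, and each of the 2^n states is
#' classified by the class occupying it more often. Ties go to control (the
#' specificity-favoring choice, configurable via `tie`). States with no
#' training occupants take the majority class among the occupied states at
#' minimum Hamming distance, again breaking ties toward control — the
#' automated analogue of assigning an empty state by its similarity to
#' neighboring states.
#'
#' @inheritParams assign_states
#' @param tie Class assigned to states with equal case and control counts.
#' @return An `mss_rules` tibble with one row per state: `state`, `pattern`,
#'   `case_n`, `control_n`, `class`, `source` (one of `"majority"`,
#'   `"tie_rule"`, `"unoccupied_rule"`).
#' @examples
#' d <- simulate_markers(n_case = 30, n_control = 30, n_markers = 3,
#'                       seed = 1)$data
#' learn_state_rules(d, c("M01", "M02", "M03"), c(2.5, 2.5, 2.5))
#' @export
learn_state_rules <- function(data, markers, thresholds,
                              tie = c("control", "case")) {
  tie <- match.arg(tie)
  st <- assign_states(data, markers, thresholds)
  if (!"class" %in% names(st)) abort("data must carry class labels")
  state_rules_from_states(st$state, st$class, length(markers), tie = tie,
                          markers = markers, thresholds = thresholds)
}

#' @rdname learn_state_rules
#' @param state Integer state index per sample (1..2^n).
#' @param class Per-sample class factor/character (`"case"`/`"control"`).
#' @param n Panel size.
#' @export
state_rules_from_states <- function(state, class, n,
                                    tie = c("control", "case"),
                                    markers = NULL, thresholds = NULL) {
  tie <- match.arg(tie)
  n_states <- as.integer(state_space_size(n))
  is_case <- as.character(class) == "case"
  case_n <- tabulate(state[is_case], nbins = n_states)
  control_n <- tabulate(state[!is_case], nbins = n_states)
  occ <- case_n + control_n > 0L
  cls <- rep(NA_character_, n_states)
  src <- rep(NA_character_, n_states)
  cls[occ] <- ifelse(case_n[occ] > control_n[occ], "case",
                     ifelse(case_n[occ] < control_n[occ], "control", tie))
  src[occ] <- ifelse(case_n[occ] != control_n[occ], "majority", "tie_rule")
  if (any(!occ)) {
    occ_idx <- which(occ)
    for (s in which(!occ)) {
      if (length(occ_idx) == 0L) {
        cls[s] <- "control"
      } else {
        d <- hamming_dist(s - 1L, occ_idx - 1L)
        nearest <- cls[occ_idx[d == min(d)]]
        cls[s] <- if (sum(nearest == "case") > sum(nearest == "control"))
          "case" else "control"
      }
      src[s] <- "unoccupied_rule"
    }
  }
  new_mss_rules(
    tibble::tibble(state = seq_len(n_states),
                   pattern = state_pattern(seq_len(n_states), n),
                   case_n = case_n, control_n = control_n,
                   class = cls, source = src),
    markers = markers, thresholds = thresholds)
}

hamming_dist <- function(a, b) {
  vapply(bitwXor(a, b), function(x) sum(as.integer(intToBits(x))), integer(1))
}

#' Construct a rule set directly from a list of case states
#'
#' Builds a complete `mss_rules` table without training data, useful for
#' expressing a published or hypothesized rule set. Occupancy counts are
#' zero and `source` is `"manual"`.
#'
#' @param n Panel size.
#' @param case_states Integer state indices (1..2^n) or bit-pattern strings
#'   (e.g. `"011"`) designated as case states; all others are control.
#' @return An `mss_rules` tibble.
#' @examples
#' manual_state_rules(3, c("011", "101", "110", "111"))
#' @export
manual_state_rules <- function(n, case_states) {
  n_states <- as.integer(state_space_size(n))
  if (is.character(case_states)) {
    case_states <- vapply(strsplit(case_states, ""), function(b) {
      encode_state(as.integer(b))
    }, integer(1))
  }
  if (any(case_states < 1 | case_states > n_states)) {
    abort("case state index out of range")
  }
  cls <- rep("control", n_states)
  cls[case_states] <- "case"
  new_mss_rules(
    tibble::tibble(state = seq_len(n_states),
                   pattern = state_pattern(seq_len(n_states), n),
                   case_n = 0L, control_n = 0L,
                   class = cls, source = "manual"))
}

#' Classify samples by the state they occupy
#'
#' @inheritParams assign_states
#' @param rules An `mss_rules` table covering the panel's state space. When
#'   `markers`/`thresholds` are omitted they are taken from the rules'
#'   attributes (set by [learn_state_rules()] and [finalize_panel()]).
#' @return The input data with `.state` and `.class_pred` columns appended.
#' @export
classify_samples <- function(data, rules, markers = NULL, thresholds = NULL) {
  if (inherits(rules, "mss_panel")) {
    markers <- rules$markers
    thresholds <- rules$thresholds
    rules <- rules$rules
  }
  if (is.null(markers)) markers <- attr(rules, "markers")
  if (is.null(thresholds)) thresholds <- attr(rules, "thresholds")
  if (is.null(markers) || is.null(thresholds)) {
    abort("markers and thresholds must be supplied or carried by the rules")
  }
  if (length(markers) != rules_n(rules)) {
    abort("panel size does not match the rule set's state space")
  }
  st <- assign_states(data, markers, thresholds)
  dplyr::mutate(data,
                .state = st$state,
                .class_pred = rules$class[st$state])
}

#' Score a panel against labeled samples
#'
#' Computes the confusion counts of the state rules on labeled data: true
#' positives are case samples occupying case states, true negatives control
#' samples occupying control states.
#'
#' @inheritParams classify_samples
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
evaluate_panel <- function(data, rules, markers = NULL, thresholds = NULL) {
  pred <- classify_samples(data, rules, markers = markers,
                           thresholds = thresholds)
  truth <- as.character(pred$class)
  if (!any(truth == "case") || !any(truth == "control")) {
    abort("both classes must be present to compute sensitivity/specificity")
  }
  performance_record(
    tp = sum(truth == "case" & pred$.class_pred == "case"),
    fp = sum(truth == "control" & pred$.class_pred == "case"),
    tn = sum(truth == "control" & pred$.class_pred == "control"),
    fn = sum(truth == "case" & pred$.class_pred == "control"))
}

performance_record <- function(tp, fp, tn, fn) {
  tibble::tibble(
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + tn + fn))
}

# ---- exact two-level Boolean minimization (Quine-McCluskey) ----

# merge implicants that differ in exactly one specified bit; implicants are
# (value, mask) pairs over n bits where mask bit 1 = specified position
qm_primes <- function(minterms, n) {
  if (length(minterms) == 0L) return(list())
  full_mask <- bitwShiftL(1L, n) - 1L
  cur <- unique(data.frame(value = as.integer(minterms), mask = full_mask))
  primes <- list()
  repeat {
    k <- nrow(cur)
    merged <- logical(k)
    nxt <- list()
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          if (cur$mask[i] != cur$mask[j]) next
          d <- bitwXor(cur$value[i], cur$value[j])
          if (d != 0L && bitwAnd(d, d - 1L) == 0L) {  # single-bit difference
            merged[i] <- merged[j] <- TRUE
            nxt[[length(nxt) + 1L]] <-
              c(bitwAnd(cur$value[i], bitwNot(d)),
                bitwAnd(cur$mask[i], bitwNot(d)))
          }
        }
      }
    }
    for (i in which(!merged)) {
      primes[[length(primes) + 1L]] <- c(cur$value[i], cur$mask[i])
    }
    if (length(nxt) == 0L) break
    m <- unique(do.call(rbind, nxt))
    cur <- data.frame(value = m[, 1], mask = m[, 2])
  }
  unique(primes)
}

implicant_covers <- function(imp, minterm) {
  bitwAnd(minterm, imp[2]) == bitwAnd(imp[1], imp[2])
}

# exact minimum cover: essential primes first, then exhaustive search over
# the remaining primes by increasing subset size
qm_min_cover <- function(primes, minterms) {
  if (length(minterms) == 0L) return(integer(0))
  cover <- vapply(primes, function(p) {
    vapply(minterms, function(m) implicant_covers(p, m), logical(1))
  }, logical(length(minterms)))
  cover <- matrix(cover, nrow = length(minterms))
  chosen <- integer(0)
  uncovered <- rep(TRUE, length(minterms))
  repeat {
    ess <- which(uncovered & rowSums(cover[, setdiff(seq_along(primes), chosen),
                                           drop = FALSE]) == 1L)
    if (length(ess) == 0L) break
    for (m in ess) {
      if (!uncovered[m]) next
      p <- setdiff(which(cover[m, ]), chosen)[1]
      chosen <- c(chosen, p)
      uncovered <- uncovered & !cover[, p]
    }
  }
  if (any(uncovered)) {
    rest <- setdiff(seq_along(primes), chosen)
    found <- NULL
    for (size in seq_along(rest)) {
      combos <- combn(rest, size)
      for (ci in seq_len(ncol(combos))) {
        sel <- combos[, ci]
        if (!any(uncovered & rowSums(cover[, sel, drop = FALSE]) == 0L)) {
          found <- sel
          break
        }
      }
      if (!is.null(found)) break
    }
    chosen <- c(chosen, found)
  }
  sort(chosen)
}

implicant_pattern <- function(imp, n) {
  bits <- character(n)
  for (pos in seq_len(n)) {
    b <- bitwShiftL(1L, n - pos)  # first marker = most significant bit
    bits[pos] <- if (bitwAnd(imp[2], b) == 0L) "X"
                 else if (bitwAnd(imp[1], b) != 0L) "1" else "0"
  }
  paste(bits, collapse = "")
}

#' Condense state rules into minimal wildcard patterns
#'
#' Performs exact two-level Boolean minimization (prime implicants followed
#' by an exact minimum cover) separately for the case states and the control
#' states, producing the smallest set of patterns over \{0, 1, X\} that
#' exactly reproduces each class's states. X matches either bit value. The
#' canonical three-marker "two or more markers elevated" rule condenses from
#' 8 states to 6 patterns.
#'
#' @param rules An `mss_rules` table.
#' @return A tibble with `class` and `pattern` columns, case patterns first,
#'   patterns sorted within class.
#' @examples
#' condense_rules(manual_state_rules(3, c("011", "101", "110", "111")))
#' @export
condense_rules <- function(rules) {
  n <- rules_n(rules)
  out <- purrr::map(c("case", "control"), function(cl) {
    minterms <- rules$state[rules$class == cl] - 1L
    primes <- qm_primes(minterms, n)
    sel <- qm_min_cover(primes, minterms)
    pats <- vapply(primes[sel], implicant_pattern, character(1), n = n)
    tibble::tibble(class = cl, pattern = sort(pats))
  })
  dplyr::bind_rows(out)
}

#' Expand a wildcard pattern to the fully-specified states it covers
#'
#' @param pattern A string over \{0, 1, X\}, e.g. `"X11"`.
#' @return Integer vector of covered state indices (1-based).
#' @examples
#' expand_pattern("X11")  # states 4 and 8
#' @export
expand_pattern <- function(pattern) {
  bits <- strsplit(pattern, "")[[1]]
  free <- which(bits == "X")
  base <- ifelse(bits == "1", 1L, 0L)
  if (length(free) == 0L) return(encode_state(base))
  fills <- expand.grid(rep(list(0:1), length(free)))
  sort(apply(fills, 1, function(f) {
    b <- base
    b[free] <- as.integer(f)
    encode_state(b)
  }))
}

#' @export
print.mss_rules <- function(x, ...) {
  n <- rules_n(x)
  cat("Marker state rules:", nrow(x), "states over", n, "markers\n")
  if (!is.null(attr(x, "markers"))) {
    cat("Panel:", paste(attr(x, "markers"), collapse = ", "), "\n")
    cat("Thresholds:", paste(format(attr(x, "thresholds")), collapse = ", "),
        "\n")
  }
  print(tibble::as_tibble(x), n = nrow(x))
  invisible(x)
}
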