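#' Binarize a measurement against a threshold
#'
#' Values strictly above the threshold become 1, values at or below it become
#' 0. Equality maps to 0: thresholds sit on grid multiples that essentially
#' never coincide with data, and the strict reading keeps the rule
#' unambiguous in the one place it is defined.
#'
#' @param value,threshold Finite numeric vectors (recycled).
#' @return Integer vector of 0/1 bits.
#' @examples
#' binarize_value(c(2.3, 1.7, 2.0), 2.0)
#' @export
binarize_value <- function(value, threshold) {
  if (!all(is.finite(value)) || !all(is.finite(threshold))) {
    abort("binarize_value() requires finite inputs")
  }
  as.integer(value > threshold)
}

#' Number of marker states for a panel of n markers
#'
#' @param n Panel size (number of markers), `n >= 1`.
#' @return `2^n` as an integer-valued numeric.
#' @examples
#' state_space_size(3)  # 8
#' @export
state_space_size <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    abort("n must be a single integer >= 1")
  }
  2^n
}

#' Convert a binary profile to its state index and back
#'
#' States are numbered 1..2^n with the first marker as the most significant
#' bit, so for three markers (0,0,0) is state 1 and (1,1,1) is state 8.
#'
#' @param bits Vector (or matrix, one row per sample) of 0/1 bits.
#' @return `encode_state()`: integer state index (vector if `bits` is a
#'   matrix). `decode_state()`: integer vector of bits.
#' @examples
#' encode_state(c(0, 1, 1))  # state 4
#' decode_state(6, 3)        # c(1, 0, 1)
#' @export
encode_state <- function(bits) {
  if (is.matrix(bits)) {
    n <- ncol(bits)
    if (n < 1L) abort("empty profile")
    if (!all(bits %in% c(0L, 1L))) abort("bits must be 0/1")
    return(as.integer(bits %*% 2^((n - 1):0)) + 1L)
  }
  n <- length(bits)
  if (n < 1L) abort("empty profile")
  if (!all(bits %in% c(0L, 1L))) abort("bits must be 0/1")
  as.integer(sum(bits * 2^((n - 1):0))) + 1L
}

#' @rdname encode_state
#' @param index State index in `1..2^n`.
#' @param n Panel size.
#' @export
decode_state <- function(index, n) {
  if (length(index) != 1L || index < 1 || index > 2^n) {
    abort("state index out of range")
  }
  as.integer(intToBits(index - 1L))[n:1]
}

#' Format a state as a bit-pattern string
#' @param index State index (vectorized).
#' @param n Panel size.
#' @return Character vector like `"011"`.
#' @export
state_pattern <- function(index, n) {
  vapply(index, function(i) paste(decode_state(i, n), collapse = ""),
         character(1))
}

#' Assign each sample its marker state under a panel
#'
#' Each sample's values for the panel markers are binarized against the
#' panel thresholds and encoded into a state index, so every sample occupies
#' exactly one of the 2^n states.
#'
#' @param data A canonical marker matrix (see [as_marker_matrix()]).
#' @param markers Character vector of panel marker columns (order defines
#'   bit significance: first marker = most significant bit).
#' @param thresholds Numeric vector, one threshold per marker.
#' @return A tibble with `sample_id`, `class` (if present), `state` and
#'   `pattern` columns.
#' @examples
#' d <- tibble::tibble(sample_id = "s1", class = factor("case",
#'        levels = c("control", "case")), A = 2.5, B = 1.0, C = 3.0)
#' assign_states(d, c("A", "B", "C"), c(2, 2, 2))  # state 6, "101"
#' @export
assign_states <- function(data, markers, thresholds) {
  missing <- setdiff(markers, names(data))
  if (length(missing) > 0L) {
    abort(paste0("unknown marker(s): ", paste(missing, collapse = ", ")))
  }
  if (length(thresholds) != length(markers)) {
    abort("one threshold per marker required")
  }
  bits <- vapply(seq_along(markers), function(m) {
    binarize_value(data[[markers[m]]], thresholds[m])
  }, integer(nrow(data)))
  bits <- matrix(bits, nrow = nrow(data))
  st <- encode_state(bits)
  out <- tibble::tibble(sample_id = data$sample_id)
  if ("class" %in% names(data)) out$class <- data$class
  out$state <- st
  out$pattern <- state_pattern(st, length(markers))
  out
}
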