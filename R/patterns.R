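#' Enumerate all binary activity patterns
#'
#' Builds the full state space of `n_units` binary units as a
#' `2^n_units x n_units` matrix with entries in `{-1, +1}`. Row `k`
#' (1-based) is the pattern whose integer code is `k - 1` under the fixed
#' bit convention: `+1` maps to bit 1, `-1` to bit 0, and unit 1 occupies
#' the most significant bit.
#'
#' @param n_units Number of binary units (networks). Must be between 1
#'   and 20; the state space grows as `2^n_units`.
#' @return Integer matrix of dimension `2^n_units x n_units`.
#' @examples
#' pattern_matrix(2)
#' @export
pattern_matrix <- function(n_units) {
  check_n_units(n_units)
  codes <- 0:(2^n_units - 1L)
  m <- vapply(seq_len(n_units), function(i) {
    bit <- bitwAnd(codes, bitwShiftL(1L, n_units - i)) > 0L
    ifelse(bit, 1L, -1L)
  }, integer(length(codes)))
  dim(m) <- c(length(codes), n_units)
  m
}

#' Encode activity patterns as integer codes
#'
#' @param patterns Matrix (or vector for a single pattern) with entries in
#'   `{-1, +1}`; one row per pattern.
#' @return Integer vector of codes in `[0, 2^N - 1]`, where `N` is the
#'   number of columns. Unit 1 is the most significant bit; `+1` is bit 1.
#' @examples
#' encode_patterns(rbind(c(1, -1), c(1, 1)))  # 2, 3
#' @export
encode_patterns <- function(patterns) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1)
  if (!all(patterns %in% c(-1L, 1L))) {
    abort("patterns must contain only -1 and +1.")
  }
  n <- ncol(patterns)
  check_n_units(n)
  bits <- (patterns + 1L) / 2L
  as.integer(bits %*% 2^((n - 1):0))
}

#' Decode integer codes back to activity patterns
#'
#' Inverse of [encode_patterns()].
#'
#' @param codes Integer vector of pattern codes in `[0, 2^n_units - 1]`.
#' @param n_units Number of binary units.
#' @return Integer matrix `length(codes) x n_units` with entries in
#'   `{-1, +1}`.
#' @export
decode_patterns <- function(codes, n_units) {
  check_n_units(n_units)
  codes <- as.integer(codes)
  if (any(codes < 0L) || any(codes >= 2^n_units)) {
    abort(sprintf("codes must lie in [0, %d].", 2^n_units - 1L))
  }
  m <- vapply(seq_len(n_units), function(i) {
    bit <- bitwAnd(codes, bitwShiftL(1L, n_units - i)) > 0L
    ifelse(bit, 1L, -1L)
  }, integer(length(codes)))
  dim(m) <- c(length(codes), n_units)
  m
}

#' Single-flip neighbours of every pattern code
#'
#' @param n_units Number of binary units.
#' @return Integer matrix `2^n_units x n_units`; row `k` holds the codes at
#'   Hamming distance 1 from code `k - 1` (column `i` flips unit `i`).
#' @keywords internal
neighbour_codes <- function(n_units) {
  codes <- 0:(2^n_units - 1L)
  m <- vapply(seq_len(n_units), function(i) {
    bitwXor(codes, bitwShiftL(1L, n_units - i))
  }, integer(length(codes)))
  dim(m) <- c(length(codes), n_units)
  m
}

check_n_units <- function(n_units) {
  if (length(n_units) != 1 || is.na(n_units) || n_units < 1 || n_units != round(n_units)) {
    abort("n_units must be a single positive integer.")
  }
  if (n_units > 20) {
    abort("n_units > 20: exact enumeration of 2^N patterns is not feasible.")
  }
  invisible(as.integer(n_units))
}
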