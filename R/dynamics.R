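#' Map a pattern series onto basin-level brain states
#'
#' Each frame's pattern code is looked up in the landscape's basin
#' assignment; the frame's state is the index of the owning local minimum.
#'
#' @param patterns A `pattern_series`.
#' @param landscape An `energy_landscape` over the same number of units.
#' @return A `state_sequence` tibble: `frame`, `code`, `state` (minimum
#'   index into `landscape$minima`), with `tr_seconds` attribute.
#' @export
label_states <- function(patterns, landscape) {
  n <- attr(patterns, "n_units")
  if (n != landscape$n_units) abort("pattern series and landscape disagree on N.")
  basin_of <- landscape$energies$basin
  state_of <- setNames(landscape$minima$state, landscape$minima$code)
  codes <- pattern_codes(patterns)
  out <- tibble(frame = patterns$frame, code = codes,
                state = as.integer(state_of[as.character(basin_of[codes + 1L])]))
  attr(out, "tr_seconds") <- attr(patterns, "tr_seconds") %||% 0.72
  attr(out, "n_states") <- nrow(landscape$minima)
  for (nm in c("subject_id", "session_id", "condition")) {
    attr(out, nm) <- attr(patterns, nm)
  }
  class(out) <- c("state_sequence", class(out))
  out
}

#' Contiguous runs of a state sequence
#'
#' @param seq A `state_sequence` (or integer vector of labels).
#' @return Tibble `state`, `start`, `length` partitioning the frame axis.
#' @export
state_runs <- function(seq) {
  labels <- if (is.numeric(seq)) as.integer(seq) else seq$state
  r <- rle(labels)
  tibble(state = r$values,
         start = cumsum(c(1L, head(r$lengths, -1L))),
         length = r$lengths)
}

#' Occupancy, dwell-time, occurrence and transition statistics
#'
#' For each visited state: fractional occupancy (share of frames), mean
#' dwell time (mean contiguous run length times TR, seconds), and
#' occurrence frequency (runs per second of scan). The transition matrix
#' counts frame-adjacent changes of state; by default self-transitions are
#' excluded and rows are normalized over observed exits.
#'
#' @param seq A `state_sequence`.
#' @param tr_seconds Repetition time; defaults to the sequence attribute.
#' @param states State universe (integer vector); defaults to visited
#'   states. Unvisited states get zero occupancy/occurrence and `NA` dwell.
#' @param include_self Keep self-transitions in the matrix (rows then sum
#'   to 1 over all states with any exit or stay).
#' @return A `state_metrics` tibble (`state`, `n_frames`, `occupancy`,
#'   `n_runs`, `dwell_s`, `occurrence_hz`) with the row-stochastic
#'   `transition_matrix` attached as an attribute (rows without observed
#'   transitions are `NA`).
#' @export
state_metrics <- function(seq, tr_seconds = NULL, states = NULL,
                          include_self = FALSE) {
  labels <- seq$state
  if (length(labels) < 1) abort("state sequence has no frames.")
  tr <- tr_seconds %||% attr(seq, "tr_seconds") %||% 0.72
  if (is.null(states)) states <- sort(unique(labels))
  runs <- state_runs(seq)
  total_s <- length(labels) * tr
  per <- lapply(states, function(s) {
    nf <- sum(labels == s)
    nr <- sum(runs$state == s)
    tibble(state = s, n_frames = nf, occupancy = nf / length(labels),
           n_runs = nr,
           dwell_s = if (nr > 0) mean(runs$length[runs$state == s]) * tr else NA_real_,
           occurrence_hz = nr / total_s)
  })
  out <- bind_rows(per)
  k <- length(states)
  tm <- matrix(0, k, k, dimnames = list(states, states))
  from <- labels[-length(labels)]
  to <- labels[-1L]
  if (!include_self) {
    keep <- from != to
    from <- from[keep]
    to <- to[keep]
  }
  for (i in seq_along(from)) {
    tm[as.character(from[i]), as.character(to[i])] <-
      tm[as.character(from[i]), as.character(to[i])] + 1
  }
  rs <- rowSums(tm)
  tm <- sweep(tm, 1, ifelse(rs > 0, rs, NA_real_), "/")
  attr(out, "transition_matrix") <- tm
  attr(out, "tr_seconds") <- tr
  for (nm in c("subject_id", "session_id", "condition")) {
    attr(out, nm) <- attr(seq, nm)
  }
  class(out) <- c("state_metrics", class(out))
  out
}

#' Transition matrix of a state sequence
#'
#' @inheritParams state_metrics
#' @return Row-stochastic matrix over `states`.
#' @export
transition_matrix <- function(seq, states = NULL, include_self = FALSE) {
  attr(state_metrics(seq, states = states, include_self = include_self),
       "transition_matrix")
}

#' Split states into major and minor groups
#'
#' Default rule (`"above-uniform"`): a state is major when its basin size
#' exceeds the uniform share `1/n_states`. Alternatives: `"top-k"` keeps
#' the `k` largest basins; `"explicit"` takes a user list. If a rule
#' yields no major state, the single largest basin is promoted (logged).
#'
#' @param landscape An `energy_landscape`.
#' @param rule One of `"above-uniform"`, `"top-k"`, `"explicit"`.
#' @param k Number of major states for `"top-k"`.
#' @param states Integer vector of major states for `"explicit"`.
#' @return A `major_minor_split` list: `major`, `minor` (state indices),
#'   `rule` (record of the applied rule).
#' @export
split_major_minor <- function(landscape, rule = c("above-uniform", "top-k", "explicit"),
                              k = NULL, states = NULL) {
  rule <- match.arg(rule)
  minima <- landscape$minima
  all_states <- minima$state
  major <- switch(rule,
    "above-uniform" = all_states[minima$basin_size > 1 / nrow(minima)],
    "top-k" = {
      if (is.null(k)) abort("rule 'top-k' needs k.")
      all_states[order(-minima$basin_size, minima$state)][seq_len(min(k, nrow(minima)))]
    },
    "explicit" = {
      if (is.null(states) || !all(states %in% all_states)) {
        abort("rule 'explicit' needs valid state indices.")
      }
      sort(unique(as.integer(states)))
    })
  if (length(major) == 0) {
    major <- all_states[which.max(minima$basin_size)]
    inform("major set empty under rule; falling back to the single largest basin.")
  }
  structure(list(major = sort(major), minor = sort(setdiff(all_states, major)),
                 rule = list(rule = rule, k = k, states = states)),
            class = "major_minor_split")
}

#' Direct versus indirect major-state transitions
#'
#' The sequence is collapsed to its runs; every excursion between
#' consecutive major-state runs is classified: direct when the two major
#' runs are adjacent, indirect when all intervening runs are minor states.
#'
#' @param seq A `state_sequence`.
#' @param split A `major_minor_split`.
#' @return Tibble with one row: `n_direct`, `n_indirect`, `direct_prob`,
#'   `indirect_prob` (`NA` when no major-to-major excursion exists).
#' @export
direct_indirect <- function(seq, split) {
  runs <- state_runs(seq)
  is_major <- runs$state %in% split$major
  maj_pos <- which(is_major)
  n_direct <- 0L
  n_indirect <- 0L
  if (length(maj_pos) >= 2) {
    for (i in seq_len(length(maj_pos) - 1L)) {
      a <- maj_pos[i]
      b <- maj_pos[i + 1L]
      if (b == a + 1L) {
        n_direct <- n_direct + 1L
      } else {
        n_indirect <- n_indirect + 1L   # gap runs are all minor by construction
      }
    }
  }
  tot <- n_direct + n_indirect
  tibble(n_direct = n_direct, n_indirect = n_indirect,
         direct_prob = if (tot > 0) n_direct / tot else NA_real_,
         indirect_prob = if (tot > 0) n_indirect / tot else NA_real_)
}

#' @describeIn state_metrics Occupancy bar chart per state.
#' @param object A `state_metrics`.
#' @param ... Unused.
#' @method autoplot state_metrics
#' @export
autoplot.state_metrics <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$state), y = .data$occupancy)) +
    geom_col() +
    labs(x = "state", y = "fractional occupancy") +
    theme_minimal()
}
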