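#' Pairwise Euclidean distance matrix of measurements
#'
#' Rows of the feature columns (everything except the metadata columns
#' `subject`, `session`, `condition`) are treated as measurement vectors;
#' connectivity matrices should be supplied flattened, one row per scan.
#'
#' @param ms Tibble with metadata columns `subject` (required), optionally
#'   `session`/`condition`, and numeric feature columns.
#' @return Symmetric numeric matrix `M x M` with zero diagonal; the
#'   subject of each row is kept in the `subject` attribute.
#' @export
distance_matrix <- function(ms) {
  if (!"subject" %in% names(ms)) abort("ms needs a 'subject' column.")
  feat <- as.matrix(ms[, setdiff(names(ms), c("subject", "session", "condition")),
                       drop = FALSE])
  if (!all(is.finite(feat))) abort("features must be finite.")
  d <- as.matrix(dist(feat))
  dimnames(d) <- NULL
  attr(d, "subject") <- as.character(ms$subject)
  d
}

#' Mean nearest-rank (MNR) discriminability index
#'
#' Rank-based test-retest reliability: for every ordered within-subject
#' measurement pair `(i, j)`, `i != j`, all of measurement `i`'s
#' same-subject distances are excluded from the comparison pool, and
#' `r_ij = 1 - (#\{between-subject D[i,] < D[i,j]\} + 0.5 #\{=\}) / (N - S)`
#' with `N` the total measurement count and `S` the size of `i`'s subject
#' group. MNR is the mean over all such pairs: 1 means every repeat of a
#' subject is closer to its other repeats than to any other subject's
#' measurements; 0.5 is chance (exchangeable measurements). Invariant to
#' strictly monotone transforms of the distances.
#'
#' @param d Distance matrix from [distance_matrix()], or any symmetric
#'   matrix with a `subject` attribute (or `subject` passed separately).
#' @param subject Character/factor vector of per-measurement subject ids.
#' @return Single number in `[0, 1]`.
#' @export
mnr <- function(d, subject = attr(d, "subject")) {
  if (is.null(subject)) abort("subject ids are required.")
  subject <- as.character(subject)
  n_total <- nrow(d)
  if (length(subject) != n_total) abort("subject length must match the matrix.")
  if (length(unique(subject)) < 2) abort("need at least 2 subjects.")
  sizes <- table(subject)
  if (!any(sizes >= 2)) abort("need at least one subject with repeated measurements.")
  r_all <- c()
  for (i in seq_len(n_total)) {
    same <- which(subject == subject[i])
    s <- length(same)
    if (s < 2) next
    pool <- d[i, setdiff(seq_len(n_total), same)]
    for (j in setdiff(same, i)) {
      dij <- d[i, j]
      r <- 1 - (sum(pool < dij) + 0.5 * sum(pool == dij)) / (n_total - s)
      r_all <- c(r_all, r)
    }
  }
  mean(r_all)
}

#' Symmetrized Kullback-Leibler divergence
#'
#' `0.5 * (sum P log(P/Q) + sum Q log(Q/P))`. When either vector contains
#' zeros, additive smoothing `eps` is applied to both followed by
#' renormalization, so unvisited states do not produce infinities.
#'
#' @param p,q Non-negative vectors of equal length (normalized internally).
#' @param eps Smoothing constant (default `1e-10`), applied only when a
#'   zero is present.
#' @return Non-negative number; 0 iff the (smoothed) distributions match.
#' @export
sym_kl <- function(p, q, eps = 1e-10) {
  if (length(p) != length(q)) abort("p and q must have the same length.")
  if (any(p < 0) || any(q < 0)) abort("p and q must be non-negative.")
  p <- p / sum(p)
  q <- q / sum(q)
  if (any(p == 0) || any(q == 0)) {
    p <- (p + eps) / sum(p + eps)
    q <- (q + eps) / sum(q + eps)
  }
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

#' All pairwise symmetrized KL divergences between conditions
#'
#' @param occ Tibble or matrix: one row per condition, columns are state
#'   occupancy/occurrence values; a `condition` column (or rownames) names
#'   the rows.
#' @return Tibble of all unordered condition pairs (`C(n, 2)` rows) with
#'   their symmetrized KL divergence.
#' @export
kl_pairwise <- function(occ) {
  if (is.matrix(occ)) {
    cond <- rownames(occ) %||% as.character(seq_len(nrow(occ)))
    m <- occ
  } else {
    cond <- if ("condition" %in% names(occ)) as.character(occ$condition) else
      as.character(seq_len(nrow(occ)))
    m <- as.matrix(occ[, setdiff(names(occ), c("condition", "subject", "session")),
                       drop = FALSE])
  }
  pairs <- utils::combn(seq_len(nrow(m)), 2)
  tibble(condition_a = cond[pairs[1, ]],
         condition_b = cond[pairs[2, ]],
         sym_kl = apply(pairs, 2, function(ij) sym_kl(m[ij[1], ], m[ij[2], ])))
}

#' Per-scan state feature table for classifiers
#'
#' Collects per-scan state metrics into one feature row per scan over a
#' common state universe (union of states, zero-filled), with subject /
#' session / condition metadata, ready for any external classifier.
#'
#' @param metrics_list List of `state_metrics` (one per scan).
#' @param states State universe; defaults to the union over scans.
#' @param value Feature to export: occurrence frequency (default,
#'   runs per second) or fractional occupancy.
#' @return Tibble: `subject`, `session`, `condition`, one numeric column
#'   per state named `<value>_<state>`.
#' @export
occupancy_features <- function(metrics_list, states = NULL,
                               value = c("occurrence_hz", "occupancy")) {
  value <- match.arg(value)
  if (is.null(states)) {
    states <- sort(unique(unlist(lapply(metrics_list, function(m) m$state))))
  }
  rows <- lapply(metrics_list, function(m) {
    v <- setNames(rep(0, length(states)), states)
    v[as.character(m$state)] <- m[[value]]
    out <- tibble(subject = attr(m, "subject_id") %||% NA_character_,
                  session = attr(m, "session_id") %||% NA_character_,
                  condition = attr(m, "condition") %||% NA_character_)
    dplyr::bind_cols(out, as_tibble(as.list(setNames(v, paste0(value, "_", states)))))
  })
  bind_rows(rows)
}
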