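#' Instantaneous phases via the analytic signal
#'
#' Each column is demeaned and turned into its analytic signal
#' `z(t) = s(t) + i H[s](t)` (Hilbert transform computed in the frequency
#' domain); the instantaneous phase is the quadrant-aware angle of `z(t)`,
#' in `(-pi, pi]`. The first and last `trim` frames are flagged as outside
#' the valid range to guard against transform end effects.
#'
#' @param scan A `scan_record` (region- or network-level).
#' @param trim Non-negative integer; frames trimmed per end (default 1).
#' @return A `phase_series` tibble: column `frame` plus one phase column
#'   per region, with attributes `valid_start`/`valid_end` (1-based frame
#'   indices) and the scan metadata.
#' @export
hilbert_phase <- function(scan, trim = 1) {
  m <- scan_matrix(scan)
  t_len <- nrow(m)
  if (t_len < 4) abort("need at least 4 frames for phase estimation.")
  if (trim < 0 || trim != round(trim)) abort("trim must be a non-negative integer.")
  if (t_len - 2 * trim < 1) abort("trim leaves no valid frames.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant column(s) (zero variance): %s",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  phases <- apply(m, 2, function(x) Arg(analytic_signal(x - mean(x))))
  out <- as_tibble(as.data.frame(phases, check.names = FALSE))
  out <- dplyr::bind_cols(tibble(frame = seq_len(t_len)), out)
  attr(out, "valid_start") <- as.integer(trim + 1)
  attr(out, "valid_end") <- as.integer(t_len - trim)
  meta <- scan_meta(scan)
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  class(out) <- c("phase_series", class(out))
  out
}

# Analytic signal by one-sided spectrum doubling (discrete Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

phase_matrix <- function(phases) {
  as.matrix(as.data.frame(phases)[, setdiff(names(phases), "frame"), drop = FALSE])
}

#' Dynamic phase-locking matrix at one frame
#'
#' Entry `(i, j)` is `cos(phi_i(t) - phi_j(t))`: 1 for perfectly locked
#' regions, -1 for antiphase, 0 for quadrature. The matrix is symmetric
#' with unit diagonal and entries in `[-1, 1]`.
#'
#' @param phases A `phase_series`.
#' @param t Frame index (1-based, must lie in the valid range).
#' @return Symmetric numeric matrix `N x N` with region dimnames.
#' @export
dpl_matrix <- function(phases, t) {
  vs <- attr(phases, "valid_start")
  ve <- attr(phases, "valid_end")
  if (t < vs || t > ve) {
    abort(sprintf("frame %d outside valid range [%d, %d].", t, vs, ve))
  }
  ph <- phase_matrix(phases)[t, ]
  m <- cos(outer(ph, ph, "-"))
  dimnames(m) <- list(names(ph), names(ph))
  m
}

#' Leading eigenvector of a phase-locking matrix
#'
#' Returns the unit eigenvector of the largest eigenvalue, sign-fixed so
#' that the vector has strictly more non-positive than positive components
#' (zero counts as negative); on an exact tie the largest-magnitude
#' component is oriented negative. This is the community-splitting
#' convention that makes the downstream binarization deterministic.
#'
#' @param dpl Symmetric numeric matrix (tolerance `1e-10`).
#' @return List with `vector` (unit norm, sign-fixed) and `value`
#'   (largest eigenvalue).
#' @export
leading_eig <- function(dpl) {
  if (!is.matrix(dpl) || nrow(dpl) != ncol(dpl)) abort("dpl must be a square matrix.")
  if (max(abs(dpl - t(dpl))) > 1e-10) abort("dpl is not symmetric within 1e-10.")
  e <- eigen(dpl, symmetric = TRUE)
  v <- fix_eig_sign(e$vectors[, 1])
  names(v) <- rownames(dpl)
  list(vector = v, value = e$values[1])
}

#' Sign-fix an eigenvector
#'
#' @param v Numeric vector.
#' @return `v` or `-v`, oriented so non-positive components are in the
#'   strict majority; ties broken by making the largest-magnitude
#'   component negative.
#' @export
fix_eig_sign <- function(v) {
  n_nonpos <- sum(v <= 0)
  n_pos <- sum(v > 0)
  if (n_nonpos > n_pos) return(v)
  if (n_pos > n_nonpos) return(-v)
  i <- which.max(abs(v))
  if (v[i] > 0) -v else v
}

#' Binarize a sign-fixed eigenvector into an activity pattern
#'
#' Strictly positive components map to `+1` (active), non-positive to `-1`
#' (inactive). The threshold is fixed at zero by the bipartite structure
#' of the eigenvector; no free parameter is involved.
#'
#' @param v Sign-fixed numeric vector.
#' @return Integer vector in `{-1, +1}`.
#' @export
binarize_vector <- function(v) {
  ifelse(v > 0, 1L, -1L)
}

#' Leading-eigenvector series of a phase series
#'
#' Computes, for every frame in the valid range, the sign-fixed leading
#' eigenvector and eigenvalue of the frame's phase-locking matrix.
#'
#' @param phases A `phase_series`.
#' @return An `eig_series` tibble: `frame`, `eigenvalue`, one column per
#'   region holding the eigenvector components.
#' @export
eig_series <- function(phases) {
  vs <- attr(phases, "valid_start")
  ve <- attr(phases, "valid_end")
  ph <- phase_matrix(phases)
  frames <- vs:ve
  res <- lapply(frames, function(t) {
    m <- cos(outer(ph[t, ], ph[t, ], "-"))
    e <- eigen(m, symmetric = TRUE)
    list(v = fix_eig_sign(e$vectors[, 1]), val = e$values[1])
  })
  vecs <- do.call(rbind, lapply(res, `[[`, "v"))
  colnames(vecs) <- colnames(ph)
  out <- dplyr::bind_cols(
    tibble(frame = frames, eigenvalue = vapply(res, `[[`, numeric(1), "val")),
    as_tibble(as.data.frame(vecs, check.names = FALSE))
  )
  for (nm in c("subject_id", "session_id", "condition", "tr_seconds")) {
    attr(out, nm) <- attr(phases, nm)
  }
  class(out) <- c("eig_series", class(out))
  out
}

eig_matrix <- function(eigs) {
  as.matrix(as.data.frame(eigs)[, setdiff(names(eigs), c("frame", "eigenvalue")),
                                drop = FALSE])
}

#' Build a binary pattern series from eigenvectors
#'
#' @param eigs An `eig_series` (or any tibble with a `frame` column and
#'   component columns).
#' @return A `pattern_series` tibble: `frame`, `code`, and one `{-1, +1}`
#'   column per unit. Codes follow the convention of [encode_patterns()].
#' @export
binarize_eigs <- function(eigs) {
  vecs <- eig_matrix(eigs)
  pats <- t(apply(vecs, 1, binarize_vector))
  if (ncol(vecs) == 1) pats <- matrix(pats, ncol = 1)
  colnames(pats) <- colnames(vecs)
  new_pattern_series(pats, frames = eigs$frame,
                     meta = attributes(eigs)[c("subject_id", "session_id",
                                               "condition", "tr_seconds")])
}

new_pattern_series <- function(patterns, frames = seq_len(nrow(patterns)),
                               meta = list()) {
  codes <- encode_patterns(patterns)
  out <- dplyr::bind_cols(
    tibble(frame = frames, code = codes),
    as_tibble(as.data.frame(patterns, check.names = FALSE))
  )
  attr(out, "n_units") <- ncol(patterns)
  attr(out, "units") <- colnames(patterns)
  for (nm in names(meta)) if (!is.null(meta[[nm]])) attr(out, nm) <- meta[[nm]]
  class(out) <- c("pattern_series", class(out))
  out
}

pattern_codes <- function(series) series$code

#' Full phase-locking front end
#'
#' Composition `aggregate_networks` (optional) -> `hilbert_phase` ->
#' per-frame phase-locking matrix -> leading eigenvector -> binarization.
#' Output has `T - 2 * trim` frames.
#'
#' @param scan A `scan_record`.
#' @param map Optional `network_map`; if supplied, regions are averaged
#'   into networks first.
#' @param trim Frames trimmed per end (default 1).
#' @return A `pattern_series`.
#' @export
phase_pipeline <- function(scan, map = NULL, trim = 1) {
  if (!is.null(map)) scan <- aggregate_networks(scan, map)
  phases <- hilbert_phase(scan, trim = trim)
  binarize_eigs(eig_series(phases))
}
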