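#' Cluster leading eigenvectors into recurrent states (LEiDA)
#'
#' K-means with Euclidean distance on the sign-fixed leading eigenvectors
#' (ROI- or network-level), `n_init` random restarts seeded from `seed`;
#' the restart with the lowest inertia is kept, so the fit is
#' deterministic given `(seed, n_init)`.
#'
#' @param eigs An `eig_series` (frames x components).
#' @param k Number of clusters (`>= 1`; `k = 1` returns the mean vector).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param n_init Number of random restarts (default 20).
#' @return A `leida_model`: `k`, `centroids` (sign-fixed, `k x N`),
#'   `assignments` (tibble `frame`, `cluster`), `inertia`, `seed`.
#' @export
leida_fit <- function(eigs, k, seed, n_init = 20) {
  x <- eig_matrix(eigs)
  if (k > nrow(x)) abort("k exceeds the number of frames.")
  if (missing(seed)) abort("seed is mandatory.")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fit <- suppressWarnings(
    kmeans(x, centers = k, nstart = n_init, iter.max = 200)
  )
  centroids <- t(apply(fit$centers, 1, fix_eig_sign))
  if (k == 1) centroids <- matrix(fix_eig_sign(fit$centers[1, ]), nrow = 1)
  colnames(centroids) <- colnames(x)
  structure(list(
    k = k,
    centroids = centroids,
    assignments = tibble(frame = eigs$frame, cluster = as.integer(fit$cluster)),
    inertia = fit$tot.withinss,
    seed = seed,
    n_init = n_init
  ), class = "leida_model")
}

#' @describeIn leida_fit Fractional occupancy of each LEiDA cluster.
#' @param model A `leida_model`.
#' @export
leida_occupancy <- function(model) {
  model$assignments %>%
    count(.data$cluster, name = "n_frames") %>%
    tidyr::complete(cluster = seq_len(model$k), fill = list(n_frames = 0L)) %>%
    mutate(occupancy = .data$n_frames / sum(.data$n_frames))
}

#' Dunn index and distortion of a clustering
#'
#' Dunn index: minimum inter-cluster point-pair distance divided by the
#' maximum intra-cluster diameter (`Inf` when every cluster is a single
#' point or has zero diameter). Distortion: k-means inertia, the sum of
#' squared distances of samples to their assigned centroid.
#'
#' @param eigs The `eig_series` the model was fitted on.
#' @param model A `leida_model` with `k >= 2`.
#' @return Tibble with columns `dunn` and `distortion`.
#' @export
cluster_quality <- function(eigs, model) {
  if (model$k < 2) abort("cluster quality needs at least 2 clusters.")
  x <- eig_matrix(eigs)
  cl <- model$assignments$cluster
  if (length(unique(cl)) < model$k) abort("empty cluster in model.")
  d <- as.matrix(dist(x))
  same <- outer(cl, cl, "==")
  diam <- max(d[same & upper.tri(d)], 0)
  sep <- min(d[!same])
  dunn <- if (diam == 0) Inf else sep / diam
  tibble(dunn = dunn, distortion = model$inertia)
}

#' Amplitude-based binarization (conventional energy-landscape input)
#'
#' Each network column is z-scored and thresholded at zero: above-mean
#' frames are active (`+1`), others inactive (`-1`). The result feeds the
#' same maximum-entropy / landscape / dynamics chain as the phase-locking
#' front end. Invariant to positive rescaling of the signals.
#'
#' @param scan A network-level `scan_record` with non-constant columns.
#' @return A `pattern_series`.
#' @export
ela_binarize <- function(scan) {
  m <- scan_matrix(scan)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant column(s): %s",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  z <- scale(m)
  pats <- ifelse(z > 0, 1L, -1L)
  colnames(pats) <- colnames(m)
  new_pattern_series(pats, frames = seq_len(nrow(m)), meta = scan_meta(scan))
}
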