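#' Run the full phase-locking energy-landscape pipeline
#'
#' Convenience driver: binarized phase-locking patterns are extracted per
#' scan ([phase_pipeline()]), pooled frame-wise across scans (group-level
#' fit), a pairwise maximum-entropy model is fitted to the pooled
#' empirical pattern distribution, the energy landscape is constructed,
#' and each scan's frames are mapped to basin-level states with per-scan
#' dynamics metrics.
#'
#' @param scans A `scan_record` or list of them.
#' @param map Optional `network_map` applied to every scan.
#' @param trim Frames trimmed per end for the phase front end.
#' @param front_end `"phase"` (leading-eigenvector binarization, default)
#'   or `"amplitude"` (z-score binarization, the conventional baseline).
#' @param lr,tol,max_iter Passed to [fit_mem()].
#' @return List with `patterns` (per scan), `fit` (`mem_fit`),
#'   `landscape` (`energy_landscape`), `sequences` (per scan),
#'   `metrics` (per scan `state_metrics`).
#' @export
eplsa_run <- function(scans, map = NULL, trim = 1,
                      front_end = c("phase", "amplitude"),
                      lr = 0.2, tol = 1e-6, max_iter = 50000) {
  front_end <- match.arg(front_end)
  if (inherits(scans, "scan_record")) scans <- list(scans)
  patterns <- lapply(scans, function(sc) {
    if (front_end == "phase") {
      phase_pipeline(sc, map = map, trim = trim)
    } else {
      ela_binarize(if (is.null(map)) sc else aggregate_networks(sc, map))
    }
  })
  n_units <- attr(patterns[[1]], "n_units")
  pooled <- unlist(lapply(patterns, pattern_codes))
  emp <- empirical_distribution(pooled, n_units = n_units)
  fit <- fit_mem(emp, lr = lr, tol = tol, max_iter = max_iter)
  fit$units <- attr(patterns[[1]], "units")
  landscape <- energy_landscape(fit)
  sequences <- lapply(patterns, label_states, landscape = landscape)
  metrics <- lapply(sequences, state_metrics,
                    states = landscape$minima$state)
  list(patterns = patterns, fit = fit, landscape = landscape,
       sequences = sequences, metrics = metrics)
}
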