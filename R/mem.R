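#' Empirical distribution over binary activity patterns
#'
#' The relative frequency with which each of the `2^N` patterns is visited.
#'
#' @param series A `pattern_series`, or an integer vector of pattern codes.
#' @param n_units Number of binary units; taken from the series attribute
#'   when absent.
#' @return A `pattern_distribution` tibble with columns `code`, `count`,
#'   `prob` covering all `2^n_units` codes; attribute `n_samples` holds the
#'   number of frames.
#' @export
empirical_distribution <- function(series, n_units = NULL) {
  codes <- if (is.numeric(series)) as.integer(series) else pattern_codes(series)
  if (is.null(n_units)) n_units <- attr(series, "n_units")
  n_units <- check_n_units(n_units)
  if (length(codes) == 0) abort("empty pattern series.")
  if (any(codes < 0L) || any(codes >= 2^n_units)) {
    abort("pattern codes exceed 2^n_units - 1.")
  }
  counts <- tabulate(codes + 1L, nbins = 2^n_units)
  new_pattern_distribution(counts / length(codes), n_units,
                           counts = counts, n_samples = length(codes))
}

new_pattern_distribution <- function(probs, n_units, counts = NULL, n_samples = 0L) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12) {
    abort("probabilities must be non-negative and sum to 1 within 1e-12.")
  }
  out <- tibble(code = 0:(2^n_units - 1L),
                count = if (is.null(counts)) rep(NA_integer_, 2^n_units) else counts,
                prob = probs)
  attr(out, "n_units") <- as.integer(n_units)
  attr(out, "n_samples") <- as.integer(n_samples)
  class(out) <- c("pattern_distribution", class(out))
  out
}

#' Construct pairwise maximum-entropy model parameters
#'
#' @param h Numeric vector of basal activities (length `N`).
#' @param J Symmetric `N x N` interaction matrix with zero diagonal.
#' @return A `mem_params` list.
#' @export
mem_params <- function(h, J) {
  n <- length(h)
  if (!is.matrix(J) || !all(dim(J) == n)) abort("J must be an N x N matrix matching h.")
  if (max(abs(J - t(J))) > 1e-12) abort("J must be symmetric.")
  if (any(diag(J) != 0)) abort("J must have a zero diagonal.")
  structure(list(h = as.numeric(h), J = (J + t(J)) / 2, n_units = n),
            class = "mem_params")
}

#' Energy of activity patterns under the pairwise model
#'
#' `E(sigma) = -sum_i h_i sigma_i - (1/2) sum_{i != j} J_ij sigma_i sigma_j`.
#' Lower energy corresponds to higher model probability.
#'
#' @param patterns Matrix of `{-1, +1}` patterns (rows) or a single vector.
#' @param params A `mem_params`.
#' @return Numeric vector of energies, one per pattern.
#' @export
pattern_energy <- function(patterns, params) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1)
  s <- patterns
  as.numeric(-s %*% params$h - 0.5 * rowSums((s %*% params$J) * s))
}

# Energies over the full state space, indexed by code + 1.
all_energies <- function(params) {
  pattern_energy(pattern_matrix(params$n_units), params)
}

#' Boltzmann distribution of a pairwise maximum-entropy model
#'
#' Exact enumeration of all `2^N` patterns: `P(sigma) ~ exp(-E(sigma))`,
#' normalized with max-subtraction for numerical stability.
#'
#' @param params A `mem_params` with `n_units <= 20`.
#' @return A `pattern_distribution` (with `n_samples = 0`).
#' @export
boltzmann_distribution <- function(params) {
  e <- all_energies(params)
  w <- exp(-(e - min(e)))
  new_pattern_distribution(w / sum(w), params$n_units)
}

#' Exact first and second moments of a pattern distribution
#'
#' @param dist A `pattern_distribution` (empirical or model).
#' @return List with `mean` (`<sigma_i>`, length `N`) and `corr`
#'   (`<sigma_i sigma_j>`, symmetric with unit diagonal).
#' @export
distribution_moments <- function(dist) {
  n <- attr(dist, "n_units")
  s <- pattern_matrix(n)
  p <- dist$prob
  list(mean = as.numeric(crossprod(s, p)), corr = crossprod(s, p * s))
}

#' Exact model moments of a pairwise maximum-entropy model
#'
#' @param params A `mem_params`.
#' @return As [distribution_moments()], under the Boltzmann distribution.
#' @export
model_moments <- function(params) {
  distribution_moments(boltzmann_distribution(params))
}

#' Fit a pairwise maximum-entropy model by exact-gradient ascent
#'
#' Moment matching: the maximum-entropy principle requires the model's
#' first moments `<sigma_i>` and second moments `<sigma_i sigma_j>` to
#' equal the empirical ones. Model moments are computed exactly by
#' enumeration, so the gradient-ascent update
#' `h <- h + lr (m_emp - m_model)`, `J <- J + lr (C_emp - C_model)` climbs
#' the log-likelihood; with a small enough learning rate the likelihood is
#' non-decreasing (concave problem).
#'
#' @param emp A `pattern_distribution` (e.g. from
#'   [empirical_distribution()]).
#' @param lr Learning rate (default 0.2).
#' @param tol Convergence tolerance on the largest absolute moment
#'   discrepancy (default `1e-6`).
#' @param max_iter Iteration cap (default 50000).
#' @return A `mem_fit` object: fields `params` (`mem_params`), `report`
#'   (iterations, `max_moment_gap`, `converged`, `log_lik`), `n_units`,
#'   and the per-code energy table. Supports [tidy()] and [glance()].
#' @export
fit_mem <- function(emp, lr = 0.2, tol = 1e-6, max_iter = 50000) {
  n <- attr(emp, "n_units")
  s <- pattern_matrix(n)
  p_emp <- emp$prob
  m_emp <- as.numeric(crossprod(s, p_emp))
  c_emp <- crossprod(s, p_emp * s)
  h <- numeric(n)
  J <- matrix(0, n, n)
  two_n <- 2^n
  gap <- Inf
  prev_gap <- Inf
  worse <- 0L
  ll <- -Inf
  iter <- 0L
  repeat {
    e <- -as.numeric(s %*% h) - 0.5 * rowSums((s %*% J) * s)
    w <- exp(-(e - min(e)))
    p_mod <- w / sum(w)
    m_mod <- as.numeric(crossprod(s, p_mod))
    c_mod <- crossprod(s, p_mod * s)
    gh <- m_emp - m_mod
    gJ <- c_emp - c_mod
    diag(gJ) <- 0
    gap <- max(abs(gh), abs(gJ))
    ll <- sum(p_emp * log(p_mod))
    if (gap <= tol || iter >= max_iter) break
    worse <- if (gap > prev_gap) worse + 1L else 0L
    if (worse >= 100L) {
      abort("moment gap increased for 100 consecutive iterations; reduce lr.")
    }
    prev_gap <- gap
    h <- h + lr * gh
    J <- J + lr * gJ
    iter <- iter + 1L
  }
  params <- mem_params(h, J)
  units <- attr(emp, "units")
  structure(list(
    params = params,
    n_units = n,
    units = units,
    energies = tibble(code = 0:(two_n - 1L),
                      energy = pattern_energy(s, params)),
    report = list(iterations = iter, max_moment_gap = gap,
                  converged = gap <= tol, log_lik = ll)
  ), class = "mem_fit")
}

#' @export
print.mem_fit <- function(x, ...) {
  cat(sprintf("Pairwise maximum-entropy model fit (N = %d, 2^N = %d patterns)\n",
              x$n_units, 2^x$n_units))
  cat(sprintf("  iterations: %d  converged: %s  max moment gap: %.3g\n",
              x$report$iterations, x$report$converged, x$report$max_moment_gap))
  cat(sprintf("  mean log-likelihood per frame: %.4f\n", x$report$log_lik))
  invisible(x)
}

#' @describeIn fit_mem Tidy the fitted parameters: one row per `h_i` and
#'   per upper-triangle `J_ij`.
#' @param x A `mem_fit`.
#' @param ... Unused.
#' @method tidy mem_fit
#' @export
tidy.mem_fit <- function(x, ...) {
  n <- x$n_units
  units <- x$units %||% paste0("u", seq_len(n))
  hrows <- tibble(term = paste0("h[", units, "]"),
                  unit_i = units, unit_j = NA_character_,
                  estimate = x$params$h)
  idx <- which(upper.tri(x$params$J), arr.ind = TRUE)
  jrows <- tibble(term = paste0("J[", units[idx[, 1]], ",", units[idx[, 2]], "]"),
                  unit_i = units[idx[, 1]], unit_j = units[idx[, 2]],
                  estimate = x$params$J[idx])
  bind_rows(hrows, jrows)
}

#' @describeIn fit_mem One-row fit summary.
#' @method glance mem_fit
#' @export
glance.mem_fit <- function(x, ...) {
  tibble(n_units = x$n_units,
         n_patterns = 2^x$n_units,
         iterations = x$report$iterations,
         converged = x$report$converged,
         max_moment_gap = x$report$max_moment_gap,
         log_lik = x$report$log_lik)
}
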