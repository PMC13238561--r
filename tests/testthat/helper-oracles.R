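# Independent oracles: deliberately naive implementations used only to
# cross-check the package's algorithms on small landscapes.

# All codes at Hamming distance 1 from `code` (0-based), n units.
oracle_neighbours <- function(code, n) {
  vapply(seq_len(n), function(i) bitwXor(code, bitwShiftL(1L, n - i)), integer(1))
}

# Local minima by literal neighbour comparison.
oracle_minima <- function(energies, n) {
  codes <- 0:(2^n - 1L)
  keep <- vapply(codes, function(c) {
    all(energies[c + 1L] < energies[oracle_neighbours(c, n) + 1L])
  }, logical(1))
  codes[keep]
}

# Bottleneck (minimax) path cost between two codes on the hypercube:
# Dijkstra-style relaxation with cost = max node energy along the path,
# endpoints included.
oracle_bottleneck <- function(energies, from, to, n) {
  two_n <- 2^n
  best <- rep(Inf, two_n)
  best[from + 1L] <- energies[from + 1L]
  done <- rep(FALSE, two_n)
  repeat {
    u <- which.min(ifelse(done, Inf, best)) - 1L
    if (done[u + 1L] || is.infinite(best[u + 1L])) break
    if (u == to) return(best[u + 1L])
    done[u + 1L] <- TRUE
    for (v in oracle_neighbours(u, n)) {
      cand <- max(best[u + 1L], energies[v + 1L])
      if (cand < best[v + 1L]) best[v + 1L] <- cand
    }
  }
  best[to + 1L]
}

oracle_barriers <- function(energies, minima, n) {
  k <- length(minima)
  b <- matrix(NA_real_, k, k, dimnames = list(minima, minima))
  for (i in seq_len(k)) {
    b[i, i] <- energies[minima[i] + 1L]
    if (i < k) for (j in (i + 1):k) {
      b[i, j] <- b[j, i] <- oracle_bottleneck(energies, minima[i], minima[j], n)
    }
  }
  b
}

# Literal steepest-descent walk (no memoization), same tie rule:
# strictly lowest-energy neighbour, smallest code on ties.
oracle_descend <- function(energies, code, n) {
  repeat {
    nbc <- oracle_neighbours(code, n)
    ne <- energies[nbc + 1L]
    if (all(ne > energies[code + 1L])) return(code)
    lower <- nbc[ne < energies[code + 1L]]
    stopifnot(length(lower) > 0)  # oracle assumes tie-free energies
    code <- min(lower[energies[lower + 1L] == min(energies[lower + 1L])])
  }
}

oracle_basins <- function(energies, n) {
  vapply(0:(2^n - 1L), function(c) oracle_descend(energies, c, n), integer(1))
}

# Plain double-loop Euclidean distances.
oracle_dist <- function(x) {
  m <- nrow(x)
  d <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  }
  d
}

# Double-loop Dunn index and distortion.
oracle_cluster_quality <- function(x, cl, centers) {
  d <- oracle_dist(x)
  inter <- Inf
  diam <- 0
  m <- nrow(x)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    if (cl[i] == cl[j]) diam <- max(diam, d[i, j]) else inter <- min(inter, d[i, j])
  }
  distortion <- sum(vapply(seq_len(m), function(i) {
    sum((x[i, ] - centers[cl[i], ])^2)
  }, numeric(1)))
  list(dunn = if (diam == 0) Inf else inter / diam, distortion = distortion)
}

# Shared fixture builders --------------------------------------------------

make_state_seq <- function(labels, tr = 1) {
  out <- tibble::tibble(frame = seq_along(labels), code = 0L,
                        state = as.integer(labels))
  attr(out, "tr_seconds") <- tr
  class(out) <- c("state_sequence", class(out))
  out
}

fake_landscape_sizes <- function(sizes) {
  structure(list(minima = tibble::tibble(state = seq_along(sizes),
                                         code = seq_along(sizes) - 1L,
                                         pattern = "",
                                         energy = -sizes,
                                         basin_size = sizes),
                 n_units = 3L),
            class = "energy_landscape")
}

random_mem_params <- function(n, scale = 0.5) {
  h <- runif(n, -scale, scale)
  J <- matrix(0, n, n)
  J[upper.tri(J)] <- runif(n * (n - 1) / 2, -scale, scale)
  mem_params(h, J + t(J))
}

# Two-latent-state antiphase oscillator setup used across tests.
osc_offsets <- function() {
  rbind(c(0, 0, 0, pi, pi, pi, pi),
        c(0, pi, pi, 0, 0, pi, pi))
}
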