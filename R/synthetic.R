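#' Derive named sub-seeds from a master seed
#'
#' All generator randomness flows from one integer seed: the master seed
#' initializes R's RNG once and draws one 31-bit sub-seed per named
#' stream, so subjects/sessions get independent reproducible streams.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` sub-seeds in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Exact i.i.d. samples from a pairwise maximum-entropy model
#'
#' Draws pattern codes by inverse-CDF sampling from the fully enumerated
#' Boltzmann distribution -- exact, not MCMC.
#'
#' @param params A `mem_params` (`n_units <= 15` recommended).
#' @param n_frames Number of samples.
#' @param seed Integer seed.
#' @return A `pattern_series` with `n_frames` rows.
#' @export
sample_ising <- function(params, n_frames, seed) {
  dist <- boltzmann_distribution(params)
  codes <- with_seed(seed,
    sample(dist$code, n_frames, replace = TRUE, prob = dist$prob))
  pats <- decode_patterns(codes, params$n_units)
  colnames(pats) <- paste0("u", seq_len(params$n_units))
  new_pattern_series(pats)
}

#' Markov-switching phase-coupled oscillator BOLD generator
#'
#' A latent state path is drawn from a discrete Markov chain; while in
#' latent state `s`, network `j`'s signal is
#' `sin(2 pi f t + theta[s, j]) + noise`. States with different phase
#' -offset groupings produce different phase-locking patterns, giving a
#' ground truth for the full pipeline.
#'
#' @param offsets Matrix `n_states x N` of per-network phase offsets
#'   (radians); row `s` defines latent state `s`.
#' @param markov Row-stochastic `n_states x n_states` transition matrix.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param freq_hz Oscillation frequency (default 0.05 Hz, inside the
#'   conventional 0.009-0.08 Hz BOLD band).
#' @param tr_seconds Repetition time (default 0.72 s).
#' @param noise_sd Gaussian noise standard deviation (default 0.1;
#'   signal amplitude is 1).
#' @param init Initial latent distribution (default uniform).
#' @param networks Column labels (default `net1..netN`).
#' @param subject_id,session_id,condition Scan metadata.
#' @return List with `scan` (a `scan_record`) and `latent` (tibble
#'   `frame`, `state` of the ground-truth path).
#' @export
gen_oscillator_bold <- function(offsets, markov, n_frames, seed,
                                freq_hz = 0.05, tr_seconds = 0.72,
                                noise_sd = 0.1, init = NULL,
                                networks = NULL,
                                subject_id = "sim", session_id = "ses1",
                                condition = "sim") {
  offsets <- as.matrix(offsets)
  n_states <- nrow(offsets)
  n_net <- ncol(offsets)
  markov <- as.matrix(markov)
  if (!all(dim(markov) == n_states) || any(abs(rowSums(markov) - 1) > 1e-12)) {
    abort("markov must be a row-stochastic n_states x n_states matrix.")
  }
  if (is.null(init)) init <- rep(1 / n_states, n_states)
  if (is.null(networks)) networks <- paste0("net", seq_len(n_net))
  seeds <- split_seed(seed, 2)
  latent <- with_seed(seeds[1], {
    path <- integer(n_frames)
    path[1] <- sample.int(n_states, 1, prob = init)
    for (t in seq_len(n_frames - 1L)) {
      path[t + 1L] <- sample.int(n_states, 1, prob = markov[path[t], ])
    }
    path
  })
  tt <- (seq_len(n_frames) - 1) * tr_seconds
  base <- outer(tt, rep(2 * pi * freq_hz, n_net))
  signal <- sin(base + offsets[latent, , drop = FALSE])
  noise <- with_seed(seeds[2],
    matrix(rnorm(n_frames * n_net, sd = noise_sd), n_frames, n_net))
  m <- signal + noise
  colnames(m) <- networks
  list(scan = scan_record(m, subject_id = subject_id, session_id = session_id,
                          condition = condition, tr_seconds = tr_seconds),
       latent = tibble(frame = seq_len(n_frames), state = latent))
}

#' Multi-subject, multi-session measurement sets for reliability tests
#'
#' Two generating modes. `"markov"`: each subject draws once a
#' stay-probability for a two-state latent chain (logit-normal around
#' `base_stay` with sd `between_sd`); every session is a fresh chain
#' realization and the features are the per-state occupancies. This makes
#' within-subject feature similarity controllable through `between_sd`
#' relative to the occupancy sampling noise (longer `n_frames` = less
#' within-subject noise). `"gaussian"`: subject mean vectors
#' `~ N(0, between_sd^2)`, sessions add `N(0, within_sd^2)` noise --
#' direct control of the two dispersions (`within_sd = 0` gives perfectly
#' repeatable subjects; `between_sd = 0` gives exchangeable measurements).
#'
#' @param n_subjects,n_sessions Counts (both `>= 2`).
#' @param seed Integer seed (split into per-subject/session streams).
#' @param mode `"markov"` or `"gaussian"`.
#' @param n_features Feature dimension (gaussian mode).
#' @param between_sd Between-subject dispersion.
#' @param within_sd Within-subject (session) noise sd (gaussian mode).
#' @param base_stay Baseline stay probability of the latent chain
#'   (markov mode, default 0.9).
#' @param n_frames Frames per session (markov mode, default 500).
#' @return Tibble with `subject`, `session` and numeric feature columns,
#'   suitable for [distance_matrix()] / [mnr()].
#' @export
gen_reliability_set <- function(n_subjects, n_sessions, seed,
                                mode = c("markov", "gaussian"),
                                n_features = 4, between_sd = 1,
                                within_sd = 0.1, base_stay = 0.9,
                                n_frames = 500) {
  mode <- match.arg(mode)
  if (n_subjects < 2 || n_sessions < 2) abort("need >= 2 subjects and >= 2 sessions.")
  seeds <- split_seed(seed, n_subjects * (n_sessions + 1L))
  rows <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    k <- k + 1L
    if (mode == "markov") {
      stay <- with_seed(seeds[k], plogis(qlogis(base_stay) + rnorm(2, sd = between_sd)))
      for (ses in seq_len(n_sessions)) {
        k <- k + 1L
        occ <- with_seed(seeds[k], {
          st <- integer(n_frames)
          st[1] <- sample(1:2, 1)
          for (t in seq_len(n_frames - 1L)) {
            st[t + 1L] <- if (runif(1) < stay[st[t]]) st[t] else 3L - st[t]
          }
          c(mean(st == 1), mean(st == 2))
        })
        rows[[length(rows) + 1L]] <- tibble(subject = paste0("sub", s),
                                            session = paste0("ses", ses),
                                            f1 = occ[1], f2 = occ[2])
      }
    } else {
      mu <- with_seed(seeds[k], rnorm(n_features, sd = between_sd))
      for (ses in seq_len(n_sessions)) {
        k <- k + 1L
        x <- mu + with_seed(seeds[k],
          if (within_sd > 0) rnorm(n_features, sd = within_sd) else numeric(n_features))
        row <- c(list(subject = paste0("sub", s), session = paste0("ses", ses)),
                 setNames(as.list(x), paste0("f", seq_len(n_features))))
        rows[[length(rows) + 1L]] <- as_tibble(row)
      }
    }
  }
  bind_rows(rows)
}
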