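#' Local minima of an energy landscape
#'
#' A pattern is a local minimum when its energy is strictly lower than the
#' energies of all `N` patterns at Hamming distance 1 (single unit flips).
#'
#' @param energies Numeric vector of length `2^n_units`, indexed by
#'   pattern code + 1.
#' @param n_units Number of binary units.
#' @return Integer vector of minimum codes, sorted by energy ascending.
#' @export
find_minima <- function(energies, n_units) {
  n_units <- check_n_units(n_units)
  if (length(energies) != 2^n_units) abort("energies must have length 2^n_units.")
  if (!all(is.finite(energies))) abort("energies must be finite.")
  nb <- neighbour_codes(n_units)
  nb_min <- apply(matrix(energies[nb + 1L], nrow = nrow(nb)), 1, min)
  codes <- which(energies < nb_min) - 1L
  codes[order(energies[codes + 1L], codes)]
}

#' Assign every pattern to an attraction basin
#'
#' Steepest-descent walk: from each pattern repeatedly move to the
#' strictly lowest-energy single-flip neighbour until a local minimum is
#' reached; the pattern belongs to that minimum's basin. Ties between
#' equally low neighbours are broken toward the smallest pattern code. A
#' pattern on a plateau (no strictly lower neighbour, but an equal-energy
#' one) moves to the smallest-code equal-energy neighbour; such landscapes
#' are flagged as degenerate.
#'
#' @inheritParams find_minima
#' @return Integer vector of length `2^n_units`: the minimum code owning
#'   each pattern.
#' @export
assign_basins <- function(energies, n_units) {
  n_units <- check_n_units(n_units)
  two_n <- 2^n_units
  if (length(energies) != two_n) abort("energies must have length 2^n_units.")
  nb <- neighbour_codes(n_units)
  label <- rep(NA_integer_, two_n)
  degenerate <- FALSE
  for (start in 0:(two_n - 1L)) {
    if (!is.na(label[start + 1L])) next
    path <- integer(0)
    code <- start
    steps <- 0L
    repeat {
      if (!is.na(label[code + 1L])) {
        final <- label[code + 1L]
        break
      }
      path <- c(path, code)
      nbc <- nb[code + 1L, ]
      ne <- energies[nbc + 1L]
      own <- energies[code + 1L]
      lower <- nbc[ne < own]
      if (length(lower) > 0) {
        best <- min(energies[lower + 1L])
        cand <- lower[energies[lower + 1L] == best]
        code <- min(cand)
      } else {
        eq <- nbc[ne == own]
        if (length(eq) == 0) {
          final <- code
          break
        }
        degenerate <- TRUE
        code <- min(eq)
      }
      steps <- steps + 1L
      if (steps > two_n) {
        abort("steepest-descent walk exceeded 2^N steps (cycling plateau).")
      }
    }
    label[path + 1L] <- final
  }
  if (degenerate) {
    warn("plateau patterns encountered: landscape is degenerate; equal-energy moves used.")
  }
  label
}

#' Basin sizes as fractions of the state space
#'
#' @param basin_label Integer vector from [assign_basins()].
#' @param minima Integer vector of minimum codes (order of the output).
#' @return Numeric vector of fractions over `minima`; sums to 1.
#' @export
basin_sizes <- function(basin_label, minima = sort(unique(basin_label))) {
  vapply(minima, function(m) mean(basin_label == m), numeric(1))
}

#' Disconnectivity structure of an energy landscape
#'
#' Implements the threshold-lowering construction on the hypercube graph:
#' conceptually the threshold starts at the largest energy and steps down
#' through the distinct energy values, removing patterns at or above it;
#' the barrier between two minima is the lowest level at which they are
#' still connected. Computed equivalently (and provably identically) by a
#' union-find sweep that activates patterns in ascending energy order and
#' records the activation energy at which two minima's components first
#' merge -- the minimax (bottleneck) path energy.
#'
#' @inheritParams find_minima
#' @param minima Integer vector of minimum codes (from [find_minima()]).
#' @return List with `barriers` (symmetric matrix over minima;
#'   `barriers[a, a]` is the minimum's own energy) and `merges`, an
#'   hclust-style tibble (`left`, `right`, `height`) where negative
#'   entries index minima and positive entries earlier merge rows.
#' @export
disconnectivity <- function(energies, minima, n_units) {
  n_units <- check_n_units(n_units)
  two_n <- 2^n_units
  m_idx <- setNames(seq_along(minima), minima)
  n_min <- length(minima)
  if (n_min < 1) abort("need at least one local minimum.")
  barriers <- matrix(NA_real_, n_min, n_min,
                     dimnames = list(minima, minima))
  diag(barriers) <- energies[minima + 1L]
  merges <- list()
  if (n_min > 1) {
    nb <- neighbour_codes(n_units)
    parent <- integer(two_n)          # 0 = inactive
    comp_minima <- vector("list", two_n)
    comp_node <- rep(NA_integer_, two_n)  # tree node: -i leaf, +k merge row
    find_root <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    ord <- order(energies, seq_len(two_n))
    for (i in ord) {
      parent[i] <- i
      code <- i - 1L
      if (!is.na(m_idx[as.character(code)])) {
        comp_minima[[i]] <- code
        comp_node[i] <- -as.integer(m_idx[as.character(code)])
      }
      for (j in nb[i, ] + 1L) {
        if (parent[j] == 0L) next
        ra <- find_root(i)
        rb <- find_root(j)
        if (ra == rb) next
        ma <- comp_minima[[ra]]
        mb <- comp_minima[[rb]]
        if (length(ma) > 0 && length(mb) > 0) {
          e_th <- energies[i]
          for (a in ma) for (b in mb) {
            barriers[m_idx[as.character(a)], m_idx[as.character(b)]] <- e_th
            barriers[m_idx[as.character(b)], m_idx[as.character(a)]] <- e_th
          }
          merges[[length(merges) + 1L]] <-
            list(left = comp_node[ra], right = comp_node[rb], height = e_th)
          node <- length(merges)
        } else {
          node <- if (length(ma) > 0) comp_node[ra] else comp_node[rb]
        }
        parent[rb] <- ra
        comp_minima[[ra]] <- c(ma, mb)
        comp_minima[[rb]] <- integer(0)
        comp_node[ra] <- node
      }
    }
  }
  merges <- if (length(merges) == 0) {
    tibble(left = integer(0), right = integer(0), height = numeric(0))
  } else {
    bind_rows(lapply(merges, as_tibble))
  }
  list(barriers = barriers, merges = merges)
}

#' Construct the full energy landscape of a fitted model
#'
#' Enumerates all `2^N` energies, finds local minima, assigns every
#' pattern to an attraction basin by steepest descent, and builds the
#' disconnectivity structure (pairwise minimax energy barriers and the
#' merge tree).
#'
#' @param x A `mem_fit`, a `mem_params`, or a numeric vector of `2^N`
#'   energies.
#' @param n_units Required when `x` is a bare energy vector.
#' @param units Optional unit (network) labels for pattern strings.
#' @return An `energy_landscape` object with fields `energies` (tibble
#'   `code`, `energy`, `basin` = owning minimum code), `minima` (tibble
#'   `state`, `code`, `pattern`, `energy`, `basin_size`), `barriers`,
#'   `merges`, `n_units`. Supports [tidy()], [glance()], [autoplot()].
#' @export
energy_landscape <- function(x, n_units = NULL, units = NULL) {
  if (inherits(x, "mem_fit")) {
    energies <- x$energies$energy
    n_units <- x$n_units
    units <- units %||% x$units
  } else if (inherits(x, "mem_params")) {
    n_units <- x$n_units
    energies <- all_energies(x)
  } else {
    if (is.null(n_units)) abort("n_units is required for a bare energy vector.")
    energies <- as.numeric(x)
  }
  n_units <- check_n_units(n_units)
  minima <- find_minima(energies, n_units)
  if (length(minima) == 0) {
    abort("landscape has no local minimum (degenerate energies).")
  }
  basin <- assign_basins(energies, n_units)
  sizes <- basin_sizes(basin, minima)
  disc <- disconnectivity(energies, minima, n_units)
  pats <- decode_patterns(minima, n_units)
  pat_str <- apply(pats, 1, function(p) paste(ifelse(p > 0, "+", "-"), collapse = ""))
  structure(list(
    energies = tibble(code = 0:(2^n_units - 1L), energy = energies, basin = basin),
    minima = tibble(state = seq_along(minima), code = minima,
                    pattern = pat_str, energy = energies[minima + 1L],
                    basin_size = sizes),
    barriers = disc$barriers,
    merges = disc$merges,
    n_units = n_units,
    units = units
  ), class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Energy landscape: N = %d units, %d patterns, %d local minima\n",
              x$n_units, 2^x$n_units, nrow(x$minima)))
  print(x$minima)
  invisible(x)
}

#' @describeIn energy_landscape One row per local minimum (state), with
#'   pattern string, energy, and basin size.
#' @param ... Unused.
#' @method tidy energy_landscape
#' @export
tidy.energy_landscape <- function(x, ...) x$minima

#' @describeIn energy_landscape One-row landscape summary.
#' @method glance energy_landscape
#' @export
glance.energy_landscape <- function(x, ...) {
  tibble(n_units = x$n_units, n_patterns = 2^x$n_units,
         n_minima = nrow(x$minima),
         min_energy = min(x$energies$energy),
         max_energy = max(x$energies$energy),
         max_barrier = if (nrow(x$minima) > 1) {
           max(x$barriers[upper.tri(x$barriers)])
         } else x$minima$energy[1])
}

#' Export a disconnectivity tree in Newick format
#'
#' Leaves are local minima named `<code>_<pattern>`; branch lengths are
#' merge height minus child height, so leaf depths reproduce minima
#' energies and internal node heights the energy barriers (ultrametric in
#' barrier space).
#'
#' @param landscape An `energy_landscape`.
#' @param path Optional file; when given the string is written there.
#' @return Newick string, invisibly when `path` is given.
#' @export
landscape_newick <- function(landscape, path = NULL) {
  minima <- landscape$minima
  leaf_name <- paste0(minima$code, "_", minima$pattern)
  merges <- landscape$merges
  node_str <- function(id, parent_height) {
    if (id < 0) {
      i <- -id
      sprintf("%s:%.10g", leaf_name[i], parent_height - minima$energy[i])
    } else {
      row <- merges[id, ]
      sprintf("(%s,%s):%.10g",
              node_str(row$left, row$height), node_str(row$right, row$height),
              parent_height - row$height)
    }
  }
  nwk <- if (nrow(merges) == 0) {
    sprintf("%s;", leaf_name[1])
  } else {
    root <- nrow(merges)
    row <- merges[root, ]
    sprintf("(%s,%s);", node_str(row$left, row$height), node_str(row$right, row$height))
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' @describeIn energy_landscape Disconnectivity-graph plot: leaves at
#'   minima energies, horizontal joins at barrier heights.
#' @param object An `energy_landscape`.
#' @method autoplot energy_landscape
#' @export
autoplot.energy_landscape <- function(object, ...) {
  minima <- object$minima
  merges <- object$merges
  n_min <- nrow(minima)
  # leaf x positions from recursive tree layout (or sequential if single)
  xpos <- numeric(n_min)
  heights <- minima$energy
  if (n_min > 1 && nrow(merges) > 0) {
    counter <- 0
    assign_x <- function(id) {
      if (id < 0) {
        counter <<- counter + 1
        xpos[-id] <<- counter
        counter
      } else {
        l <- assign_x(merges$left[id])
        r <- assign_x(merges$right[id])
        (l + r) / 2
      }
    }
    assign_x(nrow(merges))
  } else {
    xpos <- seq_len(n_min)
  }
  node_xs <- numeric(nrow(merges))
  node_x <- function(id) if (id < 0) xpos[-id] else node_xs[id]
  node_h <- function(id) if (id < 0) heights[-id] else merges$height[id]
  segs <- list()
  if (nrow(merges) > 0) {
    for (k in seq_len(nrow(merges))) {
      xl <- node_x(merges$left[k]); xr <- node_x(merges$right[k])
      hl <- node_h(merges$left[k]); hr <- node_h(merges$right[k])
      hk <- merges$height[k]
      node_xs[k] <- (xl + xr) / 2
      segs[[length(segs) + 1]] <- tibble(
        x = c(xl, xr, xl), xend = c(xl, xr, xr),
        y = c(hl, hr, hk), yend = c(hk, hk, hk))
    }
  }
  seg_df <- if (length(segs)) bind_rows(segs) else
    tibble(x = numeric(0), xend = numeric(0), y = numeric(0), yend = numeric(0))
  leaf_df <- tibble(x = xpos, y = heights, label = minima$pattern)
  ggplot() +
    geom_segment(data = seg_df,
                 aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)) +
    geom_point(data = leaf_df, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = leaf_df,
                       aes(x = .data$x, y = .data$y, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    labs(x = NULL, y = "energy", title = "Disconnectivity graph") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
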