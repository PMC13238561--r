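test_that("local minima require strictly lower energy than all neighbours", {
  n <- 3
  expect_equal(find_minima(rep(1, 2^n), n), integer(0))

  # single global minimum at code 0, energy = Hamming weight
  hw <- rowSums(pattern_matrix(4) == 1)
  expect_equal(find_minima(hw, 4), 0L)

  set.seed(41)
  for (rep in 1:10) {
    e <- runif(2^4)
    expect_setequal(find_minima(e, 4), oracle_minima(e, 4))
  }
})

test_that("minima are returned sorted by energy", {
  set.seed(42)
  e <- runif(2^5)
  m <- find_minima(e, 5)
  expect_true(all(diff(e[m + 1L]) >= 0))
})

test_that("a single-minimum landscape gives a trivial disconnectivity tree", {
  hw <- rowSums(pattern_matrix(3) == 1)
  mins <- find_minima(hw, 3)
  disc <- disconnectivity(hw, mins, 3)
  expect_equal(dim(disc$barriers), c(1L, 1L))
  expect_equal(disc$barriers[1, 1], hw[1])
  expect_equal(nrow(disc$merges), 0L)
})

test_that("the two-minimum hand-built landscape crosses the lower saddle", {
  # N = 2: minima at 00 and 11; paths 00-01-11 (saddle 2) and 00-10-11 (3)
  e <- c(0, 2, 3, 0.5)
  mins <- find_minima(e, 2)
  expect_equal(mins, c(0L, 3L))
  disc <- disconnectivity(e, mins, 2)
  expect_equal(disc$barriers["0", "3"], 2)
  expect_equal(diag(disc$barriers), c("0" = 0, "3" = 0.5))
})

test_that("barriers equal independent minimax path costs on random landscapes", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    e <- runif(2^n)
    mins <- find_minima(e, n)
    disc <- disconnectivity(e, mins, n)
    expect_equal(disc$barriers, oracle_barriers(e, mins, n), tolerance = 0)
  }
})

test_that("barriers are ultrametric over minima triples", {
  set.seed(44)
  for (rep in 1:10) {
    e <- runif(2^5)
    mins <- find_minima(e, 5)
    b <- disconnectivity(e, mins, 5)$barriers
    k <- length(mins)
    if (k < 3) next
    for (a in 1:k) for (bb in 1:k) for (cc in 1:k) {
      if (a == bb || bb == cc || a == cc) next
      expect_lte(b[a, cc], max(b[a, bb], b[bb, cc]) + 1e-12)
    }
  }
})

test_that("steepest-descent basins match the exhaustive oracle", {
  set.seed(45)
  for (rep in 1:10) {
    n <- sample(4:5, 1)
    e <- runif(2^n)
    expect_equal(assign_basins(e, n), oracle_basins(e, n))
  }
})

test_that("minima are fixed points and single-minimum basins cover everything", {
  set.seed(46)
  e <- runif(2^5)
  lab <- assign_basins(e, 5)
  mins <- find_minima(e, 5)
  expect_equal(lab[mins + 1L], mins)

  hw <- rowSums(pattern_matrix(4) == 1)
  lab1 <- assign_basins(hw, 4)
  expect_true(all(lab1 == 0L))
  expect_equal(basin_sizes(lab1), 1)
})

test_that("energy strictly decreases along descent paths", {
  set.seed(47)
  n <- 5
  e <- runif(2^n)
  nb <- eplsa:::neighbour_codes(n)
  for (start in sample(0:(2^n - 1), 10)) {
    code <- start
    repeat {
      ne <- e[nb[code + 1L, ] + 1L]
      if (all(ne > e[code + 1L])) break
      nxt <- nb[code + 1L, ][which.min(ne)]
      expect_lt(e[nxt + 1L], e[code + 1L])
      code <- nxt
    }
  }
})

test_that("a symmetric ferromagnetic double well splits the space evenly", {
  n <- 5
  J <- matrix(0.3, n, n); diag(J) <- 0
  L <- energy_landscape(mem_params(numeric(n), J))
  expect_equal(sort(L$minima$code), c(0L, 2^n - 1L))
  expect_equal(L$minima$basin_size, c(0.5, 0.5))
  expect_equal(sum(L$minima$basin_size), 1)
})

test_that("basin fractions always partition the state space", {
  set.seed(48)
  for (rep in 1:5) {
    e <- runif(2^6)
    lab <- assign_basins(e, 6)
    expect_equal(sum(basin_sizes(lab)), 1)
  }
})

test_that("the Newick export encodes leaf energies and barrier heights", {
  skip_if_not_installed("ape")
  set.seed(49)
  par <- random_mem_params(5, scale = 0.8)
  L <- energy_landscape(par)
  if (nrow(L$minima) < 2) skip("landscape drew a single minimum")
  tr <- ape::read.tree(text = landscape_newick(L))
  expect_equal(ape::Ntip(tr), nrow(L$minima))
  # depth from root + leaf energy must be constant = root merge height
  depth <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  energy <- L$minima$energy[match(as.integer(sub("_.*", "", tr$tip.label)),
                                  L$minima$code)]
  root_h <- max(L$merges$height)
  expect_equal(depth + energy, rep(root_h, length(depth)))
  # pairwise merge heights in the tree equal barrier entries
  for (i in 1:(nrow(L$minima) - 1)) {
    for (j in (i + 1):nrow(L$minima)) {
      tip_i <- which(as.integer(sub("_.*", "", tr$tip.label)) == L$minima$code[i])
      tip_j <- which(as.integer(sub("_.*", "", tr$tip.label)) == L$minima$code[j])
      d_ij <- ape::dist.nodes(tr)[tip_i, tip_j]
      expected <- 2 * L$barriers[i, j] - L$minima$energy[i] - L$minima$energy[j]
      expect_equal(unname(d_ij), expected, tolerance = 1e-8)
    }
  }
})

test_that("landscape accessors and summaries are consistent", {
  set.seed(50)
  par <- random_mem_params(6)
  L <- energy_landscape(par)
  expect_equal(nrow(L$energies), 64)
  expect_equal(tidy(L), L$minima)
  gl <- glance(L)
  expect_equal(gl$n_minima, nrow(L$minima))
  expect_s3_class(autoplot(L), "ggplot")
})
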