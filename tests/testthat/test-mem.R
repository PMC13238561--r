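test_that("empirical distribution counts pattern visits", {
  d <- empirical_distribution(c(0L, 0L, 3L), n_units = 2)
  expect_equal(d$prob, c(2 / 3, 0, 0, 1 / 3))
  expect_equal(attr(d, "n_samples"), 3L)

  d2 <- empirical_distribution(rep(5L, 10), n_units = 3)
  expect_equal(d2$prob[6], 1)

  d3 <- empirical_distribution(0:7, n_units = 3)
  expect_equal(d3$prob, rep(1 / 8, 8))

  expect_error(empirical_distribution(integer(0), n_units = 2), "empty")
  expect_error(empirical_distribution(4L, n_units = 2), "exceed")
})

test_that("pattern energies match the Ising form by hand", {
  n <- 3
  expect_equal(pattern_energy(pattern_matrix(n),
                              mem_params(numeric(n), matrix(0, n, n))),
               rep(0, 2^n))

  j <- 0.7
  J <- matrix(c(0, j, j, 0), 2, 2)
  par <- mem_params(c(0, 0), J)
  expect_equal(pattern_energy(c(1, 1), par), -j)
  expect_equal(pattern_energy(c(1, -1), par), j)

  set.seed(3)
  par2 <- random_mem_params(5)
  par2$h[] <- 0   # global spin-flip symmetry holds at zero field
  pm <- pattern_matrix(5)
  expect_equal(pattern_energy(pm, par2), pattern_energy(-pm, par2))
})

test_that("Boltzmann distribution matches closed forms and monotonicity", {
  par0 <- mem_params(numeric(7), matrix(0, 7, 7))
  expect_equal(boltzmann_distribution(par0)$prob, rep(1 / 128, 128))

  j <- 0.4
  par <- mem_params(c(0, 0), matrix(c(0, j, j, 0), 2, 2))
  d <- boltzmann_distribution(par)
  expect_equal(d$prob[4], exp(j) / (2 * exp(j) + 2 * exp(-j)))  # code 3 = (+,+)

  set.seed(8)
  par2 <- random_mem_params(5)
  d2 <- boltzmann_distribution(par2)
  e2 <- eplsa:::all_energies(par2)
  ord <- order(e2)
  expect_true(all(diff(d2$prob[ord]) <= 1e-15))
  expect_equal(sum(d2$prob), 1)
})

test_that("exact model moments behave at limits and match sampling", {
  par0 <- mem_params(numeric(4), matrix(0, 4, 4))
  mm <- model_moments(par0)
  expect_equal(mm$mean, rep(0, 4))
  expect_equal(mm$corr - diag(4), matrix(0, 4, 4))

  par_sat <- mem_params(c(6, 0, 0), matrix(0, 3, 3))
  expect_gt(model_moments(par_sat)$mean[1], 0.999)

  set.seed(21)
  par <- random_mem_params(5)
  mm2 <- model_moments(par)
  n_samp <- 1e5
  emp <- distribution_moments(
    empirical_distribution(sample_ising(par, n_samp, seed = 77)))
  se <- 1 / sqrt(n_samp)   # Var(sigma_i) <= 1
  expect_lt(max(abs(emp$mean - mm2$mean)), 3 * se * 1.5)
  expect_lt(max(abs(emp$corr - mm2$corr)), 3 * se * 1.5)
})

test_that("fitting an exact Boltzmann distribution recovers the parameters", {
  set.seed(11)
  par0 <- random_mem_params(6)
  fit <- fit_mem(boltzmann_distribution(par0))
  expect_true(fit$report$converged)
  expect_lte(fit$report$max_moment_gap, 1e-6)
  expect_lt(max(abs(fit$params$h - par0$h)), 1e-4)
  expect_lt(max(abs(fit$params$J - par0$J)), 1e-4)
})

test_that("the uniform distribution is a zero-parameter fixed point", {
  emp <- eplsa:::new_pattern_distribution(rep(1 / 16, 16), 4)
  fit <- fit_mem(emp)
  expect_equal(fit$report$iterations, 0L)
  expect_equal(fit$params$h, rep(0, 4))
  expect_equal(fit$params$J, matrix(0, 4, 4))
})

test_that("log-likelihood is non-decreasing and moments match at convergence", {
  set.seed(14)
  pat <- sample_ising(random_mem_params(5), 2000, seed = 5)
  emp <- empirical_distribution(pat)
  lls <- c()
  for (iters in c(5, 25, 100, 1000)) {
    f <- fit_mem(emp, max_iter = iters)
    lls <- c(lls, f$report$log_lik)
  }
  expect_true(all(diff(lls) >= -1e-12))
  fit <- fit_mem(emp)
  expect_true(fit$report$converged)
  memp <- distribution_moments(emp)
  mmod <- model_moments(fit$params)
  expect_lt(max(abs(memp$mean - mmod$mean)), 1e-6)
  expect_lt(max(abs(memp$corr - mmod$corr)), 2e-6)
})

test_that("the pairwise model fits at least as well as the independent model", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 4
    p <- runif(2^n); p <- p / sum(p)
    emp <- eplsa:::new_pattern_distribution(p, n)
    fit <- fit_mem(emp)
    q_pair <- boltzmann_distribution(fit$params)$prob
    m <- distribution_moments(emp)$mean
    pm <- pattern_matrix(n)
    q_ind <- apply(pm, 1, function(s) prod((1 + s * m) / 2))
    kl <- function(q) sum(p * log(p / q))
    expect_lte(kl(q_pair), kl(q_ind) + 1e-9)
  }
})

test_that("tidy and glance expose parameters and fit diagnostics", {
  set.seed(2)
  fit <- fit_mem(boltzmann_distribution(random_mem_params(4)))
  td <- tidy(fit)
  expect_equal(nrow(td), 4 + 6)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_patterns, 16)
  expect_true(gl$converged)
})
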