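cosine_scan <- function(t_len = 240, tr = 1, f = 0.04, phi0 = c(0, -pi / 2)) {
  tt <- (seq_len(t_len) - 1) * tr
  m <- sapply(phi0, function(p0) cos(2 * pi * f * tt + p0))
  colnames(m) <- paste0("s", seq_along(phi0))
  scan_record(m, tr_seconds = tr)
}

wrap_pi <- function(x) atan2(sin(x), cos(x))

test_that("a pure cosine recovers its analytic phase ramp", {
  tr <- 1; f <- 0.05; t_len <- 240   # 12 full cycles
  sc <- cosine_scan(t_len, tr, f, phi0 = c(0, 0.4))
  ph <- hilbert_phase(sc, trim = 1)
  tt <- (seq_len(t_len) - 1) * tr
  interior <- 13:(t_len - 12)
  err <- abs(wrap_pi(ph$s1[interior] - 2 * pi * f * tt[interior]))
  expect_lt(max(err), 0.05)
})

test_that("sine is the quadrature (-pi/2 shifted) phase of cosine", {
  t_len <- 240; tr <- 1; f <- 0.05
  tt <- (seq_len(t_len) - 1) * tr
  m <- cbind(c1 = cos(2 * pi * f * tt), s1 = sin(2 * pi * f * tt))
  ph <- hilbert_phase(scan_record(m, tr_seconds = tr), trim = 1)
  interior <- 25:(t_len - 24)
  err <- abs(wrap_pi(ph$s1[interior] - (ph$c1[interior] - pi / 2)))
  expect_lt(max(err), 0.05)
})

test_that("degenerate inputs to the phase front end error out", {
  m <- cbind(a = rep(1, 10), b = rnorm(10))
  expect_error(hilbert_phase(scan_record(m)), "constant column.*a")
  m2 <- cbind(a = rnorm(3), b = rnorm(3))
  expect_error(scan_record(m2) |> hilbert_phase(), "at least 4")
})

test_that("phase-locking entries follow cos of phase differences", {
  t_len <- 8
  phs <- matrix(c(0.3, 0.3, 0.3 + pi, 0.3 + pi / 2), nrow = t_len, ncol = 4,
                byrow = TRUE)
  sc <- scan_record(matrix(rnorm(t_len * 4), t_len, 4,
                           dimnames = list(NULL, paste0("n", 1:4))))
  ph <- hilbert_phase(sc, trim = 1)
  # overwrite phases with hand values to isolate dpl_matrix
  for (j in 1:4) ph[[paste0("n", j)]] <- phs[, j]
  d <- dpl_matrix(ph, 3)
  expect_equal(d[1, 2], 1)                     # identical phases
  expect_equal(d[1, 3], -1)                    # antiphase
  expect_equal(d[1, 4], 0, tolerance = 1e-12)  # quadrature
  expect_error(dpl_matrix(ph, t_len), "valid range")
})

test_that("phase-locking matrices are symmetric, unit-diagonal, bounded", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    phi <- runif(n, -pi, pi)
    d <- cos(outer(phi, phi, "-"))
    expect_equal(d, t(d))
    expect_equal(diag(d), rep(1, n))
    expect_true(all(d >= -1 - 1e-12 & d <= 1 + 1e-12))
  }
})

test_that("leading eigenvector solves closed-form and residual checks", {
  n <- 6
  ones <- matrix(1, n, n)
  e <- leading_eig(ones)
  expect_equal(e$value, n)
  expect_equal(abs(unname(e$vector)), rep(1 / sqrt(n), n))

  for (c in c(0.2, 0.9)) {
    m <- matrix(c(1, c, c, 1), 2, 2)
    e2 <- leading_eig(m)
    expect_equal(e2$value, 1 + c)
    expect_equal(abs(e2$vector[1]), abs(e2$vector[2]))
  }

  set.seed(17)
  for (rep in 1:10) {
    phi <- runif(5, -pi, pi)
    m <- cos(outer(phi, phi, "-"))
    e3 <- leading_eig(m)
    expect_lt(max(abs(m %*% e3$vector - e3$value * e3$vector)), 1e-8)
    expect_equal(sum(e3$vector^2), 1)
  }

  expect_error(leading_eig(matrix(c(1, 0.5, 0.1, 1), 2, 2)), "symmetric")
})

test_that("degenerate leading eigenvalue still yields deterministic output", {
  e1 <- leading_eig(diag(4))
  e2 <- leading_eig(diag(4))
  expect_identical(e1, e2)
  expect_equal(sum(e1$vector^2), 1)
})

test_that("sign convention puts non-positive components in the majority", {
  v <- c(0.8, -0.1, -0.2)
  expect_equal(fix_eig_sign(v), v)          # already 2 negative of 3
  expect_equal(fix_eig_sign(-v), v)         # global flip undone
  # tie at N = 2: largest-magnitude component oriented negative
  expect_equal(fix_eig_sign(c(0.9, -0.3)), c(-0.9, 0.3))
  # zero counts as negative: (0, -0.1) already outnumber (0.3), keep as is
  expect_equal(fix_eig_sign(c(0.3, 0, -0.1)), c(0.3, 0, -0.1))
})

test_that("binarization maps sign-fixed components with zero inactive", {
  expect_equal(binarize_vector(c(0.3, -0.2, 0)), c(1L, -1L, -1L))
  expect_equal(binarize_vector(c(-1, -2)), c(-1L, -1L))
  v <- c(0.5, -0.4, -0.3)
  expect_equal(binarize_vector(fix_eig_sign(v)), binarize_vector(fix_eig_sign(-v)))
})

test_that("antiphase networks binarize to opposite states every frame", {
  t_len <- 300
  tt <- seq_len(t_len) * 0.72
  m <- cbind(a = sin(2 * pi * 0.05 * tt), b = sin(2 * pi * 0.05 * tt + pi))
  pat <- phase_pipeline(scan_record(m, tr_seconds = 0.72), trim = 2)
  expect_true(all(pat$a * pat$b == -1L))
})

test_that("full synchrony yields one constant all-inactive pattern", {
  t_len <- 200
  tt <- seq_len(t_len) * 0.72
  base <- sin(2 * pi * 0.05 * tt)
  m <- cbind(a = base, b = base, c = base)
  pat <- phase_pipeline(scan_record(m, tr_seconds = 0.72), trim = 2)
  expect_equal(unique(pat$code), 0L)
})

test_that("trimming removes exactly trim frames per end", {
  m <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  pat <- phase_pipeline(scan_record(m), trim = 1)
  expect_equal(nrow(pat), 8L)
  expect_equal(pat$frame, 2:9)
})
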