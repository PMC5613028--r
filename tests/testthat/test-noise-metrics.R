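test_that("compute_stats reproduces hand-computed values", {
  s <- compute_stats(c(5, 5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$cv, 0)
  expect_equal(s$fano, 0)

  s <- compute_stats(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(s$cv, 0.5)
  expect_equal(s$fano, 1.0)

  # sum of squared deviations 32 over n - 1 = 7
  s <- compute_stats(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(s$mean, 5)
  expect_equal(s$sd^2, 32 / 7)
  expect_equal(s$cv, sqrt(32 / 7) / 5, tolerance = 1e-12)
  expect_equal(s$fano, 32 / 7 / 5, tolerance = 1e-12)
})

test_that("degenerate samples raise informative errors", {
  expect_error(compute_stats(5), "insufficient data")
  expect_error(compute_stats(numeric(0)), "insufficient data")
  expect_error(compute_stats(c(-1, 1)), "mean = 0")
})

test_that("CV is scale-invariant and Fano scales linearly", {
  chk <- scale_invariance_check(c(2, 4, 6), 10)
  expect_identical(unname(chk["cv_error"]), 0)
  s10 <- compute_stats(10 * c(2, 4, 6))
  expect_equal(s10$cv, 0.5)
  expect_equal(s10$fano, 10.0)

  set.seed(11)
  for (i in 1:100) {
    x <- stats::rlnorm(sample(5:40, 1), meanlog = 3)
    c_fac <- stats::runif(1, 0.01, 100)
    chk <- scale_invariance_check(x, c_fac)
    expect_lt(chk[["cv_error"]], 1e-12 * compute_stats(x)$cv)
    expect_lt(chk[["fano_error"]], 1e-12 * c_fac * compute_stats(x)$fano)
  }
})

test_that("sample Fano factor of Poisson counts approaches 1", {
  set.seed(7)
  n <- 20000
  x <- stats::rpois(n, lambda = 12)
  f <- compute_stats(x)$fano
  # var(Fano) ~ 2/n for Poisson
  expect_lt(abs(f - 1), 3 * sqrt(2 / n))
})
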