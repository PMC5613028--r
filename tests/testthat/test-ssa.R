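test_that("zero total propensity freezes the state", {
  tr <- simulate_ssa(promoter_rates(0, 0), kinetic_rates(0, 0, 0, 0),
                     t_end = 100, sample_interval = 10,
                     init = list(promoter = "ON", m = 5, p = 7), seed = 3)
  expect_true(all(tr$promoter == 1))
  expect_true(all(tr$mrna == 5))
  expect_true(all(tr$protein == 7))
})

test_that("unreachable species stay at zero", {
  tr <- simulate_ssa(promoter_rates(), kinetic_rates(k_p = 0),
                     t_end = 500, sample_interval = 10,
                     init = list(promoter = "OFF", m = 0, p = 0), seed = 4)
  expect_true(all(tr$protein == 0))
})

test_that("identical seeds give bit-identical trajectories", {
  a <- simulate_ssa(promoter_rates(), t_end = 400, sample_interval = 5,
                    seed = 99)
  b <- simulate_ssa(promoter_rates(), t_end = 400, sample_interval = 5,
                    seed = 99)
  expect_identical(a$protein, b$protein)
  expect_identical(a$mrna, b$mrna)
  d <- simulate_ssa(promoter_rates(), t_end = 400, sample_interval = 5,
                    seed = 100)
  expect_false(identical(a$protein, d$protein))
})

test_that("negative rates are rejected", {
  expect_error(promoter_rates(-0.1, 0.2), "non-negative")
  expect_error(kinetic_rates(k_m = -1), "non-negative")
  expect_error(simulate_ssa(promoter_rates(), t_end = -5, seed = 1), "t_end")
})

test_that("ensemble statistics agree with the moment oracle", {
  rates <- promoter_rates()
  kin <- kinetic_rates()
  mom <- moment_oracle(rates, kin)
  es <- ensemble_stats(rates, kin, n_reps = 600, seed = 5)
  expect_lt(abs(es$mean_p - mom$mean_p), 3 * es$sem_mean)
  expect_lt(abs(es$fano_p - mom$fano_p), 3 * unname(es$sem_fano))
})

test_that("changing the master seed changes trajectories but not the mean", {
  rates <- promoter_rates()
  a <- ensemble_stats(rates, n_reps = 400, seed = 10)
  b <- ensemble_stats(rates, n_reps = 400, seed = 20)
  expect_false(identical(a$protein, b$protein))
  expect_lt(abs(a$mean_p - b$mean_p),
            3 * sqrt(a$sem_mean^2 + b$sem_mean^2))
})

test_that("frozen and degenerate ensembles are reported correctly", {
  es <- ensemble_stats(promoter_rates(0, 0), kinetic_rates(0, 0, 0, 0),
                       n_reps = 10, t_end = 50, seed = 1,
                       init = list(promoter = "ON", m = 0, p = 7))
  expect_equal(es$mean_p, 7)
  expect_equal(es$cv_p, 0)
  expect_equal(es$fano_p, 0)
  expect_false(es$degenerate)

  es0 <- ensemble_stats(promoter_rates(0, 0), kinetic_rates(0, 0, 0, 0),
                        n_reps = 10, t_end = 50, seed = 1,
                        init = list(promoter = "OFF", m = 0, p = 0))
  expect_true(es0$degenerate)
  expect_true(is.na(es0$cv_p))
})

test_that("trajectory CSV round-trips", {
  tr <- simulate_ssa(promoter_rates(), t_end = 100, sample_interval = 10,
                     seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$protein, tr$protein)
  expect_equal(back$time_min, tr$time_min)
})
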