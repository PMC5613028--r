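# closed forms for the telegraph model, written out independently of the
# linear-system solver they check
closed_forms <- function(r_on, r_off, kin) {
  s <- r_on + r_off
  p_on <- r_on / s
  mean_m <- kin$k_m * p_on / kin$gamma_m
  list(p_on = p_on, mean_m = mean_m,
       fano_m = 1 + kin$k_m * r_off / (s * (s + kin$gamma_m)),
       mean_p = kin$k_p * mean_m / kin$gamma_p)
}

test_that("moment oracle matches the telegraph closed forms on a grid", {
  kin <- kinetic_rates()
  grid <- expand.grid(r_on = 0.0229 * 2^seq(-3, 3, length.out = 5),
                      r_off = 0.0348 * 2^seq(-3, 3, length.out = 5))
  for (i in seq_len(nrow(grid))) {
    mom <- moment_oracle(promoter_rates(grid$r_on[i], grid$r_off[i]), kin)
    cf <- closed_forms(grid$r_on[i], grid$r_off[i], kin)
    expect_equal(mom$p_on, cf$p_on, tolerance = 1e-10)
    expect_equal(mom$mean_m, cf$mean_m, tolerance = 1e-10)
    expect_equal(mom$fano_m, cf$fano_m, tolerance = 1e-10)
    expect_equal(mom$mean_p, cf$mean_p, tolerance = 1e-10)
  }
})

test_that("oracle limit cases behave as expected", {
  # symmetric switching: half occupancy
  expect_equal(moment_oracle(promoter_rates(0.7, 0.7))$p_on, 0.5)
  # constitutive promoter (never OFF): Poisson mRNA
  mom <- moment_oracle(promoter_rates(0.5, 0), kinetic_rates())
  expect_equal(mom$fano_m, 1, tolerance = 1e-10)
  # worked example: fitted rates, k_m = 1, gamma_m = 0.05
  mom <- moment_oracle(promoter_rates(0.0229, 0.0348),
                       kinetic_rates(k_m = 1, gamma_m = 0.05))
  expect_equal(mom$p_on, 0.3969, tolerance = 1e-4)
  expect_equal(mom$mean_m, 7.938, tolerance = 1e-4)
  expect_equal(mom$fano_m, 6.600, tolerance = 1e-4)
})

test_that("oracle rejects parameter sets without a steady state", {
  expect_error(moment_oracle(promoter_rates(0.1, 0.1),
                             kinetic_rates(gamma_m = 0)), "gamma_m")
  expect_error(moment_oracle(promoter_rates(0, 0)), "r_on \\+ r_off")
})

test_that("proportional rate scaling preserves the mean and lowers noise", {
  kin <- kinetic_rates()
  base <- moment_oracle(promoter_rates(), kin)
  prev_fano <- Inf; prev_cv <- Inf
  for (cc in c(1, 2, 4, 8, 16)) {
    mom <- moment_oracle(promoter_rates(0.0229 * cc, 0.0348 * cc), kin)
    expect_equal(mom$mean_p, base$mean_p, tolerance = 1e-12)
    expect_lt(mom$fano_p, prev_fano)
    expect_lt(mom$cv_p, prev_cv)
    prev_fano <- mom$fano_p; prev_cv <- mom$cv_p
  }
})

test_that("raising r_on at fixed r_off raises the mean", {
  kin <- kinetic_rates()
  means <- sapply(0.0229 * c(0.5, 1, 2, 4),
                  function(r) moment_oracle(promoter_rates(r, 0.0348),
                                            kin)$mean_p)
  expect_true(all(diff(means) > 0))
})

test_that("promoter-rate fitting round-trips through the oracle", {
  kin <- kinetic_rates()
  for (rates in list(promoter_rates(0.0229, 0.0348),
                     promoter_rates(0.1, 0.01),
                     promoter_rates(0.004, 0.02))) {
    mom <- moment_oracle(rates, kin)
    fit <- fit_promoter_rates(mom$mean_p, mom$cv_p, kin)
    expect_equal(fit$r_on, rates$r_on, tolerance = 1e-6)
    expect_equal(fit$r_off, rates$r_off, tolerance = 1e-6)
  }
})

test_that("fitting handles the constitutive boundary and infeasible targets", {
  kin <- kinetic_rates()
  full_mean <- kin$k_m * kin$k_p / (kin$gamma_m * kin$gamma_p)
  floor_cv <- sqrt((1 + kin$k_p / (kin$gamma_m + kin$gamma_p)) / full_mean)
  fit <- fit_promoter_rates(full_mean, floor_cv, kin)
  expect_identical(fit$r_off, 0)
  # below the floor: infeasible, error reports the floor
  expect_error(fit_promoter_rates(full_mean / 2, 1e-4, kin), "floor")
  # above the achievable mean
  expect_error(fit_promoter_rates(full_mean * 2, 0.5, kin), "exceeds")
})
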