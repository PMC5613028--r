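test_that("a single-point oracle grid equals the moment oracle", {
  kin <- kinetic_rates()
  sw <- grid_sweep(0.0229, 0.0348, kin)
  mom <- moment_oracle(promoter_rates(0.0229, 0.0348), kin)
  expect_equal(sw$mean_p, mom$mean_p)
  expect_equal(sw$cv_p, mom$cv_p)
  expect_equal(sw$fano_p, mom$fano_p)
  expect_error(grid_sweep(numeric(0), 0.03), "grids")
})

test_that("oracle mean increases with r_on along any fixed-r_off column", {
  sw <- grid_sweep(0.0229 * 2^seq(-2, 2), 0.0348 * c(0.5, 1, 2))
  for (ro in unique(sw$r_off)) {
    col <- sw[sw$r_off == ro, ]
    col <- col[order(col$r_on), ]
    expect_true(all(diff(col$mean_p) > 0))
  }
})

test_that("SSA and oracle engines agree within Monte-Carlo error", {
  kin <- kinetic_rates()
  oracle <- grid_sweep(c(0.0229, 0.08), 0.0348, kin, engine = "oracle")
  ssa <- grid_sweep(c(0.0229, 0.08), 0.0348, kin, engine = "ssa",
                    n_reps = 400, seed = 5)
  expect_true(all(abs(ssa$mean_p - oracle$mean_p) < 3 * ssa$sem_mean))
  expect_true(all(abs(ssa$fano_p - oracle$fano_p) < 3 * ssa$sem_fano))
})

test_that("diagonal sweep conserves the mean and monotonically lowers noise", {
  sw <- diagonal_sweep(promoter_rates(), scale_factors = c(1, 2, 4, 8))
  base <- moment_oracle(promoter_rates(), kinetic_rates())
  expect_equal(sw$mean_p[sw$scale == 1], base$mean_p)
  expect_true(all(abs(sw$mean_p / sw$mean_p[1] - 1) < 1e-10))
  expect_true(all(diff(sw$cv_p) < 0))
  expect_true(all(diff(sw$fano_p) < 0))
})

test_that("fast proportional switching approaches the constitutive floor", {
  kin <- kinetic_rates()
  sw <- diagonal_sweep(promoter_rates(), scale_factors = 10^(0:4), kin = kin)
  mean_p <- sw$mean_p[1]
  fano_floor <- 1 + kin$k_p / (kin$gamma_m + kin$gamma_p)
  expect_true(all(diff(sw$fano_p) < 0))
  expect_equal(sw$fano_p[nrow(sw)], fano_floor, tolerance = 1e-2)
})

test_that("vertical sweep raises the mean and does not raise the CV", {
  sw <- vertical_sweep(0.0348, 0.0229 * 2^seq(-2, 3, by = 0.5))
  expect_true(all(diff(sw$mean_p) > 0))
  expect_true(all(diff(sw$cv_p) <= 0))
})

test_that("non-chromatin sweep conserves the mean and is bounded by the diagonal mechanism", {
  nc <- nonchromatin_sweep(fold = 10, n_grid = 9)
  base <- moment_oracle(promoter_rates(), kinetic_rates())
  expect_equal(nrow(nc), 81)
  expect_true(all(abs(nc$mean_p / base$mean_p - 1) < 1e-10))
  # the unperturbed grid point reproduces the base noise exactly
  centre <- nc[nc$f_km == 1 & nc$f_gm == 1, ]
  expect_equal(centre$cv_p, base$cv_p, tolerance = 1e-12)
  di <- diagonal_sweep(promoter_rates(), scale_factors = c(1, 4))
  diag_dec <- 1 - di$cv_p[2] / di$cv_p[1]
  expect_lt(attr(nc, "max_cv_decrease"), diag_dec)
})

test_that("sweep results are reproducible and writable", {
  a <- grid_sweep(0.02, 0.03, engine = "ssa", n_reps = 50, seed = 9)
  b <- grid_sweep(0.02, 0.03, engine = "ssa", n_reps = 50, seed = 9)
  expect_identical(a$mean_p, b$mean_p)
  path <- tempfile(fileext = ".csv")
  write_sweep(a, path)
  expect_true(all(c("r_on", "cv_p", "n_reps") %in%
                  names(utils::read.csv(path))))
})
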