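test_that("the aging rate schedule follows its three modes", {
  base <- promoter_rates()
  const <- aging_schedule("constant")
  for (g in c(1, 8, 30))
    expect_equal(rate_schedule(base, const, g), base)

  prop <- aging_schedule("proportional", scale_at_plateau = 3,
                         plateau_generation = 16)
  at16 <- rate_schedule(base, prop, 16)
  expect_equal(at16$r_on, 3 * base$r_on)
  expect_equal(at16$r_off, 3 * base$r_off)
  expect_equal(rate_schedule(base, prop, 40), at16)  # plateau holds
  mid <- rate_schedule(base, prop, 8)
  expect_equal(mid$r_on / base$r_on, 2)              # halfway up the ramp

  # proportional scaling leaves the oracle mean generation-independent;
  # scaling r_on alone makes it grow
  ron <- aging_schedule("r_on_only", scale_at_plateau = 3)
  means_prop <- sapply(c(1, 8, 16), function(g)
    moment_oracle(rate_schedule(base, prop, g))$mean_p)
  means_ron <- sapply(c(1, 8, 16), function(g)
    moment_oracle(rate_schedule(base, ron, g))$mean_p)
  expect_true(all(abs(means_prop / means_prop[1] - 1) < 1e-12))
  expect_true(all(diff(means_ron) > 0))
})

test_that("generated cohorts satisfy every pipeline precondition", {
  coh <- generate_cohort(quick_cohort_config(), seed = 21)
  dir <- tempfile(); write_cohort(coh, dir)
  tr <- read_traces(file.path(dir, "traces.csv"))
  dv <- read_divisions(file.path(dir, "divisions.csv"))
  px <- read_pixels(file.path(dir, "pixels.csv"))
  expect_setequal(unique(tr$cell_id), unique(dv$cell_id))
  expect_true(all(tr$frame_id %in% px$frame_id))
  # snapshots per full generation stay in the 4-9 band
  asg <- assign_generations(subtract_background(tr, frame_backgrounds(px)),
                            dv)
  counts <- table(asg$cell_id, asg$generation)
  ls <- attr(asg, "lifespans")
  for (cell in rownames(counts)) {
    L <- ls[[cell]]
    # catastrophe generations may run longer; the baseline band is 4-9
    base_gens <- seq_len(max(L - 4, 1))
    cnt <- counts[cell, as.character(base_gens)]
    expect_true(all(cnt >= 4 & cnt <= 9))
  }
  # lifespans within the configured truncation range
  expect_true(all(ls >= 4 & ls <= 53))
})

test_that("identical seeds give byte-identical cohort tables", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_cohort(generate_cohort(quick_cohort_config(), seed = 33), d1)
  write_cohort(generate_cohort(quick_cohort_config(), seed = 33), d2)
  write_cohort(generate_cohort(quick_cohort_config(), seed = 34), d3)
  for (f in c("traces.csv", "divisions.csv", "pixels.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "traces.csv")),
                         readLines(file.path(d3, "traces.csv"))))
})

test_that("generate_cohort does not disturb the session RNG state", {
  set.seed(77); expected <- runif(3)
  set.seed(77); invisible(generate_cohort(quick_cohort_config(), seed = 5))
  expect_identical(runif(3), expected)
})

test_that("an all-OFF cohort is classified OFF throughout", {
  cfg <- cohort_config(n_cells = 6, off_fraction = 1, n_pixels = 40)
  coh <- generate_cohort(cfg, seed = 13)
  bg <- frame_backgrounds(coh$pixels)
  cls <- classify_on(subtract_background(coh$traces, bg))
  expect_true(all(!cls$on))
})

test_that("frame backgrounds are recovered within a few percent", {
  coh <- generate_cohort(quick_cohort_config(), seed = 3)
  est <- frame_backgrounds(coh$pixels)
  truth <- coh$truth$backgrounds[names(est)]
  expect_true(all(abs(est / truth - 1) < 0.06))
})

test_that("scenario presets carry the reported ON-cohort sizes", {
  expect_equal(n_on_cells(scenario_preset("wt")), 59)
  expect_equal(n_on_cells(scenario_preset("gal80del")), 102)
  expect_equal(n_on_cells(scenario_preset("rpd3del")), 52)
  expect_equal(n_on_cells(scenario_preset("synthetic_promoter")), 73)
  expect_equal(n_on_cells(scenario_preset("synthetic_gal80del")), 82)
  expect_error(scenario_preset("nonsense"), "unknown preset")
  # constitutive synthetic promoter: constant mode, near-full occupancy
  sg <- scenario_preset("synthetic_gal80del")
  expect_identical(sg$schedule$mode, "constant")
  mom <- moment_oracle(sg$base_rates)
  expect_gt(mom$p_on, 0.95)
  # gal80del starts noisier than wt at the model level
  expect_gt(moment_oracle(scenario_preset("gal80del")$base_rates)$cv_p,
            moment_oracle(scenario_preset("wt")$base_rates)$cv_p)
})

test_that("ground truth is consistent with the emitted tables", {
  coh <- generate_cohort(quick_cohort_config(), seed = 44)
  for (cell in coh$truth$cells) {
    dv <- coh$divisions$division_time_min[
      coh$divisions$cell_id == cell$cell_id]
    expect_equal(dv, cell$division_times)
    expect_equal(length(dv) - 1L, cell$lifespan)
    expect_equal(nrow(cell$rates), cell$lifespan)
  }
})
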