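# Handcrafted deterministic cohort used by the filter/window tests.
# Every generation lasts 90 min; snapshots sit on the global 10-min grid,
# so each full generation carries exactly 9 snapshots.  Intensities follow
# intensity(t) = level + amp * ((t / 10) %% 7), which is deterministic and
# easy to recompute independently.

fixture_cell <- function(cell_id, lifespan, level = 1500, amp = 200,
                         gen3_snapshots = NULL) {
  bounds <- seq(0, 90 * lifespan, by = 90)
  times <- seq(0, 90 * lifespan - 10, by = 10)
  if (!is.null(gen3_snapshots)) {
    g3 <- times[times >= 180 & times < 270]
    times <- sort(c(times[times < 180 | times >= 270],
                    g3[seq_len(gen3_snapshots)]))
  }
  list(
    traces = data.frame(
      cell_id = cell_id, time_min = times,
      frame_id = sprintf("f%04d", times / 10 + 1),
      intensity = level + amp * ((times / 10) %% 7),
      stringsAsFactors = FALSE),
    divisions = data.frame(cell_id = cell_id, division_time_min = bounds,
                           stringsAsFactors = FALSE))
}

# 12 cells with hand-enumerable filter outcomes:
#   c01 ON, lifespan 23            -> gens 1-19 retained, 9 windows
#   c02 ON, lifespan 10            -> gens 1-6, 3 windows
#   c03 ON, lifespan 9             -> excluded (short-lived)
#   c04 OFF (mean 450), lifespan 30-> excluded (OFF)
#   c05 ON, lifespan 12            -> gens 1-8, 4 windows
#   c06 ON, lifespan 23, gen 3 has only 3 snapshots -> window 2 missing, 8
#   c07..c12 ON, lifespan 14       -> gens 1-10, 5 windows each
fixture_cohort <- function() {
  cells <- list(
    fixture_cell("c01", 23),
    fixture_cell("c02", 10),
    fixture_cell("c03", 9),
    fixture_cell("c04", 30, level = 300, amp = 50),
    fixture_cell("c05", 12),
    fixture_cell("c06", 23, gen3_snapshots = 3),
    fixture_cell("c07", 14), fixture_cell("c08", 14),
    fixture_cell("c09", 14), fixture_cell("c10", 14),
    fixture_cell("c11", 14), fixture_cell("c12", 14))
  traces <- do.call(rbind, lapply(cells, `[[`, "traces"))
  divisions <- do.call(rbind, lapply(cells, `[[`, "divisions"))
  rownames(traces) <- rownames(divisions) <- NULL
  list(traces = traces, divisions = divisions)
}

# Raw-intensity version with a constant known background of 100 a.u. and a
# pixel table whose nearest-rank 10th percentile is exactly 100.
fixture_cohort_raw <- function(background = 100) {
  fx <- fixture_cohort()
  fx$traces$raw_intensity <- fx$traces$intensity + background
  fx$traces$intensity <- NULL
  frames <- sort(unique(fx$traces$frame_id))
  fx$pixels <- data.frame(
    frame_id = rep(frames, each = 20),
    pixel_intensity = rep(background, 20 * length(frames)),
    stringsAsFactors = FALSE)
  fx
}

# Independent "spreadsheet-style" statistics used to cross-check the
# pipeline: plain sum formulas, no shared code with the package.
brute_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / (n - 1)
  list(n = n, mean = mu, sd = sqrt(v), cv = sqrt(v) / mu, fano = v / mu)
}

# Small, fast cohort configuration for generator round-trip unit tests.
quick_cohort_config <- function(...) {
  cohort_config(n_cells = 12, off_fraction = 0, n_pixels = 40, ...)
}
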