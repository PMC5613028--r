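#' Configuration of the trajectory-analysis pipeline
#'
#' Holds the filtering and windowing conventions used to turn raw
#' single-cell fluorescence traces into generation-windowed noise
#' statistics.  Defaults follow the experimental analysis protocol: cells
#' whose lifespan-average corrected intensity is below 1000 a.u. are OFF
#' and excluded; cells living fewer than 10 generations are excluded;
#' snapshots from each cell's final 4 generations (the catastrophe phase)
#' are removed from the normal-aging statistics; noise is computed per cell
#' over non-overlapping two-generation windows with at least 4 snapshots
#' per generation and 8 per window; per-frame background is the
#' nearest-rank bottom 10th-percentile pixel; population summaries require
#' at least 10 cells per window.
#'
#' @param on_threshold ON/OFF classification threshold (a.u.), inclusive
#'   for ON.
#' @param min_lifespan Minimum replicative lifespan (generations).
#' @param catastrophe_len Number of terminal generations excluded from the
#'   normal-aging statistics.
#' @param window_size Generations per noise window.
#' @param min_snapshots_per_gen Minimum snapshots per generation inside a
#'   window.
#' @param min_snapshots_per_window Minimum snapshots per window.
#' @param background_percentile Pixel percentile defining the frame
#'   background (fraction in (0, 1]).
#' @param min_cells_per_window Minimum cells for a window to enter the
#'   population summary.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(on_threshold = 1000, min_lifespan = 10,
                            catastrophe_len = 4, window_size = 2,
                            min_snapshots_per_gen = 4,
                            min_snapshots_per_window = 8,
                            background_percentile = 0.10,
                            min_cells_per_window = 10) {
  cfg <- list(on_threshold = on_threshold, min_lifespan = min_lifespan,
              catastrophe_len = catastrophe_len, window_size = window_size,
              min_snapshots_per_gen = min_snapshots_per_gen,
              min_snapshots_per_window = min_snapshots_per_window,
              background_percentile = background_percentile,
              min_cells_per_window = min_cells_per_window)
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && !is.na(x),
                logical(1))
  if (!all(num)) stop("all pipeline settings must be single numbers", call. = FALSE)
  if (any(unlist(cfg) <= 0)) stop("all pipeline settings must be positive", call. = FALSE)
  if (cfg$window_size < 1) stop("'window_size' must be >= 1", call. = FALSE)
  if (cfg$background_percentile > 1)
    stop("'background_percentile' must be a fraction in (0, 1]", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Frame background from sorted pixel intensities
#'
#' Nearest-rank percentile: the value at index `ceiling(percentile * n)`
#' of the ascending sort.  With the default 10th percentile this picks the
#' "bottom 10% pixel" of a frame, which sits in the long dark tail of the
#' pixel-intensity distribution and serves as the background fluorescence
#' estimate for that frame.
#'
#' @param pixels Numeric vector of pixel intensities for one frame.
#' @param percentile Fraction in (0, 1].
#' @return Background intensity (a.u.).
#' @examples
#' estimate_background(1:100)        # 10
#' estimate_background(c(5, 1, 9, 3)) # ceil(0.4) = 1st order statistic: 1
#' @export
estimate_background <- function(pixels, percentile = 0.10) {
  if (length(pixels) == 0) stop("empty pixel vector", call. = FALSE)
  if (percentile <= 0 || percentile > 1)
    stop("'percentile' must be in (0, 1]", call. = FALSE)
  sort(pixels)[ceiling(percentile * length(pixels))]
}

#' Per-frame backgrounds from a long-form pixel table
#'
#' @param pixels Data frame with columns `frame_id`, `pixel_intensity`.
#' @param percentile Fraction in (0, 1].
#' @return Named numeric vector mapping frame id to background (a.u.).
#' @export
frame_backgrounds <- function(pixels, percentile = 0.10) {
  check_columns(pixels, c("frame_id", "pixel_intensity"), "pixels")
  vapply(split(pixels$pixel_intensity, pixels$frame_id),
         estimate_background, numeric(1), percentile = percentile)
}

#' Subtract per-frame background from raw intensities
#'
#' Corrected values may be negative (a dim cell on a bright frame); they
#' are retained rather than clamped to avoid upward bias of the means.
#'
#' @param traces Trace table with columns `cell_id`, `time_min`,
#'   `frame_id`, `raw_intensity`.
#' @param backgrounds Named vector from [frame_backgrounds()], or a data
#'   frame with columns `frame_id`, `background`.
#' @return The trace table with an added `intensity` column
#'   (background-corrected).
#' @export
subtract_background <- function(traces, backgrounds) {
  check_columns(traces, c("cell_id", "time_min", "frame_id", "raw_intensity"),
                "traces")
  if (is.data.frame(backgrounds)) {
    check_columns(backgrounds, c("frame_id", "background"), "backgrounds")
    bg <- stats::setNames(backgrounds$background,
                          as.character(backgrounds$frame_id))
  } else bg <- backgrounds
  key <- as.character(traces$frame_id)
  miss <- setdiff(unique(key), names(bg))
  if (length(miss) > 0)
    stop("no background available for frame(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  traces$intensity <- traces$raw_intensity - unname(bg[key])
  traces
}

#' Classify cells as ON or OFF from lifespan-average intensity
#'
#' A cell is OFF when its average corrected intensity over all snapshots of
#' its lifespan falls below the threshold; the comparison is inclusive, so
#' a lifespan average exactly at the threshold counts as ON.
#'
#' @param traces Trace table with columns `cell_id`, `intensity`.
#' @param on_threshold Threshold (a.u.).
#' @return Data frame with columns `cell_id`, `mean_intensity`, `on`
#'   (logical).
#' @export
classify_on <- function(traces, on_threshold = 1000) {
  check_columns(traces, c("cell_id", "intensity"), "traces")
  means <- tapply(traces$intensity, traces$cell_id, mean)
  data.frame(cell_id = names(means), mean_intensity = as.numeric(means),
             on = as.numeric(means) >= on_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign snapshots to generations from division times
#'
#' Generation `g` (1-based) of a cell spans the half-open interval from
#' division boundary `g - 1` to boundary `g`; a snapshot exactly on a
#' boundary therefore belongs to the generation that starts there.
#' Snapshots before the first or at/after the last boundary fall outside
#' every generation interval and are dropped (the count is returned in the
#' `dropped_snapshots` attribute).
#'
#' @param traces Trace table with at least `cell_id`, `time_min`.
#' @param divisions Division table with columns `cell_id`,
#'   `division_time_min` (all generation boundaries of a cell, including
#'   its first).
#' @return The trace table with an added integer `generation` column and
#'   attributes `dropped_snapshots` and `lifespans` (named vector of
#'   generations per cell).
#' @export
assign_generations <- function(traces, divisions) {
  check_columns(traces, c("cell_id", "time_min"), "traces")
  check_columns(divisions, c("cell_id", "division_time_min"), "divisions")
  bounds <- split(divisions$division_time_min, divisions$cell_id)
  bounds <- lapply(bounds, sort)
  miss <- setdiff(unique(as.character(traces$cell_id)), names(bounds))
  if (length(miss) > 0)
    stop("no division times for cell(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  gen <- integer(nrow(traces))
  for (cell in names(bounds)) {
    sel <- traces$cell_id == cell
    b <- bounds[[cell]]
    g <- findInterval(traces$time_min[sel], b)
    g[g >= length(b)] <- 0L  # at/after the last boundary: outside
    gen[sel] <- g
  }
  dropped <- sum(gen == 0L)
  out <- traces[gen > 0L, , drop = FALSE]
  out$generation <- gen[gen > 0L]
  rownames(out) <- NULL
  attr(out, "dropped_snapshots") <- dropped
  attr(out, "lifespans") <- vapply(bounds, function(b) length(b) - 1L,
                                   integer(1))
  out
}

#' Apply the cohort filters of the aging analysis
#'
#' Keeps ON cells with lifespan at or above the minimum, and removes all
#' snapshots from each surviving cell's final `catastrophe_len`
#' generations.  Returns the filtered traces together with an exclusion
#' report giving per-rule counts; adding a cell that fails a filter changes
#' only the report, never the downstream statistics.
#'
#' @param traces Generation-assigned, background-corrected trace table
#'   (from [assign_generations()]; columns `cell_id`, `generation`,
#'   `intensity`).
#' @param lifespans Named vector of lifespans per cell (as produced by
#'   [assign_generations()]), or a division table.
#' @param config A [pipeline_config()].
#' @return List with elements `traces` (filtered) and `exclusions` (list
#'   of counts: `n_cells_input`, `n_off`, `n_short_lived`, `n_kept`,
#'   `n_last_gen_snapshots_removed`).
#' @export
filter_cohort <- function(traces, lifespans = attr(traces, "lifespans"),
                          config = pipeline_config()) {
  check_columns(traces, c("cell_id", "generation", "intensity"), "traces")
  if (is.data.frame(lifespans)) {
    check_columns(lifespans, c("cell_id", "division_time_min"), "lifespans")
    lifespans <- vapply(split(lifespans$division_time_min, lifespans$cell_id),
                        function(b) length(b) - 1L, integer(1))
  }
  if (is.null(lifespans)) stop("'lifespans' required", call. = FALSE)
  cls <- classify_on(traces, config$on_threshold)
  cells <- cls$cell_id
  on <- stats::setNames(cls$on, cells)
  ls <- lifespans[cells]
  keep_cell <- on[cells] & ls >= config$min_lifespan
  n_off <- sum(!on[cells])
  n_short <- sum(on[cells] & ls < config$min_lifespan)
  kept_cells <- cells[keep_cell]
  tr <- traces[traces$cell_id %in% kept_cells, , drop = FALSE]
  last_cut <- lifespans[as.character(tr$cell_id)] - config$catastrophe_len
  in_tail <- tr$generation > last_cut
  n_tail <- sum(in_tail)
  tr <- tr[!in_tail, , drop = FALSE]
  rownames(tr) <- NULL
  if (nrow(tr) == 0)
    stop("no cells survive the cohort filters: nothing to analyze",
         call. = FALSE)
  attr(tr, "lifespans") <- lifespans
  list(traces = tr,
       exclusions = list(n_cells_input = length(cells),
                         n_off = n_off,
                         n_short_lived = n_short,
                         n_kept = length(kept_cells),
                         n_last_gen_snapshots_removed = n_tail))
}

window_of <- function(generation, window_size) {
  (generation - 1L) %/% window_size + 1L
}

#' Per-cell noise statistics over two-generation windows
#'
#' Windows are aligned from each cell's first generation: window `w`
#' covers generations `2w - 1` and `2w` (for the default window size 2).
#' A window is emitted only when every generation of the window is present
#' in the filtered trace, each has at least `min_snapshots_per_gen`
#' snapshots, and the window holds at least `min_snapshots_per_window`
#' snapshots in total; the statistics are computed on the pooled window
#' snapshots.  A trailing incomplete window is dropped.
#'
#' @param traces Filtered, generation-assigned trace table for one or many
#'   cells (columns `cell_id`, `generation`, `intensity`).
#' @param config A [pipeline_config()].
#' @return Data frame with columns `cell_id`, `window_index`, `n`, `mean`,
#'   `sd`, `cv`, `fano`.
#' @export
per_cell_windows <- function(traces, config = pipeline_config()) {
  check_columns(traces, c("cell_id", "generation", "intensity"), "traces")
  ws <- as.integer(config$window_size)
  res <- lapply(split(traces, traces$cell_id, drop = TRUE), function(tr) {
    w <- window_of(tr$generation, ws)
    rows <- lapply(sort(unique(w)), function(wi) {
      sel <- w == wi
      gens_expected <- ((wi - 1L) * ws + 1L):(wi * ws)
      counts <- table(factor(tr$generation[sel], levels = gens_expected))
      if (any(counts == 0)) return(NULL)                 # incomplete window
      if (any(counts < config$min_snapshots_per_gen)) return(NULL)
      if (sum(counts) < config$min_snapshots_per_window) return(NULL)
      s <- stat_row(tr$intensity[sel])
      data.frame(cell_id = tr$cell_id[1], window_index = wi,
                 n = as.integer(s[["n"]]), mean = s[["mean"]],
                 sd = s[["sd"]], cv = s[["cv"]], fano = s[["fano"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cell_id = character(), window_index = integer(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      cv = numeric(), fano = numeric())
  rownames(out) <- NULL
  out
}

#' Population summary of per-cell window statistics
#'
#' Averages the single-cell noise values across all cells falling into
#' each window: per window the number of cells, mean and SD of the
#' per-cell window means, and mean and SEM of the per-cell CVs and Fano
#' factors.  Windows with fewer than `min_cells_per_window` cells are
#' flagged (`included = FALSE`) and suppressed from summary use, not
#' silently dropped.
#'
#' @param windows Output of [per_cell_windows()].
#' @param config A [pipeline_config()].
#' @return Data frame of class `population_summary` with columns
#'   `window_index`, `n_cells`, `mean_expr`, `sd_expr`, `mean_cv`,
#'   `sem_cv`, `mean_fano`, `sem_fano`, `included`.
#' @export
aggregate_population <- function(windows, config = pipeline_config()) {
  check_columns(windows, c("cell_id", "window_index", "mean", "cv", "fano"),
                "windows")
  rows <- lapply(split(windows, windows$window_index), function(w) {
    n <- nrow(w)
    data.frame(window_index = w$window_index[1], n_cells = n,
               mean_expr = mean(w$mean), sd_expr = stats::sd(w$mean),
               mean_cv = mean(w$cv), sem_cv = stats::sd(w$cv) / sqrt(n),
               mean_fano = mean(w$fano),
               sem_fano = stats::sd(w$fano) / sqrt(n),
               included = n >= config$min_cells_per_window)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(window_index = integer(), n_cells = integer(),
                      mean_expr = numeric(), sd_expr = numeric(),
                      mean_cv = numeric(), sem_cv = numeric(),
                      mean_fano = numeric(), sem_fano = numeric(),
                      included = logical())
  out <- out[order(out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("population_summary", "data.frame")
  out
}

#' Mean expression per generation across the cohort
#'
#' Each cell's snapshots within a generation are averaged first (the
#' generation is the representative unit of network activity), then the
#' per-cell generation means are averaged across cells.
#'
#' @param traces Filtered, generation-assigned trace table.
#' @return Data frame with columns `generation`, `n_cells`,
#'   `mean_intensity`.
#' @export
generational_mean_profile <- function(traces) {
  check_columns(traces, c("cell_id", "generation", "intensity"), "traces")
  per_cell <- stats::aggregate(intensity ~ cell_id + generation,
                               data = traces, FUN = mean)
  rows <- lapply(split(per_cell, per_cell$generation), function(g)
    data.frame(generation = g$generation[1], n_cells = nrow(g),
               mean_intensity = mean(g$intensity)))
  out <- do.call(rbind, rows)
  out <- out[order(out$generation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Death-aligned noise and generation-duration analysis
#'
#' Aligns ON cells (lifespan at or above the minimum) by their death
#' rather than their birth: generation `g` of a cell with lifespan `L` is
#' `L - g` generations before death, and two-generation windows are formed
#' backwards from death (window 1 = the last two generations, window 2 =
#' the two before those, ...).  The final-generation data excluded from
#' the normal-aging statistics are retained here -- this is the view in
#' which the terminal catastrophe phase (elevated noise, lengthened and
#' more variable generation durations) becomes visible.
#'
#' @param traces Generation-assigned, background-corrected trace table for
#'   the full cohort (no last-generations exclusion).
#' @param divisions Division table (`cell_id`, `division_time_min`).
#' @param config A [pipeline_config()].
#' @return List with elements `windows` (per backward window:
#'   `windows_before_death`, `n_cells`, `mean_cv`, `sem_cv`, `mean_fano`,
#'   `sem_fano`, `mean_duration`, `sd_duration`) and `durations` (per
#'   generations-before-death: `gens_before_death`, `n`, `mean_duration`,
#'   `sd_duration`).
#' @export
catastrophe_analysis <- function(traces, divisions,
                                 config = pipeline_config()) {
  check_columns(traces, c("cell_id", "generation", "intensity"), "traces")
  check_columns(divisions, c("cell_id", "division_time_min"), "divisions")
  bounds <- lapply(split(divisions$division_time_min, divisions$cell_id), sort)
  lifespans <- vapply(bounds, function(b) length(b) - 1L, integer(1))
  cls <- classify_on(traces, config$on_threshold)
  keep <- cls$cell_id[cls$on & lifespans[cls$cell_id] >= config$min_lifespan]
  tr <- traces[traces$cell_id %in% keep, , drop = FALSE]
  if (nrow(tr) == 0) stop("no ON cells with sufficient lifespan", call. = FALSE)
  ws <- as.integer(config$window_size)

  # per-cell stats on backward windows
  cell_rows <- lapply(split(tr, tr$cell_id, drop = TRUE), function(x) {
    L <- lifespans[[as.character(x$cell_id[1])]]
    gbd <- L - x$generation                       # 0 = last generation
    wb <- gbd %/% ws + 1L                          # 1 = final window
    rows <- lapply(sort(unique(wb)), function(wi) {
      sel <- wb == wi
      gbd_expected <- ((wi - 1L) * ws):(wi * ws - 1L)
      gbd_expected <- gbd_expected[gbd_expected <= L - 1L]
      counts <- table(factor(gbd[sel], levels = gbd_expected))
      if (length(gbd_expected) < ws || any(counts == 0)) return(NULL)
      if (any(counts < config$min_snapshots_per_gen)) return(NULL)
      if (sum(counts) < config$min_snapshots_per_window) return(NULL)
      s <- stat_row(x$intensity[sel])
      data.frame(cell_id = x$cell_id[1], windows_before_death = wi,
                 cv = s[["cv"]], fano = s[["fano"]], mean = s[["mean"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  cw <- do.call(rbind, cell_rows)

  # generation durations aligned by death
  dur_rows <- lapply(keep, function(cell) {
    b <- bounds[[as.character(cell)]]
    L <- length(b) - 1L
    data.frame(cell_id = cell, gens_before_death = (L - 1L):0L,
               duration = diff(b), stringsAsFactors = FALSE)
  })
  durs <- do.call(rbind, dur_rows)
  dur_by_gbd <- do.call(rbind, lapply(split(durs, durs$gens_before_death),
    function(d) data.frame(gens_before_death = d$gens_before_death[1],
                           n = nrow(d), mean_duration = mean(d$duration),
                           sd_duration = stats::sd(d$duration))))
  dur_by_gbd <- dur_by_gbd[order(dur_by_gbd$gens_before_death), , drop = FALSE]
  rownames(dur_by_gbd) <- NULL

  durs$wb <- durs$gens_before_death %/% ws + 1L
  win_rows <- lapply(sort(unique(cw$windows_before_death)), function(wi) {
    w <- cw[cw$windows_before_death == wi, , drop = FALSE]
    d <- durs$duration[durs$wb == wi]
    n <- nrow(w)
    data.frame(windows_before_death = wi, n_cells = n,
               mean_cv = mean(w$cv), sem_cv = stats::sd(w$cv) / sqrt(n),
               mean_fano = mean(w$fano),
               sem_fano = stats::sd(w$fano) / sqrt(n),
               mean_duration = mean(d), sd_duration = stats::sd(d),
               included = n >= config$min_cells_per_window)
  })
  windows <- do.call(rbind, win_rows)
  rownames(windows) <- NULL
  list(windows = windows, durations = dur_by_gbd, per_cell = cw)
}

#' Correlation between expression level and division time, per generation
#'
#' For each generation index, the Pearson correlation across cells between
#' the cell's mean intensity in that generation and the generation's
#' duration.  Reported only when at least `min_cells` cells contribute and
#' both variables vary; otherwise the row carries `NA` with a reason.
#'
#' @param traces Generation-assigned, corrected trace table.
#' @param divisions Division table.
#' @param min_cells Minimum number of cells for a reported correlation.
#' @return Data frame with columns `generation`, `n`, `r`, `reason`
#'   (`NA` when a correlation is reported).
#' @export
division_time_correlation <- function(traces, divisions, min_cells = 3) {
  check_columns(traces, c("cell_id", "generation", "intensity"), "traces")
  check_columns(divisions, c("cell_id", "division_time_min"), "divisions")
  bounds <- lapply(split(divisions$division_time_min, divisions$cell_id), sort)
  per_cell <- stats::aggregate(intensity ~ cell_id + generation,
                               data = traces, FUN = mean)
  per_cell$duration <- mapply(function(cell, g) {
    b <- bounds[[as.character(cell)]]
    if (g + 1 <= length(b)) b[g + 1] - b[g] else NA_real_
  }, per_cell$cell_id, per_cell$generation)
  per_cell <- per_cell[!is.na(per_cell$duration), , drop = FALSE]
  rows <- lapply(split(per_cell, per_cell$generation), function(g) {
    n <- nrow(g)
    base <- data.frame(generation = g$generation[1], n = n, r = NA_real_,
                       reason = NA_character_, stringsAsFactors = FALSE)
    if (n < min_cells) { base$reason <- "too few cells"; return(base) }
    if (stats::sd(g$duration) == 0 || stats::sd(g$intensity) == 0) {
      base$reason <- "zero variance"; return(base)
    }
    base$r <- stats::cor(g$intensity, g$duration)
    base
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$generation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicative lifespan summary
#'
#' Survival curve (fraction of cells still alive at each generation) and
#' arithmetic mean lifespan.  Short-lived cells excluded from the noise
#' analysis are deliberately included here.
#'
#' @param lifespans Integer vector of replicative lifespans (generations).
#' @return List with elements `mean_rls` and `viability` (data frame with
#'   columns `generation`, `fraction_alive`).
#' @examples
#' rls_summary(c(4, 20, 36))$mean_rls   # 20
#' @export
rls_summary <- function(lifespans) {
  lifespans <- as.numeric(lifespans)
  if (length(lifespans) < 1 || anyNA(lifespans))
    stop("need at least one lifespan, no NAs", call. = FALSE)
  gens <- 0:max(lifespans)
  list(mean_rls = mean(lifespans),
       viability = data.frame(
         generation = gens,
         fraction_alive = vapply(gens, function(g) mean(lifespans >= g),
                                 numeric(1))))
}

#' Run the full trajectory-analysis pipeline
#'
#' Chains background estimation and subtraction, ON/OFF classification,
#' generation assignment, cohort filtering, two-generation windowing,
#' population aggregation, the generational mean profile, the
#' death-aligned catastrophe analysis, the expression/division-time
#' correlation check, and the lifespan summary.
#'
#' @param traces Raw trace table (`cell_id`, `time_min`, `frame_id`,
#'   `raw_intensity`).
#' @param divisions Division table (`cell_id`, `division_time_min`).
#' @param pixels Long-form frame pixel table (`frame_id`,
#'   `pixel_intensity`).
#' @param config A [pipeline_config()].
#' @return List of class `aging_analysis` with elements `summary`
#'   (population summary), `windows` (per-cell window stats), `profile`,
#'   `catastrophe`, `correlations`, `rls`, `exclusions`, `config`.
#' @export
run_pipeline <- function(traces, divisions, pixels,
                         config = pipeline_config()) {
  bg <- frame_backgrounds(pixels, config$background_percentile)
  corrected <- subtract_background(traces, bg)
  assigned <- assign_generations(corrected, divisions)
  lifespans <- attr(assigned, "lifespans")
  filt <- filter_cohort(assigned, lifespans, config)
  windows <- per_cell_windows(filt$traces, config)
  summary <- aggregate_population(windows, config)
  profile <- generational_mean_profile(filt$traces)
  cat_an <- catastrophe_analysis(assigned, divisions, config)
  corr <- division_time_correlation(filt$traces, divisions)
  rls <- rls_summary(lifespans)
  exclusions <- filt$exclusions
  exclusions$n_snapshots_outside_generations <-
    attr(assigned, "dropped_snapshots")
  structure(list(summary = summary, windows = windows, profile = profile,
                 catastrophe = cat_an, correlations = corr, rls = rls,
                 exclusions = exclusions, config = config),
            class = "aging_analysis")
}

#' @export
print.aging_analysis <- function(x, ...) {
  cat("aging trajectory analysis\n")
  cat(sprintf("  cells: %d analyzed of %d input (%d OFF, %d short-lived)\n",
              x$exclusions$n_kept, x$exclusions$n_cells_input,
              x$exclusions$n_off, x$exclusions$n_short_lived))
  inc <- x$summary[x$summary$included, , drop = FALSE]
  cat(sprintf("  windows reported: %d (>= %d cells each)\n", nrow(inc),
              x$config$min_cells_per_window))
  if (nrow(inc) > 0)
    cat(sprintf("  mean CV: %.3f (window %d) -> %.3f (window %d)\n",
                inc$mean_cv[1], inc$window_index[1],
                inc$mean_cv[nrow(inc)], inc$window_index[nrow(inc)]))
  cat(sprintf("  mean RLS: %.1f generations\n", x$rls$mean_rls))
  invisible(x)
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(sprintf("'%s' must be a data frame", what),
                               call. = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("'%s' is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
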