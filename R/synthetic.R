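#' Aging schedule for promoter switching rates
#'
#' Describes how the chromatin transition rates change with the generation
#' index of an aging mother cell.  In `proportional` mode both rates are
#' multiplied by the same factor, rising linearly from 1 at birth to
#' `scale_at_plateau` at `plateau_generation` and staying there -- the
#' mechanism that reduces noise while leaving mean expression unchanged.
#' `r_on_only` scales only the OFF-to-ON rate (noise falls but the mean
#' rises), and `constant` applies no aging effect.  The schedule also
#' carries the strength of the extrinsic noise ramp injected into the
#' terminal catastrophe phase (log-SD of a lognormal intensity multiplier,
#' reached at the last generation).
#'
#' @param mode One of `"proportional"`, `"r_on_only"`, `"constant"`.
#' @param scale_at_plateau Fold change reached at the plateau (>= 1).
#' @param plateau_generation Generation at which the scaling saturates.
#' @param catastrophe_sdlog Log-SD of the extrinsic intensity multiplier
#'   at the final generation (ramps linearly over the catastrophe phase).
#' @return A list of class `aging_schedule`.
#' @export
aging_schedule <- function(mode = c("proportional", "r_on_only", "constant"),
                           scale_at_plateau = 3, plateau_generation = 16,
                           catastrophe_sdlog = 0.3) {
  mode <- match.arg(mode)
  if (scale_at_plateau < 1) stop("'scale_at_plateau' must be >= 1", call. = FALSE)
  if (plateau_generation < 1) stop("'plateau_generation' must be >= 1", call. = FALSE)
  if (catastrophe_sdlog < 0) stop("'catastrophe_sdlog' must be >= 0", call. = FALSE)
  structure(list(mode = mode, scale_at_plateau = scale_at_plateau,
                 plateau_generation = plateau_generation,
                 catastrophe_sdlog = catastrophe_sdlog),
            class = "aging_schedule")
}

#' Promoter rates at a given generation under an aging schedule
#'
#' The scale factor is `s(g) = 1 + (scale_at_plateau - 1) *
#' min(g, plateau) / plateau`, applied to both rates (`proportional`), to
#' `r_on` only (`r_on_only`), or not at all (`constant`).
#'
#' @param base A [promoter_rates()] object (young-cell rates).
#' @param schedule An [aging_schedule()].
#' @param generation Generation index (>= 1).
#' @return A [promoter_rates()] object.
#' @examples
#' rate_schedule(promoter_rates(), aging_schedule("proportional"), 16)
#' @export
rate_schedule <- function(base, schedule, generation) {
  base <- as_promoter_rates(base)
  if (generation < 1) stop("'generation' must be >= 1", call. = FALSE)
  s <- 1 + (schedule$scale_at_plateau - 1) *
    min(generation, schedule$plateau_generation) / schedule$plateau_generation
  switch(schedule$mode,
    proportional = promoter_rates(s * base$r_on, s * base$r_off),
    r_on_only = promoter_rates(s * base$r_on, base$r_off),
    constant = base)
}

#' Configuration of the synthetic aging-cohort generator
#'
#' Parameterises a cohort of microfluidics-style mother-cell trajectories:
#' replicative lifespans from a discretised gamma distribution truncated
#' to the observed range, generation durations that keep the 10-minute
#' snapshot grid at 4-9 snapshots per generation, telegraph-model protein
#' dynamics with generation-dependent promoter rates, explicit binomial
#' partitioning of mRNA and protein at each division, a terminal
#' catastrophe phase with lengthened and more variable generation
#' durations plus an extrinsic noise ramp, a minority of OFF cells
#' (silenced promoter leak), and per-frame background offsets recoverable
#' from synthetic pixel samples.
#'
#' @param n_cells Total number of tracked mother cells; a fraction
#'   `off_fraction` of them are simulated with a silenced promoter (OFF).
#' @param schedule An [aging_schedule()].
#' @param base_rates Young-cell [promoter_rates()].
#' @param kinetics A [kinetic_rates()] object (protein removal inside a
#'   generation is by dilution-free accumulation; removal happens at
#'   division, see Details).
#' @param lifespan_mean,lifespan_shape Mean and gamma shape of the
#'   lifespan distribution (generations).
#' @param lifespan_range Truncation range of lifespans.
#' @param gen_duration_range Uniform range of baseline generation
#'   durations (minutes).
#' @param catastrophe_len Number of terminal catastrophe generations.
#' @param catastrophe_duration_mean_mult,catastrophe_duration_sd_mult
#'   Multipliers on the mean and SD of generation durations, reached at
#'   the final generation (both ramp linearly over the catastrophe phase).
#' @param snapshot_interval Fluorescence sampling interval (minutes).
#' @param intensity_scale Arbitrary fluorescence units per unit protein
#'   concentration (copies per birth volume).
#' @param n_warmup Unrecorded warm-up generations simulated before
#'   generation 1 so recorded traces start at the stationary
#'   explicit-division state (cultures reach steady state before loading).
#' @param off_fraction Fraction of the cohort simulated as OFF cells.
#' @param off_leak Transcription-rate multiplier of silenced (OFF) cells.
#' @param background_mean,background_sd Per-frame true background level
#'   (a.u.).
#' @param n_pixels Pixels drawn per frame.
#' @param measurement_sd Additive Gaussian measurement noise (a.u.).
#' @param retention Binomial retention probability of mRNA/protein by the
#'   mother at division.
#' @return A list of class `cohort_config`.
#' @details Within a generation the reporter is stable (no active
#'   degradation); copy numbers are halved on average by the binomial
#'   partition at division, which is the explicit-division counterpart of
#'   the continuous dilution used by the steady-state model.  The
#'   fluorescence signal is a concentration: `intensity_scale * protein /
#'   volume`, with the cell volume growing linearly from 1 to 2 over each
#'   generation (volume roughly doubles per cycle, and imaging reports
#'   average pixel intensity, i.e. concentration, not total copy number --
#'   a raw count would double every cycle and swamp the within-window
#'   noise statistics with the deterministic cell-cycle ramp).  Frame
#'   background and Gaussian measurement noise are added on top, and the
#'   lognormal catastrophe multiplier is applied to the signal during the
#'   final generations.
#' @export
cohort_config <- function(n_cells = 59,
                          schedule = aging_schedule(),
                          base_rates = promoter_rates(),
                          kinetics = kinetic_rates(),
                          lifespan_mean = 23, lifespan_shape = 5,
                          lifespan_range = c(4, 53),
                          gen_duration_range = c(40, 90),
                          catastrophe_len = 4,
                          catastrophe_duration_mean_mult = 1.8,
                          catastrophe_duration_sd_mult = 2.5,
                          snapshot_interval = 10,
                          intensity_scale = 3, n_warmup = 3,
                          off_fraction = 0.1, off_leak = 0.02,
                          background_mean = 300, background_sd = 30,
                          n_pixels = 150, measurement_sd = 25,
                          retention = 0.5) {
  cfg <- list(n_cells = n_cells, schedule = schedule,
              base_rates = as_promoter_rates(base_rates),
              kinetics = as_kinetic_rates(kinetics),
              lifespan_mean = lifespan_mean, lifespan_shape = lifespan_shape,
              lifespan_range = lifespan_range,
              gen_duration_range = gen_duration_range,
              catastrophe_len = catastrophe_len,
              catastrophe_duration_mean_mult = catastrophe_duration_mean_mult,
              catastrophe_duration_sd_mult = catastrophe_duration_sd_mult,
              snapshot_interval = snapshot_interval,
              intensity_scale = intensity_scale, n_warmup = n_warmup,
              off_fraction = off_fraction, off_leak = off_leak,
              background_mean = background_mean,
              background_sd = background_sd, n_pixels = n_pixels,
              measurement_sd = measurement_sd, retention = retention)
  if (n_cells < 1) stop("'n_cells' must be >= 1", call. = FALSE)
  if (off_fraction < 0 || off_fraction > 1)
    stop("'off_fraction' must be in [0, 1]", call. = FALSE)
  if (retention <= 0 || retention >= 1)
    stop("'retention' must be in (0, 1)", call. = FALSE)
  if (diff(lifespan_range) < 0 || lifespan_range[1] < 1)
    stop("invalid 'lifespan_range'", call. = FALSE)
  if (schedule$plateau_generation > lifespan_range[2])
    warning("plateau generation exceeds the maximum lifespan; ",
            "the plateau will never be reached", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

draw_lifespan <- function(cfg) {
  repeat {
    L <- round(stats::rgamma(1, shape = cfg$lifespan_shape,
                             scale = cfg$lifespan_mean / cfg$lifespan_shape))
    if (L >= cfg$lifespan_range[1] && L <= cfg$lifespan_range[2]) return(L)
  }
}

draw_durations <- function(cfg, L) {
  lo <- cfg$gen_duration_range[1]; hi <- cfg$gen_duration_range[2]
  mu0 <- (lo + hi) / 2; sd0 <- (hi - lo) / sqrt(12)
  durs <- stats::runif(L, lo, hi)
  n_cat <- min(cfg$catastrophe_len, L)
  if (n_cat > 0) {
    gbd <- (n_cat - 1):0                    # generations before death
    frac <- (cfg$catastrophe_len - gbd) / cfg$catastrophe_len
    mu <- mu0 * (1 + (cfg$catastrophe_duration_mean_mult - 1) * frac)
    sdv <- sd0 * (1 + (cfg$catastrophe_duration_sd_mult - 1) * frac)
    d <- stats::rnorm(n_cat, mu, sdv)
    durs[(L - n_cat + 1):L] <- pmax(d, lo)  # never shorter than baseline floor
  }
  durs
}

#' Generate a synthetic aging cohort with ground truth
#'
#' Simulates every mother cell of the configured cohort with the exact
#' stochastic simulator, generation by generation: promoter rates follow
#' the aging schedule, mRNA and protein are partitioned binomially at each
#' division, snapshots are taken on the global 10-minute grid, and raw
#' intensities combine the protein signal, the terminal catastrophe noise
#' ramp, the per-frame background, and measurement noise.  Per-frame pixel
#' samples are drawn so that their nearest-rank bottom-percentile pixel
#' recovers the true background to within a few percent.  The same seed
#' always yields byte-identical tables.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return A list of class `synthetic_cohort` with elements `traces`,
#'   `divisions`, `pixels` (the three analysis input tables) and `truth`
#'   (per-cell lifespans, ON/OFF labels, per-generation rates, division
#'   times; per-frame true backgrounds).
#' @examples
#' coh <- generate_cohort(cohort_config(n_cells = 3, off_fraction = 0), seed = 1)
#' head(coh$traces)
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as_seed(seed) %% .Machine$integer.max)

  n_total <- config$n_cells
  n_off <- round(config$off_fraction * n_total)
  n_on <- n_total - n_off
  is_off <- c(rep(FALSE, n_on), rep(TRUE, n_off))
  kin <- config$kinetics
  interval <- config$snapshot_interval
  mean_dur <- mean(config$gen_duration_range)

  traces <- vector("list", n_total)
  divisions <- vector("list", n_total)
  truth_cells <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    cell <- sprintf("cell_%03d", i)
    L <- draw_lifespan(config)
    durs <- draw_durations(config, L)
    bnds <- c(0, cumsum(durs))
    k_m_cell <- if (is_off[i]) kin$k_m * config$off_leak else kin$k_m

    # initial state: promoter at its generation-1 stationary law, mRNA at
    # its mean, protein at the post-division steady production level
    r1 <- rate_schedule(config$base_rates, config$schedule, 1)
    p_on1 <- r1$r_on / (r1$r_on + r1$r_off)
    mean_m1 <- k_m_cell * p_on1 / kin$gamma_m
    g <- as.integer(stats::runif(1) < p_on1)
    m <- round(mean_m1)
    p <- round(kin$k_p * mean_m1 * mean_dur)

    # unrecorded warm-up generations bring (g, m, p) to the stationary
    # explicit-division state before generation 1
    n_wu <- config$n_warmup
    if (n_wu > 0) {
      wu_durs <- stats::runif(n_wu, config$gen_duration_range[1],
                              config$gen_duration_range[2])
      wu_seeds <- stats::runif(n_wu) * 2^52
      for (w in seq_len(n_wu)) {
        res <- cpp_ssa_path(r1$r_on, r1$r_off, k_m_cell, kin$gamma_m,
                            kin$k_p, 0, g, m, p, 0, wu_durs[w], wu_seeds[w])
        fin <- res$final
        g <- as.integer(fin[1])
        m <- stats::rbinom(1, as.integer(fin[2]), config$retention)
        p <- stats::rbinom(1, as.integer(fin[3]), config$retention)
      }
    }

    gen_rates <- matrix(0, L, 2, dimnames = list(NULL, c("r_on", "r_off")))
    seeds <- stats::runif(L) * 2^52   # per-generation SSA substreams
    rows <- vector("list", L)
    for (gidx in seq_len(L)) {
      rg <- rate_schedule(config$base_rates, config$schedule, gidx)
      gen_rates[gidx, ] <- c(rg$r_on, rg$r_off)
      t0 <- bnds[gidx]; t1 <- bnds[gidx + 1]
      grid <- seq(ceiling(t0 / interval) * interval, t1, by = interval)
      grid <- grid[grid < t1]
      times <- c(grid, t1)               # last point = state at division
      res <- cpp_ssa_path(rg$r_on, rg$r_off, k_m_cell, kin$gamma_m,
                          kin$k_p, 0, g, m, p, t0, times, seeds[gidx])
      nsnap <- length(grid)
      if (nsnap > 0) {
        prot <- res$protein[seq_len(nsnap)]
        volume <- 1 + (grid - t0) / (t1 - t0)    # linear doubling per cycle
        gbd <- L - gidx
        mult <- rep(1, nsnap)
        if (gbd < config$catastrophe_len) {
          frac <- (config$catastrophe_len - gbd) / config$catastrophe_len
          sdl <- config$schedule$catastrophe_sdlog * frac
          if (sdl > 0)
            mult <- stats::rlnorm(nsnap, meanlog = -sdl^2 / 2, sdlog = sdl)
        }
        rows[[gidx]] <- data.frame(
          cell_id = cell, time_min = grid,
          signal = config$intensity_scale * (prot / volume) * mult,
          stringsAsFactors = FALSE)
      }
      fin <- res$final
      g <- as.integer(fin[1])
      m <- stats::rbinom(1, as.integer(fin[2]), config$retention)
      p <- stats::rbinom(1, as.integer(fin[3]), config$retention)
    }
    traces[[i]] <- do.call(rbind, rows)
    divisions[[i]] <- data.frame(cell_id = cell, division_time_min = bnds,
                                 stringsAsFactors = FALSE)
    truth_cells[[i]] <- list(cell_id = cell, lifespan = L, off = is_off[i],
                             division_times = bnds, rates = gen_rates)
  }

  tr <- do.call(rbind, traces)
  # global frames on the snapshot grid; shared background per frame
  frame_index <- tr$time_min / interval + 1
  tr$frame_id <- sprintf("f%04d", frame_index)
  all_frames <- sort(unique(tr$frame_id))
  bg_true <- pmax(stats::rnorm(length(all_frames), config$background_mean,
                               config$background_sd), 50)
  names(bg_true) <- all_frames
  tr$raw_intensity <- tr$signal + bg_true[tr$frame_id] +
    stats::rnorm(nrow(tr), 0, config$measurement_sd)
  tr <- tr[order(tr$cell_id, tr$time_min),
           c("cell_id", "time_min", "frame_id", "raw_intensity")]
  rownames(tr) <- NULL

  # pixel samples: the bottom decile sits just below the true background,
  # so the nearest-rank 10th-percentile estimator lands within a few
  # percent of it; the remaining pixels form the bright foreground tail
  n_low <- ceiling(0.10 * config$n_pixels)
  px <- lapply(all_frames, function(f) {
    b <- bg_true[[f]]
    low <- b * stats::runif(n_low, 0.95, 1)
    high <- b + stats::rexp(config$n_pixels - n_low, rate = 1 / (3 * b))
    data.frame(frame_id = f, pixel_intensity = c(sort(low), high),
               stringsAsFactors = FALSE)
  })
  pixels <- do.call(rbind, px)
  rownames(pixels) <- NULL
  divisions <- do.call(rbind, divisions)
  rownames(divisions) <- NULL

  structure(list(
    traces = tr, divisions = divisions, pixels = pixels,
    truth = list(cells = truth_cells, backgrounds = bg_true,
                 config = config, seed = seed)),
    class = "synthetic_cohort")
}

#' Scenario presets emulating the five characterized strains
#'
#' Returns a [cohort_config()] whose qualitative behavior matches one of
#' the five experimental scenarios.  Cohort sizes are chosen so that, with
#' the default 10% OFF fraction, the number of ON mother cells matches the
#' reported cohorts:
#'
#' * `wt` (59 ON cells): native promoter, fitted young-cell rates,
#'   proportional aging.
#' * `gal80del` (102 ON cells): constitutively active promoter with the
#'   upstream repressor deleted; slower young-cell switching (higher
#'   baseline noise) and higher expression, strong proportional reduction.
#' * `rpd3del` (52 ON cells): global remodeling regulator deleted; longer
#'   lifespans, the weakest aging-associated rate scaling, and a milder
#'   catastrophe phase.
#' * `synthetic_promoter` (73 ON cells): nucleosome-disfavoring sequences
#'   raise the ON-state occupancy and expression; reduction preserved.
#' * `synthetic_gal80del` (82 ON cells): both edits combined; the promoter
#'   is nearly always open, noise starts at its floor and stays there
#'   (constant mode).
#'
#' @param name Preset name.
#' @return A [cohort_config()].
#' @examples
#' n_on_cells(scenario_preset("wt"))       # 59
#' @export
scenario_preset <- function(name = c("wt", "gal80del", "rpd3del",
                                     "synthetic_promoter",
                                     "synthetic_gal80del")) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1], "'; available: wt, gal80del, ",
         "rpd3del, synthetic_promoter, synthetic_gal80del", call. = FALSE))
  base <- promoter_rates()     # fitted young-cell GAL1 rates
  # totals give 59/102/52/73/82 ON cells at the default 10% OFF fraction
  switch(name,
    wt = cohort_config(n_cells = 66),
    gal80del = cohort_config(
      n_cells = 113,
      base_rates = promoter_rates(base$r_on * 0.5, base$r_off * 0.5),
      kinetics = kinetic_rates(k_m = 1.5),
      schedule = aging_schedule("proportional", scale_at_plateau = 3.5)),
    rpd3del = cohort_config(
      n_cells = 58, lifespan_mean = 28,
      schedule = aging_schedule("proportional", scale_at_plateau = 1.5,
                                catastrophe_sdlog = 0.15),
      catastrophe_duration_mean_mult = 1.4,
      catastrophe_duration_sd_mult = 1.8),
    synthetic_promoter = cohort_config(
      n_cells = 81,
      base_rates = promoter_rates(base$r_on * 2.5, base$r_off)),
    synthetic_gal80del = cohort_config(
      n_cells = 91,
      base_rates = promoter_rates(base$r_on * 10, base$r_off * 0.1),
      schedule = aging_schedule("constant")))
}

#' Number of ON cells a cohort configuration generates
#'
#' @param config A [cohort_config()].
#' @return Integer count of ON cells.
#' @export
n_on_cells <- function(config) {
  config$n_cells - round(config$off_fraction * config$n_cells)
}

#' Write the three cohort tables (and ground truth) to a directory
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.  Writes `traces.csv`, `divisions.csv`,
#'   `pixels.csv` and `truth.json`.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$traces, file.path(outdir, "traces.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$divisions, file.path(outdir, "divisions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$pixels, file.path(outdir, "pixels.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    seed = cohort$truth$seed,
    backgrounds = as.list(cohort$truth$backgrounds),
    cells = lapply(cohort$truth$cells, function(x)
      list(cell_id = x$cell_id, lifespan = x$lifespan, off = x$off,
           division_times = x$division_times,
           r_on = x$rates[, "r_on"], r_off = x$rates[, "r_off"])))
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
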