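#' Exact stochastic simulation of the telegraph gene-expression model
#'
#' Event-by-event Gillespie simulation of the reaction set
#' OFF -> ON (`r_on`), ON -> OFF (`r_off`), ON -> ON + M (`k_m`),
#' M -> 0 (`gamma_m * m`), M -> M + P (`k_p * m`), P -> 0 (`gamma_p * p`),
#' sampled on a regular grid.  Identical inputs (including `seed`) give
#' bit-identical trajectories; randomness comes from a self-seeded
#' generator and does not touch R's RNG state.  A zero total propensity is
#' not an error: the state is simply held constant to `t_end`.
#'
#' @param rates A [promoter_rates()] object.
#' @param kin A [kinetic_rates()] object.
#' @param t_end End time of the simulation (minutes).
#' @param sample_interval Sampling grid spacing (minutes); samples are taken
#'   at `0, sample_interval, ..., t_end`.
#' @param init Initial state: a list with elements `promoter` (`"ON"` or
#'   `"OFF"`, or 1/0), `m`, `p`.  `NULL` (default) draws the promoter from
#'   its stationary distribution and sets `m`, `p` to their state-conditional
#'   steady-state means rounded to integers (shortens burn-in).
#' @param seed Integer seed (reproducibility contract).
#' @return A data frame of class `ssa_trajectory` with columns `time_min`,
#'   `promoter` (0/1), `mrna`, `protein`; the seed and final state are
#'   attached as attributes.
#' @examples
#' tr <- simulate_ssa(promoter_rates(), kinetic_rates(),
#'                    t_end = 200, sample_interval = 10, seed = 1)
#' head(tr)
#' @export
simulate_ssa <- function(rates, kin = kinetic_rates(), t_end,
                         sample_interval = 10, init = NULL, seed) {
  rates <- as_promoter_rates(rates)
  kin <- as_kinetic_rates(kin)
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  if (!is.numeric(sample_interval) || sample_interval <= 0)
    stop("'sample_interval' must be > 0", call. = FALSE)
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  init <- resolve_init(init, rates, kin)
  if (is.na(init$g)) {
    # stationary initial condition, drawn reproducibly from the seed
    init <- with_local_seed(as_seed(seed) + 1, {
      g <- as.integer(stats::runif(1) < init$p_on)
      list(g = g,
           m = round(if (g == 1L) init$m_on else init$m_off),
           p = round(if (g == 1L) init$p_on_mean else init$p_off))
    })
  }
  times <- seq(0, t_end, by = sample_interval)
  res <- cpp_ssa_path(rates$r_on, rates$r_off, kin$k_m, kin$gamma_m,
                      kin$k_p, kin$gamma_p, init$g, init$m, init$p,
                      0, times, as_seed(seed))
  out <- data.frame(time_min = times, promoter = res$promoter,
                    mrna = res$mrna, protein = res$protein)
  attr(out, "seed") <- seed
  attr(out, "final_state") <- res$final
  class(out) <- c("ssa_trajectory", "data.frame")
  out
}

resolve_init <- function(init, rates, kin) {
  if (is.null(init)) {
    if (kin$gamma_m > 0 && kin$gamma_p > 0 && rates$r_on + rates$r_off > 0) {
      mom <- moment_oracle(rates, kin)
      return(list(g = NA_integer_,      # signal: draw from stationary law
                  p_on = mom$p_on,
                  m_off = mom$cond_mean_m[["off"]],
                  m_on = mom$cond_mean_m[["on"]],
                  p_off = mom$cond_mean_p[["off"]],
                  p_on_mean = mom$cond_mean_p[["on"]]))
    }
    return(list(g = 0L, m = 0, p = 0))
  }
  g <- init$promoter
  if (is.character(g)) g <- match(toupper(g), c("OFF", "ON")) - 1L
  g <- as.integer(g)
  if (is.na(g) || !g %in% c(0L, 1L))
    stop("init$promoter must be 'ON'/'OFF' or 1/0", call. = FALSE)
  m <- as.numeric(init$m %||% 0); p <- as.numeric(init$p %||% 0)
  if (m < 0 || p < 0) stop("initial copy numbers must be >= 0", call. = FALSE)
  list(g = g, m = round(m), p = round(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_seed <- function(seed) {
  s <- as.numeric(seed)
  if (is.na(s) || s < 0) stop("'seed' must be a non-negative integer", call. = FALSE)
  s
}

#' Default relaxation time for steady-state measurement
#'
#' Ten times the slowest relaxation timescale of the model, which
#' guarantees the endpoint distribution is at steady state for practical
#' purposes regardless of the initial condition.
#'
#' @inheritParams simulate_ssa
#' @return Time in minutes.
#' @export
relaxation_time <- function(rates, kin = kinetic_rates()) {
  rates <- as_promoter_rates(rates)
  kin <- as_kinetic_rates(kin)
  10 / min(kin$gamma_m, kin$gamma_p, rates$r_on + rates$r_off)
}

#' Cross-replicate endpoint statistics of the stochastic model
#'
#' Runs `n_reps` independent stochastic replicates (replicate substreams
#' derived deterministically from the master `seed`), records the protein
#' copy number at `t_end`, and returns the cross-replicate mean, CV and
#' Fano factor with Monte-Carlo standard errors (analytic for the mean,
#' bootstrap for CV and Fano).  This mirrors per-parameter-point
#' steady-state noise estimation with N-replicate error bars.
#'
#' @inheritParams simulate_ssa
#' @param n_reps Number of replicates (>= 2); 2000 by default.
#' @param t_end Measurement time; defaults to [relaxation_time()].
#' @param init Optional fixed initial state as in [simulate_ssa()].
#' @param n_boot Bootstrap resamples for the CV/Fano standard errors.
#' @return A list of class `ensemble_stats` with elements `mean_p`, `cv_p`,
#'   `fano_p`, `sem_mean`, `sem_cv`, `sem_fano`, `n_reps`, `t_end`,
#'   `protein` (the endpoint sample), and `degenerate` (TRUE when the mean
#'   is zero and CV/Fano are undefined).
#' @examples
#' es <- ensemble_stats(promoter_rates(), kinetic_rates(),
#'                      n_reps = 50, t_end = 300, seed = 1)
#' es$mean_p
#' @export
ensemble_stats <- function(rates, kin = kinetic_rates(), n_reps = 2000,
                           t_end = NULL, seed, init = NULL, n_boot = 200) {
  rates <- as_promoter_rates(rates)
  kin <- as_kinetic_rates(kin)
  if (n_reps < 2) stop("'n_reps' must be >= 2", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (is.null(t_end)) t_end <- relaxation_time(rates, kin)
  ini <- resolve_init(init, rates, kin)
  if (is.na(ini$g)) {
    p_on_init <- ini$p_on
    m_off <- ini$m_off; m_on <- ini$m_on
    p_off <- ini$p_off; p_on_mean <- ini$p_on_mean
  } else {
    p_on_init <- as.numeric(ini$g)
    m_off <- m_on <- ini$m
    p_off <- p_on_mean <- ini$p
  }
  ends <- cpp_ssa_ensemble(rates$r_on, rates$r_off, kin$k_m, kin$gamma_m,
                           kin$k_p, kin$gamma_p, t_end, as.integer(n_reps),
                           as_seed(seed), p_on_init, m_off, m_on,
                           p_off, p_on_mean)
  p <- ends[, "protein"]
  mean_p <- mean(p)
  sd_p <- stats::sd(p)
  degenerate <- !is.finite(mean_p) || mean_p == 0
  cv <- if (degenerate) NA_real_ else sd_p / mean_p
  fano <- if (degenerate) NA_real_ else sd_p^2 / mean_p
  # deterministic bootstrap from the same master seed, R RNG state untouched
  boot <- replicate_bootstrap(p, n_boot, as_seed(seed) + 1)
  out <- list(mean_p = mean_p, cv_p = cv, fano_p = fano,
              sem_mean = sd_p / sqrt(n_reps),
              sem_cv = boot["cv"], sem_fano = boot["fano"],
              n_reps = n_reps, t_end = t_end, seed = seed,
              protein = p, degenerate = degenerate)
  class(out) <- "ensemble_stats"
  out
}

# evaluate expr with a temporary RNG seed, restoring the session RNG state
with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

replicate_bootstrap <- function(p, n_boot, seed) with_local_seed(seed, {
  n <- length(p)
  cvs <- numeric(n_boot); fanos <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    x <- p[sample.int(n, n, replace = TRUE)]
    mu <- mean(x)
    if (mu > 0) {
      cvs[b] <- stats::sd(x) / mu
      fanos[b] <- stats::var(x) / mu
    } else {
      cvs[b] <- NA_real_; fanos[b] <- NA_real_
    }
  }
  c(cv = stats::sd(cvs, na.rm = TRUE), fano = stats::sd(fanos, na.rm = TRUE))
})

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf(
    "ensemble of %d replicates at t = %.0f min: mean_p = %.4g (SEM %.3g), CV = %.4g (SEM %.3g), Fano = %.4g (SEM %.3g)%s\n",
    x$n_reps, x$t_end, x$mean_p, x$sem_mean, x$cv_p, x$sem_cv, x$fano_p,
    x$sem_fano,
    if (isTRUE(x$degenerate)) " [degenerate: zero mean, CV/Fano undefined]" else ""))
  invisible(x)
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory A data frame from [simulate_ssa()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(
    trajectory[, c("time_min", "promoter", "mrna", "protein")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
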