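#' @name sweeps
#' @title Parameter sweeps of the telegraph model
#'
#' @description
#' The sweeps explore how steady-state expression mean and noise respond to
#' the promoter switching rates and to the downstream kinetic rates:
#'
#' * `grid_sweep()` evaluates every combination of the supplied `r_on` and
#'   `r_off` values (the heatmap view).
#' * `diagonal_sweep()` scales both switching rates by common factors `c`,
#'   which leaves the mean exactly unchanged while noise falls -- the
#'   "equal proportions" aging mechanism.
#' * `vertical_sweep()` holds `r_off` fixed and varies `r_on`, the
#'   alternative route on which the mean rises as noise falls.
#' * `nonchromatin_sweep()` holds the promoter rates fixed and varies the
#'   mRNA synthesis and degradation rates by up to `fold`-fold in both
#'   directions, compensating the translation rate
#'   (`k_p' = k_p * gamma_m' * k_m / (gamma_m * k_m')`) so the mean is
#'   conserved; it quantifies how much noise reduction is achievable
#'   without touching chromatin dynamics.
#'
#' Each returns a data frame of class `sweep_result` with one row per
#' parameter point and columns `r_on`, `r_off`, `k_m`, `gamma_m`, `k_p`,
#' `gamma_p`, `mean_p`, `cv_p`, `fano_p`, `sem_mean`, `sem_cv`, `sem_fano`,
#' `n_reps` (SEM columns are `NA` under the exact oracle engine).
#'
#' @param rates,base A [promoter_rates()] object (base point).
#' @param kin A [kinetic_rates()] object.
#' @param engine `"oracle"` for exact moments (default) or `"ssa"` for
#'   Monte-Carlo ensembles with standard errors.
#' @param n_reps Ensemble size per point when `engine = "ssa"`.
#' @param seed Master seed; point `i` uses substream `seed + i`.
NULL

sweep_point <- function(r_on, r_off, kin, engine, n_reps, seed) {
  rates <- promoter_rates(r_on, r_off)
  if (engine == "oracle") {
    mom <- moment_oracle(rates, kin)
    data.frame(r_on = r_on, r_off = r_off, k_m = kin$k_m,
               gamma_m = kin$gamma_m, k_p = kin$k_p, gamma_p = kin$gamma_p,
               mean_p = mom$mean_p, cv_p = mom$cv_p, fano_p = mom$fano_p,
               sem_mean = NA_real_, sem_cv = NA_real_, sem_fano = NA_real_,
               n_reps = NA_integer_)
  } else {
    es <- ensemble_stats(rates, kin, n_reps = n_reps, seed = seed)
    data.frame(r_on = r_on, r_off = r_off, k_m = kin$k_m,
               gamma_m = kin$gamma_m, k_p = kin$k_p, gamma_p = kin$gamma_p,
               mean_p = es$mean_p, cv_p = es$cv_p, fano_p = es$fano_p,
               sem_mean = es$sem_mean, sem_cv = unname(es$sem_cv),
               sem_fano = unname(es$sem_fano), n_reps = n_reps)
  }
}

finish_sweep <- function(rows, kind, seed) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @rdname sweeps
#' @param r_on_values,r_off_values Positive rate grids (per minute).
#' @export
grid_sweep <- function(r_on_values, r_off_values, kin = kinetic_rates(),
                       engine = c("oracle", "ssa"), n_reps = 2000,
                       seed = 1) {
  engine <- match.arg(engine)
  kin <- as_kinetic_rates(kin)
  if (length(r_on_values) < 1 || length(r_off_values) < 1 ||
      any(r_on_values <= 0) || any(r_off_values <= 0))
    stop("rate grids must be non-empty and positive", call. = FALSE)
  grid <- expand.grid(r_on = r_on_values, r_off = r_off_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i)
    sweep_point(grid$r_on[i], grid$r_off[i], kin, engine, n_reps, seed + i))
  finish_sweep(rows, "grid", seed)
}

#' @rdname sweeps
#' @param scale_factors Positive common scale factors applied to both
#'   switching rates.
#' @export
diagonal_sweep <- function(base = promoter_rates(),
                           scale_factors = c(1, 2, 4, 8),
                           kin = kinetic_rates(),
                           engine = c("oracle", "ssa"), n_reps = 2000,
                           seed = 1) {
  engine <- match.arg(engine)
  base <- as_promoter_rates(base)
  kin <- as_kinetic_rates(kin)
  if (any(scale_factors <= 0)) stop("scale factors must be > 0", call. = FALSE)
  rows <- lapply(seq_along(scale_factors), function(i) {
    cc <- scale_factors[i]
    cbind(sweep_point(cc * base$r_on, cc * base$r_off, kin, engine, n_reps,
                      seed + i),
          scale = cc)
  })
  finish_sweep(rows, "diagonal", seed)
}

#' @rdname sweeps
#' @param r_off Fixed ON-to-OFF rate for the vertical sweep.
#' @param r_on_values Varying OFF-to-ON rates.
#' @export
vertical_sweep <- function(r_off = 0.0348, r_on_values,
                           kin = kinetic_rates(),
                           engine = c("oracle", "ssa"), n_reps = 2000,
                           seed = 1) {
  engine <- match.arg(engine)
  kin <- as_kinetic_rates(kin)
  if (r_off <= 0) stop("'r_off' must be > 0", call. = FALSE)
  if (any(r_on_values <= 0)) stop("'r_on_values' must be > 0", call. = FALSE)
  rows <- lapply(seq_along(r_on_values), function(i)
    sweep_point(r_on_values[i], r_off, kin, engine, n_reps, seed + i))
  finish_sweep(rows, "vertical", seed)
}

#' @rdname sweeps
#' @param fold Maximum fold change of the mRNA rates (>= 1); the grid is
#'   log-spaced on `[1/fold, fold]` in each direction.
#' @param n_grid Number of grid points per axis.
#' @return For `nonchromatin_sweep()` the result additionally carries
#'   columns `f_km`, `f_gm` (the fold changes) and the attribute
#'   `max_cv_decrease`, the maximum relative CV decrease over the grid
#'   with respect to the unperturbed base point.
#' @export
nonchromatin_sweep <- function(base = promoter_rates(),
                               kin = kinetic_rates(), fold = 10,
                               n_grid = 9,
                               engine = c("oracle", "ssa"), n_reps = 2000,
                               seed = 1) {
  engine <- match.arg(engine)
  base <- as_promoter_rates(base)
  kin <- as_kinetic_rates(kin)
  if (fold < 1) stop("'fold' must be >= 1", call. = FALSE)
  f <- 10^seq(-log10(fold), log10(fold), length.out = n_grid)
  grid <- expand.grid(f_km = f, f_gm = f, KEEP.OUT.ATTRS = FALSE)
  base_cv <- moment_oracle(base, kin)$cv_p
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    kmp <- grid$f_km[i] * kin$k_m
    gmp <- grid$f_gm[i] * kin$gamma_m
    # translation compensation keeps mean_p = k_m' k_p' p_on / (gamma_m' gamma_p)
    kpp <- kin$k_p * gmp * kin$k_m / (kin$gamma_m * kmp)
    kin_i <- kinetic_rates(kmp, gmp, kpp, kin$gamma_p)
    cbind(sweep_point(base$r_on, base$r_off, kin_i, engine, n_reps, seed + i),
          f_km = grid$f_km[i], f_gm = grid$f_gm[i])
  })
  out <- finish_sweep(rows, "nonchromatin", seed)
  attr(out, "base_cv") <- base_cv
  attr(out, "max_cv_decrease") <- max(1 - out$cv_p / base_cv)
  out
}

#' Write a sweep result to CSV
#'
#' @param sweep A `sweep_result` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
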