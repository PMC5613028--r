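#' Exact steady-state moments of the telegraph gene-expression model
#'
#' Because every reaction propensity in the two-state promoter + mRNA +
#' protein scheme is linear in the state, the first and second moments obey
#' a closed linear system.  This function assembles that system for the
#' moments \eqn{E[G], E[m], E[p], E[Gm], E[Gp], E[m^2], E[mp], E[p^2]}
#' (with \eqn{G} the ON indicator) and solves it exactly, with no
#' simulation.  It serves as the independent oracle against which the
#' stochastic simulator is validated.
#'
#' The classical closed forms fall out as special cases:
#' \eqn{p_{on} = r_{on}/(r_{on}+r_{off})},
#' \eqn{\langle m\rangle = k_m p_{on}/\gamma_m},
#' \eqn{Fano_m = 1 + k_m r_{off} / ((r_{on}+r_{off})(r_{on}+r_{off}+\gamma_m))},
#' \eqn{\langle p\rangle = k_p \langle m\rangle/\gamma_p}.
#'
#' @param rates A [promoter_rates()] object (or coercible list).
#' @param kin A [kinetic_rates()] object (or coercible list).
#' @return A list of class `telegraph_moments` with elements `p_on`,
#'   `mean_m`, `var_m`, `fano_m`, `mean_p`, `var_p`, `cv_p`, `fano_p`,
#'   `cov_mp`.
#' @examples
#' moment_oracle(promoter_rates(), kinetic_rates())
#' @export
moment_oracle <- function(rates, kin = kinetic_rates()) {
  rates <- as_promoter_rates(rates)
  kin <- as_kinetic_rates(kin)
  r_on <- rates$r_on; r_off <- rates$r_off
  k_m <- kin$k_m; g_m <- kin$gamma_m; k_p <- kin$k_p; g_p <- kin$gamma_p
  if (g_m <= 0 || g_p <= 0)
    stop("steady-state moments require gamma_m > 0 and gamma_p > 0 ",
         "(no stationary distribution otherwise)", call. = FALSE)
  if (r_on + r_off <= 0)
    stop("steady-state moments require r_on + r_off > 0", call. = FALSE)

  vars <- c("G", "m", "p", "Gm", "Gp", "m2", "mp", "p2")
  idx <- function(v) match(v, vars)
  A <- matrix(0, 8, 8, dimnames = list(vars, vars))
  b <- numeric(8)

  # d<G>/dt  = r_on - (r_on + r_off) <G>
  A[1, idx("G")] <- -(r_on + r_off); b[1] <- r_on
  # d<m>/dt  = k_m <G> - g_m <m>
  A[2, idx("G")] <- k_m; A[2, idx("m")] <- -g_m
  # d<p>/dt  = k_p <m> - g_p <p>
  A[3, idx("m")] <- k_p; A[3, idx("p")] <- -g_p
  # d<Gm>/dt = r_on <m> - (r_on + r_off + g_m) <Gm> + k_m <G>   (G^2 = G)
  A[4, idx("m")] <- r_on; A[4, idx("Gm")] <- -(r_on + r_off + g_m)
  A[4, idx("G")] <- k_m
  # d<Gp>/dt = r_on <p> - (r_on + r_off + g_p) <Gp> + k_p <Gm>
  A[5, idx("p")] <- r_on; A[5, idx("Gp")] <- -(r_on + r_off + g_p)
  A[5, idx("Gm")] <- k_p
  # d<m2>/dt = k_m (2<Gm> + <G>) + g_m (<m> - 2<m2>)
  A[6, idx("Gm")] <- 2 * k_m; A[6, idx("G")] <- k_m
  A[6, idx("m")] <- g_m; A[6, idx("m2")] <- -2 * g_m
  # d<mp>/dt = k_m <Gp> + k_p <m2> - (g_m + g_p) <mp>
  A[7, idx("Gp")] <- k_m; A[7, idx("m2")] <- k_p
  A[7, idx("mp")] <- -(g_m + g_p)
  # d<p2>/dt = k_p (2<mp> + <m>) + g_p (<p> - 2<p2>)
  A[8, idx("mp")] <- 2 * k_p; A[8, idx("m")] <- k_p
  A[8, idx("p")] <- g_p; A[8, idx("p2")] <- -2 * g_p

  x <- solve(A, -b)
  names(x) <- vars
  mean_m <- x[["m"]]; var_m <- x[["m2"]] - mean_m^2
  mean_p <- x[["p"]]; var_p <- x[["p2"]] - mean_p^2
  structure(list(
    p_on = x[["G"]],
    mean_m = mean_m,
    var_m = var_m,
    fano_m = if (mean_m > 0) var_m / mean_m else NA_real_,
    mean_p = mean_p,
    var_p = var_p,
    cv_p = if (mean_p > 0) sqrt(max(var_p, 0)) / mean_p else NA_real_,
    fano_p = if (mean_p > 0) var_p / mean_p else NA_real_,
    cov_mp = x[["mp"]] - mean_m * mean_p,
    cond_mean_m = c(off = (mean_m - x[["Gm"]]) / max(1 - x[["G"]], 1e-300),
                    on = x[["Gm"]] / max(x[["G"]], 1e-300)),
    cond_mean_p = c(off = (mean_p - x[["Gp"]]) / max(1 - x[["G"]], 1e-300),
                    on = x[["Gp"]] / max(x[["G"]], 1e-300))
  ), class = "telegraph_moments")
}

#' @export
print.telegraph_moments <- function(x, ...) {
  cat(sprintf(
    "telegraph steady state: p_on = %.4f | mRNA mean %.4g (Fano %.4g) | protein mean %.4g (CV %.4g, Fano %.4g)\n",
    x$p_on, x$mean_m, x$fano_m, x$mean_p, x$cv_p, x$fano_p))
  invisible(x)
}

#' Infer promoter switching rates from protein mean and CV
#'
#' Inverts the steady-state moment relations of the telegraph model: the
#' target protein mean pins down the ON-state occupancy
#' \eqn{p_{on} = \mu_p \gamma_m \gamma_p/(k_m k_p)}, after which the overall
#' switching speed \eqn{s = r_{on} + r_{off}} is found by one-dimensional
#' root finding on the (strictly decreasing) map from \eqn{s} to the
#' steady-state protein CV at fixed occupancy.
#'
#' The CV cannot be driven below the fast-switching (constitutive) floor
#' \eqn{CV_{floor}^2 = (1 + k_p/(\gamma_m + \gamma_p))/\mu_p}; a target below
#' that floor is infeasible and raises an error reporting the floor.  When
#' the target mean corresponds to full occupancy (`p_on = 1`) the promoter
#' never switches off and `r_off = 0` is returned (with `r_on` set to 1,
#' which is then immaterial).
#'
#' @param target_mean_p Target steady-state protein mean (molecules).
#' @param target_cv_p Target steady-state protein CV (ratio, not percent).
#' @param kin A [kinetic_rates()] object.
#' @param interval Log10 search range for the total switching rate
#'   \eqn{s} (per minute).
#' @param tol Relative root-finding tolerance.
#' @return A [promoter_rates()] object.
#' @examples
#' mom <- moment_oracle(promoter_rates(0.0229, 0.0348))
#' fit_promoter_rates(mom$mean_p, mom$cv_p)
#' @export
fit_promoter_rates <- function(target_mean_p, target_cv_p,
                               kin = kinetic_rates(),
                               interval = c(-7, 4), tol = 1e-12) {
  kin <- as_kinetic_rates(kin)
  if (!is.numeric(target_mean_p) || target_mean_p <= 0)
    stop("'target_mean_p' must be positive", call. = FALSE)
  if (!is.numeric(target_cv_p) || target_cv_p <= 0)
    stop("'target_cv_p' must be positive", call. = FALSE)
  p_on <- target_mean_p * kin$gamma_m * kin$gamma_p / (kin$k_m * kin$k_p)
  if (p_on > 1 + 1e-9)
    stop(sprintf(
      "target mean %g exceeds the maximum achievable mean %g (promoter always ON)",
      target_mean_p, kin$k_m * kin$k_p / (kin$gamma_m * kin$gamma_p)),
      call. = FALSE)
  p_on <- min(p_on, 1)
  cv_floor <- sqrt((1 + kin$k_p / (kin$gamma_m + kin$gamma_p)) / target_mean_p)
  at_floor <- abs(target_cv_p - cv_floor) <= 1e-8 * cv_floor
  if (p_on >= 1 - 1e-9) {
    # always-ON promoter: CV is the floor regardless of switching speed
    if (at_floor) return(promoter_rates(r_on = 1, r_off = 0))
    stop(sprintf(
      "at full occupancy the protein CV is fixed at the constitutive floor %g; target %g is unattainable",
      cv_floor, target_cv_p), call. = FALSE)
  }
  if (target_cv_p <= cv_floor && !at_floor)
    stop(sprintf(
      "target CV %g is at or below the fast-switching noise floor %g for this mean",
      target_cv_p, cv_floor), call. = FALSE)

  cv_at <- function(log10_s) {
    s <- 10^log10_s
    moment_oracle(promoter_rates(p_on * s, (1 - p_on) * s), kin)$cv_p
  }
  f <- function(log10_s) cv_at(log10_s) - target_cv_p
  lo <- interval[1]; hi <- interval[2]
  if (at_floor) {
    # boundary: fastest switching in range reproduces the floor
    s <- 10^hi
    return(promoter_rates(p_on * s, (1 - p_on) * s))
  }
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo < 0)
    stop(sprintf(
      "target CV %g exceeds the slow-switching ceiling %g reachable in the search range",
      target_cv_p, cv_at(lo) ), call. = FALSE)
  if (f_hi > 0)
    stop(sprintf(
      "target CV %g is below the CV %g at the fast end of the search range (floor %g)",
      target_cv_p, cv_at(hi), cv_floor), call. = FALSE)
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = tol)
  s <- 10^root$root
  promoter_rates(r_on = p_on * s, r_off = (1 - p_on) * s)
}
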