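#' Noise statistics of an expression sample
#'
#' Computes the two noise metrics used throughout the package for a vector
#' of expression measurements: the coefficient of variation (CV), the
#' standard deviation divided by the mean, and the Fano factor, the
#' variance divided by the mean.  The sample (n - 1) convention is used for
#' the variance, which is unbiased at the small per-window sample sizes
#' (8-18 snapshots) the aging pipeline produces.
#'
#' @param values Numeric vector of measurements (length >= 2).
#' @return A list of class `sample_stats` with elements `n`, `mean`, `sd`,
#'   `cv`, `fano`.
#' @examples
#' compute_stats(c(2, 4, 6))    # cv 0.5, fano 1
#' @export
compute_stats <- function(values) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2)
    stop(sprintf("insufficient data: need at least 2 values, got %d", n),
         call. = FALSE)
  mu <- mean(values)
  if (mu == 0)
    stop("mean is zero: CV and Fano factor are undefined (mean = 0)",
         call. = FALSE)
  s <- stats::sd(values)
  structure(list(n = n, mean = mu, sd = s, cv = s / mu, fano = s^2 / mu),
            class = "sample_stats")
}

#' @export
print.sample_stats <- function(x, ...) {
  cat(sprintf("n = %d: mean = %.6g, sd = %.6g, CV = %.6g, Fano = %.6g\n",
              x$n, x$mean, x$sd, x$cv, x$fano))
  invisible(x)
}

# Vectorised internals used by the pipeline (same conventions as
# compute_stats but tolerant of degenerate groups, returning NA).
stat_row <- function(values) {
  n <- length(values)
  if (n < 2) return(c(n = n, mean = mean(values), sd = NA, cv = NA, fano = NA))
  mu <- mean(values); s <- stats::sd(values)
  c(n = n, mean = mu, sd = s,
    cv = if (mu != 0) s / mu else NA_real_,
    fano = if (mu != 0) s^2 / mu else NA_real_)
}

#' Check the scaling identities of the noise metrics
#'
#' For any positive scale factor `c`, the CV is invariant under rescaling
#' of the measurement units while the Fano factor scales linearly:
#' `cv(c * x) == cv(x)` and `fano(c * x) == c * fano(x)`.  Returns the two
#' absolute identity violations, useful in property tests.
#'
#' @param values Numeric vector (length >= 2, nonzero mean).
#' @param c Positive scale factor.
#' @return Named numeric vector with elements `cv_error` and `fano_error`.
#' @export
scale_invariance_check <- function(values, c) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    stop("'c' must be a single positive number", call. = FALSE)
  s0 <- compute_stats(values)
  s1 <- compute_stats(c * values)
  c(cv_error = abs(s1$cv - s0$cv),
    fano_error = abs(s1$fano - c * s0$fano))
}
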