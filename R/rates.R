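#' Promoter switching rates
#'
#' Container for the two chromatin-state transition rates of the two-state
#' (telegraph) promoter model: `r_on` is the rate of switching from the
#' closed (OFF) to the open (ON) chromatin state, `r_off` the reverse rate.
#' The defaults are the fitted values for the native GAL1 promoter in young
#' cells.
#'
#' @param r_on OFF-to-ON transition rate (per minute).
#' @param r_off ON-to-OFF transition rate (per minute).
#' @return An object of class `promoter_rates`: a list with elements
#'   `r_on` and `r_off`.
#' @examples
#' promoter_rates()                 # fitted GAL1 rates
#' promoter_rates(0.05, 0.01)
#' @export
promoter_rates <- function(r_on = 0.0229, r_off = 0.0348) {
  if (!is.numeric(r_on) || length(r_on) != 1L || is.na(r_on) || r_on < 0)
    stop("'r_on' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(r_off) || length(r_off) != 1L || is.na(r_off) || r_off < 0)
    stop("'r_off' must be a single non-negative number", call. = FALSE)
  structure(list(r_on = r_on, r_off = r_off), class = "promoter_rates")
}

#' Kinetic rates of the expression stages downstream of the promoter
#'
#' Transcription, mRNA turnover, translation and protein removal rates for
#' the telegraph gene-expression model.  Defaults describe a stable
#' fluorescent reporter in budding yeast: a ~14 min mRNA half-life and
#' protein loss purely by dilution at a 90-minute generation time (the
#' reporter itself is not actively degraded).
#'
#' @param k_m Transcription rate while the promoter is ON (mRNA per minute).
#' @param gamma_m mRNA degradation rate (per minute).
#' @param k_p Translation rate (protein per mRNA per minute).
#' @param gamma_p Protein removal/dilution rate (per minute).
#' @return An object of class `kinetic_rates`.
#' @examples
#' kinetic_rates()
#' kinetic_rates(k_m = 2, gamma_m = 0.1)
#' @export
kinetic_rates <- function(k_m = 1, gamma_m = 0.05, k_p = 2,
                          gamma_p = log(2) / 90) {
  vals <- c(k_m = k_m, gamma_m = gamma_m, k_p = k_p, gamma_p = gamma_p)
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0))
    stop("all kinetic rates must be non-negative numbers", call. = FALSE)
  structure(as.list(vals), class = "kinetic_rates")
}

#' @export
print.promoter_rates <- function(x, ...) {
  cat(sprintf("promoter rates: r_on = %g, r_off = %g (per min)\n",
              x$r_on, x$r_off))
  invisible(x)
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf(
    "kinetic rates: k_m = %g, gamma_m = %g, k_p = %g, gamma_p = %g (per min)\n",
    x$k_m, x$gamma_m, x$k_p, x$gamma_p))
  invisible(x)
}

as_promoter_rates <- function(x) {
  if (inherits(x, "promoter_rates")) return(x)
  if (is.numeric(x) && !is.null(names(x)) &&
      all(c("r_on", "r_off") %in% names(x)))
    return(promoter_rates(unname(x[["r_on"]]), unname(x[["r_off"]])))
  if (is.list(x) && all(c("r_on", "r_off") %in% names(x)))
    return(promoter_rates(x$r_on, x$r_off))
  stop("cannot interpret 'rates' as promoter rates", call. = FALSE)
}

as_kinetic_rates <- function(x) {
  if (inherits(x, "kinetic_rates")) return(x)
  if (is.list(x) && all(c("k_m", "gamma_m", "k_p", "gamma_p") %in% names(x)))
    return(kinetic_rates(x$k_m, x$gamma_m, x$k_p, x$gamma_p))
  stop("cannot interpret 'kin' as kinetic rates", call. = FALSE)
}
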