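# Particle-size statistics for diameter samples (TEM-style counts).

#' Gaussian fit of a particle-diameter histogram
#'
#' Reproduces the common microscopy workflow: histogram the measured
#' diameters and least-squares fit a Gaussian `A exp(-(x - mu)^2 / (2
#' s^2))` to the bin counts.  For fewer than 30 particles, a degenerate
#' (all-equal) sample, or a failed fit, the function falls back to plain
#' sample moments and flags it.
#'
#' @param diameters Numeric vector of diameters, nm, all positive.
#' @param n_bins Number of equal-width histogram bins; default chosen by
#'   the Freedman-Diaconis rule.
#' @return List with `mean` (nm), `sd` (nm), `method` (`"gaussian_fit"` or
#'   `"moments"`), `n`, and for the fit path `amplitude` and `r_squared`.
#' @export
gaussian_fit_diameters <- function(diameters, n_bins = NULL) {
  .check_positive(diameters, "diameters")
  n <- length(diameters)
  mom <- list(mean = mean(diameters),
              sd = if (n > 1) stats::sd(diameters) else 0,
              method = "moments", n = n)
  if (n < 30 || mom$sd == 0) return(mom)
  if (is.null(n_bins)) {
    iqr <- stats::IQR(diameters)
    width <- 2 * iqr / n^(1 / 3)
    n_bins <- if (width > 0) {
      max(5L, ceiling(diff(range(diameters)) / width))
    } else 10L
  }
  h <- graphics::hist(diameters, breaks = seq(min(diameters),
                                              max(diameters),
                                              length.out = n_bins + 1),
                      plot = FALSE)
  x <- h$mids; y <- h$counts
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(A = max(y), mu = mom$mean, s = mom$sd),
                      lower = c(0, 0, 1e-6 * mom$sd)),
    error = function(e) NULL)
  if (is.null(fit)) return(mom)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(mean = unname(co["mu"]), sd = unname(abs(co["s"])),
       method = "gaussian_fit", n = n, amplitude = unname(co["A"]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Polydispersity index
#'
#' `PDI = sd / mean` of the diameter distribution.  Note: this is the
#' microscopy definition (coefficient of variation of the measured
#' diameters), not the DLS cumulant PDI.
#'
#' @param mean Mean diameter, nm; must be > 0.
#' @param sd Standard deviation of the diameters, nm.
#' @return Dimensionless PDI.
#' @export
pdi <- function(mean, sd) {
  if (!is.numeric(mean) || any(mean <= 0)) stop("mean must be positive")
  if (any(sd < 0)) stop("sd must be non-negative")
  sd / mean
}

#' Moments of a log-normal diameter distribution
#'
#' Converts (median, sigma_log) of a log-normal diameter distribution to
#' its arithmetic mean and standard deviation:
#' `mean = median exp(sigma^2/2)`, `sd = mean sqrt(exp(sigma^2) - 1)`.
#'
#' @param median Median diameter, nm.
#' @param sigma_log Standard deviation of log diameter, `>= 0`.
#' @return Named numeric vector `c(mean, sd)`, nm.
#' @export
lognormal_summary <- function(median, sigma_log) {
  .check_positive(median, "median")
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  m <- median * exp(sigma_log^2 / 2)
  c(mean = m, sd = m * sqrt(exp(sigma_log^2) - 1))
}

#' Log-normal parameters from target moments
#'
#' Inverse of [lognormal_summary()]: solves for (median, sigma_log) such
#' that the log-normal has the requested arithmetic mean and SD.
#'
#' @param mean,sd Target arithmetic mean and standard deviation, nm.
#' @return Named numeric vector `c(median, sigma_log)`.
#' @export
lognormal_from_moments <- function(mean, sd) {
  .check_positive(mean, "mean")
  if (sd < 0) stop("sd must be non-negative")
  s2 <- log(1 + (sd / mean)^2)
  c(median = mean * exp(-s2 / 2), sigma_log = sqrt(s2))
}
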