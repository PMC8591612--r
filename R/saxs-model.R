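# Form-factor model: homogeneous spheres with a log-normal diameter
# distribution, on absolute intensity scale.
#
# I(q) = drho^2 * n * <V(R)^2 P(q,R)> + background,
# where the number density n is set so the total particle volume per unit
# sample volume equals the volume fraction phi:
#   n = phi / <V(R)>   =>   I(q) = drho^2 * phi * <V^2 P> / <V> + bkg.
# Averages <.> are over the number-weighted log-normal diameter
# distribution, evaluated by fixed-order Gauss-Legendre quadrature in
# log-diameter.

#' Sphere form factor
#'
#' Normalized single-particle scattering function of a homogeneous sphere,
#' `P(q) = [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2`, with the q -> 0 limit
#' (P = 1) evaluated analytically.
#'
#' @param q Scattering vector, 1/Angstrom; `q >= 0`.
#' @param radius Sphere radius, Angstrom.
#' @return P(q), dimensionless, in `[0, 1]`.
#' @export
sphere_form_factor <- function(q, radius) {
  if (!is.numeric(radius) || any(radius <= 0)) stop("radius must be positive")
  if (any(q < 0)) stop("q must be non-negative")
  x <- q * radius
  p <- rep(1, length(x))
  big <- x > 1e-4
  xb <- x[big]
  p[big] <- (3 * (sin(xb) - xb * cos(xb)) / xb^3)^2
  # series for small x: amplitude 1 - x^2/10 + O(x^4)
  p[!big] <- (1 - x[!big]^2 / 10)^2
  p
}

#' Sphere/log-normal intensity model parameters
#'
#' @param median_diameter Median of the number-weighted log-normal diameter
#'   distribution, nm.
#' @param sigma_log Log-normal width (SD of log diameter), dimensionless,
#'   `>= 0`.
#' @param volume_fraction Particle volume fraction phi, in (0, 1).
#' @param contrast Scattering length density difference particle-solvent,
#'   1/Angstrom^2.
#' @param background Flat background, internal intensity units (1/Angstrom).
#' @return Object of class `sphere_lognormal_model`.
#' @export
sphere_lognormal_model <- function(median_diameter, sigma_log,
                                   volume_fraction, contrast,
                                   background = 0) {
  .check_positive(median_diameter, "median_diameter")
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  if (volume_fraction <= 0 || volume_fraction >= 1) {
    stop("volume_fraction must be in (0, 1)")
  }
  .check_positive(contrast, "contrast")
  if (background < 0) stop("background must be >= 0")
  structure(list(median_diameter = median_diameter, sigma_log = sigma_log,
                 volume_fraction = volume_fraction, contrast = contrast,
                 background = background),
            class = "sphere_lognormal_model")
}

#' @export
print.sphere_lognormal_model <- function(x, ...) {
  m <- lognormal_summary(x$median_diameter, x$sigma_log)
  cat(sprintf(paste0(
    "sphere/log-normal model: median D = %.3g nm, sigma_log = %.3g\n",
    "  mean D = %.3g nm, SD = %.3g nm, phi = %.3g, drho = %.3g A^-2, ",
    "bkg = %.3g\n"),
    x$median_diameter, x$sigma_log, m[["mean"]], m[["sd"]],
    x$volume_fraction, x$contrast, x$background))
  invisible(x)
}

# Quadrature nodes/weights over the number-weighted log-normal diameter
# density, diameters in Angstrom.  151-point Gauss-Legendre on
# log(D) in median +/- 5 sigma.
.lognormal_quadrature <- function(median_diameter_nm, sigma_log, n = 151) {
  mu <- log(median_diameter_nm * 10)  # nm -> Angstrom
  if (sigma_log == 0) {
    return(list(d = exp(mu), w = 1))
  }
  if (sigma_log > 2) {
    stop("sigma_log > 2: log-normal too broad for reliable quadrature")
  }
  gl <- pracma::gaussLegendre(n, mu - 5 * sigma_log, mu + 5 * sigma_log)
  dens <- stats::dnorm(gl$x, mean = mu, sd = sigma_log)
  w <- gl$w * dens
  if (abs(sum(w) - 1) > 1e-3) {
    stop("quadrature covers less than 99.9% of the size distribution")
  }
  list(d = exp(gl$x), w = w / sum(w))
}

#' Model intensity of polydisperse homogeneous spheres
#'
#' Absolute-scale scattering intensity of dilute homogeneous spheres with a
#' number-weighted log-normal diameter distribution plus a flat background.
#' No structure factor (dilute limit).
#'
#' @param q Scattering vector grid, 1/Angstrom.
#' @param model A [sphere_lognormal_model()].
#' @return Intensity in internal units (1/Angstrom), same length as `q`.
#' @export
model_intensity <- function(q, model) {
  stopifnot(inherits(model, "sphere_lognormal_model"))
  quad <- .lognormal_quadrature(model$median_diameter, model$sigma_log)
  r <- quad$d / 2
  v <- 4 / 3 * pi * r^3
  # <V^2 P(q)> and <V> over the diameter distribution
  pmat <- outer(q, r, sphere_form_factor)           # nq x nr
  mean_v2p <- drop(pmat %*% (v^2 * quad$w))
  mean_v <- sum(v * quad$w)
  model$contrast^2 * model$volume_fraction * mean_v2p / mean_v +
    model$background
}
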