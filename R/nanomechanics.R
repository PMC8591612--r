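# Hertzian contact mechanics on AFM force-indentation curves.
#
# Sphere-on-flat Hertz model with a rigid tip:
#   F = (4/3) * E/(1 - nu^2) * sqrt(R) * delta^(3/2)
# Units: E in GPa, R and delta in nm, F in nN (1 GPa == 1 nN/nm^2, so no
# numeric conversion factor is needed).

#' Construct an AFM force curve
#'
#' @param indentation Indentation depths, nm, non-negative and
#'   non-decreasing (approach segment after contact-point alignment).
#' @param force Forces, nN.
#' @param tip_radius Tip radius, nm; default 50.
#' @param poisson_ratio Sample Poisson ratio; default 0.3.
#' @return Object of class `force_curve`.
#' @export
force_curve <- function(indentation, force, tip_radius = 50,
                        poisson_ratio = 0.3) {
  indentation <- as.numeric(indentation); force <- as.numeric(force)
  if (length(indentation) != length(force)) {
    stop("indentation and force must have equal length")
  }
  if (any(indentation < 0)) stop("indentation must be non-negative")
  if (any(diff(indentation) < 0)) {
    stop("indentation must be non-decreasing on the approach segment")
  }
  .check_positive(tip_radius, "tip_radius")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop("poisson_ratio must be in [0, 0.5)")
  }
  structure(list(indentation = indentation, force = force,
                 tip_radius = tip_radius, poisson_ratio = poisson_ratio),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(paste0("force_curve: %d points, max indentation %.3g nm, ",
                     "max force %.3g nN (R = %g nm, nu = %g)\n"),
              length(x$force), max(x$indentation), max(x$force),
              x$tip_radius, x$poisson_ratio))
  invisible(x)
}

#' Hertzian sphere-on-flat force
#'
#' @param indentation Indentation depth(s), nm, `>= 0`.
#' @param modulus Sample Young's modulus E, GPa.
#' @param tip_radius Tip radius R, nm.
#' @param poisson_ratio Sample Poisson ratio nu.
#' @return Force in nN.
#' @examples
#' hertz_force(3, 2.7, 50, 0.3)
#' @export
hertz_force <- function(indentation, modulus, tip_radius = 50,
                        poisson_ratio = 0.3) {
  if (any(indentation < 0)) stop("indentation must be non-negative")
  .check_positive(modulus, "modulus")
  .check_positive(tip_radius, "tip_radius")
  4 / 3 * modulus / (1 - poisson_ratio^2) * sqrt(tip_radius) *
    indentation^1.5
}

#' Fit the Hertz model to a force curve
#'
#' Nonlinear least squares of `F = (4/3) E/(1-nu^2) sqrt(R) (delta -
#' delta0)^{3/2}` on the segment of the curve between `window[1]` and
#' `window[2]` of the maximum applied force.  The contact-point offset
#' `delta0` is co-fitted by default, bounded to +/- 5 nm; pass
#' `fit_offset = FALSE` to pin it at zero.
#'
#' @param curve A [force_curve()].
#' @param window Force-fraction window; default `c(0.05, 0.50)` (5-50% of
#'   the maximum force).
#' @param fit_offset Co-fit the contact-point offset; default `TRUE`.
#' @param particle_height Optional particle height, nm; a warning is issued
#'   when the fitted window spans more than 10% of it (substrate-affected
#'   thin-sample regime).
#' @return Object of class `hertz_fit`: `youngs_modulus` (GPa),
#'   `contact_point_offset` (nm), `fit_window`, `residual_rms` (nN),
#'   `n_points`.
#' @export
fit_hertz <- function(curve, window = c(0.05, 0.50), fit_offset = TRUE,
                      particle_height = NULL) {
  stopifnot(inherits(curve, "force_curve"), length(window) == 2)
  if (window[1] < 0 || window[2] > 1 || window[1] >= window[2]) {
    stop("window must satisfy 0 <= lo < hi <= 1")
  }
  fmax <- max(curve$force)
  sel <- curve$force >= window[1] * fmax & curve$force <= window[2] * fmax
  if (sum(sel) < 10) stop("fewer than 10 points inside the force window")
  d <- curve$indentation[sel]; f <- curve$force[sel]
  pref <- 4 / 3 * sqrt(curve$tip_radius) / (1 - curve$poisson_ratio^2)
  e0 <- max(stats::median(f / pmax(pref * d^1.5, 1e-12)), 1e-3)
  if (fit_offset) {
    fit <- minpack.lm::nlsLM(
      f ~ pref * E * pmax(d - d0, 0)^1.5,
      start = list(E = e0, d0 = 0),
      lower = c(1e-6, -5), upper = c(Inf, 5),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(
      f ~ pref * E * d^1.5, start = list(E = e0), lower = 1e-6,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  co <- stats::coef(fit)
  E <- unname(co["E"])
  if (!is.finite(E) || E <= 0) stop("Hertz fit failed: non-positive modulus")
  if (!is.null(particle_height) &&
      diff(range(d)) > 0.1 * particle_height) {
    warning("fit window spans more than 10% of the particle height; ",
            "thin-sample (substrate) artifacts likely")
  }
  structure(list(youngs_modulus = E,
                 contact_point_offset = if (fit_offset) unname(co["d0"]) else 0,
                 fit_window = window,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = sum(sel)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(paste0("Hertz fit: E = %.3g GPa, contact offset = %.3g nm, ",
                     "RMS = %.3g nN (%d points, %g-%g%% force window)\n"),
              x$youngs_modulus, x$contact_point_offset, x$residual_rms,
              x$n_points, 100 * x$fit_window[1], 100 * x$fit_window[2]))
  invisible(x)
}

#' Contact-stiffness proxy from the top of a force curve
#'
#' Linear slope of force versus indentation over the top `top_fraction`
#' of the maximum force -- a documented slope-based stand-in for
#' arbitrary-unit intermodulation-AFM stiffness.  For a Hertz curve the
#' slope approaches the analytic contact stiffness `2 E/(1-nu^2)
#' sqrt(R delta_max)`.
#'
#' @param curve A [force_curve()].
#' @param top_fraction Fraction of the maximum force defining the segment;
#'   default 0.2.
#' @return Slope in nN/nm (equivalently N/m).
#' @export
stiffness_proxy <- function(curve, top_fraction = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]")
  }
  sel <- curve$force >= (1 - top_fraction) * max(curve$force)
  if (sum(sel) < 5) stop("fewer than 5 points in the top force fraction")
  unname(stats::coef(stats::lm(curve$force[sel] ~
                                 curve$indentation[sel]))[2])
}

#' Modulus (or stiffness) versus particle height
#'
#' Bins per-particle records by height and reports per-bin mean and SD of
#' the modulus after flagging substrate-affected records: any record with
#' modulus above `substrate_cutoff` or height below `substrate_height` is
#' excluded from the particle statistics.  A linear regression of modulus
#' on height over the particle-only records tests for a size effect.
#'
#' @param height Particle heights, nm.
#' @param modulus Moduli (GPa) or stiffness values, one per record.
#' @param height_bins Bin breaks (nm) or a bin count; default 8 bins.
#' @param substrate_cutoff Modulus above which a record is attributed to
#'   the substrate; default 4 GPa.
#' @param substrate_height Height below which the substrate dominates;
#'   default 15 nm.
#' @return List with `table` (per-bin n, mean, sd), `substrate_affected`
#'   (logical per record), and `size_effect` (slope, t value, p value of
#'   modulus ~ height on particle records).
#' @export
modulus_vs_height <- function(height, modulus, height_bins = 8,
                              substrate_cutoff = 4, substrate_height = 15) {
  stopifnot(length(height) == length(modulus), length(height) >= 1)
  .check_positive(height, "height")
  flag <- modulus > substrate_cutoff | height < substrate_height
  h <- height[!flag]; m <- modulus[!flag]
  if (length(height_bins) == 1) {
    rng <- range(height)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    height_bins <- seq(rng[1], rng[2], length.out = height_bins + 1)
  }
  bin <- cut(h, breaks = height_bins, include.lowest = TRUE)
  tab <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    mean = as.numeric(tapply(m, bin, mean)),
    sd = as.numeric(tapply(m, bin, stats::sd)),
    row.names = NULL)
  size_effect <- list(slope = NA_real_, t_value = NA_real_,
                      p_value = NA_real_)
  if (length(unique(h)) >= 3) {
    sm <- summary(stats::lm(m ~ h))$coefficients
    if (nrow(sm) == 2) {
      size_effect <- list(slope = sm[2, 1], t_value = sm[2, 3],
                          p_value = sm[2, 4])
    }
  }
  list(table = tab, substrate_affected = flag, size_effect = size_effect)
}
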