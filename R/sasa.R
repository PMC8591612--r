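# Solvent-accessible surface area (Shrake-Rupley).

# Deterministic quasi-uniform unit-sphere point set: Fibonacci spiral.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley SASA: each atom is covered with a deterministic
#' quasi-uniform point set (Fibonacci spiral) on a sphere of radius
#' `r_i + probe`; a point is accessible when it lies outside every other
#' atom's probe-expanded sphere (minimum-image convention).  The per-atom
#' area is the accessible fraction times `4 pi (r_i + probe)^2`.
#'
#' @param config A `molecular_configuration`.
#' @param atom_radii Named numeric vector of van der Waals radii (nm) by
#'   element symbol; defaults to [bondi_radii()].
#' @param probe Probe radius, nm; default 0.14 (water).
#' @param n_sphere_points Points per atom; default 960.
#' @param atoms Optional subset of atom indices to report (occlusion still
#'   considers all atoms).
#' @return List with `total` (nm^2) and `per_atom` (nm^2, one entry per
#'   selected atom).
#' @export
solvent_accessible_area <- function(config, atom_radii = bondi_radii(),
                                    probe = 0.14, n_sphere_points = 960,
                                    atoms = NULL) {
  stopifnot(inherits(config, "molecular_configuration"))
  if (probe < 0) stop("probe must be >= 0")
  .check_positive(n_sphere_points, "n_sphere_points")
  if (is.null(atoms)) atoms <- seq_len(nrow(config$coordinates))
  miss <- setdiff(unique(config$element), names(atom_radii))
  if (length(miss)) {
    stop("no van der Waals radius for element(s): ",
         paste(miss, collapse = ", "))
  }
  r <- atom_radii[config$element] + probe
  xyz <- config$coordinates
  box <- config$box
  pts <- .fibonacci_sphere(n_sphere_points)
  per_atom <- numeric(length(atoms))
  for (k in seq_along(atoms)) {
    i <- atoms[k]
    # neighbors able to occlude atom i
    dd <- minimum_image_displacement(
      xyz[rep(i, nrow(xyz)), , drop = FALSE], xyz, box)
    neigh <- which(dd$distance < r[i] + r & seq_len(nrow(xyz)) != i)
    if (!length(neigh)) {
      per_atom[k] <- 4 * pi * r[i]^2
      next
    }
    surf <- pts * r[i]  # points relative to atom i center
    # neighbor centers relative to atom i (minimum image)
    nb <- rbind(dd$displacement)[neigh, , drop = FALSE]
    acc <- rep(TRUE, nrow(surf))
    for (m in seq_len(nrow(nb))) {
      d2 <- (surf[, 1] - nb[m, 1])^2 + (surf[, 2] - nb[m, 2])^2 +
        (surf[, 3] - nb[m, 3])^2
      # a surface point exactly on a neighbor's sphere is owned by the
      # lower-index atom, so fully overlapping atoms count their shared
      # surface once
      tol <- 1e-12
      blocked <- if (neigh[m] < i) d2 < r[neigh[m]]^2 + tol else
        d2 < r[neigh[m]]^2 - tol
      acc <- acc & !blocked
      if (!any(acc)) break
    }
    per_atom[k] <- mean(acc) * 4 * pi * r[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}
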