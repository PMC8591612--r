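# Seeded synthetic-data generators.  Every generator returns the inputs the
# analysis functions consume together with the ground truth used to make
# them, so the whole pipeline is testable without instrument data.  All
# randomness comes from R's default RNG seeded with the `seed` argument;
# the same seed and parameters reproduce identical output.

#' Synthetic absolute-scale SAXS curve
#'
#' Evaluates [model_intensity()] on a q-grid and applies multiplicative
#' Gaussian noise of a stated fractional magnitude (an approximation to
#' counting statistics on absolute-scaled, azimuthally averaged data).
#'
#' @param model A [sphere_lognormal_model()] (its `background` is the flat
#'   background of the synthetic measurement).
#' @param q_grid Scattering-vector grid, 1/Angstrom; default 200
#'   log-spaced points on 0.003-0.3 (a typical laboratory SAXS range at
#'   1 m sample-detector distance).
#' @param noise_fraction SD of the multiplicative noise as a fraction of
#'   the intensity; default 0.01.
#' @param seed Integer RNG seed.
#' @return List with `curve` (a [scattering_curve()], sigma set to the
#'   noise level) and `truth` (the generating model).
#' @export
make_saxs_curve <- function(model, q_grid = NULL, noise_fraction = 0.01,
                            seed = 1) {
  stopifnot(inherits(model, "sphere_lognormal_model"))
  if (is.null(q_grid)) {
    q_grid <- exp(seq(log(0.003), log(0.3), length.out = 200))
  }
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  ideal <- model_intensity(q_grid, model)
  if (noise_fraction > 0) {
    set.seed(seed)
    I <- ideal * (1 + noise_fraction * stats::rnorm(length(q_grid)))
    sigma <- noise_fraction * ideal
  } else {
    I <- ideal
    sigma <- NULL
  }
  list(curve = scattering_curve(q_grid, I, sigma = sigma), truth = model)
}

#' Synthetic Hertzian force-curve set
#'
#' Generates `n_curves` approach curves `F = (4/3) E/(1-nu^2) sqrt(R)
#' delta^{3/2}` with additive Gaussian force noise.  A fraction
#' `substrate_mix` of the curves is replaced by stiff-substrate curves
#' (modulus drawn from `substrate_modulus_range`, heights below the 15 nm
#' substrate regime) to exercise substrate flagging downstream.
#'
#' @param modulus Particle Young's modulus, GPa.
#' @param tip_radius Tip radius, nm; default 50.
#' @param n_curves Number of curves.
#' @param noise Additive force-noise SD as a fraction of each curve's
#'   maximum force; default 0.02.
#' @param substrate_mix Fraction of curves replaced by substrate curves;
#'   default 0.
#' @param max_indentation Maximum indentation, nm; default 3.
#' @param n_points Points per curve; default 200.
#' @param poisson_ratio Poisson ratio; default 0.3.
#' @param height_range Particle-height range, nm; default `c(20, 80)`.
#' @param substrate_modulus_range Substrate modulus range, GPa; default
#'   `c(10, 60)`.
#' @param seed Integer RNG seed.
#' @return List with `curves` (list of [force_curve()]) and `truth` (data
#'   frame: curve, modulus, height, substrate flag).
#' @export
make_force_curves <- function(modulus, tip_radius = 50, n_curves = 100,
                              noise = 0.02, substrate_mix = 0,
                              max_indentation = 3, n_points = 200,
                              poisson_ratio = 0.3,
                              height_range = c(20, 80),
                              substrate_modulus_range = c(10, 60),
                              seed = 1) {
  .check_positive(modulus, "modulus")
  .check_positive(n_curves, "n_curves")
  if (substrate_mix < 0 || substrate_mix > 1) {
    stop("substrate_mix must be in [0, 1]")
  }
  set.seed(seed)
  is_sub <- stats::runif(n_curves) < substrate_mix
  E <- ifelse(is_sub,
              stats::runif(n_curves, substrate_modulus_range[1],
                           substrate_modulus_range[2]),
              modulus)
  height <- ifelse(is_sub,
                   stats::runif(n_curves, 2, 12),
                   stats::runif(n_curves, height_range[1], height_range[2]))
  delta <- seq(0, max_indentation, length.out = n_points)
  curves <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    f <- hertz_force(delta, E[i], tip_radius, poisson_ratio)
    if (noise > 0) f <- f + noise * max(f) * stats::rnorm(n_points)
    curves[[i]] <- force_curve(delta, f, tip_radius, poisson_ratio)
  }
  list(curves = curves,
       truth = data.frame(curve = seq_len(n_curves), modulus = E,
                          height = height, substrate = is_sub))
}

# Idealized rigid molecule templates (nm, arbitrary orientation).  These
# carry realistic bond lengths but no energetics; they exist so that
# H-bond/RDF/SASA code sees plausible atom geometries.
.molecule_templates <- function() {
  water <- list(
    element = c("O", "H", "H"),
    atom_name = c("OW", "HW1", "HW2"),
    xyz = rbind(c(0, 0, 0), c(0.09572, 0, 0),
                c(-0.02399, 0.09268, 0)))
  acetone <- list(
    element = c("C", "O", "C", "C", "H", "H", "H", "H", "H", "H"),
    atom_name = c("C2", "O", "C1", "C3", "H11", "H12", "H13",
                  "H31", "H32", "H33"),
    xyz = rbind(c(0, 0, 0), c(0, 0.122, 0),
                c(0.128, -0.078, 0), c(-0.128, -0.078, 0),
                c(0.205, -0.025, 0.05), c(0.14, -0.18, 0.04),
                c(0.13, -0.09, -0.11),
                c(-0.205, -0.025, 0.05), c(-0.14, -0.18, 0.04),
                c(-0.13, -0.09, -0.11)))
  ring <- function(n, radius) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(radius * cos(th), radius * sin(th), 0)
  }
  thf_ring <- ring(5, 0.120)
  thf <- list(
    element = c("O", "C", "C", "C", "C", rep("H", 8)),
    atom_name = c("O", "C1", "C2", "C3", "C4", paste0("H", 1:8)),
    xyz = rbind(thf_ring,
                thf_ring[rep(2:5, each = 2), ] +
                  cbind(0, 0, rep(c(0.09, -0.09), 4))))
  dxn_ring <- ring(6, 0.140)
  dxn <- list(
    element = c("O", "C", "C", "O", "C", "C", rep("H", 8)),
    atom_name = c("O1", "C2", "C3", "O4", "C5", "C6", paste0("H", 1:8)),
    xyz = rbind(dxn_ring,
                dxn_ring[rep(c(2, 3, 5, 6), each = 2), ] +
                  cbind(0, 0, rep(c(0.09, -0.09), 4))))
  dmso <- list(
    element = c("S", "O", "C", "C", rep("H", 6)),
    atom_name = c("S", "O", "C1", "C2", paste0("H", 1:6)),
    xyz = rbind(c(0, 0, 0), c(0, 0.150, 0),
                c(0.135, -0.090, 0), c(-0.135, -0.090, 0),
                c(0.20, -0.03, 0.06), c(0.15, -0.19, 0.03),
                c(0.14, -0.10, -0.11),
                c(-0.20, -0.03, 0.06), c(-0.15, -0.19, 0.03),
                c(-0.14, -0.10, -0.11)))
  list(water = water, acetone = acetone, thf = thf, dxn = dxn, dmso = dmso)
}

# Uniform random rotation matrix (from a random quaternion).
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Integer molecule counts hitting target weight fractions at a target
# total mass: rounded seed counts refined by a +/-2 local search
# minimizing the summed squared weight-fraction error.
.optimal_counts <- function(fractions, molar_masses, total_mass) {
  n0 <- pmax(round(total_mass * fractions / molar_masses), 1)
  if (length(n0) == 1) return(n0)
  grid <- expand.grid(lapply(n0, function(n) pmax(n + (-2:2), 1)))
  err <- apply(grid, 1, function(n) {
    w <- n * molar_masses / sum(n * molar_masses)
    sum((w - fractions)^2)
  })
  best <- unlist(grid[which.min(err), ])
  stats::setNames(as.numeric(best), names(fractions))
}

#' Synthetic solvent box
#'
#' Builds an orthorhombic box of rigid idealized solvent molecules (water,
#' acetone, THF, DXN, DMSO) at prescribed weight fractions.  Molecule
#' counts are chosen by integer optimization so the realized weight
#' fractions match the request as closely as possible at the target total
#' mass; molecules are then placed uniformly at random with random
#' orientations and no overlap check, so the box has ideal-gas pair
#' statistics by construction.
#'
#' @param fractions Named weight-fraction vector over species in
#'   `c("water", "acetone", "thf", "dxn", "dmso")`; must sum to 1 within
#'   1e-6.
#' @param box Box edge length(s), nm; scalar for a cubic box. Default
#'   5.316 (a typical solvation-box scale for a single 7-unit lignin).
#' @param density Target total mass density, g/cm^3, used to set the total
#'   mass in the box; default 0.85.
#' @param seed Integer RNG seed.
#' @return List with `config` (a `molecular_configuration`) and `truth`
#'   (requested fractions, realized counts and realized fractions).
#' @export
make_solvent_box <- function(fractions, box = 5.316, density = 0.85,
                             seed = 1) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  if (!all(names(fractions) %in% names(.species_molar_mass))) {
    stop("unknown species: ",
         paste(setdiff(names(fractions), names(.species_molar_mass)),
               collapse = ", "))
  }
  if (length(box) == 1) box <- rep(box, 3)
  .check_positive(box, "box")
  tmpl <- .molecule_templates()
  mm <- .species_molar_mass[names(fractions)]
  vol_cm3 <- prod(box) * 1e-21
  total_mass <- density * vol_cm3 * lnp_constants[["N_A"]]  # g/mol in box
  counts <- .optimal_counts(fractions, mm, total_mass)
  n_mol <- sum(counts)
  n_atoms_per <- vapply(tmpl[names(counts)], function(t) length(t$element),
                        integer(1))
  if (n_mol * 3 > 5e5) stop("box too large: more than ~170k molecules")
  set.seed(seed)
  coords <- vector("list", n_mol)
  element <- character(0); atom_name <- character(0)
  molecule_id <- integer(0); molecule_type <- character(0)
  mol <- 0
  for (sp in names(counts)) {
    t <- tmpl[[sp]]
    for (i in seq_len(counts[[sp]])) {
      mol <- mol + 1
      center <- stats::runif(3) * box
      xyz <- t$xyz %*% t(.random_rotation())
      coords[[mol]] <- sweep(xyz, 2, center, "+")
      element <- c(element, t$element)
      atom_name <- c(atom_name, t$atom_name)
      molecule_id <- c(molecule_id, rep(mol, length(t$element)))
      molecule_type <- c(molecule_type, rep(sp, length(t$element)))
    }
  }
  cfg <- molecular_configuration(do.call(rbind, coords), element,
                                 atom_name, molecule_id, molecule_type,
                                 box)
  realized <- box_mass_fractions(counts, mm)
  list(config = cfg,
       truth = list(requested = fractions, counts = counts,
                    realized = realized, total_mass = total_mass))
}

#' Synthetic hydrogen-bond scene
#'
#' Plants `n_bonds` donor-H/acceptor triples strictly inside both
#' geometric cutoffs (10% margin) and `n_decoys` triples violating exactly
#' one criterion each (alternating distance and angle violations, also
#' with 10% margins).  Scenes are laid out on a widely spaced grid so no
#' unintended cross-scene bonds can form; donors are water-like O-H
#' fragments, acceptors lone O atoms.
#'
#' @param n_bonds,n_decoys Non-negative counts.
#' @param criteria An [hbond_criteria()].
#' @param seed Integer RNG seed.
#' @return List with `config`, `truth` (data frame of planted triples with
#'   their kind), and `n_bonds`.
#' @export
make_hbond_scene <- function(n_bonds, n_decoys = 0,
                             criteria = hbond_criteria(), seed = 1) {
  if (n_bonds < 0 || n_decoys < 0) stop("counts must be >= 0")
  n <- n_bonds + n_decoys
  if (n == 0) {
    cfg <- molecular_configuration(rbind(c(0.5, 0.5, 0.5)), "O", "OA",
                                   1L, "acceptor", rep(1, 3))
    return(list(config = cfg,
                truth = data.frame(scene = integer(0), kind = character(0)),
                n_bonds = 0L))
  }
  set.seed(seed)
  spacing <- 4 * criteria$max_da_distance   # no cross-scene contacts
  ncell <- max(ceiling(n^(1 / 3)), 2)
  box <- rep(ncell * spacing, 3)
  cells <- as.matrix(expand.grid(seq_len(ncell), seq_len(ncell),
                                 seq_len(ncell))) - 0.5
  cells <- cells[sample(nrow(cells), n), , drop = FALSE] * spacing
  d_oh <- 0.09572
  coords <- list(); element <- character(0); atom_name <- character(0)
  molecule_id <- integer(0); molecule_type <- character(0)
  truth <- data.frame(scene = seq_len(n),
                      kind = rep(c("bond", "decoy"),
                                 c(n_bonds, n_decoys)))
  mol <- 0
  rand_unit <- function() {
    v <- stats::rnorm(3); v / sqrt(sum(v^2))
  }
  rotate_by_angle <- function(u, alpha) {
    # unit vector at angle alpha from u
    p <- stats::rnorm(3)
    p <- p - sum(p * u) * u
    p <- p / sqrt(sum(p^2))
    cos(alpha) * u + sin(alpha) * p
  }
  for (i in seq_len(n)) {
    center <- cells[i, ]
    u <- rand_unit()                     # donor -> H direction
    kind <- truth$kind[i]
    if (kind == "bond") {
      dist <- criteria$max_da_distance * stats::runif(1, 0.65, 0.9)
      ang <- criteria$max_hda_angle * stats::runif(1, 0, 0.9) * pi / 180
    } else if (i %% 2 == 0) {            # distance violation
      dist <- criteria$max_da_distance * stats::runif(1, 1.1, 1.4)
      ang <- criteria$max_hda_angle * stats::runif(1, 0, 0.9) * pi / 180
    } else {                             # angle violation
      dist <- criteria$max_da_distance * stats::runif(1, 0.65, 0.9)
      ang <- stats::runif(1, criteria$max_hda_angle * 1.1 * pi / 180,
                          pi * 0.9)
    }
    a_dir <- rotate_by_angle(u, ang)
    donor <- center
    hpos <- center + d_oh * u
    acc <- center + dist * a_dir
    mol <- mol + 1
    coords[[length(coords) + 1]] <- rbind(donor, hpos)
    element <- c(element, "O", "H")
    atom_name <- c(atom_name, "OD", "HD")
    molecule_id <- c(molecule_id, mol, mol)
    molecule_type <- c(molecule_type, "donor", "donor")
    mol <- mol + 1
    coords[[length(coords) + 1]] <- rbind(acc)
    element <- c(element, "O")
    atom_name <- c(atom_name, "OA")
    molecule_id <- c(molecule_id, mol)
    molecule_type <- c(molecule_type, "acceptor")
  }
  cfg <- molecular_configuration(do.call(rbind, coords), element,
                                 atom_name, molecule_id, molecule_type,
                                 box)
  list(config = cfg, truth = truth, n_bonds = n_bonds)
}
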