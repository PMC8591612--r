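# Configuration-level structural analyses under periodic boundary
# conditions: minimum-image geometry, geometric hydrogen bonds, radial
# distribution functions and box composition accounting.

#' Minimum-image displacement
#'
#' Displacement `p2 - p1` with each component wrapped into `[-L/2, L/2)`
#' for an orthorhombic box, plus its Euclidean norm.
#'
#' @param p1,p2 Length-3 positions, nm (or N x 3 matrices, paired rows).
#' @param box Orthorhombic box edge lengths, nm.
#' @return List with `displacement` and `distance`.
#' @export
minimum_image_displacement <- function(p1, p2, box) {
  .check_positive(box, "box")
  p1 <- rbind(p1); p2 <- rbind(p2)
  d <- unname(sweep(p2 - p1, 2, box,
                    function(x, L) x - L * floor(x / L + 0.5)))
  dist <- unname(sqrt(rowSums(d^2)))
  if (nrow(d) == 1) d <- drop(d)
  list(displacement = d, distance = dist)
}

# Pairwise minimum-image distance matrix between coordinate sets (nm).
.pbc_dist <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - box[k] * floor(d / box[k] + 0.5)
    out <- out + d^2
  }
  sqrt(out)
}

# Cell-list neighbor candidates: for each point in `a`, indices of points
# in `b` whose minimum-image distance can be below `cutoff`.  Falls back
# to all-pairs when the box is too small for 3 cells per edge.
.cell_pairs <- function(a, b, box, cutoff) {
  ncell <- pmax(1L, floor(box / cutoff))
  if (any(ncell < 3L)) {
    return(cbind(rep(seq_len(nrow(a)), each = nrow(b)),
                 rep(seq_len(nrow(b)), times = nrow(a))))
  }
  key <- function(p) {
    ix <- floor(sweep(p %% rep(box, each = nrow(p)), 2, box / ncell, "/"))
    ix <- pmin(pmax(ix, 0), rep(ncell - 1L, each = nrow(p)))
    ix[, 1] + ncell[1] * (ix[, 2] + ncell[2] * ix[, 3])
  }
  wrap <- function(p) sweep(p, 2, box, function(x, L) x - L * floor(x / L))
  ka <- key(wrap(a)); kb <- key(wrap(b))
  b_by_cell <- split(seq_len(nrow(b)), kb)
  # neighbor cell keys for each cell id
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res_i <- integer(0); res_j <- integer(0)
  cid <- cbind(ka %% ncell[1],
               (ka %/% ncell[1]) %% ncell[2],
               ka %/% (ncell[1] * ncell[2]))
  for (i in seq_len(nrow(a))) {
    neigh <- sweep(offs, 2, cid[i, ], "+") %% rep(ncell, each = 27)
    keys <- unique(neigh[, 1] + ncell[1] * (neigh[, 2] + ncell[2] * neigh[, 3]))
    js <- unlist(b_by_cell[as.character(keys)], use.names = FALSE)
    if (length(js)) {
      res_i <- c(res_i, rep.int(i, length(js)))
      res_j <- c(res_j, js)
    }
  }
  cbind(res_i, res_j)
}

#' Hydrogen-bond geometric criteria
#'
#' @param max_da_distance Donor--acceptor (heavy-atom) distance cutoff, nm;
#'   default 0.35.  The comparison is strict (`<`).
#' @param max_hda_angle Hydrogen--donor--acceptor angle cutoff, degrees
#'   (vertex at the donor heavy atom); default 30, strict.
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 0.35, max_hda_angle = 30) {
  .check_positive(max_da_distance, "max_da_distance")
  if (max_hda_angle <= 0 || max_hda_angle > 180) {
    stop("max_hda_angle must be in (0, 180]")
  }
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle),
            class = "hbond_criteria")
}

# Donor/acceptor auto-selection: donors are N/O heavy atoms with a
# covalently attached H (same molecule, within 0.12 nm); acceptors are all
# N/O atoms.
.hbond_selections <- function(config) {
  heavy <- which(config$element %in% c("N", "O"))
  hyd <- which(config$element == "H")
  donors <- NULL
  if (length(heavy) && length(hyd)) {
    for (d in heavy) {
      same <- hyd[config$molecule_id[hyd] == config$molecule_id[d]]
      if (!length(same)) next
      dd <- minimum_image_displacement(
        config$coordinates[rep(d, length(same)), , drop = FALSE],
        config$coordinates[same, , drop = FALSE], config$box)$distance
      att <- same[dd < 0.12]
      if (length(att)) donors <- rbind(donors, cbind(donor = d, h = att))
    }
  }
  list(donors = donors, acceptors = heavy)
}

#' Find hydrogen bonds by geometric criteria
#'
#' A (donor, H, acceptor) triple is a hydrogen bond iff the minimum-image
#' donor--acceptor heavy-atom distance is strictly below
#' `criteria$max_da_distance` and the H--donor--acceptor angle (vertex at
#' the donor) is strictly below `criteria$max_hda_angle`.  Intra-molecular
#' donor--acceptor pairs are excluded by default.  Candidate pairs come
#' from a cell-list neighbor search (`method = "cell"`); results are
#' identical to the all-pairs search (`method = "brute"`).
#'
#' @param config A `molecular_configuration`.
#' @param criteria An [hbond_criteria()].
#' @param donors Optional 2-column matrix (donor heavy-atom index, attached
#'   H index); auto-detected N/O-H pairs when omitted.
#' @param acceptors Optional acceptor heavy-atom indices; auto-detected N/O
#'   atoms when omitted.
#' @param exclude_intramolecular Drop donor--acceptor pairs within one
#'   molecule; default `TRUE`.
#' @param method `"cell"` (default) or `"brute"`.
#' @return List with `bonds` (data frame donor/h/acceptor/distance/angle)
#'   and `count`.
#' @export
find_hydrogen_bonds <- function(config, criteria = hbond_criteria(),
                                donors = NULL, acceptors = NULL,
                                exclude_intramolecular = TRUE,
                                method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "molecular_configuration"),
            inherits(criteria, "hbond_criteria"))
  if (is.null(donors) || is.null(acceptors)) {
    sel <- .hbond_selections(config)
    if (is.null(donors)) donors <- sel$donors
    if (is.null(acceptors)) acceptors <- sel$acceptors
  }
  empty <- data.frame(donor = integer(0), h = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (is.null(donors) || nrow(donors) == 0 || length(acceptors) == 0) {
    return(list(bonds = empty, count = 0L))
  }
  donors <- as.matrix(donors)
  dh <- minimum_image_displacement(
    config$coordinates[donors[, 1], , drop = FALSE],
    config$coordinates[donors[, 2], , drop = FALSE], config$box)$distance
  if (any(dh > 0.15)) {
    stop("donor without attached hydrogen (D-H distance > 0.15 nm)")
  }
  dc <- config$coordinates[donors[, 1], , drop = FALSE]
  ac <- config$coordinates[acceptors, , drop = FALSE]
  pairs <- if (method == "cell") {
    .cell_pairs(dc, ac, config$box, criteria$max_da_distance)
  } else {
    cbind(rep(seq_len(nrow(dc)), each = length(acceptors)),
          rep(seq_along(acceptors), times = nrow(dc)))
  }
  if (nrow(pairs) == 0) return(list(bonds = empty, count = 0L))
  di <- pairs[, 1]; ai <- pairs[, 2]
  keep <- donors[di, 1] != acceptors[ai]
  if (exclude_intramolecular) {
    keep <- keep & (config$molecule_id[donors[di, 1]] !=
                      config$molecule_id[acceptors[ai]])
  }
  di <- di[keep]; ai <- ai[keep]
  if (!length(di)) return(list(bonds = empty, count = 0L))
  da <- minimum_image_displacement(dc[di, , drop = FALSE],
                                   ac[ai, , drop = FALSE], config$box)
  ok <- da$distance < criteria$max_da_distance
  di <- di[ok]; ai <- ai[ok]; dist <- da$distance[ok]
  if (!length(di)) return(list(bonds = empty, count = 0L))
  # H-D-A angle, vertex at the donor heavy atom
  vh <- minimum_image_displacement(
    config$coordinates[donors[di, 1], , drop = FALSE],
    config$coordinates[donors[di, 2], , drop = FALSE],
    config$box)$displacement
  va <- minimum_image_displacement(
    config$coordinates[donors[di, 1], , drop = FALSE],
    ac[ai, , drop = FALSE], config$box)$displacement
  vh <- rbind(vh); va <- rbind(va)
  cosang <- rowSums(vh * va) /
    (sqrt(rowSums(vh^2)) * sqrt(rowSums(va^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- ang < criteria$max_hda_angle
  bonds <- data.frame(donor = donors[di[ok], 1], h = donors[di[ok], 2],
                      acceptor = acceptors[ai[ok]],
                      distance = dist[ok], angle = ang[ok])
  bonds <- bonds[order(bonds$donor, bonds$acceptor), , drop = FALSE]
  rownames(bonds) <- NULL
  list(bonds = bonds, count = nrow(bonds))
}

#' Per-frame hydrogen-bond counts
#'
#' Applies [find_hydrogen_bonds()] to each frame and aggregates counts by
#' donor-molecule-type / acceptor-molecule-type pair.
#'
#' @param configs List of `molecular_configuration` frames with identical
#'   topology (atom counts, elements, molecule ids).
#' @param criteria An [hbond_criteria()].
#' @param ... Passed to [find_hydrogen_bonds()].
#' @return List with `per_frame` (counts per frame), and `by_class`: a data
#'   frame of donor type, acceptor type, mean and SD of the per-frame
#'   count.
#' @export
hbond_timeseries <- function(configs, criteria = hbond_criteria(), ...) {
  stopifnot(is.list(configs), length(configs) >= 1)
  ref <- configs[[1]]
  cls_counts <- list()
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    if (nrow(cfg$coordinates) != nrow(ref$coordinates) ||
        !identical(cfg$element, ref$element) ||
        !identical(cfg$molecule_id, ref$molecule_id)) {
      stop("topology mismatch at frame ", i)
    }
    hb <- find_hydrogen_bonds(cfg, criteria, ...)
    key <- if (hb$count) {
      paste(cfg$molecule_type[hb$bonds$donor],
            cfg$molecule_type[hb$bonds$acceptor], sep = "->")
    } else character(0)
    cls_counts[[i]] <- table(key)
  }
  all_keys <- sort(unique(unlist(lapply(cls_counts, names))))
  mat <- vapply(cls_counts, function(tb) {
    v <- stats::setNames(numeric(length(all_keys)), all_keys)
    v[names(tb)] <- as.numeric(tb)
    v
  }, numeric(length(all_keys)))
  mat <- matrix(mat, nrow = length(all_keys),
                dimnames = list(all_keys, NULL))
  per_frame <- colSums(mat)
  by_class <- data.frame(
    class = all_keys,
    mean = if (length(all_keys)) rowMeans(mat) else numeric(0),
    sd = if (length(all_keys)) apply(mat, 1, stats::sd) else numeric(0),
    row.names = NULL)
  if (length(configs) == 1) by_class$sd <- 0
  list(per_frame = per_frame, by_class = by_class)
}

#' Radial distribution function specification
#'
#' @param group_a,group_b Integer atom indices of the two groups.
#' @param bin_width Bin width, nm.
#' @param r_max Maximum distance, nm; must not exceed half the smallest box
#'   edge.
#' @return Object of class `rdf_spec`.
#' @export
rdf_spec <- function(group_a, group_b, bin_width = 0.002, r_max) {
  .check_positive(bin_width, "bin_width")
  .check_positive(r_max, "r_max")
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  structure(list(group_a = as.integer(group_a),
                 group_b = as.integer(group_b),
                 bin_width = bin_width, r_max = r_max),
            class = "rdf_spec")
}

#' Radial distribution function
#'
#' `g(r)` between two atom groups over one or more frames: a histogram of
#' minimum-image pair distances normalized by shell volume, the ideal
#' (bulk) density of group b, the size of group a, and the frame count,
#' so `g(r) -> 1` at large r for homogeneous fluids.  When the two groups
#' are identical, self-pairs are excluded and the ideal density uses
#' `N_b - 1`.
#'
#' @param configs A `molecular_configuration` or list of frames.
#' @param spec An [rdf_spec()].
#' @return Data frame with `r` (bin centers, nm) and `g`.
#' @export
radial_distribution <- function(configs, spec) {
  stopifnot(inherits(spec, "rdf_spec"))
  if (inherits(configs, "molecular_configuration")) configs <- list(configs)
  breaks <- seq(0, spec$r_max, by = spec$bin_width)
  if (utils::tail(breaks, 1) < spec$r_max) {
    breaks <- c(breaks, utils::tail(breaks, 1) + spec$bin_width)
  }
  counts <- numeric(length(breaks) - 1)
  same <- identical(sort(spec$group_a), sort(spec$group_b))
  norm <- 0
  for (cfg in configs) {
    if (spec$r_max > min(cfg$box) / 2) {
      stop("r_max exceeds half the smallest box edge")
    }
    a <- cfg$coordinates[spec$group_a, , drop = FALSE]
    b <- cfg$coordinates[spec$group_b, , drop = FALSE]
    d <- .pbc_dist(a, b, cfg$box)
    if (same) {
      d <- d[outer(spec$group_a, spec$group_b, "!=")]
    }
    d <- d[d < spec$r_max & d > 0]
    counts <- counts + graphics::hist(d, breaks = breaks,
                                      plot = FALSE)$counts
    nb_eff <- length(spec$group_b) - if (same) 1 else 0
    rho_b <- nb_eff / prod(cfg$box)
    norm <- norm + length(spec$group_a) * rho_b
  }
  shell <- 4 / 3 * pi * diff(breaks^3)
  g <- counts / (shell * norm)
  data.frame(r = (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2,
             g = g)
}

#' Mass fractions of a solvent box
#'
#' `w_t = n_t M_t / sum(n M)` from molecule counts and molar masses.
#'
#' @param counts Named numeric vector, molecules per species.
#' @param molar_masses Named numeric vector, g/mol; names must cover
#'   `names(counts)`.  Defaults cover water/acetone/thf/dxn/dmso.
#' @return Named numeric vector of weight fractions summing to 1.
#' @examples
#' box_mass_fractions(c(acetone = 954, water = 1031))  # ~75 wt% acetone
#' @export
box_mass_fractions <- function(counts, molar_masses = .species_molar_mass) {
  .check_positive(counts, "counts")
  if (!all(names(counts) %in% names(molar_masses))) {
    stop("missing molar mass for: ",
         paste(setdiff(names(counts), names(molar_masses)), collapse = ", "))
  }
  m <- counts * molar_masses[names(counts)]
  m / sum(m)
}
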