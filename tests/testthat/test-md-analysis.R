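test_that("minimum-image displacement matches 27-image enumeration", {
  box <- c(3, 4, 5)
  p <- c(1, 1, 1)
  expect_equal(minimum_image_displacement(p, p, box)$distance, 0)
  # wrap case on one axis
  r <- minimum_image_displacement(c(0.1, 2, 2), c(2.9, 2, 2), box)
  expect_equal(r$distance, 0.2, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:50) {
    p1 <- runif(3) * box; p2 <- runif(3) * box
    expect_equal(minimum_image_displacement(p1, p2, box)$distance,
                 oracle_pbc_distance(p1, p2, box), tolerance = 1e-12)
  }
})

test_that("constructed donor-acceptor geometries follow both cutoffs", {
  # O-H...O with d(O,O) = 0.29 nm and a 5 degree H-D-A angle: a bond
  build <- function(doo, ang_deg) {
    a <- ang_deg * pi / 180
    coords <- rbind(c(1, 1, 1),
                    c(1 + 0.096, 1, 1),
                    c(1 + doo * cos(a), 1 + doo * sin(a), 1))
    molecular_configuration(coords, c("O", "H", "O"), c("OD", "HD", "OA"),
                            c(1, 1, 2), c("donor", "donor", "acceptor"),
                            rep(4, 3))
  }
  expect_equal(find_hydrogen_bonds(build(0.29, 5))$count, 1)
  expect_equal(find_hydrogen_bonds(build(0.36, 5))$count, 0)
  expect_equal(find_hydrogen_bonds(build(0.29, 35))$count, 0)
  # cutoff values are excluded (strict inequalities)
  expect_equal(find_hydrogen_bonds(build(0.35, 5))$count, 0)
  expect_equal(find_hydrogen_bonds(build(0.29, 30.001))$count, 0)
})

test_that("cell-list hydrogen-bond search equals the independent O(N^2)
           oracle on random boxes", {
  for (seed in 1:5) {
    cfg <- random_hbond_box(n_donors = 120, n_acceptors = 150,
                            box_edge = 2.5, seed = seed)
    hb_cell <- find_hydrogen_bonds(cfg, method = "cell")
    hb_brute <- find_hydrogen_bonds(cfg, method = "brute")
    expect_identical(hb_cell$bonds, hb_brute$bonds)

    sel <- lnptools:::.hbond_selections(cfg)
    oracle <- oracle_hbonds(cfg$coordinates, cfg$box, sel$donors,
                            sel$acceptors, cfg$molecule_id)
    n_oracle <- if (is.null(oracle)) 0L else nrow(oracle)
    expect_equal(hb_cell$count, n_oracle)
    if (n_oracle > 0) {
      o <- oracle[order(oracle[, 1], oracle[, 3]), , drop = FALSE]
      expect_equal(hb_cell$bonds$donor, o[, 1])
      expect_equal(hb_cell$bonds$acceptor, o[, 3])
    }
  }
})

test_that("hydrogen-bond counts are invariant under global translation", {
  cfg <- random_hbond_box(60, 80, 2.0, seed = 7)
  n0 <- find_hydrogen_bonds(cfg)$count
  shifted <- cfg
  shifted$coordinates <- sweep(cfg$coordinates, 2, c(0.37, -1.2, 5.1), "+")
  expect_equal(find_hydrogen_bonds(shifted)$count, n0)
  # box-commensurate shift
  shifted$coordinates <- sweep(cfg$coordinates, 2, cfg$box, "+")
  expect_equal(find_hydrogen_bonds(shifted)$count, n0)
})

test_that("donor without an attached hydrogen is rejected", {
  coords <- rbind(c(1, 1, 1), c(1.5, 1, 1), c(1.2, 1.2, 1))
  cfg <- molecular_configuration(coords, c("O", "H", "O"),
                                 c("O1", "H1", "O2"), c(1, 1, 2),
                                 c("a", "a", "b"), rep(4, 3))
  expect_error(find_hydrogen_bonds(cfg, donors = cbind(1, 2),
                                   acceptors = 3),
               "attached hydrogen")
})

test_that("hbond_timeseries aggregates per frame and is order-invariant", {
  frames <- lapply(1:4, function(s) {
    make_hbond_scene(5, 3, seed = s)$config
  })
  ts <- hbond_timeseries(frames)
  expect_equal(unname(ts$per_frame), rep(5, 4))
  expect_equal(sum(ts$by_class$mean), 5)
  expect_equal(ts$by_class$sd, rep(0, nrow(ts$by_class)))

  ts_perm <- hbond_timeseries(frames[c(3, 1, 4, 2)])
  expect_equal(ts_perm$by_class, ts$by_class)

  # identical frames give SD = 0
  ts_same <- hbond_timeseries(frames[c(1, 1, 1)])
  expect_equal(ts_same$by_class$sd, rep(0, nrow(ts_same$by_class)))

  bad <- frames
  bad[[2]] <- random_hbond_box(3, 3, 2, seed = 1)
  expect_error(hbond_timeseries(bad), "topology mismatch")
})

test_that("ideal-gas RDF is unity within counting bands", {
  set.seed(31)
  n <- 500; box <- rep(4, 3)
  xyz <- matrix(runif(n * 3) * 4, ncol = 3)
  cfg <- molecular_configuration(xyz, rep("C", n), rep("C", n), 1:n,
                                 rep("gas", n), box)
  sp <- rdf_spec(1:n, 1:n, bin_width = 0.1, r_max = 1.9)
  g <- radial_distribution(cfg, sp)
  sel <- g$r > 0.25
  # 3 sigma Poisson band per bin; each unordered pair is counted twice,
  # so sigma_g = sqrt(2 / ordered pairs per bin)
  shell <- 4 / 3 * pi * diff(seq(0, max(g$r) + 0.05, by = 0.1)^3)
  ordered_pairs <- shell[sel] * (n - 1) / prod(box) * n
  band <- 3 * sqrt(2 / ordered_pairs)
  expect_true(all(abs(g$g[sel] - 1) < band))
  expect_equal(mean(g$g[sel]), 1, tolerance = 0.02)
})

test_that("two fixed atoms give a single occupied RDF bin at their
           distance", {
  coords <- rbind(c(1, 1, 1), c(1.71, 1, 1))
  cfg <- molecular_configuration(coords, c("C", "C"), c("C1", "C2"), 1:2,
                                 c("a", "b"), rep(4, 3))
  g <- radial_distribution(cfg, rdf_spec(1, 2, bin_width = 0.05,
                                         r_max = 1.9))
  expect_equal(sum(g$g > 0), 1)
  expect_equal(g$r[g$g > 0], 0.725, tolerance = 0.05)
})

test_that("coordination count is conserved under bin-width changes", {
  set.seed(41)
  n <- 300; box <- rep(3.5, 3)
  cfg <- molecular_configuration(matrix(runif(n * 3) * 3.5, ncol = 3),
                                 rep("C", n), rep("C", n), 1:n,
                                 rep("gas", n), box)
  coord_number <- function(bin) {
    g <- radial_distribution(cfg, rdf_spec(1:n, 1:n, bin_width = bin,
                                           r_max = 1.6))
    rho <- (n - 1) / prod(box)
    sum(rho * g$g * 4 * pi * g$r^2 * bin)
  }
  expect_equal(coord_number(0.02), coord_number(0.04), tolerance = 0.02)
})

test_that("RDF spec validates r_max against the box", {
  cfg <- molecular_configuration(rbind(c(1, 1, 1)), "C", "C", 1, "a",
                                 rep(3, 3))
  expect_error(radial_distribution(cfg, rdf_spec(1, 1, 0.05, r_max = 2)),
               "half")
})

test_that("box mass fractions reproduce the solvation-box accounting", {
  w <- box_mass_fractions(c(acetone = 954, water = 1031))
  expect_equal(round(unname(w["acetone"]), 2), 0.75)
  expect_equal(unname(box_mass_fractions(c(water = 500))), 1)

  mm <- c(lnptools:::.species_molar_mass, l1 = molar_mass("C68H74O22"))
  w3 <- box_mass_fractions(c(l1 = 1, acetone = 954, water = 1031), mm)
  expect_equal(round(unname(w3["l1"]), 3), 0.017, tolerance = 1e-6)
  expect_equal(sum(w3), 1)
  expect_error(box_mass_fractions(c(xenon = 3)), "xenon")
})
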