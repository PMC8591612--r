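test_that("a minimal water GRO round-trips and is typed", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "water in a box",
    "    3",
    "    1SOL     OW    1   1.000   1.200   1.400",
    "    1SOL    HW1    2   1.096   1.200   1.400",
    "    1SOL    HW2    3   0.976   1.293   1.400",
    "   3.00000   3.00000   3.00000"), path)
  cfg <- read_configuration(path)
  expect_s3_class(cfg, "molecular_configuration")
  expect_equal(unique(cfg$molecule_type), "water")
  expect_equal(cfg$element, c("O", "H", "H"))
  expect_equal(cfg$coordinates[1, ], c(1.0, 1.2, 1.4))
  expect_equal(cfg$box, rep(3, 3))

  out <- withr::local_tempfile(fileext = ".gro")
  write_gro(cfg, out)
  cfg2 <- read_gro(out)
  expect_equal(cfg2$coordinates, cfg$coordinates, tolerance = 1e-3)
  expect_equal(cfg2$molecule_type, cfg$molecule_type)
})

test_that("multi-frame GRO concatenations are split into frames", {
  sc <- make_hbond_scene(3, 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(list(sc$config, sc$config), path)
  frames <- read_gro(path)
  expect_length(frames, 2)
  expect_equal(frames[[1]]$molecule_id, sc$config$molecule_id)
})

test_that("generated boxes survive the writer/reader round trip", {
  bx <- make_solvent_box(c(acetone = 0.75, water = 0.25), box = 3,
                         density = 0.4, seed = 5)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(bx$config, path)
  back <- read_gro(path)
  expect_equal(back$coordinates, bx$config$coordinates, tolerance = 1e-3)
  expect_equal(back$molecule_type, bx$config$molecule_type)
  expect_equal(back$element, bx$config$element)
})

test_that("malformed GRO files give parse errors", {
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "2",
               "    1SOL     OW    1   1.000   1.200   1.400"), p)
  expect_error(read_gro(p), "truncated")
  writeLines(c("t", "1",
               "    1SOL     OW    1   1.000   1.200   1.400",
               "  bad box"), p)
  expect_error(read_gro(p), "box")
})

test_that("extended XYZ reads with Lattice box and Angstrom conversion", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "3",
    'Lattice="30.0 0 0 0 30.0 0 0 0 30.0" comment',
    "O  10.0 12.0 14.0",
    "H  10.96 12.0 14.0",
    "H  9.76 12.93 14.0"), p)
  sidecar <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,molecule_type", "1,water", "1,water",
               "1,water"), sidecar)
  cfg <- read_xyz(p, typing_sidecar = sidecar)
  expect_equal(cfg$box, rep(3, 3))
  expect_equal(cfg$coordinates[1, ], c(1.0, 1.2, 1.4))
  expect_equal(cfg$molecule_type, rep("water", 3))
})

test_that("multi-type XYZ without a sidecar is rejected", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "6", "10.0 10.0 10.0",
    "O 1 1 1", "H 1.9 1 1", "H 0.8 1.9 1",
    "O 5 5 5", "H 5.9 5 5", "H 4.8 5.9 5"), p)
  expect_error(read_xyz(p), "sidecar")
})

test_that("scattering ASCII round-trips losslessly to 12 digits", {
  q <- exp(seq(log(0.004), log(0.25), length.out = 40))
  I <- 1.23456789012e-3 / q^4 + 0.017
  sig <- 0.01 * I
  crv <- scattering_curve(q, I, sig, unit = "mm-1")
  p <- withr::local_tempfile(fileext = ".dat")
  write_scattering_ascii(crv, p)
  back <- read_scattering_ascii(p)
  expect_equal(back$q, crv$q, tolerance = 1e-11)
  expect_equal(back$intensity, crv$intensity, tolerance = 1e-11)
  expect_equal(back$sigma, crv$sigma, tolerance = 1e-11)
})

test_that("scattering ASCII parse errors carry line context", {
  p <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# only a header"), p)
  expect_error(read_scattering_ascii(p), "no data")
  writeLines(c("# h", "0.01 2.0", "0.02 oops"), p)
  expect_error(read_scattering_ascii(p), "line 3")
  writeLines(c("0.02 1.0", "0.01 2.0"), p)
  expect_error(read_scattering_ascii(p), "increasing")
})

test_that("curve construction enforces its invariants", {
  expect_error(scattering_curve(c(0.1, 0.1), c(1, 1)), "increasing")
  expect_error(scattering_curve(c(-0.1, 0.2), c(1, 1)), "positive")
  expect_error(scattering_curve(c(0.1, 0.2), c(1, NA)), "finite")
  expect_error(scattering_curve(c(0.1, 0.2), c(1, 1), sigma = c(1, -1)),
               "sigma")
})
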