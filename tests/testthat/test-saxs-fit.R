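test_that("Guinier fit recovers Rg on synthetic dissolved-polymer data", {
  # dissolved Kraft lignin scale: Rg = 1.6 nm (16 Angstrom)
  q <- seq(0.005, 0.25, length.out = 120)
  rg <- 16
  I <- 5e-10 * exp(-rg^2 * q^2 / 3)
  crv <- scattering_curve(q, I)
  gf <- guinier_fit(crv, c(0.005, 1.3 / rg))
  expect_equal(gf$rg, 1.6, tolerance = 1e-6)
  expect_equal(gf$i0, 5e-10, tolerance = 1e-6)
})

test_that("Guinier fit on a monodisperse sphere satisfies Rg^2 = 3/5 R^2", {
  R <- 220
  m <- sphere_lognormal_model(2 * R / 10, 0, 0.005, 3.13e-6)
  sim <- make_saxs_curve(m, noise_fraction = 0, seed = 1)
  rg_true <- sqrt(3 / 5) * R
  gf <- guinier_fit(sim$curve, c(min(sim$curve$q), 0.9 / rg_true))
  expect_equal(gf$rg * 10, rg_true, tolerance = 0.02)
})

test_that("Guinier fit shifts under a flat background and recovers when
           it is pre-subtracted", {
  q <- seq(0.004, 0.08, length.out = 80)
  rg <- 20
  I0 <- 2e-9; bkg <- 2e-10
  crv_bkg <- scattering_curve(q, I0 * exp(-rg^2 * q^2 / 3) + bkg)
  crv_sub <- scattering_curve(q, I0 * exp(-rg^2 * q^2 / 3))
  win <- c(0.004, 1.3 / rg)
  rg_biased <- guinier_fit(crv_bkg, win)$rg * 10
  rg_clean <- guinier_fit(crv_sub, win)$rg * 10
  expect_gt(abs(rg_biased - rg), 0.5)
  expect_equal(rg_clean, rg, tolerance = 1e-6)
})

test_that("Guinier fit validates its window", {
  q <- seq(0.01, 0.2, length.out = 50)
  crv <- scattering_curve(q, exp(-100 * q^2))
  expect_error(guinier_fit(crv, c(0.01, 0.012)), "fewer than 5")
  expect_warning(guinier_fit(crv, c(0.01, 0.2)), "1.3")
})

test_that("Porod fit recovers the analytic sphere constant within 2%", {
  # K_P = 2 pi drho^2 (3 phi / R) for monodisperse spheres
  R <- 220; phi <- 0.005; drho <- 3.13e-6
  m <- sphere_lognormal_model(44, 0, phi, drho)
  sim <- make_saxs_curve(m, noise_fraction = 0, seed = 1)
  pf <- porod_fit(sim$curve, c(0.02, 0.1))
  kp_true <- 2 * pi * drho^2 * 3 * phi / R
  expect_equal(pf$porod_constant, kp_true, tolerance = 0.02)
})

test_that("Porod fit is exact on pure K/q^4 data and rejects noise-only
           curves", {
  q <- seq(0.02, 0.1, length.out = 60)
  K <- 4e-15
  pf <- porod_fit(scattering_curve(q, K / q^4), c(0.02, 0.1))
  expect_equal(pf$porod_constant, K, tolerance = 1e-10)
  expect_equal(pf$flat_background, 0, tolerance = K * 1e-6 / min(q)^4)

  set.seed(3)
  noise <- scattering_curve(q, rnorm(60, 0, 1e-12))
  expect_error(porod_fit(noise, c(0.02, 0.1)), "Porod")
})

test_that("sphere/log-normal fit is an identity on noiseless self-generated
           data", {
  p <- lognormal_from_moments(44, 16)
  truth <- sphere_lognormal_model(p[["median"]], p[["sigma_log"]],
                                  0.005, 3.13e-6, background = 1e-12)
  sim <- make_saxs_curve(truth, noise_fraction = 0, seed = 1)
  init <- truth
  init$median_diameter <- 30; init$sigma_log <- 0.2
  fit <- fit_sphere_lognormal(sim$curve, init = init)
  expect_true(fit$converged)
  expect_equal(fit$model$median_diameter, truth$median_diameter,
               tolerance = 1e-4)
  expect_equal(fit$model$sigma_log, truth$sigma_log, tolerance = 1e-3)
  expect_equal(fit$mean_diameter, 44, tolerance = 1e-4)
  expect_equal(fit$sd_diameter, 16, tolerance = 1e-3)
})

test_that("sphere/log-normal fit recovers LNP-scale sizes from noisy data", {
  p <- lognormal_from_moments(44, 16)
  truth <- sphere_lognormal_model(p[["median"]], p[["sigma_log"]],
                                  0.005, 3.13e-6, background = 1e-12)
  for (seed in 1:2) {
    sim <- make_saxs_curve(truth, noise_fraction = 0.01, seed = seed)
    fit <- fit_sphere_lognormal(sim$curve)
    expect_equal(fit$mean_diameter, 44, tolerance = 0.05)
    expect_equal(fit$sd_diameter, 16, tolerance = 0.05)
  }
})

test_that("fitting a featureless flat curve fails or flags a vanishing
           volume fraction", {
  q <- exp(seq(log(0.003), log(0.3), length.out = 80))
  flat <- scattering_curve(q, rep(2e-9, 80))
  res <- tryCatch(fit_sphere_lognormal(flat), error = function(e) e)
  if (inherits(res, "error")) {
    succeed()
  } else {
    expect_lt(res$model$volume_fraction, 1e-8)
    expect_equal(res$model$background, 2e-9, tolerance = 0.05)
  }
})

test_that("fit input contracts are enforced", {
  q <- seq(0.01, 0.02, length.out = 25)
  crv <- scattering_curve(q, 1e-9 / q^4)
  expect_error(fit_sphere_lognormal(crv), "decade")
  q2 <- exp(seq(log(0.01), log(0.2), length.out = 10))
  expect_error(fit_sphere_lognormal(scattering_curve(q2, 1e-9 / q2^4)),
               "20 points")
})
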