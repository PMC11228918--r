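test_that("scattering vector follows the optical geometry", {
  ins <- instrument_spec(wavelength = 633, scattering_angle = 180,
                         refractive_index = 1.33)
  expect_equal(scattering_vector(ins), 4 * pi * 1.33 / 633, tolerance = 1e-12)
  # q -> 0 as the angle closes
  q_small <- scattering_vector(instrument_spec(scattering_angle = 0.01))
  expect_lt(q_small, 1e-5)
  # doubling the wavelength halves q
  q1 <- scattering_vector(instrument_spec(wavelength = 500))
  q2 <- scattering_vector(instrument_spec(wavelength = 1000))
  expect_equal(q1 / q2, 2, tolerance = 1e-12)
  expect_error(instrument_spec(scattering_angle = 190), "angle")
  expect_error(instrument_spec(wavelength = -1), "wavelength")
})

test_that("cumulant fit inverts a noiseless single exponential exactly", {
  tau <- exp(seq(log(0.5), log(60), length.out = 80))
  y <- 0.8 * exp(-2 * 0.05 * tau)
  fit <- fit_cumulants(correlogram(tau, y))
  expect_equal(fit$gamma, 0.05, tolerance = 1e-10)
  expect_equal(fit$intercept_beta, 0.8, tolerance = 1e-10)
  expect_equal(fit$pdi, 0, tolerance = 1e-8)
})

test_that("restricted window on a bimodal decay yields an intermediate rate", {
  tau <- exp(seq(log(0.5), log(300), length.out = 150))
  y <- 0.4 * exp(-2 * 0.01 * tau) + 0.4 * exp(-2 * 0.1 * tau)
  fit <- fit_cumulants(correlogram(tau, y))
  expect_gt(fit$gamma, 0.01)
  expect_lt(fit$gamma, 0.1)
})

test_that("cumulant fit rejects degenerate inputs", {
  tau <- seq(1, 20, length.out = 20)
  expect_error(fit_cumulants(correlogram(tau, rep(-0.1, 20))),
               "positive|usable")
  expect_error(fit_cumulants(correlogram(tau, 0.8 * exp(-0.1 * tau)),
                             fit_window = c(1, 2)),
               "fewer than 10")
})

test_that("Stokes-Einstein conversion has the right magnitude and scalings", {
  # D_t = 1 um^2/s at 298 K, 1 mPa s -> about 436.6 nm
  ins <- instrument_spec(temperature = 298, viscosity = 1)
  q <- scattering_vector(ins)
  gamma <- 1 * q^2   # D_t = 1 nm^2/us = 1e-12 m^2/s
  expect_equal(diameter_from_gamma(list(gamma = gamma), ins), 436.6,
               tolerance = 1e-3)
  # round trip through gamma_from_diameter
  expect_equal(
    diameter_from_gamma(list(gamma = gamma_from_diameter(400, ins)), ins),
    400, tolerance = 1e-10)
  # strictly decreasing in gamma
  d1 <- diameter_from_gamma(list(gamma = 0.01), ins)
  d2 <- diameter_from_gamma(list(gamma = 0.02), ins)
  expect_gt(d1, d2)
  # at fixed measured decay rate, doubling viscosity halves the inferred
  # diameter (D_h = kB T / (3 pi eta D_t) with D_t fixed by Gamma)
  ins2 <- instrument_spec(temperature = 298, viscosity = 2)
  expect_equal(diameter_from_gamma(list(gamma = 0.01), ins2) / d1, 0.5,
               tolerance = 1e-12)
  expect_error(diameter_from_gamma(list(gamma = -1), ins), "positive")
})

test_that("generated correlograms round-trip and recover under noise", {
  # exact inversion without noise or polydispersity
  cg <- gen_correlogram(400, pdi = 0, sigma = 0)
  expect_equal(size_correlogram(cg)$diameter_nm, 400, tolerance = 1e-8)
  # planted polydispersity recovered at low noise
  cgp <- gen_correlogram(400, pdi = 0.2, sigma = 1e-4, seed = 3)
  expect_equal(size_correlogram(cgp)$pdi, 0.2, tolerance = 0.2)
  # recovery study at the stated noise level (reduced-size version)
  errs <- vapply(1:30, function(i) {
    set.seed(i)
    d <- stats::runif(1, 100, 2000)
    cg <- gen_correlogram(d, pdi = stats::runif(1, 0, 0.2),
                          sigma = 1e-3, seed = i)
    abs(size_correlogram(cg)$diameter_nm - d) / d
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  # determinism under a fixed seed
  a <- gen_correlogram(400, pdi = 0.1, sigma = 1e-3, seed = 7)
  b <- gen_correlogram(400, pdi = 0.1, sigma = 1e-3, seed = 7)
  expect_identical(a$g2_minus_1, b$g2_minus_1)
})

test_that("correlogram CSV round-trips through read_correlogram", {
  cg <- gen_correlogram(250, sigma = 1e-3, seed = 2)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(lag_us = cg$lags, g2_minus_1 = cg$g2_minus_1),
                   f, row.names = FALSE)
  back <- read_correlogram(f, cg$instrument)
  expect_equal(back$lags, cg$lags, tolerance = 1e-12)
  expect_equal(back$g2_minus_1, cg$g2_minus_1, tolerance = 1e-12)
})
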