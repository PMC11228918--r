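cons <- molecular_constants(0.169)

test_that("cluster occupancy follows the solute-dense-sphere formula", {
  expect_equal(nsmc(0, cons), 0)
  # the sphere holding exactly one molecule
  d1 <- (6 * 0.169 / pi)^(1 / 3)
  expect_equal(nsmc(d1, cons), 1, tolerance = 1e-12)
  expect_equal(d1, 0.686, tolerance = 1e-3)
  # independent arithmetic at the experimental cluster scale
  expect_equal(nsmc(400, cons), (pi / 6) * 400^3 / 0.169, tolerance = 1e-12)
  expect_equal(nsmc(400, cons) / 1.98e8, 1, tolerance = 0.01)
  # cubic scaling
  expect_equal(nsmc(2 * 37.3, cons), 8 * nsmc(37.3, cons), tolerance = 1e-12)
  expect_error(nsmc(-1, cons), "non-negative")
})

test_that("NSMC rates are forward differences at interval midpoints", {
  sol <- solution_spec("x", 1.05, 1)
  # constant diameters give zero rates
  s0 <- size_series(sol, 0:5, rep(300, 6))
  expect_equal(nsmc_rate(s0, cons)$rate_per_h, rep(0, 5))
  # hand-computed two-point rate: occupancies 1 and 1001 one hour apart
  d_a <- (6 * 1 * 0.169 / pi)^(1 / 3)
  d_b <- (6 * 1001 * 0.169 / pi)^(1 / 3)
  s2 <- size_series(sol, c(0, 1), c(d_a, d_b))
  r <- nsmc_rate(s2, cons)
  expect_equal(r$rate_per_h, 1000, tolerance = 1e-9)
  expect_equal(r$time_h, 0.5)
  # linear-in-NSMC series gives a constant rate equal to the slope
  tt <- seq(1, 10)
  slope <- 5e4
  dd <- (6 * (1e6 + slope * tt) * 0.169 / pi)^(1 / 3)
  s3 <- size_series(sol, tt, dd)
  expect_equal(nsmc_rate(s3, cons)$rate_per_h, rep(slope, 9),
               tolerance = 1e-9)
  # telescoping conservation on an arbitrary series
  set.seed(1)
  dd2 <- 100 + cumsum(stats::runif(12, 0, 30))
  s4 <- size_series(sol, seq(2, 46, by = 4), dd2)
  r4 <- nsmc_rate(s4, cons)
  expect_equal(sum(r4$rate_per_h * diff(s4$times)),
               nsmc(dd2[12], cons) - nsmc(dd2[1], cons), tolerance = 1e-9)
})

test_that("growth integrator matches the closed-form solutions", {
  for (reg in c("diffusion", "interface_transfer")) {
    rate <- if (reg == "diffusion") 2e4 else 180
    s <- gen_growth_series(reg, rate = rate, d0 = 50, sigma = 0)
    cf <- growth_closed_form(reg, rate, 50, s$times)
    expect_lt(max(abs(s$diameters - cf) / cf), 1e-6)
  }
})

test_that("noiseless growth series are classified by their true mechanism", {
  s_int <- gen_growth_series("interface_transfer", sigma = 0)
  r_int <- regime_statistics(s_int, cons)
  expect_identical(r_int$classification, "interface_transfer")
  # small residual from the finite-difference discretization only
  expect_lt(abs(r_int$trend_int), 5e-3)
  expect_gt(r_int$trend_diff, 0.5)

  s_dif <- gen_growth_series("diffusion", sigma = 0)
  r_dif <- regime_statistics(s_dif, cons)
  expect_identical(r_dif$classification, "diffusion")
  expect_lt(abs(r_dif$trend_diff), 5e-3)
  expect_lt(r_dif$trend_int, -0.5)
})

test_that("a constant-size series is indeterminate", {
  sol <- solution_spec("x", 1.05, 1)
  s <- size_series(sol, 1:6, rep(200, 6))
  r <- regime_statistics(s, cons)
  expect_identical(r$classification, "indeterminate")
  expect_equal(r$ratios$q_diff, rep(0, 5))
})

test_that("growth generator is deterministic under a fixed seed", {
  a <- gen_growth_series("diffusion", sigma = 0.02, seed = 11)
  b <- gen_growth_series("diffusion", sigma = 0.02, seed = 11)
  expect_identical(a$diameters, b$diameters)
})

test_that("saturation normalization labels the solution state", {
  expect_equal(as.numeric(normalize_saturation(solution_spec("m", 2, 2))), 1)
  expect_identical(attr(normalize_saturation(solution_spec("m", 1, 2)),
                        "state"), "undersaturated")
  expect_identical(attr(normalize_saturation(solution_spec("m", 3, 2)),
                        "state"), "supersaturated")
  expect_error(solution_spec("m", 1, 0), "positive")
})

test_that("size interpolation in S is exact, order-free and flags extrapolation", {
  pts <- data.frame(S = c(1.0, 1.1), D_s = c(100, 200))
  expect_equal(interpolate_size(pts, 1.05)$D_s, 150)
  expect_equal(interpolate_size(pts, 1.1)$D_s, 200)
  # hand-computed value for the packaged ethyl acetate bracket
  etac <- data.frame(S = c(1.02, 1.07), D_s = c(1439, 2807))
  expect_equal(interpolate_size(etac, 1.05)$D_s, 2259.8, tolerance = 1e-9)
  # exact on affine data, invariant to point ordering
  aff <- data.frame(S = c(1.4, 1.1, 1.3, 1.2), D_s = 1000 * c(1.4, 1.1, 1.3, 1.2) - 500)
  expect_equal(interpolate_size(aff, 1.27)$D_s, 1000 * 1.27 - 500,
               tolerance = 1e-12)
  expect_equal(interpolate_size(aff[c(3, 1, 4, 2), ], 1.27)$D_s,
               interpolate_size(aff, 1.27)$D_s)
  # extrapolation warns and flags
  expect_warning(res <- interpolate_size(pts, 1.2), "extrapolation")
  expect_true(res$extrapolated)
  expect_equal(res$D_s, 300)
  expect_error(interpolate_size(data.frame(S = c(1, 1), D_s = c(1, 2)), 1),
               "duplicate")
})

test_that("size-series CSV reader splits conditions and orders times", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(solvent = rep(c("methanol", "methanol"), each = 3),
                   temperature_K = 298.15,
                   x_mol_L = rep(c(1.0, 1.1), each = 3),
                   x_star_mol_L = 1.045,
                   time_h = c(3, 1, 2, 1, 2, 3),
                   diameter_nm = c(130, 110, 120, 210, 220, 230))
  utils::write.csv(df, f, row.names = FALSE)
  ss <- read_size_series(f)
  expect_length(ss, 2)
  s1 <- ss[[which(vapply(ss, function(s) s$solution$x, 1) == 1.0)]]
  expect_equal(s1$times, c(1, 2, 3))
  expect_equal(s1$diameters, c(110, 120, 130))
})
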