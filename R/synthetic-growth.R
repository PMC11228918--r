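#' Simulate a cluster-growth size series with known kinetics
#'
#' Integrates the growth law dN/dt = a r (diffusion-limited) or
#' dN/dt = b r^2 (interface-transfer-limited), with N the cluster occupancy
#' and r the cluster radius linked through the solute-dense-sphere relation
#' N = (pi/6) D^3 / v, using an adaptive ODE solver (lsoda, relative
#' tolerance 1e-8). The sampled diameters receive multiplicative Gaussian
#' noise D (1 + sigma Z). Both laws also admit closed forms
#' (r^2 = r0^2 + a v t / (2 pi); r = r0 + b v t / (4 pi)) which the test
#' suite uses as an independent oracle.
#'
#' Defaults emulate the study conditions: growth from 50 nm towards the
#' several-hundred-nm scale over 72 h sampled every 3 h, with 2% diameter
#' noise.
#'
#' @param regime "diffusion" or "interface_transfer".
#' @param rate Rate constant: molecules/(h nm) for diffusion (default 2e4),
#'   molecules/(h nm^2) for interface transfer (default 180).
#' @param d0 Initial diameter, nm (default 50).
#' @param times Sampling times, h (default seq(3, 72, by = 3)).
#' @param sigma Noise level as a fraction of D (default 0.02).
#' @param seed Integer RNG seed (required when sigma > 0).
#' @param constants A [molecular_constants()]; defaults to the salicylamide
#'   molecular volume.
#' @param solution A [solution_spec()] attached to the series (default: a
#'   generic supersaturated condition).
#' @return A [size_series()] with attribute `truth` holding the generator
#'   parameters and the noiseless diameters.
#' @export
gen_growth_series <- function(regime = c("diffusion", "interface_transfer"),
                              rate = NULL, d0 = 50,
                              times = seq(3, 72, by = 3),
                              sigma = 0.02, seed = 1,
                              constants = molecular_constants(0.169),
                              solution = solution_spec("synthetic", 1.05, 1)) {
  regime <- match.arg(regime)
  if (is.null(rate)) rate <- if (regime == "diffusion") 2e4 else 180
  stopifnot(rate > 0, d0 > 0, sigma >= 0, all(times > 0))
  v <- constants$molecular_volume
  n0 <- nsmc(d0, constants)
  deriv <- if (regime == "diffusion") {
    function(t, y, p) {
      r <- (3 * y[1] * v / (4 * pi))^(1 / 3)
      list(rate * r)
    }
  } else {
    function(t, y, p) {
      r <- (3 * y[1] * v / (4 * pi))^(1 / 3)
      list(rate * r^2)
    }
  }
  sol <- deSolve::ode(y = c(N = n0), times = c(0, times), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-6)
  d_true <- diameter_from_nsmc(sol[-1, "N"], constants)
  if (sigma > 0) {
    set.seed(seed)
    d_obs <- d_true * (1 + sigma * stats::rnorm(length(d_true)))
  } else {
    d_obs <- d_true
  }
  out <- size_series(solution, times, d_obs)
  attr(out, "truth") <- list(regime = regime, rate = rate, d0 = d0,
                             sigma = sigma, seed = seed,
                             diameters_true = d_true)
  out
}

#' Closed-form radius for the synthetic growth laws
#'
#' The analytic solution of the two growth ODEs, used as an independent
#' check of the numerical integrator.
#'
#' @inheritParams gen_growth_series
#' @param t Times, h.
#' @return Diameter(s) in nm.
#' @export
growth_closed_form <- function(regime = c("diffusion", "interface_transfer"),
                               rate, d0, t,
                               constants = molecular_constants(0.169)) {
  regime <- match.arg(regime)
  v <- constants$molecular_volume
  r0 <- d0 / 2
  r <- if (regime == "diffusion") {
    sqrt(r0^2 + rate * v * t / (2 * pi))
  } else {
    r0 + rate * v * t / (4 * pi)
  }
  2 * r
}

#' Simulate a DLS correlogram with known ground truth
#'
#' g2 - 1 = beta exp(-2 Gamma tau + mu2 tau^2) on a geometric lag grid
#' covering the decay, with Gamma derived from the target diameter through
#' the Stokes-Einstein relation and mu2 = pdi Gamma^2; additive Gaussian
#' noise of standard deviation `sigma`.
#'
#' @param true_diameter Target solvodynamic diameter, nm.
#' @param instrument An [instrument_spec()].
#' @param pdi Planted polydispersity index (default 0).
#' @param sigma Additive noise SD on g2 - 1 (default 0).
#' @param seed Integer RNG seed.
#' @param beta Intercept (coherence factor), default 0.8.
#' @param n_lags Number of lag points (default 200).
#' @return A [correlogram()] with attribute `truth` (diameter, gamma, pdi,
#'   beta, sigma, seed).
#' @export
gen_correlogram <- function(true_diameter, instrument = instrument_spec(),
                            pdi = 0, sigma = 0, seed = 1, beta = 0.8,
                            n_lags = 200) {
  stopifnot(true_diameter > 0, pdi >= 0, sigma >= 0)
  gamma <- gamma_from_diameter(true_diameter, instrument)
  mu2 <- pdi * gamma^2
  lags <- exp(seq(log(0.005 / gamma), log(1.5 / gamma),
                  length.out = n_lags))
  y <- beta * exp(-2 * gamma * lags + mu2 * lags^2)
  if (sigma > 0) {
    set.seed(seed)
    y <- y + sigma * stats::rnorm(n_lags)
  }
  out <- correlogram(lags, y, instrument)
  attr(out, "truth") <- list(diameter = true_diameter, gamma = gamma,
                             pdi = pdi, beta = beta, sigma = sigma,
                             seed = seed)
  out
}
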