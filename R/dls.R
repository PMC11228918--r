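#' Instrument specification for dynamic light scattering
#'
#' Describes the optical geometry and solution conditions of a DLS
#' measurement. The defaults correspond to a typical backscatter instrument
#' (633 nm laser, 173 degree detection); the refractive index, temperature
#' and viscosity are solution properties and must be supplied per solvent.
#'
#' @param wavelength Laser wavelength in vacuo, nm.
#' @param scattering_angle Detection angle, degrees, in (0, 180].
#' @param refractive_index Solution refractive index (dimensionless).
#' @param temperature Absolute temperature, K.
#' @param viscosity Solution dynamic viscosity, mPa s (= cP).
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(wavelength = 633, scattering_angle = 173,
                            refractive_index = 1.33, temperature = 298.15,
                            viscosity = 1.0) {
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be a positive number of nm", call. = FALSE)
  if (!is.numeric(scattering_angle) || scattering_angle <= 0 ||
      scattering_angle > 180)
    stop("scattering_angle must lie in (0, 180] degrees", call. = FALSE)
  if (!is.numeric(refractive_index) || refractive_index <= 0)
    stop("refractive_index must be positive", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive (K)", call. = FALSE)
  if (!is.numeric(viscosity) || viscosity <= 0)
    stop("viscosity must be positive (mPa s)", call. = FALSE)
  structure(list(wavelength = wavelength,
                 scattering_angle = scattering_angle,
                 refractive_index = refractive_index,
                 temperature = temperature,
                 viscosity = viscosity),
            class = "instrument_spec")
}

#' Intensity autocorrelation record
#'
#' Holds a normalized intensity correlation function g2(tau) - 1 on a grid of
#' positive, strictly increasing lag times, together with the instrument it
#' was recorded on.
#'
#' @param lags Lag times, microseconds; strictly increasing, all positive.
#' @param g2_minus_1 Normalized intensity correlation minus its baseline;
#'   finite values, same length as `lags`. At least 10 points are required.
#' @param instrument An [instrument_spec()].
#' @return An object of class `correlogram`.
#' @export
correlogram <- function(lags, g2_minus_1, instrument = instrument_spec()) {
  stopifnot(inherits(instrument, "instrument_spec"))
  lags <- as.numeric(lags); g2_minus_1 <- as.numeric(g2_minus_1)
  if (length(lags) < 10)
    stop("a correlogram needs at least 10 lag points", call. = FALSE)
  if (length(lags) != length(g2_minus_1))
    stop("lags and g2_minus_1 must have equal length", call. = FALSE)
  if (any(!is.finite(lags)) || any(lags <= 0) || any(diff(lags) <= 0))
    stop("lags must be finite, positive and strictly increasing", call. = FALSE)
  if (any(!is.finite(g2_minus_1)))
    stop("g2_minus_1 values must be finite", call. = FALSE)
  structure(list(lags = lags, g2_minus_1 = g2_minus_1,
                 instrument = instrument),
            class = "correlogram")
}

#' Read a correlogram from CSV
#'
#' Expects columns `lag_us` and `g2_minus_1`.
#'
#' @param path CSV file path.
#' @param instrument An [instrument_spec()] for the measurement.
#' @return A `correlogram`.
#' @export
read_correlogram <- function(path, instrument = instrument_spec()) {
  df <- utils::read.csv(path)
  if (!all(c("lag_us", "g2_minus_1") %in% names(df)))
    stop("correlogram CSV must have columns lag_us, g2_minus_1", call. = FALSE)
  correlogram(df$lag_us, df$g2_minus_1, instrument)
}

#' Scattering vector magnitude
#'
#' q = 4 pi n sin(theta/2) / lambda, the magnitude of the scattering
#' wavevector probed by the instrument.
#'
#' @param instrument An [instrument_spec()].
#' @return q in 1/nm.
#' @export
scattering_vector <- function(instrument) {
  stopifnot(inherits(instrument, "instrument_spec"))
  theta <- instrument$scattering_angle * pi / 180
  4 * pi * instrument$refractive_index * sin(theta / 2) / instrument$wavelength
}

#' Second-order cumulant fit of a correlogram
#'
#' Fits ln(g2 - 1) = ln beta - 2 Gamma tau + mu2 tau^2 by weighted least
#' squares with weights (g2 - 1)^2, the standard stabilization of the
#' log-linearized cumulant expansion. The default fit window keeps lags where
#' g2 - 1 >= 0.1 * beta0 (beta0 estimated from the head of the decay), which
#' avoids the noise-dominated tail.
#'
#' A negative fitted second cumulant (possible under noise) is truncated to
#' zero, so the polydispersity index PDI = mu2 / Gamma^2 is always
#' non-negative.
#'
#' @param corr A [correlogram()].
#' @param fit_window Optional numeric length-2 vector of lag bounds
#'   (microseconds) overriding the default window.
#' @return An object of class `cumulant_fit` with fields `intercept_beta`,
#'   `gamma` (1/us), `mu2` ((1/us)^2), `pdi`, and `fit_window`.
#' @export
fit_cumulants <- function(corr, fit_window = NULL) {
  stopifnot(inherits(corr, "correlogram"))
  tau <- corr$lags; y <- corr$g2_minus_1
  if (is.null(fit_window)) {
    beta0 <- max(y)
    keep <- y >= 0.1 * beta0
  } else {
    stopifnot(is.numeric(fit_window), length(fit_window) == 2)
    keep <- tau >= fit_window[1] & tau <= fit_window[2]
  }
  keep <- keep & y > 0
  if (sum(keep) < 10)
    stop("fit window contains fewer than 10 usable points; ",
         "the correlogram head must be positive over at least 10 lags",
         call. = FALSE)
  tt <- tau[keep]; yy <- y[keep]
  fit <- stats::lm(log(yy) ~ tt + I(tt^2), weights = yy^2)
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)))
    stop("ill-conditioned cumulant fit: window too short or degenerate",
         call. = FALSE)
  gamma <- -cf[[2]] / 2
  if (!is.finite(gamma) || gamma <= 0)
    stop("cumulant fit produced a non-positive decay rate; ",
         "correlogram does not decay over the fit window", call. = FALSE)
  mu2 <- max(cf[[3]], 0)
  structure(list(intercept_beta = exp(cf[[1]]),
                 gamma = gamma,
                 mu2 = mu2,
                 pdi = mu2 / gamma^2,
                 fit_window = range(tt)),
            class = "cumulant_fit")
}

#' Solvodynamic diameter from a cumulant decay rate
#'
#' Converts the mean decay rate Gamma into a translational diffusion
#' coefficient D_t = Gamma / q^2 and then into the solvodynamic
#' (hydrodynamic) diameter via the Stokes-Einstein relation
#' D_h = kB T / (3 pi eta D_t).
#'
#' @param fit A `cumulant_fit` (or any list with a positive `gamma` in 1/us).
#' @param instrument The [instrument_spec()] used for the measurement.
#' @return Diameter in nm.
#' @export
diameter_from_gamma <- function(fit, instrument) {
  gamma <- fit$gamma
  if (!is.numeric(gamma) || gamma <= 0)
    stop("gamma must be positive", call. = FALSE)
  q <- scattering_vector(instrument)          # 1/nm
  dt_si <- gamma / q^2 * 1e-12                # nm^2/us -> m^2/s
  eta <- instrument$viscosity * 1e-3          # mPa s -> Pa s
  dh_m <- prenuc_constants$kB * instrument$temperature / (3 * pi * eta * dt_si)
  dh_m * 1e9
}

#' Cumulant decay rate corresponding to a diameter
#'
#' Inverse of [diameter_from_gamma()]: the Gamma (1/us) that a particle of
#' the given solvodynamic diameter produces on the given instrument. Used by
#' the correlogram generator and for round-trip checks.
#'
#' @param diameter_nm Solvodynamic diameter, nm.
#' @param instrument An [instrument_spec()].
#' @return Decay rate Gamma in 1/us.
#' @export
gamma_from_diameter <- function(diameter_nm, instrument) {
  stopifnot(is.numeric(diameter_nm), diameter_nm > 0)
  q <- scattering_vector(instrument)
  eta <- instrument$viscosity * 1e-3
  dt_si <- prenuc_constants$kB * instrument$temperature /
    (3 * pi * eta * diameter_nm * 1e-9)       # m^2/s
  dt_si * 1e12 * q^2                          # -> nm^2/us * (1/nm)^2 = 1/us
}

#' Size a correlogram end to end
#'
#' Convenience wrapper: cumulant fit followed by Stokes-Einstein conversion.
#'
#' @inheritParams fit_cumulants
#' @return A one-row data.frame with columns `gamma_per_us`, `pdi`, `beta`,
#'   `diameter_nm`.
#' @export
size_correlogram <- function(corr, fit_window = NULL) {
  fit <- fit_cumulants(corr, fit_window)
  data.frame(gamma_per_us = fit$gamma,
             pdi = fit$pdi,
             beta = fit$intercept_beta,
             diameter_nm = diameter_from_gamma(fit, corr$instrument))
}
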