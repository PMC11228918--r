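#' Classical nucleation theory parameter set
#'
#' @param gamma Crystal-solution interfacial energy, mJ/m^2.
#' @param molar_volume Solute molar volume, m^3/mol.
#' @param temperature Absolute temperature, K.
#' @param gas_constant Gas constant, J/(mol K); 8.314 by convention.
#' @return An object of class `cnt_parameters`.
#' @export
cnt_parameters <- function(gamma, molar_volume, temperature = 298.15,
                           gas_constant = prenuc_constants$R_gas) {
  if (!is.numeric(gamma) || gamma <= 0)
    stop("gamma must be positive (mJ/m^2)", call. = FALSE)
  if (!is.numeric(molar_volume) || molar_volume <= 0)
    stop("molar_volume must be positive (m^3/mol)", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive (K)", call. = FALSE)
  structure(list(gamma = gamma, molar_volume = molar_volume,
                 temperature = temperature, gas_constant = gas_constant),
            class = "cnt_parameters")
}

#' Thermodynamic driving force for nucleation
#'
#' RT ln S, the chemical-potential difference per mole between solution at
#' saturation ratio S and at equilibrium. Negative for undersaturated
#' solutions.
#'
#' @param S Degree of saturation x / x_star; must be positive. Vectorized.
#' @param temperature Absolute temperature, K.
#' @param gas_constant Gas constant, J/(mol K).
#' @return Driving force in J/mol.
#' @export
driving_force <- function(S, temperature = 298.15,
                          gas_constant = prenuc_constants$R_gas) {
  if (any(!is.finite(S)) || any(S <= 0))
    stop("S must be positive", call. = FALSE)
  gas_constant * temperature * log(S)
}

#' Critical nucleus diameter (Gibbs-Thomson)
#'
#' D_c = 4 gamma v_m / (R T ln S), the diameter above which a nucleus grows
#' rather than redissolves. Defined only for S > 1. Unit handling: gamma is
#' supplied in mJ/m^2 and converted to J/m^2; the result is converted from m
#' to nm.
#'
#' @param params A [cnt_parameters()].
#' @param S Degree of saturation; must exceed 1. Vectorized.
#' @return Critical diameter in nm.
#' @export
critical_diameter <- function(params, S) {
  stopifnot(inherits(params, "cnt_parameters"))
  if (any(!is.finite(S)) || any(S <= 1))
    stop("critical diameter is defined only for S > 1", call. = FALSE)
  df <- driving_force(S, params$temperature, params$gas_constant)  # J/mol
  dc_m <- 4 * (params$gamma * 1e-3) * params$molar_volume / df
  dc_m * 1e9
}

#' Ordinary least-squares line and Pearson correlation
#'
#' Descriptive linear association between two short numeric sequences (the
#' per-solvent correlation plots relate only three points, so no inferential
#' statistics are attached).
#'
#' @param xs,ys Equal-length numeric vectors, length >= 2; `xs` must not be
#'   constant.
#' @return A list with `slope`, `intercept` and `r`.
#' @export
linear_correlation <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) != length(ys) || length(xs) < 2)
    stop("xs and ys must have equal length >= 2", call. = FALSE)
  if (stats::sd(xs) == 0) stop("xs is constant; slope undefined", call. = FALSE)
  cf <- stats::lsfit(xs, ys)$coefficients
  r <- if (stats::sd(ys) == 0) 0 else stats::cor(xs, ys)
  list(slope = cf[[2]], intercept = cf[[1]], r = r)
}
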