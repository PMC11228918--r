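#' Solution condition for one clustering experiment
#'
#' @param solvent Solvent label.
#' @param x Solute concentration, mol/L.
#' @param x_star Solubility at the working temperature, mol/L.
#' @param temperature Absolute temperature, K.
#' @return An object of class `solution_spec` carrying the derived degree of
#'   saturation `S = x / x_star`.
#' @export
solution_spec <- function(solvent, x, x_star, temperature = 298.15) {
  if (!is.numeric(x) || x <= 0) stop("x must be positive", call. = FALSE)
  if (!is.numeric(x_star) || x_star <= 0)
    stop("x_star (solubility) must be positive", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  structure(list(solvent = as.character(solvent), x = x, x_star = x_star,
                 temperature = temperature, S = x / x_star),
            class = "solution_spec")
}

#' Degree of saturation of a solution
#'
#' S = x / x_star; S < 1 is undersaturated, S = 1 saturated, S > 1
#' supersaturated.
#'
#' @param solution A [solution_spec()].
#' @return S (dimensionless), with attribute `state` giving the label.
#' @export
normalize_saturation <- function(solution) {
  stopifnot(inherits(solution, "solution_spec"))
  s <- solution$x / solution$x_star
  state <- if (s < 1) "undersaturated" else if (s > 1) "supersaturated"
           else "saturated"
  structure(s, state = state)
}

#' Time series of solvodynamic diameters for one condition
#'
#' @param solution A [solution_spec()].
#' @param times Measurement times, hours; strictly increasing, length >= 2.
#' @param diameters Solvodynamic diameters, nm; all positive.
#' @param sd Optional per-point standard deviations, nm.
#' @return An object of class `size_series`.
#' @export
size_series <- function(solution, times, diameters, sd = NULL) {
  stopifnot(inherits(solution, "solution_spec"))
  times <- as.numeric(times); diameters <- as.numeric(diameters)
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  if (length(times) != length(diameters))
    stop("times and diameters must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("diameters must be finite and positive", call. = FALSE)
  if (!is.null(sd) && length(sd) != length(times))
    stop("sd must match the number of time points", call. = FALSE)
  structure(list(solution = solution, times = times, diameters = diameters,
                 sd = sd),
            class = "size_series")
}

#' Read size-series conditions from CSV
#'
#' Expects columns `solvent, temperature_K, x_mol_L, x_star_mol_L, time_h,
#' diameter_nm` and optionally `sd_nm`; one [size_series()] is built per
#' unique (solvent, x) condition.
#'
#' @param path CSV file path.
#' @return A list of `size_series`.
#' @export
read_size_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("solvent", "temperature_K", "x_mol_L", "x_star_mol_L",
            "time_h", "diameter_nm")
  if (!all(need %in% names(df)))
    stop("size-series CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- interaction(df$solvent, df$x_mol_L, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), ]
    sol <- solution_spec(d$solvent[1], d$x_mol_L[1], d$x_star_mol_L[1],
                         d$temperature_K[1])
    size_series(sol, d$time_h, d$diameter_nm,
                sd = if ("sd_nm" %in% names(d)) d$sd_nm else NULL)
  })
}

#' Number of solute molecules per cluster (NSMC)
#'
#' Occupancy of a solute-dense sphere of solvodynamic diameter D:
#' NSMC = (pi/6) D^3 / v, with v the solute molecular volume.
#'
#' @param diameter Diameter(s), nm; non-negative.
#' @param constants A [molecular_constants()] (or any list with
#'   `molecular_volume` in nm^3).
#' @return Number of molecules (dimensionless), vectorized over `diameter`.
#' @export
nsmc <- function(diameter, constants) {
  if (any(!is.finite(diameter)) || any(diameter < 0))
    stop("diameter must be non-negative and finite", call. = FALSE)
  (pi / 6) * diameter^3 / constants$molecular_volume
}

#' Diameter of a cluster holding a given NSMC
#'
#' Inverse of [nsmc()].
#'
#' @param n Number of molecules, non-negative.
#' @inheritParams nsmc
#' @return Diameter in nm.
#' @export
diameter_from_nsmc <- function(n, constants) {
  stopifnot(all(n >= 0))
  (6 * n * constants$molecular_volume / pi)^(1 / 3)
}

#' Rate of NSMC increase by forward differences
#'
#' Simple difference calculation: forward differences of NSMC over
#' consecutive measurements divided by the time step, reported at interval
#' midpoints.
#'
#' @param series A [size_series()].
#' @param constants A [molecular_constants()].
#' @return A data.frame with columns `time_h` (interval midpoints) and
#'   `rate_per_h` (molecules/h), n - 1 rows.
#' @export
nsmc_rate <- function(series, constants) {
  stopifnot(inherits(series, "size_series"))
  t <- series$times
  if (any(diff(t) == 0)) stop("duplicate time stamps", call. = FALSE)
  n <- nsmc(series$diameters, constants)
  data.frame(time_h = (t[-1] + t[-length(t)]) / 2,
             rate_per_h = diff(n) / diff(t))
}

normalized_trend <- function(t, q) {
  m <- mean(q)
  if (!is.finite(m) || m == 0) return(NA_real_)
  sl <- stats::lsfit(t, q)$coefficients[[2]]
  sl * (max(t) - min(t)) / m
}

#' Diagnose the rate-limiting cluster-growth mechanism
#'
#' Diffusion-limited attachment makes the NSMC growth rate proportional to
#' the cluster radius, so rate / r is constant in time; interface-transfer
#' control makes the rate proportional to the surface area, so rate / r^2 is
#' constant. Both ratio series are formed at interval midpoints (radius
#' linearly interpolated), each is summarized by a normalized trend (OLS
#' slope times the time span divided by the series mean), and the mechanism
#' whose ratio is flatter is reported. If both trends exceed `threshold` in
#' magnitude, or their magnitudes differ by less than `margin`, the result is
#' `indeterminate`.
#'
#' @param series A [size_series()] with at least 4 points.
#' @param constants A [molecular_constants()].
#' @param threshold Maximum |normalized trend| accepted as "flat" (default
#'   0.6).
#' @param margin Minimum difference between the two |trends| needed to call a
#'   winner (default 0.1).
#' @return An object of class `regime_result`: data.frame `ratios` (midpoint
#'   time, q_diff, q_int), scalars `trend_diff`, `trend_int`, and
#'   `classification` in {"diffusion", "interface_transfer", "indeterminate"}.
#' @export
regime_statistics <- function(series, constants, threshold = 0.6,
                              margin = 0.1) {
  stopifnot(inherits(series, "size_series"))
  if (length(series$times) < 4)
    stop("need at least 4 time points for a regime diagnostic", call. = FALSE)
  rate <- nsmc_rate(series, constants)
  if (any(!is.finite(rate$rate_per_h))) stop("NaN in rate series", call. = FALSE)
  r <- series$diameters / 2
  r_mid <- (r[-1] + r[-length(r)]) / 2
  q_diff <- rate$rate_per_h / r_mid
  q_int  <- rate$rate_per_h / r_mid^2
  trend_diff <- normalized_trend(rate$time_h, q_diff)
  trend_int  <- normalized_trend(rate$time_h, q_int)
  classification <- if (is.na(trend_diff) || is.na(trend_int)) {
    "indeterminate"
  } else if (abs(trend_diff) > threshold && abs(trend_int) > threshold) {
    "indeterminate"
  } else if (abs(abs(trend_diff) - abs(trend_int)) < margin) {
    "indeterminate"
  } else if (abs(trend_diff) < abs(trend_int)) {
    "diffusion"
  } else {
    "interface_transfer"
  }
  structure(list(ratios = data.frame(time_h = rate$time_h,
                                     q_diff = q_diff, q_int = q_int),
                 trend_diff = trend_diff, trend_int = trend_int,
                 threshold = threshold, margin = margin,
                 classification = classification),
            class = "regime_result")
}

#' Piecewise-linear interpolation of cluster size versus saturation
#'
#' Interpolates measured solvodynamic diameters D_s linearly in the degree of
#' saturation S. Targets outside the supplied range are linearly extrapolated
#' from the nearest segment and flagged.
#'
#' @param points A data.frame (or 2-column matrix) with columns `S` and `D_s`
#'   (any order-insensitive point set; duplicate S values are an error).
#' @param target_S Saturation at which to evaluate.
#' @return A list with `D_s` (nm) and logical `extrapolated`.
#' @export
interpolate_size <- function(points, target_S) {
  points <- as.data.frame(points)
  if (!all(c("S", "D_s") %in% names(points)))
    stop("points must have columns S and D_s", call. = FALSE)
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  o <- order(points$S)
  s <- points$S[o]; d <- points$D_s[o]
  if (any(duplicated(s))) stop("duplicate S values", call. = FALSE)
  extrap <- target_S < s[1] || target_S > s[length(s)]
  if (extrap) {
    i <- if (target_S < s[1]) 1:2 else (length(s) - 1):length(s)
    slope <- (d[i[2]] - d[i[1]]) / (s[i[2]] - s[i[1]])
    val <- d[i[1]] + slope * (target_S - s[i[1]])
    warning("target S outside supplied range; linear extrapolation used",
            call. = FALSE)
  } else {
    val <- stats::approx(s, d, xout = target_S)$y
  }
  list(D_s = val, extrapolated = extrap)
}
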