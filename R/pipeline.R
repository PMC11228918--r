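#' Read and validate a study configuration
#'
#' YAML (or JSON) configuration describing a full clustering study:
#' \preformatted{
#' molar_volume: 1.01853e-4        # m^3/mol
#' molecular_volume: 0.169         # nm^3/molecule
#' temperature: 298.15             # K
#' target_S: 1.05
#' regime_threshold: 0.6
#' regime_margin: 0.1
#' solvents:                       # one entry per solvent
#'   - solvent: methanol
#'     gamma_mJ_m2: 3.97
#'     x_star_mol_L: 1.045
#'     driving_force_2000s_J_mol: 1619   # optional
#'     g_solv_pb_kJ_mol: -22.11          # optional
#'     carbonyl_peak_cm1: 1707           # optional
#' series_files:                   # size-series CSVs (see read_size_series)
#'   - sizes_methanol.csv
#' }
#' Relative paths are resolved against the config file's directory.
#'
#' @param path Config file path (.yaml/.yml/.json).
#' @return A validated `study_config` list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg$molar_volume <- cfg$molar_volume %||% 1.01853e-4
  cfg$molecular_volume <- cfg$molecular_volume %||% 0.169
  cfg$temperature <- cfg$temperature %||% 298.15
  cfg$target_S <- cfg$target_S %||% 1.05
  cfg$regime_threshold <- cfg$regime_threshold %||% 0.6
  cfg$regime_margin <- cfg$regime_margin %||% 0.1
  if (is.null(cfg$solvents) || !length(cfg$solvents))
    stop("config must list at least one solvent", call. = FALSE)
  cfg$solvents <- if (is.data.frame(cfg$solvents)) cfg$solvents
                  else do.call(rbind, lapply(cfg$solvents, as.data.frame))
  need <- c("solvent", "gamma_mJ_m2", "x_star_mol_L")
  miss <- setdiff(need, names(cfg$solvents))
  if (length(miss))
    stop("solvent entries missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  base <- dirname(path)
  cfg$series_files <- vapply(cfg$series_files %||% character(0),
                             function(f) {
    p <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(p)) stop("series file not found: ", f, call. = FALSE)
    p
  }, character(1))
  structure(cfg, class = "study_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the clustering-to-nucleation pipeline
#'
#' Orchestrates the full analysis for one study configuration: reads every
#' size series, computes cluster occupancies, growth rates and the growth
#' regime per condition; assembles a per-solvent table of supersaturation,
#' measured 72 h cluster size and recomputed critical nucleus diameter;
#' interpolates cluster size to the target supersaturation and pairs it with
#' the critical nucleus size there; and reports the descriptive linear
#' correlations among cluster size, driving force, interfacial energy,
#' critical size, solvation free energy and IR carbonyl shift. All tables
#' carry a `provenance` column separating measured pass-through values from
#' computed ones. Results are written as CSV when `out_dir` is given; a
#' structured log (thresholds, file names) goes to standard error.
#'
#' @param config A `study_config` from [read_study_config()], or a list with
#'   the same fields.
#' @param out_dir Optional output directory; created if missing.
#' @return A list of data.frames: `conditions` (per-condition regime
#'   diagnostics), `table_supersat` (per measured supersaturation),
#'   `table_target` (at the target S) and `correlations`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  solv <- config$solvents
  cons <- molecular_constants(config$molecular_volume, config$molar_volume)
  msg <- function(...) message("[prenuc] ", ...)
  msg("temperature = ", config$temperature, " K; target S = ",
      config$target_S, "; regime threshold = ", config$regime_threshold,
      ", margin = ", config$regime_margin)

  # --- per-condition series analysis -------------------------------------
  series <- unlist(lapply(config$series_files, read_size_series),
                   recursive = FALSE)
  conditions <- NULL
  cond_rows <- lapply(series, function(s) {
    sv <- s$solution$solvent
    if (!sv %in% solv$solvent)
      stop("no solubility entry for solvent: ", sv, call. = FALSE)
    reg <- regime_statistics(s, cons, threshold = config$regime_threshold,
                             margin = config$regime_margin)
    last <- length(s$times)
    data.frame(solvent = sv, x_mol_L = s$solution$x,
               S = s$solution$S,
               time_last_h = s$times[last],
               D_s_last_nm = s$diameters[last],
               nsmc_last = nsmc(s$diameters[last], cons),
               trend_diff = reg$trend_diff, trend_int = reg$trend_int,
               regime = reg$classification,
               provenance = "computed")
  })
  if (length(cond_rows)) conditions <- do.call(rbind, cond_rows)

  # --- supersaturation table (measured D_s + computed D_c) ---------------
  make_dc <- function(solvent, S) {
    g <- solv$gamma_mJ_m2[solv$solvent == solvent]
    critical_diameter(cnt_parameters(g, config$molar_volume,
                                     config$temperature), S)
  }
  sup <- NULL
  if (!is.null(conditions)) {
    sup <- conditions[conditions$S > 1,
                      c("solvent", "S", "D_s_last_nm")]
    names(sup)[3] <- "D_s_nm"
    sup$provenance_D_s <- "measured"
  } else if (!is.null(config$conditions)) {
    sup <- as.data.frame(config$conditions)
    names(sup)[names(sup) == "D_s_72h_nm"] <- "D_s_nm"
    sup$provenance_D_s <- "measured"
    sup <- sup[sup$S > 1, c("solvent", "S", "D_s_nm", "provenance_D_s")]
  }
  if (!is.null(sup) && nrow(sup)) {
    sup$driving_force_J_mol <- driving_force(sup$S, config$temperature)
    sup$D_c_nm <- mapply(make_dc, sup$solvent, sup$S)
    sup$provenance_D_c <- "computed"
  }

  # --- target-S table ----------------------------------------------------
  tgt <- NULL
  if (!is.null(sup) && nrow(sup)) {
    tgt <- do.call(rbind, lapply(unique(sup$solvent), function(sv) {
      pts <- sup[sup$solvent == sv, ]
      ds <- if (nrow(pts) >= 2)
        suppressWarnings(interpolate_size(
          data.frame(S = pts$S, D_s = pts$D_s_nm), config$target_S))
      else list(D_s = NA_real_, extrapolated = NA)
      data.frame(solvent = sv, S = config$target_S,
                 D_s_nm = ds$D_s,
                 extrapolated = ds$extrapolated,
                 provenance_D_s = "interpolated from measured",
                 D_c_nm = make_dc(sv, config$target_S),
                 provenance_D_c = "computed")
    }))
  }

  # --- correlation summary ----------------------------------------------
  correlations <- NULL
  if (!is.null(tgt) && nrow(tgt) >= 2) {
    j <- merge(tgt, solv, by = "solvent")
    pairs <- list(
      c("driving_force_2000s_J_mol", "D_s_nm"),
      c("gamma_mJ_m2", "D_s_nm"),
      c("D_c_nm", "D_s_nm"),
      c("g_solv_pb_kJ_mol", "gamma_mJ_m2"),
      c("carbonyl_peak_cm1", "gamma_mJ_m2"))
    rows <- lapply(pairs, function(p) {
      if (!all(p %in% names(j)) || anyNA(j[, p]) ||
          stats::sd(j[[p[1]]]) == 0) return(NULL)
      lc <- linear_correlation(j[[p[1]]], j[[p[2]]])
      data.frame(x = p[1], y = p[2], slope = lc$slope,
                 intercept = lc$intercept, r = lc$r, n = nrow(j))
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) correlations <- do.call(rbind, rows)
  }

  out <- list(conditions = conditions, table_supersat = sup,
              table_target = tgt, correlations = correlations)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) if (!is.null(out[[nm]])) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(out[[nm]], f, row.names = FALSE)
      msg("wrote ", f)
    }
  }
  out
}

#' Reproduce the packaged clustering-and-nucleation tables
#'
#' Recomputes every critical-nucleus-diameter cell of the packaged study
#' tables from the printed inputs (per-solvent interfacial energy, the
#' molar volume 1.01853e-4 m^3/mol, T = 298.15 K and the stated
#' supersaturations). Measured cluster sizes are echoed as data with
#' `provenance = "measured"` and are never recomputed.
#'
#' @param out_dir Optional directory to write `table_supersat.csv` and
#'   `table_target.csv`.
#' @param target_S Comparison supersaturation (default 1.05).
#' @param temperature Temperature used in the critical-diameter cells, K
#'   (default 298.15).
#' @return A list with data.frames `table_supersat` (six measured
#'   supersaturations) and `table_target` (three solvents at `target_S`).
#' @export
reproduce_tables <- function(out_dir = NULL, target_S = 1.05,
                             temperature = 298.15) {
  solv <- salicylamide_solvents()
  cond <- salicylamide_conditions()
  mv <- salicylamide_constants()$molar_volume
  dc <- function(sv, S)
    critical_diameter(cnt_parameters(solv$gamma_mJ_m2[solv$solvent == sv],
                                     mv, temperature), S)
  t3 <- data.frame(
    solvent = cond$solvent,
    driving_force_2000s_J_mol = solv$driving_force_2000s_J_mol[
      match(cond$solvent, solv$solvent)],
    gamma_mJ_m2 = solv$gamma_mJ_m2[match(cond$solvent, solv$solvent)],
    S = cond$S,
    D_s_72h_nm = cond$D_s_72h_nm,
    provenance_D_s = "measured",
    D_c_nm = mapply(dc, cond$solvent, cond$S),
    provenance_D_c = "computed")
  s105 <- salicylamide_sizes_s105()
  t4 <- data.frame(
    solvent = s105$solvent,
    S = target_S,
    D_s_72h_nm = s105$D_s_72h_nm,
    provenance_D_s = "measured",
    D_c_nm = mapply(dc, s105$solvent, target_S),
    provenance_D_c = "computed")
  out <- list(table_supersat = t3, table_target = t4)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(t3, file.path(out_dir, "table_supersat.csv"),
                     row.names = FALSE)
    utils::write.csv(t4, file.path(out_dir, "table_target.csv"),
                     row.names = FALSE)
  }
  out
}
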