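#' Read sorption isotherm data from CSV
#'
#' Expects columns `temperature_c`, `emc_percent` and exactly one of `aw`
#' (fraction) or `rh_percent` (converted via /100). Rows are grouped by
#' temperature into [sorption_dataset()] objects.
#'
#' @param path Path to a CSV file.
#' @return List of `sorption_dataset` objects, one per temperature.
#' @export
read_sorption_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_c", "emc_percent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_parse(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  has_aw <- "aw" %in% names(df)
  has_rh <- "rh_percent" %in% names(df)
  if (has_aw == has_rh)
    abort_parse("need exactly one of columns `aw` or `rh_percent`")
  aw <- if (has_aw) df$aw else df$rh_percent / 100
  bad <- which(!is.finite(aw) | aw < 0 | aw >= 1)
  if (length(bad))
    abort_parse(sprintf("water activity out of [0, 1) at row(s): %s",
                        paste(bad, collapse = ", ")))
  dup <- which(duplicated(data.frame(df$temperature_c, aw)))
  if (length(dup))
    abort_parse(sprintf("duplicate (temperature, aw) at row(s): %s",
                        paste(dup, collapse = ", ")))
  lapply(split(seq_len(nrow(df)), df$temperature_c), function(idx) {
    sorption_dataset(df$temperature_c[idx[1]], aw[idx], df$emc_percent[idx],
                     label = sprintf("%g degC", df$temperature_c[idx[1]]))
  })
}

#' Write sorption datasets to CSV
#'
#' @param datasets List of [sorption_dataset()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sorption_csv <- function(datasets, path) {
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(temperature_c = d$temperature_c, aw = d$aw,
               emc_percent = d$emc_percent)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read moisture-uptake kinetic series from CSV
#'
#' Expects columns `temperature_c`, `rh_percent`, `time_h` and either
#' `mgr_percent` or raw `mass_g`. With `mass_g`, the moisture gain rate is
#' computed against the mass at the earliest time of each (temperature, RH)
#' condition using [compute_mgr()] and the supplied skin mass fraction.
#'
#' @param path Path to a CSV file.
#' @param mfs Skin mass fraction, required when the file carries `mass_g`.
#' @return List of [kinetic_series()] objects, one per condition.
#' @export
read_kinetics_csv <- function(path, mfs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_c", "rh_percent", "time_h")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_parse(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  has_mgr <- "mgr_percent" %in% names(df)
  has_mass <- "mass_g" %in% names(df)
  if (!has_mgr && !has_mass)
    abort_parse("need column `mgr_percent` or `mass_g`")
  if (!has_mgr && is.null(mfs))
    abort_parse("`mfs` is required to convert raw masses to moisture gain")
  key <- interaction(df$temperature_c, df$rh_percent, drop = TRUE)
  lapply(split(seq_len(nrow(df)), key), function(idx) {
    idx <- idx[order(df$time_h[idx])]
    mgr <- if (has_mgr) df$mgr_percent[idx] else {
      m0 <- df$mass_g[idx[1]]
      compute_mgr(m0, df$mass_g[idx], mfs)
    }
    kinetic_series(df$time_h[idx], mgr, df$temperature_c[idx[1]],
                   df$rh_percent[idx[1]])
  })
}

#' Write kinetic series to CSV
#'
#' @param series List of [kinetic_series()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(temperature_c = s$temperature_c, rh_percent = s$rh_percent,
               time_h = s$time_h, mgr_percent = s$mgr_percent)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Run the full sorption analysis pipeline
#'
#' Sequences the stages of the capsule stability analysis: (1) fit all five
#' isotherm models at each temperature and select the best by R2/RSS; (2)
#' fit all four kinetic models to each uptake series and select the best;
#' (3) with at least two temperatures, run the differential thermodynamic
#' chain on the selected isotherms: isosteric heat / differential entropy
#' grid, Gibbs free energy curves, spreading pressure from per-temperature
#' GAB constants, harmonic mean temperature and the enthalpy-entropy
#' compensation fit. With fewer than two temperatures the thermodynamic
#' stage is skipped with a warning.
#'
#' @param config Either a [study_config()] (inputs are simulated) or a list
#'   with elements `sorption` (list of [sorption_dataset()]) and optionally
#'   `kinetics` (list of [kinetic_series()]); may also carry `seed`.
#' @param emc_grid,aw_range,n_grid Passed to [isosteric_analysis()].
#' @param seed Fitting seed (default: config seed, else 1).
#' @return An object of class `analysis_report`; see [report_json()].
#' @export
run_pipeline <- function(config, emc_grid = NULL, aw_range = c(0.43, 0.92),
                         n_grid = 20, seed = NULL) {
  if (inherits(config, "study_config")) {
    sorption <- simulate_isotherm_study(config)
    kinetics <- simulate_kinetics(config)
    if (is.null(seed)) seed <- config$seed
  } else if (is.list(config) && !is.null(config$sorption)) {
    sorption <- config$sorption
    kinetics <- config$kinetics
    if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1
  } else {
    abort_config("`config` must be a study_config or a list with $sorption")
  }
  if (is.null(seed)) seed <- 1

  temp_labels <- vapply(sorption, function(d) sprintf("%g", d$temperature_c),
                        character(1))
  isotherm_fits <- stats::setNames(
    lapply(sorption, fit_all_isotherms, seed = seed), temp_labels)
  selected <- vapply(isotherm_fits, select_best, character(1))

  kinetic_fits <- NULL
  kinetic_selected <- NULL
  if (!is.null(kinetics) && length(kinetics)) {
    klab <- vapply(kinetics, function(s)
      sprintf("%g degC / %g%% RH", s$temperature_c, s$rh_percent), character(1))
    kinetic_fits <- stats::setNames(
      lapply(kinetics, fit_all_kinetics, seed = seed), klab)
    kinetic_selected <- vapply(kinetic_fits, select_best, character(1))
  }

  thermo <- NULL
  if (length(sorption) >= 2) {
    temps_k <- vapply(sorption, `[[`, numeric(1), "temperature_k")
    best_fits <- stats::setNames(
      Map(function(fl, m) fl[[m]], isotherm_fits, selected),
      sprintf("%g", temps_k))
    points <- isosteric_analysis(best_fits, emc_grid = emc_grid,
                                 aw_range = aw_range, n_grid = n_grid)
    comp <- compensation_fit(points, temps_k)
    gibbs <- lapply(seq_along(temps_k), function(j) {
      aw <- points[[sprintf("aw_%g", temps_k[j])]]
      data.frame(temperature_k = temps_k[j],
                 emc_percent = points$emc_percent, aw = aw,
                 dg = gibbs_free_energy(temps_k[j], aw))
    })
    spread <- lapply(seq_along(sorption), function(j) {
      gabfit <- isotherm_fits[[j]][["GAB"]]
      k <- gabfit$params[["k"]]
      aw <- seq(0, min(0.95, 1 / k - 1e-6), length.out = 40)
      data.frame(temperature_k = temps_k[j], aw = aw,
                 phi = spreading_pressure(gabfit, temps_k[j], aw))
    })
    thermo <- list(points = points, compensation = comp,
                   gibbs_curves = do.call(rbind, gibbs),
                   spreading_pressure_curves = do.call(rbind, spread))
  } else {
    warning("fewer than 2 temperatures: thermodynamic stage skipped")
  }

  structure(list(
    isotherm_fits = isotherm_fits, selected_models = selected,
    kinetic_fits = kinetic_fits, kinetic_selected = kinetic_selected,
    thermo = thermo,
    provenance = list(seed = seed,
                      n_temperatures = length(sorption),
                      aw_range = aw_range, n_grid = n_grid,
                      package_version = as.character(utils::packageVersion("hygrosorb")))),
    class = "analysis_report")
}

#' Serialize an analysis report to JSON
#'
#' Produces a stable JSON rendering of a pipeline report (fits, selected
#' models, thermodynamic block, provenance). Re-serializing the same report
#' yields the identical string, so reports can be diffed across runs.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Optional file to write to.
#' @return The JSON string (invisibly if `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  fit_block <- function(f) list(model = f$model, params = as.list(f$params),
                                r2 = f$r2, rss = f$rss, n_points = f$n_points,
                                converged = f$converged)
  x <- list(
    isotherm_fits = lapply(report$isotherm_fits,
                           function(fl) lapply(fl, fit_block)),
    selected_models = as.list(report$selected_models),
    kinetic_fits = if (!is.null(report$kinetic_fits))
      lapply(report$kinetic_fits, function(fl) lapply(fl, fit_block)),
    kinetic_selected = as.list(report$kinetic_selected),
    thermo = if (!is.null(report$thermo)) list(
      points = as.data.frame(report$thermo$points),
      compensation = unclass(report$thermo$compensation),
      gibbs_curves = report$thermo$gibbs_curves,
      spreading_pressure_curves = report$thermo$spreading_pressure_curves),
    provenance = report$provenance)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<sorption analysis report>\n")
  cat("selected isotherm models:\n")
  for (nm in names(x$selected_models))
    cat(sprintf("  %s degC: %s\n", nm, x$selected_models[[nm]]))
  if (!is.null(x$kinetic_selected)) {
    cat("selected kinetic models:\n")
    for (nm in names(x$kinetic_selected))
      cat(sprintf("  %s: %s\n", nm, x$kinetic_selected[[nm]]))
  }
  if (!is.null(x$thermo)) print(x$thermo$compensation)
  invisible(x)
}
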