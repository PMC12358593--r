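#' Configuration of a synthetic sorption study
#'
#' Describes a simulated saturated-salt-solution sorption study: a set of
#' storage temperatures, the salts providing the humidity ladder, per
#' temperature ground-truth isotherms, per temperature first-order kinetic
#' truths at 68\% RH, and Gaussian measurement noise. Raw capsule
#' measurements are not publicly deposited for this system, so the generator
#' is the package's reference input source for end-to-end runs and tests.
#'
#' Default truths are the fitted isotherms of the capsule study: Smith
#' (a = -8.05, b = -17.01) at 25 degC, Smith (a = -2.63, b = -7.98) at 37
#' degC, and at 32 degC a GAB curve with k = 0.89, c = 13.17 and a
#' *synthetic* capacity x0 = 3.0 chosen so the 32 degC curve lies on the
#' same EMC scale as its neighbours (the experimentally printed x0 is on an
#' incommensurate scale and is not used for simulation). Default kinetic
#' truths are the fitted first-order pairs (a, b) = (8.48, 2.05), (7.95,
#' 1.84) and (7.13, 2.40) at 25/32/37 degC and 68\% RH.
#'
#' @param temperatures_c Storage temperatures in degC (default 25, 32, 37).
#' @param salts Salts providing the humidity ladder (default the six-salt
#'   ladder of [salt_rh_table()]).
#' @param isotherm_truth Named list (names = temperatures as character) of
#'   [isotherm_params()] truths.
#' @param kinetic_truth Named list of first-order truth vectors `c(a=, b=)`.
#' @param kinetic_rh_percent RH of the kinetic runs (default 68).
#' @param noise_sd_emc Gaussian noise SD on EMC, in \% units (default 0.5).
#' @param noise_sd_mgr Gaussian noise SD on Mgr, in \% units (default 0.2).
#' @param noise_model `"additive"` (homoscedastic, default) or
#'   `"proportional"` (SD = noise_sd * |true value|).
#' @param replicate_count Replicates per condition (default 3); reported
#'   values are replicate means.
#' @param seed Mandatory RNG seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(temperatures_c = c(25, 32, 37),
                         salts = unique(salt_rh_table()$salt),
                         isotherm_truth = default_isotherm_truth(),
                         kinetic_truth = default_kinetic_truth(),
                         kinetic_rh_percent = 68,
                         noise_sd_emc = 0.5, noise_sd_mgr = 0.2,
                         noise_model = c("additive", "proportional"),
                         replicate_count = 3, seed) {
  if (missing(seed)) abort_validation("`seed` is mandatory in study_config")
  noise_model <- match.arg(noise_model)
  if (noise_sd_emc < 0 || noise_sd_mgr < 0)
    abort_validation("noise SDs must be non-negative")
  if (replicate_count < 1) abort_validation("replicate_count must be >= 1")
  missing_iso <- setdiff(as.character(temperatures_c), names(isotherm_truth))
  if (length(missing_iso))
    abort_config(sprintf("no isotherm truth for temperature(s) %s",
                         paste(missing_iso, collapse = ", ")))
  structure(list(temperatures_c = temperatures_c, salts = salts,
                 isotherm_truth = isotherm_truth,
                 kinetic_truth = kinetic_truth,
                 kinetic_rh_percent = kinetic_rh_percent,
                 noise_sd_emc = noise_sd_emc, noise_sd_mgr = noise_sd_mgr,
                 noise_model = noise_model,
                 replicate_count = replicate_count,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' @rdname study_config
#' @export
default_isotherm_truth <- function() {
  list(`25` = isotherm_params("Smith", c(a = -8.05, b = -17.01)),
       `32` = isotherm_params("GAB", c(k = 0.89, c = 13.17, x0 = 3.0)),
       `37` = isotherm_params("Smith", c(a = -2.63, b = -7.98)))
}

#' @rdname study_config
#' @export
default_kinetic_truth <- function() {
  list(`25` = c(a = 8.48, b = 2.05),
       `32` = c(a = 7.95, b = 1.84),
       `37` = c(a = 7.13, b = 2.40))
}

noise_sd_vector <- function(truth, sd, model) {
  if (model == "proportional") sd * abs(truth) else rep(sd, length(truth))
}

#' Simulate an isotherm study
#'
#' For each configured temperature, the water activities are the salt
#' humidities divided by 100 and the EMC values are the truth isotherm plus
#' Gaussian noise; reported EMC is the mean over replicates (the full
#' replicate matrix is attached as attribute `"replicates"`). Deterministic
#' given the config seed.
#'
#' @param cfg A [study_config()].
#' @return List of [sorption_dataset()] objects, one per temperature.
#' @export
simulate_isotherm_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  with_seed(cfg$seed, {
    lapply(cfg$temperatures_c, function(tc) {
      truth <- cfg$isotherm_truth[[as.character(tc)]]
      aw <- unname(vapply(cfg$salts, salt_rh, numeric(1), temp_c = tc)) / 100
      sup <- isotherm_aw_sup(truth)
      if (any(aw >= sup))
        abort_config(sprintf(
          "truth model %s at %g degC is undefined at aw = %.3g (domain sup %.3g)",
          truth$model, tc, max(aw), sup))
      mu <- evaluate_isotherm(truth, aw)
      sds <- noise_sd_vector(mu, cfg$noise_sd_emc, cfg$noise_model)
      reps <- matrix(stats::rnorm(length(aw) * cfg$replicate_count,
                                  mean = mu, sd = sds),
                     nrow = length(aw))
      ds <- sorption_dataset(tc, aw, rowMeans(reps),
                             label = sprintf("synthetic %g degC", tc))
      attr(ds, "replicates") <- reps
      attr(ds, "truth") <- truth
      ds
    })
  })
}

#' Simulate moisture-uptake kinetic runs
#'
#' First-order moisture gain \eqn{a(1 - e^{-bt})} plus Gaussian noise at each
#' configured temperature and the configured kinetic RH; replicate means are
#' reported. Deterministic given the config seed.
#'
#' @param cfg A [study_config()].
#' @param times Sampling times in hours (default every 0.5 h up to 6 h).
#' @return List of [kinetic_series()] objects, one per configured condition.
#' @export
simulate_kinetics <- function(cfg, times = seq(0.5, 6, by = 0.5)) {
  stopifnot(inherits(cfg, "study_config"))
  if (any(times < 0)) abort_validation("times must be non-negative")
  conds <- names(cfg$kinetic_truth)
  with_seed(cfg$seed, {
    lapply(conds, function(tc) {
      th <- cfg$kinetic_truth[[tc]]
      p <- kinetic_params("first_order", th)
      mu <- evaluate_kinetic(p, times)
      sds <- noise_sd_vector(mu, cfg$noise_sd_mgr, cfg$noise_model)
      reps <- matrix(stats::rnorm(length(times) * cfg$replicate_count,
                                  mean = mu, sd = sds),
                     nrow = length(times))
      ks <- kinetic_series(times, rowMeans(reps), as.numeric(tc),
                           rh_percent = cfg$kinetic_rh_percent)
      attr(ks, "replicates") <- reps
      attr(ks, "truth") <- p
      ks
    })
  })
}

#' Simulate an enthalpy-entropy compensation series
#'
#' Generates thermodynamic points lying on (or scattered about) the
#' compensation line \eqn{q_{st} = T_\beta \Delta S_d + \Delta G_\beta}; a
#' fixture for round-trip checks of [compensation_fit()].
#'
#' @param t_beta Isokinetic temperature (K).
#' @param dg_beta Gibbs free energy at the isokinetic temperature (J/mol).
#' @param ds_grid Non-empty grid of differential entropies (J/(mol K)).
#' @param noise_sd Gaussian noise SD on qst (J/mol, default 0).
#' @param seed RNG seed (default 1).
#' @return A `thermo_points` data frame with columns `emc_percent`
#'   (nominal index), `qst`, `ds`.
#' @export
simulate_compensation_series <- function(t_beta, dg_beta, ds_grid,
                                         noise_sd = 0, seed = 1) {
  if (length(ds_grid) == 0) abort_validation("`ds_grid` must be non-empty")
  if (noise_sd < 0) abort_validation("`noise_sd` must be non-negative")
  qst <- with_seed(seed,
    t_beta * ds_grid + dg_beta + stats::rnorm(length(ds_grid), 0, noise_sd))
  out <- data.frame(emc_percent = seq_along(ds_grid), qst = qst, ds = ds_grid,
                    fit_r2 = NA_real_)
  class(out) <- c("thermo_points", "data.frame")
  out
}
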