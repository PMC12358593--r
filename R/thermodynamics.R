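#' Physical constants used by the thermodynamic chain
#'
#' @return List with `R` (gas constant, 8.314 J/(mol K)), `kB` (Boltzmann
#'   constant, 1.38e-23 J/K), `AM` (cross-sectional area of a water molecule,
#'   1.06e-19 m^2) and `latent_heat_water` (latent heat of evaporation of
#'   pure water, 44000 J/mol, reference only).
#' @export
physical_constants <- function() {
  list(R = 8.314, kB = 1.38e-23, AM = 1.06e-19, latent_heat_water = 44000)
}

.R_GAS <- 8.314
.K_BOLTZMANN <- 1.38e-23
.WATER_AREA <- 1.06e-19

#' Gibbs free energy of water sorption
#'
#' \eqn{\Delta G = -R T \ln A_w} (J/mol): the affinity of the material for
#' water vapor. Positive for water activity below 1 (sorption from a
#' sub-saturated atmosphere is non-spontaneous), zero at saturation.
#'
#' @param temp_k Absolute temperature (K), positive.
#' @param aw Water activity in (0, 1\].
#' @return Gibbs free energy in J/mol. Vectorized.
#' @export
gibbs_free_energy <- function(temp_k, aw) {
  if (any(temp_k <= 0)) abort_domain("temperature must be positive (K)")
  if (any(aw <= 0 | aw > 1)) abort_domain("water activity must lie in (0, 1]")
  -.R_GAS * temp_k * log(aw)
}

#' Net isosteric heat and differential entropy across temperatures
#'
#' For each equilibrium moisture content on a grid, inverts each
#' temperature's isotherm to the water activity reaching that moisture
#' content, then regresses \eqn{\ln A_w} on \eqn{1/T} (ordinary least
#' squares). By the Clausius-Clapeyron relation the slope gives the net
#' isosteric heat \eqn{q_{st} = -R \cdot slope} and the intercept the
#' differential entropy \eqn{\Delta S_d = R \cdot intercept}.
#'
#' @param fits_by_temp Named list mapping absolute temperature (K, as names)
#'   to either [isotherm_params()] objects or [fit_model()] results of
#'   isotherm fits; at least 2 temperatures.
#' @param emc_grid Optional numeric vector of EMC values (\%). When `NULL`,
#'   `n_grid` values evenly spaced over the intersection of the
#'   per-temperature attainable EMC ranges on `aw_range` are used.
#' @param aw_range Water-activity window used to build the default grid
#'   (default `c(0.43, 0.92)`, the humidity span of a saturated-salt study).
#' @param n_grid Number of default grid points (default 20).
#' @return A data frame of class `thermo_points` with columns `emc_percent`,
#'   `qst` (J/mol), `ds` (J/(mol K)), `fit_r2`, plus one `aw_<T>` column of
#'   inverted water activities per temperature. With exactly 2 temperatures
#'   the regression is exact and `fit_r2` is 1 by construction.
#' @export
isosteric_analysis <- function(fits_by_temp, emc_grid = NULL,
                               aw_range = c(0.43, 0.92), n_grid = 20) {
  if (length(fits_by_temp) < 2)
    abort_size("isosteric analysis needs at least 2 temperatures")
  if (is.null(names(fits_by_temp)) || anyNA(as.numeric(names(fits_by_temp))))
    abort_validation("`fits_by_temp` must be named by temperature in K")
  temps <- as.numeric(names(fits_by_temp))
  pars <- lapply(fits_by_temp, as_isotherm_params)

  if (is.null(emc_grid)) {
    ranges <- vapply(pars, function(p) {
      hi <- min(aw_range[2], isotherm_aw_sup(p) - 1e-9)
      evaluate_isotherm(p, c(aw_range[1], hi))
    }, numeric(2))
    lo <- max(ranges[1, ])
    hi <- min(ranges[2, ])
    if (hi <= lo)
      abort_range("attainable EMC ranges do not overlap across temperatures")
    emc_grid <- seq(lo, hi, length.out = n_grid)
  }

  aw_mat <- matrix(NA_real_, length(emc_grid), length(temps),
                   dimnames = list(NULL, sprintf("aw_%g", temps)))
  qst <- ds <- r2 <- numeric(length(emc_grid))
  inv_t <- 1 / temps
  for (i in seq_along(emc_grid)) {
    aw_i <- vapply(seq_along(pars), function(j) {
      tryCatch(invert_isotherm(pars[[j]], emc_grid[i]),
               hygrosorb_range_error = function(e) abort_range(sprintf(
                 "EMC %.4g unreachable at T = %g K: %s",
                 emc_grid[i], temps[j], conditionMessage(e))))
    }, numeric(1))
    aw_mat[i, ] <- aw_i
    cf <- stats::lm.fit(cbind(1, inv_t), log(aw_i))
    qst[i] <- -.R_GAS * cf$coefficients[2]
    ds[i] <- .R_GAS * cf$coefficients[1]
    res <- sum(cf$residuals^2)
    tot <- sum((log(aw_i) - mean(log(aw_i)))^2)
    r2[i] <- if (tot == 0) 1 else 1 - res / tot
  }
  out <- data.frame(emc_percent = emc_grid, qst = qst, ds = ds, fit_r2 = r2)
  out <- cbind(out, aw_mat)
  class(out) <- c("thermo_points", "data.frame")
  attr(out, "temperatures_k") <- temps
  out
}

as_isotherm_params <- function(x) {
  if (inherits(x, "isotherm_params")) return(x)
  if (inherits(x, "fit_result")) return(isotherm_params(x$model, x$params))
  abort_validation("expected an isotherm_params or fit_result object")
}

#' Spreading pressure from GAB constants
#'
#' Surface excess free energy of sorption per unit area,
#' \eqn{\phi = (k_B T / A_M) \ln((1 - k_g A_w + k_g c_g A_w)/(1 - k_g A_w))},
#' where \eqn{k_g, c_g} are the GAB constants, \eqn{k_B} the Boltzmann
#' constant and \eqn{A_M} the area of a water molecule. Zero at `aw = 0` and
#' nondecreasing in `aw` whenever \eqn{c_g \ge 1}.
#'
#' @param gab An [isotherm_params()] object with `model == "GAB"` (or a GAB
#'   `fit_result`).
#' @param temp_k Absolute temperature (K).
#' @param aw Water activity in \[0, 1/k).
#' @return Spreading pressure in J/m^2. Vectorized over `aw`.
#' @export
spreading_pressure <- function(gab, temp_k, aw) {
  gab <- as_isotherm_params(gab)
  if (gab$model != "GAB")
    abort_unsupported("spreading pressure is computed from GAB constants")
  if (any(temp_k <= 0)) abort_domain("temperature must be positive (K)")
  k <- gab$params[["k"]]; cc <- gab$params[["c"]]
  if (any(aw < 0 | aw >= 1 / k))
    abort_domain(sprintf("water activity must lie in [0, 1/k) = [0, %.6g)", 1 / k))
  (.K_BOLTZMANN * temp_k / .WATER_AREA) *
    log((1 - k * aw + k * cc * aw) / (1 - k * aw))
}

#' Harmonic mean temperature
#'
#' \eqn{T_{hm} = N / \sum_i 1/T_i} over the isotherm temperatures; the
#' reference temperature against which the isokinetic temperature is compared
#' in the enthalpy-entropy compensation test.
#'
#' @param temps_k Non-empty numeric vector of absolute temperatures (K).
#' @return Harmonic mean temperature in K.
#' @examples
#' harmonic_mean_temperature(celsius_to_kelvin(c(25, 32, 37))) # 304.40
#' @export
harmonic_mean_temperature <- function(temps_k) {
  if (length(temps_k) == 0) abort_validation("empty temperature list")
  if (any(!is.finite(temps_k)) || any(temps_k <= 0))
    abort_validation("temperatures must be positive and finite (K)")
  length(temps_k) / sum(1 / temps_k)
}

#' Enthalpy-entropy compensation fit
#'
#' Fits the compensation line \eqn{q_{st} = T_\beta \Delta S_d + \Delta
#' G_\beta} by ordinary least squares over the thermodynamic points. The
#' slope is the isokinetic temperature \eqn{T_\beta}; the intercept the
#' Gibbs free energy at that temperature (J/mol). Following the Krug
#' criterion, compensation is deemed applicable when \eqn{T_\beta} differs
#' from the harmonic mean temperature by more than `tolerance_k`; sorption is
#' classified enthalpy-driven when \eqn{T_{hm} < T_\beta} and entropy-driven
#' when \eqn{T_{hm} > T_\beta}.
#'
#' @param points A `thermo_points` data frame (from [isosteric_analysis()] or
#'   [simulate_compensation_series()]) or any data frame with finite `qst`
#'   and `ds` columns; at least 3 rows.
#' @param temps_k Absolute temperatures (K) of the underlying isotherms.
#' @param tolerance_k Below this |T_beta - T_hm| the classification is
#'   reported as `"indeterminate"` (default 1 K).
#' @return An object of class `compensation_fit`: `t_beta` (K), `dg_beta`
#'   (J/mol), `r2`, `t_hm` (K), `driving` (`"enthalpy"`, `"entropy"` or
#'   `"indeterminate"`), `applicable`, `spontaneous` (`dg_beta <= 0`).
#' @export
compensation_fit <- function(points, temps_k, tolerance_k = 1) {
  qst <- points$qst
  ds <- points$ds
  ok <- is.finite(qst) & is.finite(ds)
  qst <- qst[ok]; ds <- ds[ok]
  if (length(qst) < 3)
    abort_size("compensation fit needs at least 3 finite (qst, ds) points")
  if (stats::var(ds) == 0)
    abort_degenerate("differential entropy has zero variance")
  cf <- stats::lm.fit(cbind(1, ds), qst)
  t_beta <- unname(cf$coefficients[2])
  dg_beta <- unname(cf$coefficients[1])
  res <- sum(cf$residuals^2)
  tot <- sum((qst - mean(qst))^2)
  r2 <- if (tot == 0) {
    if (res <= 1e-20) 1 else 0
  } else 1 - res / tot
  t_hm <- harmonic_mean_temperature(temps_k)
  applicable <- abs(t_beta - t_hm) > tolerance_k
  driving <- if (!applicable) "indeterminate"
    else if (t_hm < t_beta) "enthalpy" else "entropy"
  structure(list(t_beta = t_beta, dg_beta = dg_beta, r2 = r2, t_hm = t_hm,
                 driving = driving, applicable = applicable,
                 spontaneous = dg_beta <= 0, n_points = length(qst)),
            class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat("<enthalpy-entropy compensation fit>\n")
  cat(sprintf("  T_beta  = %.2f K (isokinetic temperature)\n", x$t_beta))
  cat(sprintf("  dG_beta = %.2f J/mol at T_beta (%s)\n", x$dg_beta,
              if (x$spontaneous) "spontaneous" else "non-spontaneous"))
  cat(sprintf("  T_hm    = %.2f K (harmonic mean)\n", x$t_hm))
  cat(sprintf("  R2 = %.4f over %d points; driving force: %s%s\n",
              x$r2, x$n_points, x$driving,
              if (x$applicable) "" else " (compensation not applicable)"))
  invisible(x)
}
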