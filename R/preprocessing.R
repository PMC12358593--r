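#' Equilibrium moisture change rate from raw masses
#'
#' Converts a pair of capsule masses (before and after moisture absorption)
#' into the equilibrium moisture change rate of the capsule skin,
#' \eqn{EMC\% = 100 (W_1 - W_0) / (W_0 M_{fs})}, where `mfs` is the skin mass
#' fraction. Negative values (net desorption) are allowed and returned as is.
#'
#' @param w0 Mass before absorption (g), positive.
#' @param w1 Mass after absorption (g).
#' @param mfs Skin mass fraction (shell mass / capsule mass), in (0, 1\].
#' @return EMC in percent of skin mass. Vectorized over `w0`, `w1`.
#' @examples
#' compute_emc(w0 = 10, w1 = 10.5, mfs = 0.5) # 10
#' @export
compute_emc <- function(w0, w1, mfs) {
  if (!is.numeric(w0) || !is.numeric(w1) || !is.numeric(mfs) ||
      anyNA(c(w0, w1, mfs)))
    abort_validation("masses and mfs must be numeric without NAs")
  if (any(w0 <= 0)) abort_validation("mass before absorption must be positive")
  if (any(mfs <= 0 | mfs > 1))
    abort_validation("skin mass fraction must lie in (0, 1]")
  100 * (w1 - w0) / (w0 * mfs)
}

#' Moisture gain rate from raw masses
#'
#' Time-resolved analogue of [compute_emc()]:
#' \eqn{Mgr\% = 100 (m_1 - m_0) / (m_0 M_{fs})}.
#'
#' @param m0 Mass before absorption (g), positive.
#' @param m1 Mass after absorption (g).
#' @param mfs Skin mass fraction, in (0, 1\].
#' @return Mgr in percent of skin mass.
#' @export
compute_mgr <- function(m0, m1, mfs) compute_emc(m0, m1, mfs)

#' Skin mass fraction from per-capsule weighings
#'
#' Computes the skin mass fraction as mean skin mass divided by mean whole
#' capsule mass, the normalizer used in [compute_emc()] and [compute_mgr()].
#'
#' @param capsule_mass Numeric vector of whole-capsule masses (g).
#' @param skin_mass Numeric vector of shell masses (g).
#' @return Skin mass fraction in (0, 1).
#' @export
skin_mass_fraction <- function(capsule_mass, skin_mass) {
  if (any(capsule_mass <= 0) || any(skin_mass <= 0))
    abort_validation("masses must be positive")
  mfs <- mean(skin_mass) / mean(capsule_mass)
  if (mfs >= 1)
    abort_validation("mean skin mass must be below mean capsule mass")
  mfs
}

# Equilibrium RH (%) above saturated salt solutions at the three study
# temperatures.
.salt_rh <- data.frame(
  salt = rep(c("K2CO3", "KBr", "KI", "NaCl", "KCl", "Na2CO3"), each = 3),
  temperature_c = rep(c(25, 32, 37), times = 6),
  rh_percent = c(45, 46, 45,
                 62, 61, 58,
                 73, 72, 71,
                 79, 77, 79,
                 88, 84, 87,
                 92, 92, 97),
  stringsAsFactors = FALSE
)

#' Saturated-salt-solution relative humidity reference
#'
#' `salt_rh()` looks up the equilibrium relative humidity maintained above a
#' saturated salt solution at one of the study temperatures (25, 32, 37
#' degrees C); `salt_rh_table()` returns the full 6-salt x 3-temperature
#' reference as a data frame.
#'
#' @param salt Salt name: one of `"K2CO3"`, `"KBr"`, `"KI"`, `"NaCl"`,
#'   `"KCl"`, `"Na2CO3"`.
#' @param temp_c Temperature in degrees Celsius: 25, 32 or 37.
#' @return `salt_rh()`: relative humidity in percent. `salt_rh_table()`: a
#'   data frame with columns `salt`, `temperature_c`, `rh_percent`.
#' @examples
#' salt_rh("KBr", 32) # 61
#' @export
salt_rh <- function(salt, temp_c) {
  hit <- .salt_rh$salt == salt & .salt_rh$temperature_c == temp_c
  if (!any(hit))
    abort_lookup(sprintf(
      "no RH entry for (%s, %s degC); valid salts: %s; valid temperatures: %s",
      salt, temp_c, paste(unique(.salt_rh$salt), collapse = ", "),
      paste(unique(.salt_rh$temperature_c), collapse = ", ")))
  .salt_rh$rh_percent[hit]
}

#' @rdname salt_rh
#' @export
salt_rh_table <- function() .salt_rh

#' Celsius to Kelvin
#'
#' @param t Temperature in degrees Celsius, above absolute zero.
#' @return Absolute temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(t) {
  if (!is.numeric(t) || anyNA(t)) abort_validation("`t` must be numeric")
  if (any(t <= -273.15)) abort_domain("temperature below absolute zero")
  t + 273.15
}
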