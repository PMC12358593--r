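# Shared fixtures: the published fit parameters of the capsule study, an
# independent bisection oracle for isotherm inversion, and random valid
# parameter generators for property tests.

smith_25 <- isotherm_params("Smith", c(a = -8.05, b = -17.01))
smith_37 <- isotherm_params("Smith", c(a = -2.63, b = -7.98))
gab_32 <- isotherm_params("GAB", c(k = 0.89, c = 13.17, x0 = 177.03))

first_order_truth <- list(
  `25` = c(a = 8.48, b = 2.05),
  `32` = c(a = 7.95, b = 1.84),
  `37` = c(a = 7.13, b = 2.40))

# Published goodness-of-fit table for the five isotherm models.
isotherm_metrics <- list(
  `25` = data.frame(
    model = c("GAB", "Peleg", "Smith", "Halsey", "Henderson"),
    r2 = c(0.9892, 0.9882, 0.9965, 0.9719, 0.8692),
    rss = c(0.9633, 1.7610, 1.0379, 8.3792, 39.0666)),
  `32` = data.frame(
    model = c("GAB", "Peleg", "Smith", "Halsey", "Henderson"),
    r2 = c(0.9925, 0.9159, 0.9608, 0.7553, 0.5203),
    rss = c(0.9956, 7.5203, 7.0124, 43.7983, 85.8499)),
  `37` = data.frame(
    model = c("GAB", "Peleg", "Smith", "Halsey", "Henderson"),
    r2 = c(0.9782, 0.9626, 0.9827, 0.7263, 0.9183),
    rss = c(11.6500, 14.0896, 13.0120, 206.2091, 61.5527)))

# Water activities of the six-salt humidity ladder at each temperature.
salt_aw <- function(temp_c) {
  tab <- salt_rh_table()
  sort(tab$rh_percent[tab$temperature_c == temp_c] / 100)
}

# Independent inversion oracle: plain interval bisection on the forward
# formula, no reuse of invert_isotherm() internals.
bisect_invert <- function(params, target, hi, tol = 1e-12) {
  lo <- 0
  f <- function(x) evaluate_isotherm(params, x) - target
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Draw a random valid parameter set for a given isotherm model.
random_isotherm_params <- function(model) {
  p <- switch(model,
    GAB = c(k = runif(1, 0.3, 0.95), c = runif(1, 1.5, 30),
            x0 = runif(1, 1, 50)),
    Peleg = c(a = runif(1, 1, 20), b = runif(1, 0.2, 0.9),
              c = runif(1, 1, 30), d = runif(1, 2, 9)),
    Smith = c(a = runif(1, -10, 5), b = runif(1, -25, -2)),
    Halsey = c(a = runif(1, 0.5, 5), b = runif(1, 0.8, 3)),
    Henderson = c(a = runif(1, 0.005, 0.1), b = runif(1, 0.8, 2.5)))
  isotherm_params(model, p)
}
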