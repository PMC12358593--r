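#' Isotherm model parameter sets
#'
#' Constructs a validated parameter set for one of the five moisture sorption
#' isotherm models used for gelatin-shell capsules: GAB, Peleg, Smith, Halsey
#' and Henderson. All models map water activity `aw` (a dimensionless fraction
#' in \[0, 1)) to the equilibrium moisture change rate EMC (percent of skin
#' mass).
#'
#' Model forms (x = water activity, y = EMC \%):
#' \itemize{
#'   \item GAB: \eqn{y = k c x x_0 / ((1 - kx)(1 - kx + kcx))}, parameters
#'     `k` in (0, 1\], `c > 0`, `x0 > 0`; defined for `aw < 1/k`.
#'   \item Peleg: \eqn{y = a x^b + c x^d}, `a, c >= 0`, `b, d > 0`.
#'   \item Smith: \eqn{y = a + b \ln(1 - x)}; `b` is typically negative so
#'     that moisture uptake increases with water activity.
#'   \item Halsey: \eqn{y = (-a / \ln x)^{1/b}}, `a, b > 0`.
#'   \item Henderson: \eqn{y = (-(1/a) \ln(1 - x))^{1/b}}, `a, b > 0`.
#' }
#'
#' @param model One of `"GAB"`, `"Peleg"`, `"Smith"`, `"Halsey"`,
#'   `"Henderson"` (case sensitive).
#' @param params Named numeric vector or list with the model's parameters, in
#'   any order: GAB `k, c, x0`; Peleg `a, b, c, d`; Smith/Halsey/Henderson
#'   `a, b`.
#' @return An object of class `isotherm_params`.
#' @examples
#' p <- isotherm_params("Smith", c(a = -8.05, b = -17.01))
#' evaluate_isotherm(p, 0.61)
#' @export
isotherm_params <- function(model, params) {
  info <- isotherm_model_info(model)
  params <- unlist(params)
  if (!all(info$params %in% names(params)))
    abort_validation(sprintf(
      "%s requires parameters %s; got %s", model,
      paste(info$params, collapse = ", "),
      paste(names(params), collapse = ", ")))
  params <- params[info$params]
  if (anyNA(params) || any(!is.finite(params)))
    abort_validation(sprintf("%s parameters must be finite", model))
  check <- switch(model,
    GAB = {
      if (params[["k"]] <= 0 || params[["k"]] > 1)
        abort_validation("GAB: k must lie in (0, 1]")
      if (params[["c"]] <= 0) abort_validation("GAB: c must be positive")
      if (params[["x0"]] <= 0) abort_validation("GAB: x0 must be positive")
    },
    Peleg = {
      if (params[["a"]] < 0 || params[["c"]] < 0)
        abort_validation("Peleg: a and c must be non-negative")
      if (params[["b"]] <= 0 || params[["d"]] <= 0)
        abort_validation("Peleg: b and d must be positive")
    },
    Smith = NULL, # a, b unconstrained; b < 0 gives an increasing isotherm
    Halsey = ,
    Henderson = {
      if (params[["a"]] <= 0 || params[["b"]] <= 0)
        abort_validation(sprintf("%s: a and b must be positive", model))
    })
  structure(list(model = model, params = params), class = "isotherm_params")
}

# Registry of isotherm model definitions. `fn` evaluates the displayed
# formula; `lower`/`upper` are box constraints for fitting; `starts` builds a
# deterministic multi-start grid from the data.
isotherm_model_info <- function(model) {
  info <- .isotherm_registry[[model]]
  if (is.null(info))
    abort_lookup(sprintf("unknown isotherm model '%s'; valid models: %s",
                         model, paste(names(.isotherm_registry), collapse = ", ")))
  info
}

#' Names of the supported isotherm models
#' @return Character vector of model names.
#' @export
isotherm_model_names <- function() names(.isotherm_registry)

.isotherm_registry <- list(
  GAB = list(
    params = c("k", "c", "x0"),
    lower = c(k = 1e-6, c = 1e-6, x0 = 1e-6),
    upper = c(k = 1, c = Inf, x0 = Inf),
    fn = function(p, x) {
      kx <- p[["k"]] * x
      p[["k"]] * p[["c"]] * x * p[["x0"]] /
        ((1 - kx) * (1 - kx + p[["c"]] * kx))
    },
    starts = function(x, y) {
      ymax <- max(abs(y))
      as.matrix(expand.grid(k = c(0.5, 0.9), c = c(2, 20),
                            x0 = ymax * c(0.2, 1, 5)))
    }),
  Peleg = list(
    params = c("a", "b", "c", "d"),
    lower = c(a = 0, b = 1e-6, c = 0, d = 1e-6),
    upper = c(a = Inf, b = Inf, c = Inf, d = Inf),
    fn = function(p, x) p[["a"]] * x^p[["b"]] + p[["c"]] * x^p[["d"]],
    starts = function(x, y) {
      ymax <- max(abs(y))
      as.matrix(expand.grid(a = ymax * c(0.5, 1), b = c(0.3, 1),
                            c = ymax * c(0.5, 2), d = c(3, 8)))
    }),
  Smith = list(
    params = c("a", "b"),
    lower = c(a = -Inf, b = -Inf),
    upper = c(a = Inf, b = Inf),
    fn = function(p, x) p[["a"]] + p[["b"]] * log(1 - x),
    starts = function(x, y) {
      # Smith is linear in (1, log(1-x)); one OLS start suffices
      cf <- stats::coef(stats::lm(y ~ log(1 - x)))
      matrix(c(cf[[1]], cf[[2]]), nrow = 1,
             dimnames = list(NULL, c("a", "b")))
    }),
  Halsey = list(
    params = c("a", "b"),
    lower = c(a = 1e-8, b = 1e-8),
    upper = c(a = Inf, b = Inf),
    fn = function(p, x) (-p[["a"]] / log(x))^(1 / p[["b"]]),
    starts = function(x, y) {
      # linearize: log(y) = (1/b) * (log a - log(-log x))
      ok <- x > 0 & y > 0
      if (sum(ok) >= 2) {
        cf <- stats::coef(stats::lm(log(y[ok]) ~ log(-log(x[ok]))))
        b0 <- max(-1 / cf[[2]], 1e-3)
        a0 <- max(exp(cf[[1]] * b0), 1e-6)
        rbind(c(a = a0, b = b0), c(a = 1, b = 1), c(a = 5, b = 2))
      } else rbind(c(a = 1, b = 1), c(a = 5, b = 2))
    }),
  Henderson = list(
    params = c("a", "b"),
    lower = c(a = 1e-8, b = 1e-8),
    upper = c(a = Inf, b = Inf),
    fn = function(p, x) (-log(1 - x) / p[["a"]])^(1 / p[["b"]]),
    starts = function(x, y) {
      ok <- x > 0 & y > 0
      if (sum(ok) >= 2) {
        cf <- stats::coef(stats::lm(log(-log(1 - x[ok])) ~ log(y[ok])))
        b0 <- max(cf[[2]], 1e-3)
        a0 <- max(exp(cf[[1]]), 1e-8)
        rbind(c(a = a0, b = b0), c(a = 1, b = 1), c(a = 0.01, b = 2))
      } else rbind(c(a = 1, b = 1), c(a = 0.01, b = 2))
    })
)

# Upper end of the water-activity domain for a model (open bound).
isotherm_aw_sup <- function(params) {
  if (params$model == "GAB") min(1, 1 / params$params[["k"]]) else 1
}

#' Evaluate a sorption isotherm
#'
#' Computes the equilibrium moisture change rate (EMC, \% of skin mass)
#' predicted by an isotherm model at the given water activities.
#'
#' @param params An [isotherm_params()] object.
#' @param aw Numeric vector of water activities in \[0, 1); for the GAB model
#'   additionally `aw < 1/k`.
#' @return Numeric vector of EMC values (\%).
#' @export
evaluate_isotherm <- function(params, aw) {
  stopifnot(inherits(params, "isotherm_params"))
  if (!is.numeric(aw) || anyNA(aw))
    abort_domain("`aw` must be numeric without NAs")
  sup <- isotherm_aw_sup(params)
  if (any(aw < 0 | aw >= sup))
    abort_domain(sprintf(
      "%s model: water activity must lie in [0, %s)", params$model,
      if (params$model == "GAB") sprintf("min(1, 1/k) = %.6g", sup) else "1"))
  info <- isotherm_model_info(params$model)
  y <- info$fn(as.list(params$params), aw)
  # Halsey/Henderson at aw = 0 are defined by their limit, 0
  y[aw == 0 & params$model %in% c("Halsey", "Henderson")] <- 0
  y
}

#' Invert a sorption isotherm
#'
#' Finds the water activity at which the model attains a given EMC. Smith is
#' inverted in closed form, GAB by solving its quadratic in `k*aw`, and
#' Peleg/Halsey/Henderson by monotone bisection.
#'
#' @param params An [isotherm_params()] object.
#' @param emc_percent Numeric vector of target EMC values (\%).
#' @param aw_max Upper bound of the search interval; defaults to 0.9999
#'   (capped at `1/k - 1e-9` for GAB).
#' @return Numeric vector of water activities.
#' @export
invert_isotherm <- function(params, emc_percent, aw_max = NULL) {
  stopifnot(inherits(params, "isotherm_params"))
  if (is.null(aw_max)) aw_max <- min(0.9999, isotherm_aw_sup(params) - 1e-9)
  if (aw_max <= 0 || aw_max >= isotherm_aw_sup(params))
    abort_validation("`aw_max` must lie in (0, sup of the model domain)")
  vapply(emc_percent, invert_isotherm_one, numeric(1),
         params = params, aw_max = aw_max)
}

invert_isotherm_one <- function(params, emc, aw_max) {
  p <- params$params
  y_lo <- evaluate_isotherm(params, 0)
  y_hi <- evaluate_isotherm(params, aw_max)
  rng <- sort(c(y_lo, y_hi))
  if (emc < rng[1] || emc > rng[2])
    abort_range(sprintf(
      "%s model: EMC %.6g is outside the attainable range [%.6g, %.6g] for aw in [0, %.6g]",
      params$model, emc, rng[1], rng[2], aw_max))
  aw <- switch(params$model,
    Smith = 1 - exp((emc - p[["a"]]) / p[["b"]]),
    GAB = invert_gab(p, emc),
    {
      f <- function(x) evaluate_isotherm(params, x) - emc
      stats::uniroot(f, lower = 0, upper = aw_max, tol = 1e-12,
                     maxiter = 2000)$root
    })
  min(max(aw, 0), aw_max)
}

# GAB inversion: with u = k*aw, y*(1-u)*(1-u+cu) = c*x0*u rearranges to
#   -(c-1)*y*u^2 + ((c-2)*y - c*x0)*u + y = 0.
# The physical root has u in (0, 1), i.e. aw in (0, 1/k).
invert_gab <- function(p, emc) {
  if (emc == 0) return(0)
  k <- p[["k"]]; cc <- p[["c"]]; x0 <- p[["x0"]]
  A <- -(cc - 1) * emc
  B <- (cc - 2) * emc - cc * x0
  C <- emc
  if (abs(A) < 1e-14 * max(abs(B), abs(C))) {
    u <- -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) abort_range("GAB inversion: no real root for this EMC")
    roots <- (-B + c(1, -1) * sqrt(disc)) / (2 * A)
    ok <- roots > 0 & roots < 1
    if (!any(ok))
      abort_range("GAB inversion: no root in (0, 1/k) for this EMC")
    u <- min(roots[ok]) # both in range is a numerical corner; take smaller
  }
  u / k
}
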