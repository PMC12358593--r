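#' Hygroscopic kinetic model parameter sets
#'
#' Constructs a validated parameter set for one of the four moisture-uptake
#' kinetic models. All models map storage time `t` (hours) to the moisture
#' gain rate Mgr (percent of skin mass).
#'
#' Model forms (x = time in hours, y = Mgr \%):
#' \itemize{
#'   \item zero_order: \eqn{y = a + b x}
#'   \item first_order: \eqn{y = a (1 - e^{-bx})}; `a > 0` is the saturation
#'     moisture gain (\%), `b > 0` the uptake rate (1/h)
#'   \item second_order: \eqn{y = a b^2 x / (1 + a b x)}, `a, b > 0`
#'   \item biexponential: \eqn{y = A_1 e^{-x/c} + A_2 e^{-x/d} + y_0},
#'     `c, d > 0`; `A1`, `A2` may be negative (rising uptake curves fit with
#'     negative amplitudes)
#' }
#'
#' @param model One of `"zero_order"`, `"first_order"`, `"second_order"`,
#'   `"biexponential"`.
#' @param params Named numeric vector or list of parameters (zero/first/second
#'   order: `a, b`; biexponential: `A1, A2, c, d, y0`).
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params("first_order", c(a = 8.48, b = 2.05))
#' evaluate_kinetic(p, c(0.5, 1, 2))
#' @export
kinetic_params <- function(model, params) {
  info <- kinetic_model_info(model)
  params <- unlist(params)
  if (!all(info$params %in% names(params)))
    abort_validation(sprintf("%s requires parameters %s", model,
                             paste(info$params, collapse = ", ")))
  params <- params[info$params]
  if (anyNA(params) || any(!is.finite(params)))
    abort_validation(sprintf("%s parameters must be finite", model))
  switch(model,
    first_order = ,
    second_order = {
      if (params[["a"]] <= 0 || params[["b"]] <= 0)
        abort_validation(sprintf("%s: a and b must be positive", model))
    },
    biexponential = {
      if (params[["c"]] <= 0 || params[["d"]] <= 0)
        abort_validation("biexponential: time constants c and d must be positive")
    })
  structure(list(model = model, params = params), class = "kinetic_params")
}

kinetic_model_info <- function(model) {
  info <- .kinetic_registry[[model]]
  if (is.null(info))
    abort_lookup(sprintf("unknown kinetic model '%s'; valid models: %s",
                         model, paste(names(.kinetic_registry), collapse = ", ")))
  info
}

#' Names of the supported kinetic models
#' @return Character vector of model names.
#' @export
kinetic_model_names <- function() names(.kinetic_registry)

.kinetic_registry <- list(
  zero_order = list(
    params = c("a", "b"),
    lower = c(a = -Inf, b = -Inf),
    upper = c(a = Inf, b = Inf),
    fn = function(p, x) p[["a"]] + p[["b"]] * x,
    starts = function(x, y) {
      cf <- stats::coef(stats::lm(y ~ x))
      matrix(c(cf[[1]], cf[[2]]), nrow = 1, dimnames = list(NULL, c("a", "b")))
    }),
  first_order = list(
    params = c("a", "b"),
    lower = c(a = 1e-8, b = 1e-8),
    upper = c(a = Inf, b = Inf),
    fn = function(p, x) p[["a"]] * (1 - exp(-p[["b"]] * x)),
    starts = function(x, y) {
      a0 <- max(max(y), 1e-3)
      as.matrix(expand.grid(a = a0 * c(1, 1.5), b = c(0.2, 1, 4)))
    }),
  second_order = list(
    params = c("a", "b"),
    lower = c(a = 1e-8, b = 1e-8),
    upper = c(a = Inf, b = Inf),
    fn = function(p, x) p[["a"]] * p[["b"]]^2 * x / (1 + p[["a"]] * p[["b"]] * x),
    starts = function(x, y) {
      # saturation value of this form is b
      b0 <- max(max(y), 1e-3)
      as.matrix(expand.grid(a = c(0.1, 1, 10), b = b0 * c(1, 1.5)))
    }),
  biexponential = list(
    params = c("A1", "A2", "c", "d", "y0"),
    lower = c(A1 = -Inf, A2 = -Inf, c = 1e-8, d = 1e-8, y0 = -Inf),
    upper = c(A1 = Inf, A2 = Inf, c = Inf, d = Inf, y0 = Inf),
    fn = function(p, x) p[["A1"]] * exp(-x / p[["c"]]) +
      p[["A2"]] * exp(-x / p[["d"]]) + p[["y0"]],
    starts = function(x, y) {
      y0 <- max(y)
      amp <- -(max(y) - min(y))
      as.matrix(expand.grid(A1 = amp * c(0.5, 1), A2 = amp * c(0.25, 0.5),
                            c = c(0.3, 1), d = c(2, 5), y0 = y0))
    })
)

#' Evaluate a hygroscopic kinetic model
#'
#' @param params A [kinetic_params()] object.
#' @param t Numeric vector of times (hours), all non-negative.
#' @return Numeric vector of moisture gain rates (\%).
#' @export
evaluate_kinetic <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    abort_domain("`t` must be numeric and non-negative")
  info <- kinetic_model_info(params$model)
  info$fn(as.list(params$params), t)
}

#' Time to reach a fraction of first-order saturation
#'
#' For the first-order model \eqn{y = a(1 - e^{-bt})}, returns the time at
#' which the moisture gain reaches `fraction * a`, i.e.
#' \eqn{-\ln(1 - fraction)/b}. Useful for checking saturation times (the
#' capsules saturate within roughly 2 hours at the fitted rates).
#'
#' @param params A [kinetic_params()] object with `model == "first_order"`.
#' @param fraction Fraction of the saturation moisture gain, in \[0, 1).
#' @return Time in hours.
#' @export
time_to_fraction <- function(params, fraction) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model != "first_order")
    abort_unsupported("time_to_fraction is defined for the first_order model only")
  if (!is.numeric(fraction) || anyNA(fraction) ||
      any(fraction < 0 | fraction >= 1))
    abort_domain("`fraction` must lie in [0, 1)")
  -log(1 - fraction) / params$params[["b"]]
}
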