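#' Sorption dataset: one temperature's equilibrium points
#'
#' Bundles the (water activity, EMC) pairs measured at a single temperature.
#' Points are sorted by water activity; duplicated activities are rejected.
#'
#' @param temperature_c Storage temperature in degrees Celsius.
#' @param aw Numeric vector of water activities in \[0, 1).
#' @param emc_percent Numeric vector of equilibrium moisture change rates (\%).
#' @param initial_aw Optional initial water activity of the material before
#'   exposure (metadata only).
#' @param label Optional text label.
#' @return An object of class `sorption_dataset` with elements
#'   `temperature_k`, `temperature_c`, `aw`, `emc_percent`, `initial_aw`,
#'   `label`.
#' @export
sorption_dataset <- function(temperature_c, aw, emc_percent,
                             initial_aw = NA_real_, label = "") {
  if (length(aw) != length(emc_percent))
    abort_validation("`aw` and `emc_percent` must have equal length")
  if (length(aw) < 2) abort_size("a sorption dataset needs at least 2 points")
  if (any(aw < 0 | aw >= 1)) abort_validation("water activities must lie in [0, 1)")
  if (anyDuplicated(aw)) abort_validation("water activities must be unique")
  ord <- order(aw)
  structure(list(temperature_k = celsius_to_kelvin(temperature_c),
                 temperature_c = temperature_c,
                 aw = aw[ord], emc_percent = emc_percent[ord],
                 initial_aw = initial_aw, label = label),
            class = "sorption_dataset")
}

#' Kinetic series: a moisture-gain time course at one storage condition
#'
#' @param time_h Strictly increasing times (hours), non-negative.
#' @param mgr_percent Moisture gain rate (\%) at each time.
#' @param temperature_c Storage temperature (degrees Celsius).
#' @param rh_percent Storage relative humidity (\%).
#' @return An object of class `kinetic_series`.
#' @export
kinetic_series <- function(time_h, mgr_percent, temperature_c,
                           rh_percent = NA_real_) {
  if (length(time_h) != length(mgr_percent))
    abort_validation("`time_h` and `mgr_percent` must have equal length")
  if (length(time_h) < 2) abort_size("a kinetic series needs at least 2 points")
  if (any(time_h < 0)) abort_validation("times must be non-negative")
  if (any(diff(time_h) <= 0)) abort_validation("times must be strictly increasing")
  structure(list(temperature_k = celsius_to_kelvin(temperature_c),
                 temperature_c = temperature_c, rh_percent = rh_percent,
                 time_h = time_h, mgr_percent = mgr_percent),
            class = "kinetic_series")
}

#' Goodness of fit: R-squared and residual sum of squares
#'
#' @param observed Numeric vector of observations.
#' @param predicted Numeric vector of model predictions, same length.
#' @return List with `r2` (\eqn{1 - RSS/TSS}, TSS about the mean) and `rss`.
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    abort_validation("`observed` and `predicted` must have equal length")
  if (length(observed) < 2)
    abort_size("goodness of fit needs at least 2 points")
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0)
    abort_degenerate("all observations identical: total sum of squares is zero")
  list(r2 = 1 - rss / tss, rss = rss)
}

#' Fit a sorption or kinetic model by multi-start nonlinear least squares
#'
#' Minimizes the residual sum of squares with the Levenberg-Marquardt
#' algorithm (box-constrained, via \pkg{minpack.lm}) from a deterministic
#' per-model start grid plus seeded random perturbations, keeping the best
#' converged start. Kinetic fits prepend an implicit (0, 0) anchor point by
#' default, since uptake starts from the dry reference mass.
#'
#' @param data A [sorption_dataset()] or [kinetic_series()].
#' @param model Model name; see [isotherm_model_names()] and
#'   [kinetic_model_names()].
#' @param n_starts Total number of starts (grid first, then random
#'   perturbations of the grid), default 16.
#' @param seed Seed for the random starts (default 1).
#' @param include_origin Kinetic fits only: prepend the (t = 0, Mgr = 0)
#'   anchor if not already present (default TRUE).
#' @param ... Unused.
#' @return An object of class `fit_result`: `model`, `params` (named vector),
#'   `r2`, `rss`, `n_points`, `n_params`, `converged`, `param_se` (from the
#'   Jacobian at the optimum; an asymptotic measure, not the replicate-based
#'   spread an experiment would report), `seed_trace`.
#' @export
fit_model <- function(data, model, ...) UseMethod("fit_model")

#' @rdname fit_model
#' @export
fit_model.sorption_dataset <- function(data, model, n_starts = 16, seed = 1,
                                       ...) {
  info <- isotherm_model_info(model)
  x <- data$aw
  y <- data$emc_percent
  if (model == "GAB") {
    # aw must stay below 1/k for every candidate k; enforced via the bound
    if (any(x >= 1)) abort_domain("GAB requires aw < 1")
  }
  fit <- fit_nls(x, y, info, model, n_starts, seed, kind = "isotherm")
  if (model == "Peleg") fit <- canonicalize_peleg(fit)
  fit
}

#' @rdname fit_model
#' @export
fit_model.kinetic_series <- function(data, model, n_starts = 16, seed = 1,
                                     include_origin = TRUE, ...) {
  info <- kinetic_model_info(model)
  x <- data$time_h
  y <- data$mgr_percent
  if (include_origin && !any(x == 0)) {
    x <- c(0, x)
    y <- c(0, y)
  }
  fit <- fit_nls(x, y, info, model, n_starts, seed, kind = "kinetic")
  if (model == "biexponential") fit <- canonicalize_biexponential(fit)
  fit
}

# Core multi-start Levenberg-Marquardt driver shared by both data kinds.
fit_nls <- function(x, y, info, model, n_starts, seed, kind) {
  n_params <- length(info$params)
  if (length(y) <= n_params)
    abort_size(sprintf(
      "%s has %d free parameters but only %d points are available",
      model, n_params, length(y)))
  grid <- info$starts(x, y)
  colnames(grid) <- info$params
  starts <- grid
  if (nrow(starts) < n_starts) {
    extra <- with_seed(seed, {
      idx <- sample(nrow(grid), n_starts - nrow(grid), replace = TRUE)
      jitter <- matrix(stats::runif(length(idx) * n_params, 0.5, 2),
                       ncol = n_params)
      grid[idx, , drop = FALSE] * jitter +
        (grid[idx, , drop = FALSE] == 0) * (jitter - 1)
    })
    starts <- rbind(starts, extra)
  } else if (nrow(starts) > n_starts) {
    starts <- starts[seq_len(n_starts), , drop = FALSE]
  }
  # clamp starts into bounds
  starts <- pmin(pmax(starts, rep(info$lower + 1e-10, each = nrow(starts))),
                 rep(ifelse(is.finite(info$upper), info$upper, Inf),
                     each = nrow(starts)))

  resid_fn <- function(par) {
    names(par) <- info$params
    y - info$fn(as.list(par), x)
  }
  best <- NULL
  n_ok <- 0L
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     gtol = 0, maxiter = 1000, maxfev = 10000)
  for (i in seq_len(nrow(starts))) {
    # maxiter stops at these tolerances are still usable local optima;
    # keep them as candidates instead of surfacing the solver warning
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[i, ], lower = info$lower,
                           upper = info$upper, fn = resid_fn, control = ctrl)),
      error = function(e) NULL)
    if (is.null(res) || anyNA(res$par) || !is.finite(res$deviance)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    abort_convergence(sprintf(
      "%s: none of %d starts converged (n = %d points)", model,
      nrow(starts), length(y)))
  par <- best$par
  names(par) <- info$params
  gof <- goodness_of_fit(y, info$fn(as.list(par), x))
  se <- fit_param_se(info, par, x, best$deviance, length(y))
  structure(list(model = model, kind = kind, params = par,
                 r2 = gof$r2, rss = gof$rss,
                 n_points = length(y), n_params = n_params,
                 converged = n_ok > 0L, param_se = se,
                 seed_trace = sprintf("seed=%d; starts=%d (%d grid, %d random); converged=%d",
                                      seed, nrow(starts), nrow(grid),
                                      max(0L, nrow(starts) - nrow(grid)), n_ok)),
            class = "fit_result")
}

# Asymptotic standard errors via a central-difference Jacobian at the optimum.
fit_param_se <- function(info, par, x, rss, n) {
  p <- length(par)
  if (n <= p) return(NULL)
  tryCatch({
    J <- vapply(seq_len(p), function(j) {
      h <- max(abs(par[j]), 1) * 1e-6
      up <- par; up[j] <- up[j] + h
      dn <- par; dn[j] <- dn[j] - h
      (info$fn(as.list(up), x) - info$fn(as.list(dn), x)) / (2 * h)
    }, numeric(length(x)))
    sig2 <- rss / (n - p)
    se <- sqrt(diag(solve(crossprod(J))) * sig2)
    names(se) <- names(par)
    se
  }, error = function(e) NULL)
}

# Peleg a*x^b + c*x^d is invariant under swapping (a,b) <-> (c,d);
# report the term with the smaller exponent first.
canonicalize_peleg <- function(fit) {
  p <- fit$params
  if (p[["b"]] > p[["d"]]) {
    fit$params <- c(a = p[["c"]], b = p[["d"]], c = p[["a"]], d = p[["b"]])
    if (!is.null(fit$param_se)) {
      fit$param_se <- fit$param_se[c("c", "d", "a", "b")]
      names(fit$param_se) <- c("a", "b", "c", "d")
    }
  }
  fit
}

# Same exchange symmetry for the biexponential (A1,c) <-> (A2,d).
canonicalize_biexponential <- function(fit) {
  p <- fit$params
  if (p[["c"]] > p[["d"]]) {
    fit$params <- c(A1 = p[["A2"]], A2 = p[["A1"]], c = p[["d"]],
                    d = p[["c"]], y0 = p[["y0"]])
    if (!is.null(fit$param_se)) {
      fit$param_se <- fit$param_se[c("A2", "A1", "d", "c", "y0")]
      names(fit$param_se) <- c("A1", "A2", "c", "d", "y0")
    }
  }
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s fit: %s>\n", x$kind, x$model))
  print(round(x$params, 6))
  cat(sprintf("R2 = %.6f, RSS = %.6g, n = %d\n", x$r2, x$rss, x$n_points))
  invisible(x)
}

#' Select the best-fitting model
#'
#' Ranks candidate fits of the same dataset by the coefficient of
#' determination (higher is better). R-squared ties at 4 decimal places are
#' broken by lower RSS (differences under 1e-8 count as ties), then by fewer
#' free parameters, then alphabetically, so the choice is deterministic and
#' independent of input order.
#'
#' @param fits Either a list of [fit_model()] results or a data frame with
#'   columns `model`, `r2`, `rss` (and optionally `n_params`).
#' @return The winning model name (character scalar).
#' @examples
#' tab <- data.frame(model = c("GAB", "Smith"), r2 = c(0.9892, 0.9965),
#'                   rss = c(0.9633, 1.0379))
#' select_best(tab) # "Smith"
#' @export
select_best <- function(fits) {
  if (is.data.frame(fits)) {
    if (!all(c("model", "r2", "rss") %in% names(fits)))
      abort_validation("data frame input needs columns model, r2, rss")
    tab <- fits
    if (is.null(tab$n_params))
      tab$n_params <- vapply(tab$model, model_param_count, integer(1))
  } else {
    if (length(fits) == 0) abort_validation("empty fit list")
    tab <- data.frame(
      model = vapply(fits, `[[`, character(1), "model"),
      r2 = vapply(fits, `[[`, numeric(1), "r2"),
      rss = vapply(fits, `[[`, numeric(1), "rss"),
      n_params = vapply(fits, `[[`, numeric(1), "n_params"))
  }
  if (nrow(tab) == 0) abort_validation("empty fit list")
  # RSS differences below 1e-8 (%^2) are numerical noise between fits that
  # both interpolate the data; treat them as ties and prefer parsimony
  ord <- order(-round(tab$r2, 4), floor(tab$rss / 1e-8), tab$n_params,
               tab$model)
  tab$model[ord[1]]
}

model_param_count <- function(model) {
  if (model %in% names(.isotherm_registry))
    return(length(.isotherm_registry[[model]]$params))
  if (model %in% names(.kinetic_registry))
    return(length(.kinetic_registry[[model]]$params))
  NA_integer_
}

#' Fit every isotherm (or kinetic) model to a dataset
#'
#' Convenience wrappers returning one [fit_model()] result per model.
#'
#' @param data A [sorption_dataset()] (`fit_all_isotherms`) or
#'   [kinetic_series()] (`fit_all_kinetics`).
#' @param models Model names to fit; defaults to all supported.
#' @param ... Passed to [fit_model()].
#' @return Named list of `fit_result` objects.
#' @export
fit_all_isotherms <- function(data, models = isotherm_model_names(), ...) {
  stats::setNames(lapply(models, function(m) fit_model(data, m, ...)), models)
}

#' @rdname fit_all_isotherms
#' @export
fit_all_kinetics <- function(data, models = kinetic_model_names(), ...) {
  stats::setNames(lapply(models, function(m) fit_model(data, m, ...)), models)
}
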