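test_that("goodness of fit computes R2 about the mean and raw RSS", {
  o <- c(1, 2, 3)
  expect_equal(goodness_of_fit(o, o), list(r2 = 1, rss = 0))
  expect_equal(goodness_of_fit(o, rep(mean(o), 3)), list(r2 = 0, rss = 2))
  g <- goodness_of_fit(o, c(1, 2, 4))
  expect_equal(g$rss, 1)
  expect_equal(g$r2, 0.5)
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)),
               class = "hygrosorb_degenerate_error")
  expect_error(goodness_of_fit(1:3, 1:4), class = "hygrosorb_validation_error")
})

test_that("noise-free data reproduce the published isotherm parameters", {
  d25 <- sorption_dataset(25, salt_aw(25), evaluate_isotherm(smith_25, salt_aw(25)))
  f25 <- fit_model(d25, "Smith")
  expect_equal(unname(f25$params), c(-8.05, -17.01), tolerance = 1e-6)
  expect_equal(f25$r2, 1, tolerance = 1e-10)
  expect_lt(f25$rss, 1e-12)

  d32 <- sorption_dataset(32, salt_aw(32), evaluate_isotherm(gab_32, salt_aw(32)))
  f32 <- fit_model(d32, "GAB")
  expect_equal(unname(f32$params), c(0.89, 13.17, 177.03), tolerance = 1e-5)

  d37 <- sorption_dataset(37, salt_aw(37), evaluate_isotherm(smith_37, salt_aw(37)))
  f37 <- fit_model(d37, "Smith")
  expect_equal(unname(f37$params), c(-2.63, -7.98), tolerance = 1e-6)
})

test_that("every isotherm model recovers its generating parameters", {
  truths <- list(
    GAB = c(k = 0.89, c = 13.17, x0 = 177.03),
    Peleg = c(a = 5, b = 0.5, c = 10, d = 5),
    Smith = c(a = -8.05, b = -17.01),
    Halsey = c(a = 2, b = 1.5),
    Henderson = c(a = 0.02, b = 1.5))
  aw <- seq(0.1, 0.9, length.out = 9)
  for (model in names(truths)) {
    p <- isotherm_params(model, truths[[model]])
    d <- sorption_dataset(25, aw, evaluate_isotherm(p, aw))
    f <- fit_model(d, model)
    expect_equal(unname(f$params / truths[[model]][names(f$params)]),
                 rep(1, length(f$params)), tolerance = 1e-5,
                 label = sprintf("%s recovery", model))
  }
})

test_that("every kinetic model recovers its generating parameters", {
  truths <- list(
    zero_order = c(a = 1, b = 2),
    first_order = c(a = 8.48, b = 2.05),
    second_order = c(a = 2, b = 8),
    biexponential = c(A1 = -5, A2 = -3, c = 0.4, d = 2, y0 = 8))
  times <- seq(0.5, 6, by = 0.5)
  for (model in names(truths)) {
    p <- kinetic_params(model, truths[[model]])
    s <- kinetic_series(times, evaluate_kinetic(p, times), 25, 68)
    # the (0,0) anchor belongs to the data only when the truth passes
    # through the origin
    f <- fit_model(s, model, include_origin = evaluate_kinetic(p, 0) == 0)
    expect_equal(unname(f$params / truths[[model]][names(f$params)]),
                 rep(1, length(f$params)), tolerance = 1e-5,
                 label = sprintf("%s recovery", model))
  }
})

test_that("published first-order parameter pairs are recovered at all conditions", {
  times <- seq(0.5, 6, by = 0.5)
  for (cond in names(first_order_truth)) {
    th <- first_order_truth[[cond]]
    p <- kinetic_params("first_order", th)
    s <- kinetic_series(times, evaluate_kinetic(p, times), as.numeric(cond), 68)
    f <- fit_model(s, "first_order")
    expect_equal(unname(f$params), unname(th), tolerance = 1e-6,
                 label = sprintf("first order at %s degC", cond))
  }
})

test_that("underdetermined fits raise a size error", {
  d <- sorption_dataset(25, c(0.4, 0.6), c(2, 5))
  expect_error(fit_model(d, "GAB"), class = "hygrosorb_size_error")
  s <- kinetic_series(c(1, 2), c(3, 4), 25, 68)
  expect_error(fit_model(s, "biexponential", include_origin = FALSE),
               class = "hygrosorb_size_error")
})

test_that("parameter bias under noise stays within twice the empirical SE", {
  truth <- c(a = 8.48, b = 2.05)
  p <- kinetic_params("first_order", truth)
  times <- seq(0.5, 6, by = 0.5)
  mu <- evaluate_kinetic(p, times)
  est <- t(vapply(1:100, function(s) {
    y <- withr::with_seed(1000 + s, mu + rnorm(length(mu), sd = 0.2))
    fit_model(kinetic_series(times, y, 25, 68), "first_order",
              n_starts = 6)$params
  }, numeric(2)))
  for (j in 1:2) {
    bias <- abs(mean(est[, j]) - truth[j])
    se <- sd(est[, j]) / sqrt(nrow(est))
    expect_lt(bias, 2 * sd(est[, j]), label = colnames(est)[j])
    # and the mean itself is close on the SE scale
    expect_lt(bias, 4 * se)
  }
})

test_that("the best objective never worsens with more starts", {
  set.seed(55)
  aw <- salt_aw(32)
  y <- evaluate_isotherm(gab_32, aw) + rnorm(length(aw), sd = 2)
  d <- sorption_dataset(32, aw, y)
  rss <- vapply(c(4, 8, 16, 32), function(ns)
    fit_model(d, "GAB", n_starts = ns)$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("model selection reproduces the published choices and is order-stable", {
  expect_equal(select_best(isotherm_metrics[["25"]]), "Smith")
  expect_equal(select_best(isotherm_metrics[["32"]]), "GAB")
  expect_equal(select_best(isotherm_metrics[["37"]]), "Smith")
  # order invariance
  set.seed(9)
  for (tab in isotherm_metrics) {
    shuffled <- tab[sample(nrow(tab)), ]
    expect_equal(select_best(shuffled), select_best(tab))
  }
  # R2 ties at 4 decimals break on lower RSS
  tie <- data.frame(model = c("A", "B"), r2 = c(0.95, 0.95), rss = c(2, 1),
                    n_params = c(2, 2))
  expect_equal(select_best(tie), "B")
  # then on parameter count
  tie2 <- data.frame(model = c("GAB", "Smith"), r2 = c(0.99, 0.99),
                     rss = c(1, 1))
  expect_equal(select_best(tie2), "Smith")
  expect_error(select_best(list()), class = "hygrosorb_validation_error")
})

test_that("fit results expose asymptotic parameter uncertainties", {
  set.seed(77)
  times <- seq(0.5, 6, by = 0.5)
  mu <- evaluate_kinetic(kinetic_params("first_order", c(a = 8.48, b = 2.05)),
                         times)
  f <- fit_model(kinetic_series(times, mu + rnorm(length(mu), sd = 0.2), 25, 68),
                 "first_order")
  expect_named(f$param_se, c("a", "b"))
  expect_true(all(f$param_se > 0))
  expect_match(f$seed_trace, "seed=")
})
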