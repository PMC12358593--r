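test_that("Gibbs free energy follows -RT ln(aw)", {
  expect_equal(gibbs_free_energy(298.15, 1), 0)
  expect_equal(gibbs_free_energy(350, 1), 0)
  # frozen hand value of 8.314 * 298.15 * ln 2
  expect_equal(gibbs_free_energy(298.15, 0.5), 1718.1864702831411,
               tolerance = 1e-12)
  expect_error(gibbs_free_energy(298.15, 1.1), class = "hygrosorb_domain_error")
  expect_error(gibbs_free_energy(298.15, 0), class = "hygrosorb_domain_error")
  expect_error(gibbs_free_energy(-1, 0.5), class = "hygrosorb_domain_error")
  # strictly decreasing in aw, approaching 0 at saturation
  aw <- seq(0.05, 1, length.out = 100)
  dg <- gibbs_free_energy(298.15, aw)
  expect_true(all(diff(dg) < 0))
  expect_true(all(dg >= 0))
})

test_that("isosteric regression recovers constructed heat and entropy exactly", {
  # construct ln(aw) = -q/(R T) + s/R at the study temperatures, for a
  # ladder of (q, s) pairs; the regression must return them exactly
  temps <- c(298.15, 305.15, 310.15)
  R <- physical_constants()$R
  cases <- list(c(1000, -5), c(1000, 3), c(5000, -5), c(5000, 10),
                c(11665, 30))
  for (case in cases) {
    q <- case[1]; s <- case[2]
    {
      aw_t <- exp(-q / (R * temps) + s / R)
      expect_true(all(aw_t > 0 & aw_t < 1))
      # build per-temperature Smith models that pass through (aw_t, emc = 5)
      fits <- lapply(aw_t, function(a)
        isotherm_params("Smith", c(a = 5 - (-10) * log(1 - a), b = -10)))
      names(fits) <- temps
      pts <- isosteric_analysis(fits, emc_grid = 5)
      expect_equal(pts$qst, q, tolerance = 1e-6 * q)
      expect_equal(pts$ds, s, tolerance = 1e-6 * max(abs(s), 1))
      expect_equal(pts$fit_r2, 1, tolerance = 1e-9)
    }
  }
})

test_that("identical water activities across temperatures give zero heat", {
  temps <- c(298.15, 305.15, 310.15)
  fits <- setNames(replicate(3, smith_25, simplify = FALSE), temps)
  pts <- isosteric_analysis(fits, emc_grid = c(2, 5, 10))
  expect_equal(pts$qst, rep(0, 3), tolerance = 1e-8)
  aw <- invert_isotherm(smith_25, c(2, 5, 10))
  expect_equal(pts$ds, physical_constants()$R * log(aw), tolerance = 1e-8)
})

test_that("isosteric analysis validates its inputs", {
  expect_error(isosteric_analysis(list(`298` = smith_25)),
               class = "hygrosorb_size_error")
  fits <- list(`298.15` = smith_25, `310.15` = smith_37)
  err <- expect_error(isosteric_analysis(fits, emc_grid = 1e6),
                      class = "hygrosorb_range_error")
  expect_match(conditionMessage(err), "T = ")
})

test_that("default EMC grid spans the shared attainable range", {
  # GAB with capacity on the same EMC scale as the Smith curves
  gab_scaled <- default_isotherm_truth()[["32"]]
  fits <- list(`298.15` = smith_25, `305.15` = gab_scaled, `310.15` = smith_37)
  pts <- isosteric_analysis(fits, n_grid = 20)
  expect_equal(nrow(pts), 20)
  expect_true(all(is.finite(pts$qst)) && all(is.finite(pts$ds)))
  # every grid point inverts inside (0, 1) at every temperature
  aw_cols <- grep("^aw_", names(pts))
  expect_true(all(pts[, aw_cols] > 0 & pts[, aw_cols] < 1))
})

test_that("spreading pressure is zero at dryness and grows with humidity", {
  expect_equal(spreading_pressure(gab_32, 305.15, 0), 0)
  # frozen hand substitution with the published GAB constants
  expect_equal(spreading_pressure(gab_32, 305.15, 0.5), 0.097233109043734725,
               tolerance = 1e-12)
  phi <- spreading_pressure(gab_32, 305.15, seq(0, 0.9, length.out = 50))
  expect_true(all(phi >= 0))
  expect_true(all(diff(phi) > 0))
  expect_error(spreading_pressure(gab_32, 305.15, 1 / 0.89),
               class = "hygrosorb_domain_error")
  expect_error(spreading_pressure(smith_25, 305.15, 0.5),
               class = "hygrosorb_unsupported_model_error")
})

test_that("harmonic mean temperature matches its definition and bound", {
  expect_equal(round(harmonic_mean_temperature(c(298.15, 305.15, 310.15)), 2),
               304.40)
  expect_equal(harmonic_mean_temperature(c(300, 300, 300)), 300)
  expect_error(harmonic_mean_temperature(numeric(0)),
               class = "hygrosorb_validation_error")
  expect_error(harmonic_mean_temperature(c(300, -1)),
               class = "hygrosorb_validation_error")
  set.seed(21)
  for (i in 1:50) {
    temps <- runif(sample(2:6, 1), 250, 350)
    expect_lte(harmonic_mean_temperature(temps), mean(temps))
  }
})

test_that("compensation fit recovers a collinear line exactly", {
  pts <- simulate_compensation_series(324.76, 45.57, 0:35)
  cf <- compensation_fit(pts, c(298.15, 305.15, 310.15))
  expect_equal(cf$t_beta, 324.76, tolerance = 1e-9)
  expect_equal(cf$dg_beta, 45.57, tolerance = 1e-9)
  expect_equal(cf$r2, 1, tolerance = 1e-12)
  # isokinetic above harmonic temperature: enthalpy-driven, non-spontaneous
  expect_equal(cf$driving, "enthalpy")
  expect_true(cf$applicable)
  expect_false(cf$spontaneous)
})

test_that("compensation fit handles flat and degenerate inputs", {
  flat <- data.frame(qst = rep(7, 5), ds = 1:5)
  cf <- compensation_fit(flat, c(298.15, 310.15, 320))
  expect_equal(cf$t_beta, 0, tolerance = 1e-10)
  expect_equal(cf$dg_beta, 7, tolerance = 1e-10)
  expect_error(compensation_fit(data.frame(qst = 1:2, ds = 1:2), c(300, 310)),
               class = "hygrosorb_size_error")
  expect_error(compensation_fit(data.frame(qst = 1:5, ds = rep(1, 5)),
                                c(300, 310)),
               class = "hygrosorb_degenerate_error")
})

test_that("classification flips with the harmonic temperature and tolerance", {
  pts <- simulate_compensation_series(324.76, 45.57, 0:10)
  entro <- compensation_fit(pts, c(330, 340, 350))
  expect_equal(entro$driving, "entropy")
  close <- compensation_fit(pts, c(324.5, 324.76, 325))
  expect_false(close$applicable)
  expect_equal(close$driving, "indeterminate")
})
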