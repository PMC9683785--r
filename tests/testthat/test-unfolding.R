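test_that("mean residue-weighted ellipticity normalization", {
  expect_equal(mrw_normalize(5, 50, 0.1, 0.1), 1000)
  expect_equal(mrw_normalize(0, 50, 0.1, 0.1), 0)
  expect_equal(mrw_normalize(-12, 60, 0.04, 1.0), -500)
  expect_error(mrw_normalize(5, 0, 0.1, 0.1), "> 0")
})

test_that("two-state signal model mixes anchored baselines", {
  p <- thermal_params(320, 130)
  # at Tm with flat baselines the signal is the baseline average
  b <- baseline_pair(-4000, 0, -1000, 0)
  expect_equal(predict_unfolding_signal(320, p, b), (-4000 - 1000) / 2)
  # far below Tm the native baseline dominates
  b2 <- baseline_pair(-4000, 5, -1000, 2)
  expect_equal(predict_unfolding_signal(250, p, b2), -4000 + 5 * (250 - 320),
               tolerance = 1e-6)
})

test_that("thermal fit recovers exact model data to optimizer precision", {
  p <- thermal_params(320, 130)
  b <- baseline_pair(-4200, 6, -1200, 2)
  curve <- gen_thermal_curve(p, b, celsius_to_kelvin(seq(20, 95, 0.5)),
                             sigma = 0, seed = 1)
  fit <- fit_thermal_two_state(curve)
  expect_true(fit$converged)
  expect_equal(fit$params$Tm, 320, tolerance = 1e-6)
  expect_equal(fit$params$dH_Tm, 130, tolerance = 1e-6)
  expect_equal(fit$baselines$yN, -4200, tolerance = 1e-6)
  expect_equal(fit$baselines$mU, 2, tolerance = 1e-4)
  # refitting its own output leaves zero residuals
  expect_lt(fit$deviance, 1e-12 * sum(curve$signal^2))
})

test_that("thermal fit recovers the EcRfaH-like CD regime under noise", {
  scn <- kow_scenarios()$EcRfaH_CD_pH7
  truth <- celsius_to_kelvin(ref_thermal_EcRfaH_CD$Tm_C)
  curve <- gen_scenario("EcRfaH_CD_pH7", seed = 7)
  fit <- fit_thermal_two_state(curve)
  expect_true(fit$reliable)
  comb <- sqrt(fit$se[["Tm"]]^2 + ref_thermal_EcRfaH_CD$Tm_se^2)
  expect_lt(abs(fit$params$Tm - truth), 2 * comb)
})

test_that("featureless melts are flagged rather than trusted", {
  x <- celsius_to_kelvin(seq(20, 95, 1))
  curve <- unfolding_curve(x, -3000 + 4 * (x - 300), axis_kind = "temperature")
  fit <- fit_thermal_two_state(curve)
  expect_false(isTRUE(fit$reliable))
})

test_that("melts lacking the unfolded baseline are flagged unreliable", {
  # transition barely begun at the end of the scan
  p <- thermal_params(celsius_to_kelvin(105), 200)
  b <- baseline_pair(-4000, 0, -1000, 0)
  curve <- gen_thermal_curve(p, b, celsius_to_kelvin(seq(20, 95, 0.5)),
                             sigma = 20, seed = 3)
  fit <- fit_thermal_two_state(curve)
  expect_false(isTRUE(fit$reliable))
})

test_that("chemical LEM fit recovers exact model data and the midpoint", {
  p <- lem_params(14.0, 2.98)
  b <- baseline_pair(-2500, 20, -700, 10)
  curve <- gen_chem_curve(p, b, seq(0, 10, length.out = 25), sigma = 0)
  fit <- fit_chemical_lem(curve)
  expect_true(fit$converged)
  expect_equal(fit$params$dG_H2O, 14.0, tolerance = 1e-6)
  expect_equal(fit$params$m_value, 2.98, tolerance = 1e-6)
  # midpoint is derived, not fitted
  expect_identical(fit$midpoint, fit$params$dG_H2O / fit$params$m_value)
  # the model signal at the midpoint sits at the local baseline average
  mid_sig <- predict_unfolding_signal(fit$midpoint, fit$params,
                                      fit$baselines)
  bl_avg <- mean(c(-2500 + 20 * fit$midpoint, -700 + 10 * fit$midpoint))
  expect_equal(mid_sig, bl_avg, tolerance = 1e-6)
})

test_that("LEM fit recovers noisy curves in the VcRfaH urea regime", {
  curve <- gen_scenario("VcRfaH_urea_pH7", seed = 5)
  fit <- fit_chemical_lem(curve)
  expect_true(fit$reliable)
  comb <- sqrt(fit$se[["dG_H2O"]]^2 + ref_lem_VcRfaH_urea$dG_se^2)
  expect_lt(abs(fit$params$dG_H2O - 14.0), 2 * comb)
})

test_that("peak-volume style denaturation (S139 regime) is recoverable", {
  curve <- gen_scenario("S139_NMR_urea", seed = 9)
  fit <- fit_chemical_lem(curve)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$dG_H2O - 7) / 7, 0.35)
  expect_lt(abs(fit$params$m_value - 3.4) / 3.4, 0.35)
})

test_that("all-native series gives no-denaturation flag", {
  # very stable domain: no transition below 10 M
  p <- lem_params(45, 3)
  b <- baseline_pair(-2500, 20, -700, 10)
  curve <- gen_chem_curve(p, b, seq(0, 10, length.out = 25), sigma = 10,
                          seed = 2)
  fit <- fit_chemical_lem(curve)
  expect_false(isTRUE(fit$reliable))
  expect_true(any(grepl("transition|midpoint", fit$flags)))
})

test_that("midpoint identity reproduces printed (dG, m, midpoint) triples", {
  printed <- list(
    list(dG = 19.8, m = 2.51, mid = 7.89),
    list(dG = 22.4, m = 4.18, mid = 5.36),
    list(dG = 6.24, m = 3.25, mid = 1.92),
    list(dG = 10.8, m = 2.91, mid = 3.71),
    list(dG = 27.7, m = 3.84, mid = 7.21),
    list(dG = 26.4, m = 5.71, mid = 4.62),
    list(dG = 14.3, m = 3.83, mid = 3.73),
    list(dG = 14.0, m = 2.98, mid = 4.70),
    list(dG = 11.7, m = 5.22, mid = 2.24),
    list(dG = 15.7, m = 8.26, mid = 1.90),
    list(dG = 45.4, m = 9.02, mid = 5.03),
    list(dG = 7.37, m = 4.95, mid = 1.49),
    list(dG = 2.87, m = 7.71, mid = 0.37))
  for (row in printed) {
    expect_equal(round(lem_midpoint(lem_params(row$dG, row$m)), 2), row$mid)
  }
  expect_equal(lem_midpoint(lem_params(0, 1)), 0)
  expect_error(lem_midpoint(lem_params(10, -1)), "m_value")
})

test_that("fits are invariant to affine rescaling of the signal axis", {
  curve <- gen_scenario("EcRfaH_CD_pH7", seed = 21)
  fit1 <- fit_thermal_two_state(curve)
  curve2 <- curve
  curve2$signal <- 2.5 * curve$signal + 300
  fit2 <- fit_thermal_two_state(curve2)
  expect_equal(fit2$params$Tm, fit1$params$Tm, tolerance = 1e-5)
  expect_equal(fit2$params$dH_Tm, fit1$params$dH_Tm, tolerance = 1e-4)
  expect_equal(fit2$baselines$yN, 2.5 * fit1$baselines$yN + 300,
               tolerance = 1e-4)
})

test_that("parameter recovery is accurate over repeated noisy draws", {
  # thermal: median |Tm error| under 0.5 K at 2% span noise
  errs_tm <- vapply(1:50, function(s) {
    fit <- fit_thermal_two_state(gen_scenario("EcRfaH_CD_pH7", seed = s))
    fit$params$Tm - celsius_to_kelvin(50.3)
  }, numeric(1))
  expect_lt(median(abs(errs_tm)), 0.5)
  # chemical: median relative dG error under 10%
  errs_dg <- vapply(1:50, function(s) {
    fit <- fit_chemical_lem(gen_scenario("VcRfaH_urea_pH7", seed = s))
    (fit$params$dG_H2O - 14.0) / 14.0
  }, numeric(1))
  expect_lt(median(abs(errs_dg)), 0.10)
})

test_that("structured residuals raise the multi-state diagnostic", {
  # superpose two transitions (midpoints ~2.25 and ~4.25 M) and fit one
  x <- seq(0, 8, length.out = 41)
  s1 <- predict_unfolding_signal(x, lem_params(9, 4),
                                 baseline_pair(1, 0, 0.5, 0))
  s2 <- predict_unfolding_signal(x, lem_params(17, 4),
                                 baseline_pair(0.5, 0, 0, 0)) - 0.25
  curve <- unfolding_curve(x, s1 + s2, axis_kind = "urea")
  fit <- fit_chemical_lem(curve)
  expect_true(fit$diagnostics$multistate_suspected)
  expect_true("multi-state suspected" %in% fit$flags)
})

test_that("Savitzky-Golay prefilter smooths without shifting the curve", {
  x <- seq(0, 8, length.out = 81)
  clean <- predict_unfolding_signal(x, lem_params(10, 3),
                                    baseline_pair(1, 0, 0, 0))
  noisy <- clean + withr::with_seed(4, rnorm(81, 0, 0.02))
  sm <- savitzky_golay(noisy, 7)
  expect_length(sm, length(noisy))
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)))
})
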