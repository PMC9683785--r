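make_dsc <- function(a = 0, b = 0, c = 0, Tm = 360.15, dH = 222,
                     a0 = 3, b0 = 0.03) {
  dsc_params(a0, b0, a, b, c, Tm, dH)
}

test_that("model heat capacity has the correct limits", {
  p <- make_dsc()
  # far below the transition only the native baseline remains
  expect_equal(dsc_model_cp(280, p), 3 + 0.03 * 280, tolerance = 1e-8)
  # at Tm with no dCp the excess term is dH^2/(4 R Tm^2)
  expect_equal(dsc_model_cp(p$Tm, p),
               3 + 0.03 * p$Tm + 222^2 / (4 * RGAS * p$Tm^2),
               tolerance = 1e-10)
  # overflow-safe far above the transition: baseline + dCp(T)
  p2 <- make_dsc(a = 1, dH = 500)
  expect_true(is.finite(dsc_model_cp(500, p2)))
  expect_equal(dsc_model_cp(500, p2), 3 + 0.03 * 500 + 1, tolerance = 1e-6)
})

test_that("excess heat integrates to the unfolding enthalpy", {
  p <- make_dsc()
  exc <- function(T_K) dsc_model_cp(T_K, p, components = TRUE)$dCp_exc
  area <- stats::integrate(exc, p$Tm - 40, p$Tm + 40,
                           rel.tol = 1e-9)$value
  expect_equal(area, p$dH_Tm, tolerance = 0.005)
})

test_that("excess heat equals dH * dfU/dT for arbitrary dCp parabolas", {
  p <- make_dsc(a = -2.8, b = 0.0209, c = -3e-5, Tm = 350, dH = 180)
  fU <- function(T_K) {
    hs <- dsc_enthalpy_entropy(T_K, p)
    stats::plogis(-hs$dG / (RGAS * T_K))
  }
  exc <- function(T_K) dsc_model_cp(T_K, p, components = TRUE)$dCp_exc
  lhs <- stats::integrate(exc, 300, 400, rel.tol = 1e-9)$value
  rhs <- stats::integrate(function(T_K) {
    h <- 1e-4
    dsc_enthalpy_entropy(T_K, p)$dH * (fU(T_K + h) - fU(T_K - h)) / (2 * h)
  }, 300, 400, rel.tol = 1e-8)$value
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("internal heat-capacity term is a sigmoid and excess is positive", {
  p <- make_dsc(a = -2.8, b = 0.0209, c = -3e-5, Tm = 350, dH = 180)
  comp <- dsc_model_cp(seq(280, 420, 0.5), p, components = TRUE)
  expect_true(all(comp$dCp_exc >= 0))
  fU_ratio <- comp$dCp_int / dcp_unfolding(comp$T_K, p)
  expect_true(all(diff(fU_ratio) > 0))        # monotone 0 -> 1
  expect_lt(fU_ratio[1], 0.01)
  expect_gt(fU_ratio[nrow(comp)], 0.99)
  # with a = b = c = 0 the peak of the excess term sits at Tm up to the
  # small downward pull of the 1/T^2 prefactor
  p0 <- make_dsc(Tm = 350, dH = 180)
  grid <- seq(300, 400, 0.01)
  exc <- dsc_model_cp(grid, p0, components = TRUE)$dCp_exc
  expect_lt(abs(grid[which.max(exc)] - 350), 0.5)
})

test_that("parabola coefficient comes from an OLS quadratic fit", {
  T_K <- celsius_to_kelvin(c(5, 25, 50, 75, 100, 125))
  expect_equal(cp_parabola_coefficient(data.frame(T_K, Cp = 2 + 3 * T_K)), 0,
               tolerance = 1e-12)
  y <- 1 + 0.1 * T_K - 0.004 * T_K^2
  expect_equal(cp_parabola_coefficient(data.frame(T_K, Cp = y)), -0.004,
               tolerance = 1e-10)
  # symmetric perturbation at the outer temperatures: compare against
  # the closed-form normal equations
  eps <- 0.5
  y2 <- y; y2[1] <- y2[1] + eps; y2[6] <- y2[6] + eps
  X <- cbind(1, T_K, T_K^2)
  beta <- solve(crossprod(X), crossprod(X, y2))
  expect_equal(cp_parabola_coefficient(data.frame(T_K, Cp = y2)), beta[3],
               tolerance = 1e-10)
  expect_error(cp_parabola_coefficient(data.frame(T_K = c(1, 1, 1),
                                                  Cp = c(1, 2, 3))),
               "distinct")
})

test_that("unfolded-state heat capacity sums group contributions", {
  tab <- read_residue_cp_table()
  # additivity: "AA" is exactly one extra A side chain + backbone unit
  p1 <- unfolded_cp_points("A", tab)
  p2 <- unfolded_cp_points("AA", tab)
  extra <- (tab["A", ] + tab["backbone", ]) / 1000
  expect_equal(p2$Cp_U - p1$Cp_U, unname(extra), tolerance = 1e-12)
  # zero-contribution table gives zero everywhere
  zero <- tab; zero[] <- 0
  expect_equal(unfolded_cp_points("ACDEFG", zero)$Cp_U, rep(0, 6))
  # unknown residue is named in the error
  expect_error(unfolded_cp_points("AXZ", tab), "X")
  # packaged table has the rising-then-flattening shape (validated on load)
  d <- apply(tab, 1, diff)
  expect_true(all(d >= 0))
  expect_true(all(d[5, ] < d[1, ]))   # increments shrink with T
  # a decreasing table is rejected at load time
  bad <- tempfile(fileext = ".tsv")
  df <- utils::read.delim(system.file("extdata", "unfolded_cp_synthetic.tsv",
                                      package = "kowtherm"))
  df$T125C[2] <- 0
  utils::write.table(df, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_residue_cp_table(bad), "non-decreasing")
})

test_that("DSC fit recovers exact model data", {
  scn <- kow_scenarios()$EcNusG_DSC_pH7
  p <- do.call(dsc_params, scn$params)
  tg <- gen_dsc(p, celsius_to_kelvin(scn$grid_C), sigma = 0)
  fit <- fit_dsc(tg, c_fixed = p$c)
  expect_true(fit$converged)
  expect_equal(fit$params$Tm, p$Tm, tolerance = 1e-7)
  expect_equal(fit$params$dH_Tm, p$dH_Tm, tolerance = 1e-6)
  expect_equal(fit$params$a, p$a, tolerance = 1e-4)
  expect_equal(fit$params$b0, p$b0, tolerance = 1e-6)
})

test_that("DSC fit recovers the EcNusG calorimetric regime under noise", {
  scn <- kow_scenarios()$EcNusG_DSC_pH7
  p <- do.call(dsc_params, scn$params)
  tg <- gen_scenario("EcNusG_DSC_pH7", seed = 13)
  fit <- fit_dsc(tg, c_fixed = p$c)
  expect_true(fit$reliable)
  comb <- sqrt(fit$se[["Tm"]]^2 + ref_dsc_EcNusG$Tm_se^2)
  expect_lt(abs(fit$params$Tm - p$Tm), 2 * comb)
})

test_that("thermograms without a transition peak are flagged", {
  T_K <- celsius_to_kelvin(seq(5, 130, 0.5))
  flat <- thermogram(T_K, 3 + 0.03 * T_K +
                       withr::with_seed(1, rnorm(length(T_K), 0, 0.05)))
  fit <- fit_dsc(flat, c_fixed = -3e-5)
  expect_false(isTRUE(fit$reliable))
})

test_that("repeated noisy fits show negligible parameter bias", {
  scn <- kow_scenarios()$EcNusG_DSC_pH7
  p <- do.call(dsc_params, scn$params)
  peak <- p$dH_Tm^2 / (4 * RGAS * p$Tm^2)
  ests <- t(vapply(1:20, function(s) {
    tg <- gen_dsc(p, celsius_to_kelvin(seq(5, 130, 0.4)),
                  sigma = 0.005 * peak, seed = 100 + s)
    f <- fit_dsc(tg, c_fixed = p$c)
    c(Tm = f$params$Tm, dH = f$params$dH_Tm, a0 = f$params$a0)
  }, numeric(3)))
  expect_lt(abs(mean(ests[, "Tm"]) - p$Tm) / p$Tm, 0.01)
  expect_lt(abs(mean(ests[, "dH"]) - p$dH_Tm) / p$dH_Tm, 0.01)
  expect_lt(abs(mean(ests[, "a0"]) - p$a0) / p$a0, 0.01)
})
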