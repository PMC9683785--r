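test_that("saturation profile has the expected one-state limits", {
  sp <- spin_params(118, -3, 1.5, 8, 20)
  nearly_one_state <- exchange_params(1e-4, 0.01)
  offs <- seq(110, 126, 0.25)
  y <- simulate_cest(sp, nearly_one_state, 13, 0.5, offs, 60.81)
  # single dip at the major resonance
  expect_equal(offs[which.min(y)], 118)
  # no secondary dip at the minor position
  i_minor <- which.min(abs(offs - 115))
  expect_gt(y[i_minor], 0.9 * exp(-1.5 * 0.5))
  # far-offset limit: pure longitudinal decay
  y_far <- simulate_cest(sp, nearly_one_state, 13, 0.5, 400, 60.81)
  expect_equal(y_far, exp(-1.5 * 0.5), tolerance = 1e-3)
})

test_that("matrix-exponential propagation matches ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(31)
  for (i in 1:5) {
    sp <- spin_params(runif(1, 105, 130), runif(1, -5, 5),
                      runif(1, 0.5, 3), runif(1, 4, 30), runif(1, 10, 60))
    ex <- exchange_params(runif(1, 0.002, 0.2), runif(1, 5, 300))
    offs <- sp$delta_A + c(-4, -1, 0, 0.5, 3)
    y1 <- simulate_cest(sp, ex, 17, 0.4, offs, 60.81)
    y2 <- ode_cest(sp, ex, 17, 0.4, offs, 60.81)
    expect_lt(max(abs(y1 - y2)), 1e-8)
  }
})

test_that("saturation only removes magnetization", {
  sp <- spin_params(118, -3, 1.5, 8, 20)
  ex <- exchange_params(0.055, 15)
  y <- simulate_cest(sp, ex, 26, 0.5, seq(108, 128, 0.25), 60.81)
  expect_true(all(y <= exp(-1.5 * 0.5) * (1 + 1e-9)))
  expect_true(all(y > -1e-9))
})

test_that("state-label swap mirrors the profile", {
  sp <- spin_params(118, -3, 1.5, 8, 20)
  ex <- exchange_params(0.055, 15)
  offs <- seq(108, 128, 0.25)
  y_A <- simulate_cest(sp, ex, 13, 0.5, offs, 60.81)
  # swapped labels: B is now the major state at delta_A + delta_omega,
  # with opposite shift difference and swapped R2; read Iz_B / pB via the
  # same entry point by relabelling
  sp_swap <- spin_params(118 - 3, +3, 1.5, 20, 8)
  ex_swap <- exchange_params(ex$pB, ex$kex)        # same rates, roles swapped
  # evolve the swapped system and compare against direct propagation of the
  # original generator read out on state B
  y_swap <- simulate_cest(sp_swap, ex_swap, 13, 0.5, offs, 60.81)
  v0 <- c(0, 0, ex$pA, 0, 0, ex$pB)
  y_B <- vapply(offs, function(off) {
    # original generator with populations swapped: A minor, B major
    ex2 <- list(pA = ex$pB, pB = ex$pA, k_AB = ex$k_BA, k_BA = ex$k_AB)
    L <- kowtherm:::bloch_mcconnell_generator(off, 13, sp, ex2, 60.81)
    v <- c(0, 0, ex2$pA, 0, 0, ex2$pB)
    as.numeric(Matrix::expm(L * 0.5) %*% v)[6] / ex2$pB
  }, numeric(1))
  expect_equal(y_swap, y_B, tolerance = 1e-10)
})

test_that("minor species shifts follow the sign convention", {
  expect_equal(minor_species_shift(120, 0), 120)
  expect_equal(minor_species_shift(120, -2.5), 117.5)
  # the simulated secondary dip sits at delta_B
  sp <- spin_params(120, -3, 1.5, 8, 20)
  ex <- exchange_params(0.08, 20)
  offs <- seq(112, 128, 0.1)
  y <- simulate_cest(sp, ex, 13, 0.5, offs, 60.81)
  away <- abs(offs - 120) > 1
  minor_dip <- offs[away][which.min(y[away])]
  expect_equal(minor_dip, minor_species_shift(120, -3), tolerance = 0.11)
})

test_that("exchange parameters satisfy their identities", {
  # printed global-fit columns: kex must equal kAB + kBA
  h <- exchange_thermodynamics(0.0085, 89.38)
  expect_equal(h$k_AB + h$k_BA, 89.38)
  expect_equal(h$k_AB, 0.76, tolerance = 0.01)
  expect_equal(h$tau_A, 1.31, tolerance = 0.01)
  ec <- exchange_thermodynamics(0.0553, 14.80)
  expect_equal(ec$k_AB, 0.82, tolerance = 0.01)
  expect_equal(ec$k_BA, 13.98, tolerance = 0.01)
  expect_equal(1000 * ec$tau_B, 71.52, tolerance = 0.1)
  # symmetric exchange lifetimes
  sym <- exchange_thermodynamics(0.4999999, 100)
  expect_equal(sym$tau_A, 0.02, tolerance = 1e-5)
  # detailed balance holds exactly on random instances
  set.seed(17)
  for (i in 1:20) {
    e <- exchange_params(runif(1, 1e-4, 0.49), runif(1, 0.1, 1000))
    expect_identical(e$k_AB + e$k_BA, e$kex)
    expect_equal(e$k_AB * e$pA, e$k_BA * e$pB, tolerance = 1e-14)
  }
  expect_error(exchange_params(0.6, 10), "pB")
  expect_error(exchange_params(0.1, -1), "kex")
})

test_that("per-residue fit recovers noise-free profiles exactly", {
  sp <- spin_params(118, -3, 1.5, 8, 20)
  ex <- exchange_params(0.055, 15)
  offs <- seq(112, 124, 0.5)
  profs <- lapply(c(13, 26), function(n1) {
    cest_profile("r1", offs, simulate_cest(sp, ex, n1, 0.5, offs, 60.81),
                 nu1_Hz = n1, freq_MHz = 60.81)
  })
  fit <- fit_cest_residue(profs)
  expect_true(fit$converged)
  expect_equal(fit$exchange$pB, 0.055, tolerance = 1e-5)
  expect_equal(fit$exchange$kex, 15, tolerance = 1e-4)
  expect_equal(fit$spin$delta_omega, -3, tolerance = 1e-5)
  expect_equal(fit$spin$R2_B, 20, tolerance = 1e-2)
})

test_that("per-residue fit recovers a noisy EcRfaH-like residue within error", {
  sp <- spin_params(118, -3, 1.5, 8, 20)
  ex <- exchange_params(0.055, 15)
  offs <- seq(110, 126, 0.25)
  profs <- withr::with_seed(23, lapply(c(13, 26), function(n1) {
    y <- simulate_cest(sp, ex, n1, 0.5, offs, 60.81) +
      rnorm(length(offs), 0, 0.01)
    cest_profile("r1", offs, y, nu1_Hz = n1, freq_MHz = 60.81)
  }))
  fit <- fit_cest_residue(profs)
  expect_true(fit$converged)
  expect_lt(abs(fit$exchange$pB - 0.055), 2 * fit$se[["pB"]] + 0.005)
  expect_lt(abs(fit$exchange$kex - 15), 2 * fit$se[["kex"]] + 1.5)
})

test_that("profiles without a shift difference are flagged degenerate", {
  sp <- spin_params(118, 0, 1.5, 8, 20)
  ex <- exchange_params(0.055, 15)
  offs <- seq(112, 124, 0.5)
  profs <- lapply(c(13, 26), function(n1) {
    cest_profile("r1", offs, simulate_cest(sp, ex, n1, 0.5, offs, 60.81),
                 nu1_Hz = n1, freq_MHz = 60.81)
  })
  fit <- fit_cest_residue(profs)
  expect_true(length(fit$flags) > 0)
  expect_true(any(grepl("no resolvable minor dip|poorly determined",
                        fit$flags)))
})

test_that("global fit shares exchange parameters and applies the dw filter", {
  ex <- exchange_params(0.055, 15)
  spins <- small_cest_spins(3)
  # add a residue below the inclusion threshold
  spins$res_small <- spin_params(119, 0.5, 1.5, 8, 20)
  data <- gen_cest(spins, ex, nu1_Hz = c(13, 26), sigma = 0.008, seed = 41,
                   offset_halfwidth = 6, offset_step = 0.5)
  fit <- fit_cest_global(data, dw_min = 1)
  expect_true(fit$converged)
  expect_true("res_small" %in% fit$excluded)
  expect_setequal(fit$included, c("res1", "res2", "res3"))
  expect_lt(abs(fit$exchange$pB - 0.055), 3 * fit$se[["pB"]] + 0.01)
  # duplicating one residue's profiles must not move the shared estimates
  data2 <- data
  data2$res1_copy <- data$res1
  fit2 <- fit_cest_global(data2, dw_min = 1)
  expect_equal(fit2$exchange$pB, fit$exchange$pB, tolerance = 0.02)
  expect_equal(fit2$exchange$kex, fit$exchange$kex, tolerance = 0.05)
})

test_that("global fit refuses underdetermined datasets", {
  ex <- exchange_params(0.055, 15)
  spins <- list(r1 = spin_params(118, 0.3, 1.5, 8, 20),
                r2 = spin_params(120, 0.4, 1.5, 8, 20))
  data <- gen_cest(spins, ex, nu1_Hz = c(13, 26), sigma = 0,
                   offset_halfwidth = 5, offset_step = 0.5)
  expect_error(fit_cest_global(data, dw_min = 1), ">= 2 residues")
})

test_that("minor-shift comparison computes correlation and rmsd", {
  v <- c(a = 1, b = 2, c = 4, d = 7)
  same <- compare_to_reference(v, v)
  expect_equal(same$r_squared, 1)
  expect_equal(same$rmsd, 0)
  shifted <- compare_to_reference(v + 0.8, v)
  expect_equal(shifted$r_squared, 1)
  expect_equal(shifted$rmsd, 0.8)
  expect_equal(shifted$differences, setNames(rep(0.8, 4), names(v)))
  # brute-force formula oracle on a seeded random pairing
  set.seed(3)
  m <- setNames(rnorm(10, 120, 3), paste0("r", 1:10))
  r <- setNames(m + rnorm(10, 0, 0.5), names(m))
  cmp <- compare_to_reference(m, r)
  d <- m - r
  expect_equal(cmp$rmsd, sqrt(sum(d^2) / 10))
  expect_equal(cmp$r_squared,
               (sum((m - mean(m)) * (r - mean(r)))^2 /
                  (sum((m - mean(m))^2) * sum((r - mean(r))^2))))
  expect_error(compare_to_reference(v[1:2], v[1:2]), ">= 3")
})
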