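#' Construct a spectroscopic unfolding curve
#'
#' Holds an `(x, signal)` series from CD, fluorescence, or NMR peak-volume
#' detection, with the metadata the fitters need. The x axis is either
#' absolute temperature (thermal melts) or denaturant concentration
#' (chemical denaturation). Points are sorted by x on ingest; NA rows are
#' dropped with a warning.
#'
#' @param x temperature (K, unless `x_unit = "C"`) or denaturant
#'   concentration (M)
#' @param signal observed signal (mean residue-weighted ellipticity in
#'   deg cm^2/dmol, fluorescence intensity, or normalized peak volume)
#' @param axis_kind one of `"temperature"`, `"urea"`, `"GdmCl"`
#' @param technique one of `"CD_far_UV"`, `"CD_near_UV"`, `"fluorescence"`,
#'   `"NMR_peak_volume"`
#' @param x_unit `"K"`, `"C"` or `"M"`; Celsius input is converted to Kelvin
#' @param pH,protein,wavelength_nm optional condition metadata
#' @return object of class `unfolding_curve`
#' @export
unfolding_curve <- function(x, signal,
                            axis_kind = c("temperature", "urea", "GdmCl"),
                            technique = c("CD_far_UV", "CD_near_UV",
                                          "fluorescence", "NMR_peak_volume"),
                            x_unit = NULL,
                            pH = NA_real_, protein = NA_character_,
                            wavelength_nm = NA_real_) {
  axis_kind <- match.arg(axis_kind)
  technique <- match.arg(technique)
  if (length(x) != length(signal)) stop("x and signal must have equal length")
  if (is.null(x_unit)) x_unit <- if (axis_kind == "temperature") "K" else "M"
  if (axis_kind == "temperature" && x_unit == "C") x <- celsius_to_kelvin(x)
  if (axis_kind != "temperature" && x_unit != "M") {
    stop("denaturant axes must be in M")
  }
  keep <- is.finite(x) & is.finite(signal)
  if (!all(keep)) {
    warning(sprintf("dropping %d non-finite point(s)", sum(!keep)))
    x <- x[keep]; signal <- signal[keep]
  }
  ord <- order(x)
  x <- x[ord]; signal <- signal[ord]
  if (anyDuplicated(x)) {
    # replicate concentrations are legitimate; keep them but never identical
    # rows produced by accident at ingest
    x <- x + 0
  }
  structure(
    list(x = x, signal = signal, axis_kind = axis_kind,
         technique = technique, pH = pH, protein = protein,
         wavelength_nm = wavelength_nm),
    class = "unfolding_curve")
}

#' @export
print.unfolding_curve <- function(x, ...) {
  cat(sprintf("<unfolding_curve> %s / %s, %d points, x in [%.3g, %.3g]\n",
              x$technique, x$axis_kind, length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' Mean residue-weighted ellipticity
#'
#' `Theta_MRW = 100 * theta / (N * c * d)` converts a raw ellipticity in mdeg
#' to deg cm^2/dmol.
#'
#' @param theta ellipticity, mdeg (any sign, vectorised)
#' @param n_residues number of amino acids (> 0)
#' @param conc_mM protein concentration, mM (> 0)
#' @param path_cm cuvette pathlength, cm (> 0)
#' @return mean residue-weighted ellipticity, deg cm^2/dmol
#' @export
#' @examples
#' mrw_normalize(5, 50, 0.1, 0.1)   # 1000
mrw_normalize <- function(theta, n_residues, conc_mM, path_cm) {
  if (n_residues <= 0 || conc_mM <= 0 || path_cm <= 0) {
    stop("n_residues, conc_mM and path_cm must all be > 0")
  }
  100 * theta / (n_residues * conc_mM * path_cm)
}

#' Evaluate the two-state unfolding signal model
#'
#' Thermal melts: `S(T) = fN (yN + mN (T - Tm)) + (1 - fN)(yU + mU (T - Tm))`
#' with `fN` from the van't Hoff Gibbs energy (baselines anchored at `Tm`).
#' Chemical denaturation: `S(d) = fN (yN + mN d) + (1 - fN)(yU + mU d)` with
#' the linear extrapolation Gibbs energy evaluated at `T_K`.
#'
#' @param x temperature (K) or denaturant concentration (M)
#' @param params [thermal_params()] or [lem_params()]
#' @param baselines [baseline_pair()]
#' @param T_K evaluation temperature for chemical curves (default 298.15 K)
#' @return model signal at `x`
#' @export
predict_unfolding_signal <- function(x, params, baselines, T_K = .TREF) {
  b <- baselines
  if (inherits(params, "thermal_params")) {
    dG <- dG_thermal(x, params$Tm, params$dH_Tm)
    fN <- folded_fraction(equilibrium_constant(dG, x))
    fN * (b$yN + b$mN * (x - params$Tm)) +
      (1 - fN) * (b$yU + b$mU * (x - params$Tm))
  } else if (inherits(params, "lem_params")) {
    dG <- dG_chemical(x, params$dG_H2O, params$m_value)
    fN <- folded_fraction(equilibrium_constant(dG, T_K))
    fN * (b$yN + b$mN * x) + (1 - fN) * (b$yU + b$mU * x)
  } else {
    stop("params must be thermal_params or lem_params")
  }
}

#' Transition midpoint of a chemical denaturation
#'
#' `[denat]_1/2 = dG_H2O / m`: the denaturant concentration at which folded
#' and unfolded states are equally populated.
#'
#' @param params [lem_params()] (or anything with `dG_H2O` and `m_value`)
#' @return midpoint, M
#' @export
#' @examples
#' lem_midpoint(lem_params(19.8, 2.51))   # 7.89 M
lem_midpoint <- function(params) {
  if (params$m_value <= 0) stop("m_value must be > 0 for a midpoint")
  params$dG_H2O / params$m_value
}

# Wald-Wolfowitz runs test on residual signs (normal approximation).
# Small p -> residuals are serially structured, i.e. the two-state model is
# systematically missing signal (multi-state behaviour suspected).
runs_test_pvalue <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 == 0 || n2 == 0 || n < 8) return(NA_real_)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  # one-sided: too few runs = clumped residuals
  stats::pnorm((runs - mu) / sqrt(v))
}

# standard errors from a converged nls.lm fit; NA if the information matrix
# is singular (degenerate data)
.nlslm_se <- function(fit, n_resid) {
  p <- length(fit$par)
  dof <- max(n_resid - p, 1)
  s2 <- fit$deviance / dof
  vc <- try(solve(fit$hessian) * s2, silent = TRUE)
  if (inherits(vc, "try-error")) return(rep(NA_real_, p))
  d <- diag(vc)
  d[d < 0] <- NA_real_
  sqrt(d)
}

# end-tertile linear baselines + steepest-descent midpoint heuristics
.baseline_guess <- function(x, y) {
  n <- length(x)
  lo <- seq_len(max(3, floor(n / 4)))
  hi <- seq(n - max(3, floor(n / 4)) + 1, n)
  fN <- stats::coef(stats::lm(y[lo] ~ x[lo]))
  fU <- stats::coef(stats::lm(y[hi] ~ x[hi]))
  sm <- if (n >= 7) stats::filter(y, rep(1 / 3, 3), sides = 2) else y
  sm[is.na(sm)] <- y[is.na(sm)]
  dy <- diff(as.numeric(sm)) / diff(x)
  x_mid <- x[which.max(abs(dy))]
  list(iN = unname(fN[1]), sN = unname(fN[2]),
       iU = unname(fU[1]), sU = unname(fU[2]), x_mid = x_mid)
}

.fit_quality <- function(x, y, fitted_y, fN_hat) {
  resid <- y - fitted_y
  list(
    residual_norm = sqrt(sum(resid^2)),
    runs_p = runs_test_pvalue(resid),
    multistate_suspected = isTRUE(runs_test_pvalue(resid) < 0.01),
    baseline_coverage = c(native = max(fN_hat), unfolded = 1 - min(fN_hat))
  )
}

#' Fit a two-state thermal unfolding curve
#'
#' Nonlinear least squares over `{Tm, dH_Tm, yN, mN, yU, mU}` for the
#' anchored-baseline two-state melt model (see
#' [predict_unfolding_signal()]). When no initial guesses are supplied, a
#' small multi-start is run from heuristic initialisations (midpoint from the
#' steepest signal change, baselines from the end tertiles, a ladder of
#' enthalpy guesses) and the best converged fit is kept.
#'
#' The fit is flagged `reliable = FALSE` when either baseline is not covered
#' by the data (folded fraction never near 0 or 1 within the scanned range,
#' as for a melt lacking the unfolded-state baseline) or when the fitted `Tm`
#' falls outside the scanned range extended by 20%. A Wald-Wolfowitz runs
#' test on the residual signs (p < 0.01) raises `multistate_suspected`.
#'
#' @param curve an [unfolding_curve()] with `axis_kind = "temperature"`
#' @param init optional named list/vector with any of
#'   `Tm, dH_Tm, yN, mN, yU, mU`
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return list of class `thermal_fit`: `params` ([thermal_params()]),
#'   `baselines` ([baseline_pair()]), `se` (named std. errors), `converged`,
#'   `reliable`, `flags`, `diagnostics`, `fitted`, `curve`
#' @export
fit_thermal_two_state <- function(curve, init = NULL,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500, maxfev = 100000, ftol = 1e-13, ptol = 1e-13)) {
  stopifnot(inherits(curve, "unfolding_curve"))
  if (curve$axis_kind != "temperature") {
    stop("fit_thermal_two_state requires a temperature axis")
  }
  x <- curve$x; y <- curve$signal
  if (length(x) < 8) stop("need at least 8 points to fit")

  model <- function(p) {
    predict_unfolding_signal(
      x, thermal_params(p[["Tm"]], p[["dH_Tm"]]),
      baseline_pair(p[["yN"]], p[["mN"]], p[["yU"]], p[["mU"]]))
  }
  resid_fn <- function(p) y - model(p)

  g <- .baseline_guess(x, y)
  starts <- list()
  if (!is.null(init)) {
    p0 <- c(Tm = g$x_mid, dH_Tm = 150,
            yN = g$iN + g$sN * g$x_mid, mN = g$sN,
            yU = g$iU + g$sU * g$x_mid, mU = g$sU)
    p0[names(init)] <- unlist(init)
    starts <- list(p0)
  } else {
    for (dH0 in c(80, 150, 250)) {
      starts[[length(starts) + 1]] <-
        c(Tm = g$x_mid, dH_Tm = dH0,
          yN = g$iN + g$sN * g$x_mid, mN = g$sN,
          yU = g$iU + g$sU * g$x_mid, mU = g$sU)
    }
  }

  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(par = p0, fn = resid_fn,
                                  lower = c(Tm = min(x) - 0.5 * diff(range(x)),
                                            dH_Tm = 1, yN = -Inf, mN = -Inf,
                                            yU = -Inf, mU = -Inf),
                                  control = control), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, reliable = FALSE,
                          message = "all starts failed", curve = curve),
                     class = "thermal_fit"))
  }

  p <- best$par
  se <- .nlslm_se(best, length(y))
  names(se) <- names(p)
  fitted_y <- model(p)
  dG <- dG_thermal(x, p[["Tm"]], p[["dH_Tm"]])
  fN_hat <- folded_fraction(equilibrium_constant(dG, x))
  q <- .fit_quality(x, y, fitted_y, fN_hat)

  span20 <- 0.2 * diff(range(x))
  tm_in_range <- p[["Tm"]] >= min(x) - span20 && p[["Tm"]] <= max(x) + span20
  cover <- q$baseline_coverage["native"] > 0.9 &&
    q$baseline_coverage["unfolded"] > 0.9
  # the transition amplitude (baseline separation at Tm) must stand clear
  # of the fit noise, otherwise any step placed anywhere "fits"
  resid_sd <- sqrt(best$deviance / max(length(y) - length(p), 1))
  amplitude_seen <- abs(p[["yN"]] - p[["yU"]]) > 5 * resid_sd
  converged <- best$info %in% 1:4
  flags <- character(0)
  if (!cover) flags <- c(flags, "insufficient baseline coverage")
  if (!tm_in_range) flags <- c(flags, "Tm outside scanned range")
  if (!amplitude_seen) flags <- c(flags, "transition amplitude below noise")
  if (q$multistate_suspected) flags <- c(flags, "multi-state suspected")

  structure(list(
    params = thermal_params(p[["Tm"]], p[["dH_Tm"]]),
    baselines = baseline_pair(p[["yN"]], p[["mN"]], p[["yU"]], p[["mU"]]),
    se = se, converged = converged,
    reliable = converged && cover && tm_in_range && amplitude_seen,
    flags = flags, diagnostics = q, fitted = fitted_y, curve = curve,
    deviance = best$deviance, message = best$message),
    class = "thermal_fit")
}

#' @export
print.thermal_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<thermal_fit> NOT converged:", x$message, "\n"); return(invisible(x))
  }
  cat(sprintf("<thermal_fit> Tm = %.2f K (%.2f degC) +/- %.2f, dHu(Tm) = %.1f +/- %.1f kJ/mol\n",
              x$params$Tm, kelvin_to_celsius(x$params$Tm), x$se[["Tm"]],
              x$params$dH_Tm, x$se[["dH_Tm"]]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit a chemical denaturation by the linear extrapolation method
#'
#' Nonlinear least squares over `{dG_H2O, m, yN, mN, yU, mU}` for the
#' two-state denaturation model; applies equally to far-UV CD, fluorescence
#' and normalized NMR peak-volume detection. The midpoint is derived as
#' `dG_H2O / m`, never fitted independently.
#'
#' All-native or all-unfolded series (no transition inside the measured
#' range, as for a domain that cannot be denatured) yield
#' `reliable = FALSE` with an explanatory flag. A runs test on residual
#' signs (p < 0.01) raises `multistate_suspected`, mirroring domains whose
#' denaturation is not two-state.
#'
#' @param curve an [unfolding_curve()] with a denaturant axis
#' @param init optional named list/vector with any of
#'   `dG_H2O, m_value, yN, mN, yU, mU`
#' @param T_K temperature of the denaturation (default 298.15 K)
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return list of class `lem_fit`: `params` ([lem_params()]), `baselines`,
#'   `midpoint` (M, derived), `se`, `converged`, `reliable`, `flags`,
#'   `diagnostics`, `fitted`, `curve`
#' @export
fit_chemical_lem <- function(curve, init = NULL, T_K = .TREF,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500, maxfev = 100000, ftol = 1e-13, ptol = 1e-13)) {
  stopifnot(inherits(curve, "unfolding_curve"))
  if (!curve$axis_kind %in% c("urea", "GdmCl")) {
    stop("fit_chemical_lem requires a denaturant axis (urea or GdmCl)")
  }
  x <- curve$x; y <- curve$signal
  if (length(x) < 8) stop("need at least 8 points to fit")

  model <- function(p) {
    predict_unfolding_signal(
      x, lem_params(p[["dG_H2O"]], p[["m_value"]]),
      baseline_pair(p[["yN"]], p[["mN"]], p[["yU"]], p[["mU"]]), T_K = T_K)
  }
  resid_fn <- function(p) y - model(p)

  g <- .baseline_guess(x, y)
  starts <- list()
  if (!is.null(init)) {
    p0 <- c(dG_H2O = 3 * max(g$x_mid, 0.5), m_value = 3,
            yN = g$iN, mN = g$sN, yU = g$iU, mU = g$sU)
    p0[names(init)] <- unlist(init)
    starts <- list(p0)
  } else {
    for (m0 in c(1, 3, 6)) {
      starts[[length(starts) + 1]] <-
        c(dG_H2O = m0 * max(g$x_mid, 0.5), m_value = m0,
          yN = g$iN, mN = g$sN, yU = g$iU, mU = g$sU)
    }
  }

  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(par = p0, fn = resid_fn,
                                  lower = c(dG_H2O = -Inf, m_value = 1e-3,
                                            yN = -Inf, mN = -Inf,
                                            yU = -Inf, mU = -Inf),
                                  control = control), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, reliable = FALSE,
                          message = "all starts failed", curve = curve),
                     class = "lem_fit"))
  }

  p <- best$par
  se <- .nlslm_se(best, length(y))
  names(se) <- names(p)
  fitted_y <- model(p)
  dG <- dG_chemical(x, p[["dG_H2O"]], p[["m_value"]])
  fN_hat <- folded_fraction(equilibrium_constant(dG, T_K))
  q <- .fit_quality(x, y, fitted_y, fN_hat)

  mid <- p[["dG_H2O"]] / p[["m_value"]]
  transition_seen <- max(fN_hat) > 0.9 && min(fN_hat) < 0.1
  mid_in_range <- mid >= min(x) && mid <= max(x)
  # baseline separation at the midpoint must stand clear of the fit noise
  resid_sd <- sqrt(best$deviance / max(length(y) - length(p), 1))
  amp <- abs((p[["yN"]] + p[["mN"]] * mid) - (p[["yU"]] + p[["mU"]] * mid))
  amplitude_seen <- amp > 5 * resid_sd
  converged <- best$info %in% 1:4
  flags <- character(0)
  if (!transition_seen) flags <- c(flags, "no complete transition in range")
  if (!mid_in_range) flags <- c(flags, "midpoint outside measured range")
  if (!amplitude_seen) flags <- c(flags, "transition amplitude below noise")
  if (q$multistate_suspected) flags <- c(flags, "multi-state suspected")

  structure(list(
    params = lem_params(p[["dG_H2O"]], p[["m_value"]]),
    baselines = baseline_pair(p[["yN"]], p[["mN"]], p[["yU"]], p[["mU"]]),
    midpoint = mid, se = se, converged = converged,
    reliable = converged && transition_seen && mid_in_range &&
      amplitude_seen,
    flags = flags, diagnostics = q, fitted = fitted_y, curve = curve,
    deviance = best$deviance, message = best$message),
    class = "lem_fit")
}

#' @export
print.lem_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<lem_fit> NOT converged:", x$message, "\n"); return(invisible(x))
  }
  cat(sprintf("<lem_fit> dGu(H2O) = %.2f +/- %.2f kJ/mol, m = %.2f +/- %.2f kJ/(mol M), midpoint = %.2f M\n",
              x$params$dG_H2O, x$se[["dG_H2O"]],
              x$params$m_value, x$se[["m_value"]], x$midpoint))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Savitzky-Golay pre-filter for noisy near-UV CD series
#'
#' Optional smoothing applied before fitting titration-style near-UV data;
#' plain quadratic SG convolution with edge padding. Off by default in every
#' fitting path.
#'
#' @param y signal vector
#' @param width odd window width (default 5)
#' @return smoothed vector, same length
#' @export
savitzky_golay <- function(y, width = 5) {
  if (width %% 2 != 1 || width < 3) stop("width must be odd and >= 3")
  half <- (width - 1) / 2
  i <- -half:half
  A <- cbind(1, i, i^2)
  w <- solve(crossprod(A), t(A))[1, ]   # centre-point quadratic weights
  ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(ypad, rev(w), sides = 2))[(half + 1):(half + length(y))]
}
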