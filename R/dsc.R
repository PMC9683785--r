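#' Construct a molar-normalized DSC thermogram
#'
#' @param T_K temperatures, K (strictly increasing after sorting); use
#'   `x_unit = "C"` for Celsius input
#' @param Cp molar heat capacity, kJ/(K mol)
#' @param x_unit `"K"` (default) or `"C"`
#' @param scan_rate_K_min,protein,pH optional metadata
#' @return object of class `thermogram`
#' @export
thermogram <- function(T_K, Cp, x_unit = "K", scan_rate_K_min = NA_real_,
                       protein = NA_character_, pH = NA_real_) {
  if (length(T_K) != length(Cp)) stop("T and Cp must have equal length")
  if (x_unit == "C") T_K <- celsius_to_kelvin(T_K)
  keep <- is.finite(T_K) & is.finite(Cp)
  if (!all(keep)) {
    warning(sprintf("dropping %d non-finite point(s)", sum(!keep)))
    T_K <- T_K[keep]; Cp <- Cp[keep]
  }
  ord <- order(T_K)
  T_K <- T_K[ord]; Cp <- Cp[ord]
  if (length(T_K) < 50) stop("a thermogram needs at least 50 points")
  if (any(diff(T_K) <= 0)) stop("temperatures must be strictly increasing")
  structure(list(T_K = T_K, Cp = Cp, scan_rate_K_min = scan_rate_K_min,
                 protein = protein, pH = pH),
            class = "thermogram")
}

#' DSC model parameters
#'
#' Native baseline `Cp_0(T) = a0 + b0 T` (the intercept absorbs any
#' instrument-specific offset), unfolding heat-capacity change
#' `dCp_u(T) = a + b T + c T^2` (with `c` conventionally held fixed during
#' fitting), and the two-state transition parameters `(Tm, dH_Tm)`.
#'
#' @param a0,b0 native baseline intercept (kJ/(K mol)) and slope
#'   (kJ/(K^2 mol))
#' @param a,b,c heat-capacity-change parabola coefficients
#'   (kJ/(K mol), kJ/(K^2 mol), kJ/(K^3 mol))
#' @param Tm transition temperature, K
#' @param dH_Tm unfolding enthalpy at `Tm`, kJ/mol (> 0)
#' @return list of class `dsc_params`
#' @export
dsc_params <- function(a0, b0, a, b, c, Tm, dH_Tm) {
  v <- c(a0, b0, a, b, c, Tm, dH_Tm)
  if (any(!is.finite(v))) stop("all DSC parameters must be finite")
  if (Tm <= 0) stop("Tm must be > 0 K")
  if (dH_Tm <= 0) stop("dH_Tm must be > 0")
  structure(list(a0 = a0, b0 = b0, a = a, b = b, c = c,
                 Tm = Tm, dH_Tm = dH_Tm), class = "dsc_params")
}

#' Heat-capacity change of unfolding at a temperature
#'
#' `dCp_u(T) = a + b T + c T^2`.
#'
#' @param T_K temperature, K (vectorised)
#' @param p [dsc_params()]
#' @return kJ/(K mol)
#' @export
dcp_unfolding <- function(T_K, p) p$a + p$b * T_K + p$c * T_K^2

#' Temperature-dependent unfolding enthalpy and entropy
#'
#' Kirchhoff integration of the parabolic heat-capacity change from `Tm`:
#' `dH(T) = dH_Tm + a (T - Tm) + b/2 (T^2 - Tm^2) + c/3 (T^3 - Tm^3)` and
#' `dS(T) = dH_Tm/Tm + a ln(T/Tm) + b (T - Tm) + c/2 (T^2 - Tm^2)`.
#'
#' @param T_K temperature, K (vectorised)
#' @param p [dsc_params()]
#' @return list with `dH` (kJ/mol), `dS` (kJ/(K mol)), `dG` (kJ/mol)
#' @export
dsc_enthalpy_entropy <- function(T_K, p) {
  dH <- p$dH_Tm + p$a * (T_K - p$Tm) + p$b / 2 * (T_K^2 - p$Tm^2) +
    p$c / 3 * (T_K^3 - p$Tm^3)
  dS <- p$dH_Tm / p$Tm + p$a * log(T_K / p$Tm) + p$b * (T_K - p$Tm) +
    p$c / 2 * (T_K^2 - p$Tm^2)
  list(dH = dH, dS = dS, dG = dH - T_K * dS)
}

#' Model molar heat capacity of a two-state DSC thermogram
#'
#' `Cp(T) = Cp_0 + dCp_int + dCp_exc` where `Cp_0 = a0 + b0 T` is the native
#' baseline, `dCp_int = dCp_u(T) Ku/(1 + Ku)` is the population-weighted
#' internal heat-capacity change, and
#' `dCp_exc = dH(T)^2 / (R T^2) * Ku/(1 + Ku)^2` is the excess heat
#' absorption of the transition. `Ku` comes from the Kirchhoff-integrated
#' Gibbs energy; the population fractions are evaluated in log-space
#' (`plogis`) so very large or small `Ku` cannot overflow.
#'
#' @param T_K temperature, K (vectorised)
#' @param p [dsc_params()]
#' @param components if `TRUE` return a data.frame with the three terms
#' @return kJ/(K mol), or a data.frame when `components = TRUE`
#' @export
dsc_model_cp <- function(T_K, p, components = FALSE) {
  if (any(T_K <= 0)) stop("temperature must be > 0 K")
  hs <- dsc_enthalpy_entropy(T_K, p)
  lnKu <- -hs$dG / (.RGAS * T_K)
  fU <- stats::plogis(lnKu)            # Ku/(1+Ku), overflow-safe
  frac2 <- fU * (1 - fU)               # Ku/(1+Ku)^2
  cp0 <- p$a0 + p$b0 * T_K
  dint <- dcp_unfolding(T_K, p) * fU
  dexc <- hs$dH^2 / (.RGAS * T_K^2) * frac2
  if (components) {
    return(data.frame(T_K = T_K, Cp0 = cp0, dCp_int = dint, dCp_exc = dexc,
                      Cp = cp0 + dint + dexc))
  }
  cp0 + dint + dexc
}

#' Theoretical unfolded-state heat capacity of a sequence
#'
#' Sums per-residue unfolded-state partial molar heat-capacity contributions
#' at the six reference temperatures (5, 25, 50, 75, 100, 125 degC),
#' following the group-additivity convention: one backbone-unit contribution
#' per residue, one side-chain contribution per residue type, plus N- and
#' C-terminal corrections.
#'
#' The packaged default table (`unfolded_cp_synthetic.tsv`) is a synthetic
#' stand-in with the qualitative shape of published group-contribution data
#' (rising with temperature, flattening above ~75 degC); see
#' [read_residue_cp_table()]. For quantitative work supply your own table,
#' or bypass this path entirely and fix the quadratic coefficient `c`
#' directly in [fit_dsc()].
#'
#' @param sequence one-letter amino-acid string (standard 20 residues)
#' @param table residue table from [read_residue_cp_table()]
#' @return data.frame with `T_K` and `Cp_U` (kJ/(K mol)) at the six
#'   reference temperatures
#' @export
unfolded_cp_points <- function(sequence, table = read_residue_cp_table()) {
  sequence <- toupper(trimws(sequence))
  if (nchar(sequence) == 0) stop("sequence must be non-empty")
  res <- strsplit(sequence, "")[[1]]
  known <- setdiff(rownames(table), c("backbone", "Nterm", "Cterm"))
  bad <- setdiff(unique(res), known)
  if (length(bad)) {
    stop("residue(s) not in heat-capacity table: ", paste(bad, collapse = ", "))
  }
  temps_C <- c(5, 25, 50, 75, 100, 125)
  cp <- vapply(seq_along(temps_C), function(j) {
    sum(table[res, j]) + length(res) * table["backbone", j] +
      table["Nterm", j] + table["Cterm", j]
  }, numeric(1))
  data.frame(T_K = celsius_to_kelvin(temps_C), Cp_U = cp / 1000)  # J -> kJ
}

#' Quadratic coefficient of a parabola through heat-capacity points
#'
#' Ordinary least-squares fit of `Cp = p0 + p1 T + p2 T^2`; returns `p2`,
#' the coefficient conventionally held fixed while fitting a thermogram.
#'
#' @param points data.frame with columns `T_K` and `Cp` (or `Cp_U`)
#' @return quadratic coefficient, kJ/(K^3 mol) when fed kJ-based points
#' @export
cp_parabola_coefficient <- function(points) {
  cp <- if ("Cp" %in% names(points)) points$Cp else points$Cp_U
  if (length(unique(points$T_K)) < 3) stop("need >= 3 distinct temperatures")
  fit <- stats::lm(cp ~ points$T_K + I(points$T_K^2))
  unname(stats::coef(fit)[3])
}

#' Fit a two-state DSC thermogram with temperature-dependent dCp
#'
#' Least-squares fit of [dsc_model_cp()] to a buffer-subtracted,
#' molar-normalized thermogram. Parameters `a0, b0, a, b, Tm, dH_Tm` float;
#' the quadratic coefficient `c` is held fixed (supply it directly, or
#' derive it from the protein sequence via [unfolded_cp_points()] +
#' [cp_parabola_coefficient()]).
#'
#' Initial values, when not given, come from the thermogram itself: `Tm`
#' from the baseline-detrended peak, `dH_Tm` from the peak height through
#' the two-state relation `Cp_exc(Tm) = dH^2/(4 R Tm^2)`, and the native
#' baseline from the pre-transition region.
#'
#' @param tg a [thermogram()]
#' @param c_fixed fixed quadratic coefficient, kJ/(K^3 mol)
#' @param init optional named vector/list of starting values
#' @param baseline_subtract optional pre-fit linear baseline subtraction
#'   (off by default; instrument steps are assumed done upstream)
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return list of class `dsc_fit` with `params` ([dsc_params()]), `se`,
#'   `converged`, `reliable`, `flags`, `fitted`, `thermogram`
#' @export
fit_dsc <- function(tg, c_fixed, init = NULL, baseline_subtract = FALSE,
                    control = minpack.lm::nls.lm.control(
                      maxiter = 1000, maxfev = 100000, ftol = 1e-14, ptol = 1e-14)) {
  stopifnot(inherits(tg, "thermogram"))
  x <- tg$T_K; y <- tg$Cp
  if (baseline_subtract) {
    n <- length(x)
    lo <- seq_len(max(5, floor(n / 10)))
    bl <- stats::lm(y[lo] ~ x[lo])
    y <- y - (stats::coef(bl)[1] + stats::coef(bl)[2] * x)
  }

  model <- function(p) {
    dsc_model_cp(x, dsc_params(p[["a0"]], p[["b0"]], p[["a"]], p[["b"]],
                               c_fixed, p[["Tm"]], p[["dH_Tm"]]))
  }
  resid_fn <- function(p) y - model(p)

  # heuristics: native baseline from the first decile, Tm from the
  # detrended peak, dH from the peak height
  n <- length(x)
  lo <- seq_len(max(5, floor(n / 10)))
  bl <- stats::coef(stats::lm(y[lo] ~ x[lo]))
  detr <- y - (bl[1] + bl[2] * x)
  i_pk <- which.max(detr)
  Tm0 <- x[i_pk]
  pk <- max(detr[i_pk], 0.5)
  dH0 <- sqrt(4 * .RGAS * Tm0^2 * pk)
  a0_0 <- unname(bl[1]); b0_0 <- unname(bl[2])
  a_0 <- 0.5 - c_fixed * Tm0^2   # small positive dCp(Tm) to start
  p0 <- c(a0 = a0_0, b0 = b0_0, a = a_0, b = 0, Tm = Tm0, dH_Tm = dH0)
  if (!is.null(init)) p0[names(init)] <- unlist(init)

  fit <- try(minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    lower = c(a0 = -Inf, b0 = -Inf, a = -Inf, b = -Inf,
              Tm = min(x), dH_Tm = 1),
    upper = c(a0 = Inf, b0 = Inf, a = Inf, b = Inf,
              Tm = max(x), dH_Tm = Inf),
    control = control), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(converged = FALSE, reliable = FALSE,
                          message = as.character(fit), thermogram = tg),
                     class = "dsc_fit"))
  }

  p <- fit$par
  se <- .nlslm_se(fit, length(y))
  names(se) <- names(p)
  fitted_y <- model(p)
  converged <- fit$info %in% 1:4
  # evidence for a transition: the two-state model must clearly beat a
  # plain quadratic baseline (a broad shallow "peak" that a smooth
  # baseline reproduces just as well is not a transition)
  rss_baseline <- sum(stats::resid(stats::lm(y ~ x + I(x^2)))^2)
  peak_seen <- fit$deviance < 0.8 * rss_baseline
  interior <- p[["Tm"]] > min(x) + 1 && p[["Tm"]] < max(x) - 1
  flags <- character(0)
  if (!peak_seen) flags <- c(flags, "no resolvable transition peak")
  if (!interior) flags <- c(flags, "Tm at edge of scanned range")

  structure(list(
    params = dsc_params(p[["a0"]], p[["b0"]], p[["a"]], p[["b"]], c_fixed,
                        p[["Tm"]], p[["dH_Tm"]]),
    se = se, converged = converged,
    reliable = converged && peak_seen && interior,
    flags = flags, fitted = fitted_y, thermogram = tg,
    deviance = fit$deviance, message = fit$message),
    class = "dsc_fit")
}

#' @export
print.dsc_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<dsc_fit> NOT converged:", x$message, "\n"); return(invisible(x))
  }
  cat(sprintf("<dsc_fit> Tm = %.2f K (%.2f degC) +/- %.3f, dHu(Tm) = %.1f +/- %.2f kJ/mol, dCp(Tm) = %.3f kJ/(K mol)\n",
              x$params$Tm, kelvin_to_celsius(x$params$Tm), x$se[["Tm"]],
              x$params$dH_Tm, x$se[["dH_Tm"]],
              dcp_unfolding(x$params$Tm, x$params)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
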