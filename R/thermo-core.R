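#' Physical constants used throughout the package
#'
#' All internal energies are in kJ/mol and temperatures in K, so the gas
#' constant is carried in kJ/(mol K). `T_ref` is the reference temperature at
#' which chemical denaturations and CEST experiments were performed (25 degC).
#'
#' @return Named list with `R` (8.314e-3 kJ/(mol K)) and `T_ref` (298.15 K).
#' @export
#' @examples
#' kow_constants()$R * 298.15   # RT at 25 degC, kJ/mol
kow_constants <- function() {
  list(R = 8.314e-3, T_ref = 298.15)
}

.RGAS <- 8.314e-3   # kJ/(mol K)
.TREF <- 298.15     # K

#' Convert between Celsius and Kelvin
#'
#' User-facing tables mix degC and K; everything internal is Kelvin.
#'
#' @param x temperature(s)
#' @return converted temperature(s)
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' Equilibrium constant of unfolding from a Gibbs energy
#'
#' `Ku = exp(-dG / (R T))`, the two-state unfolding constant `[U]/[N]`.
#'
#' @param dG Gibbs energy of unfolding, kJ/mol (vectorised)
#' @param T_K absolute temperature, K
#' @return dimensionless equilibrium constant, strictly positive
#' @export
#' @examples
#' equilibrium_constant(0, 298.15)                      # 1
#' equilibrium_constant(8.314e-3 * 298.15 * log(2), 298.15)  # 0.5
equilibrium_constant <- function(dG, T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("temperature must be finite and > 0 K")
  }
  exp(-dG / (.RGAS * T_K))
}

#' Fraction of folded molecules from the unfolding constant
#'
#' `fN = 1 / (1 + Ku)`.
#'
#' @param Ku unfolding equilibrium constant, `>= 0`
#' @return folded fraction in `[0, 1]`
#' @export
folded_fraction <- function(Ku) {
  if (any(!is.finite(Ku)) || any(Ku < 0)) stop("Ku must be finite and >= 0")
  1 / (1 + Ku)
}

#' Gibbs energy of thermal unfolding (no heat-capacity term)
#'
#' `dG(T) = dH_Tm * (1 - T/Tm)`: the van't Hoff form used for spectroscopic
#' melts, where the folded and unfolded baselines absorb any residual
#' temperature dependence. Zero exactly at `T = Tm`. The heat-capacity change
#' enters only the calorimetric model (see [dsc_model_cp()]).
#'
#' @param T_K absolute temperature, K (vectorised)
#' @param Tm melting temperature, K
#' @param dH_Tm unfolding enthalpy at `Tm`, kJ/mol
#' @return kJ/mol
#' @export
dG_thermal <- function(T_K, Tm, dH_Tm) {
  if (!is.finite(Tm) || Tm <= 0) stop("Tm must be finite and > 0 K")
  if (!is.finite(dH_Tm)) stop("dH_Tm must be finite")
  if (any(T_K <= 0)) stop("temperature must be > 0 K")
  dH_Tm * (1 - T_K / Tm)
}

#' Gibbs energy of unfolding under the linear extrapolation method
#'
#' `dG([denat]) = dG_H2O - m * [denat]`; zero at the transition midpoint
#' `[denat]_1/2 = dG_H2O / m`.
#'
#' @param denat denaturant concentration, M (vectorised, `>= 0`)
#' @param dG_H2O Gibbs energy of unfolding in water, kJ/mol
#' @param m_value denaturant m value, kJ/(mol M)
#' @return kJ/mol
#' @export
dG_chemical <- function(denat, dG_H2O, m_value) {
  if (any(denat < 0)) stop("denaturant concentration must be >= 0")
  dG_H2O - m_value * denat
}

#' Gibbs energy difference between two exchanging species from populations
#'
#' `dG = -R T log(pB / pA)`; positive when the minor species B is less
#' populated than A. This is how CEST-derived populations are converted to the
#' energy gap separating the exchanging states.
#'
#' @param pA,pB populations of the major and minor species (must sum to 1
#'   within `tol`)
#' @param T_K absolute temperature, K (default 298.15, the measurement
#'   temperature of the exchange experiments)
#' @param tol tolerance on `pA + pB = 1`
#' @return kJ/mol
#' @export
#' @examples
#' dG_from_populations(0.9915, 0.0085)   # ~11.80 kJ/mol
dG_from_populations <- function(pA, pB, T_K = .TREF, tol = 1e-6) {
  if (any(pA <= 0) || any(pB <= 0)) stop("populations must be > 0")
  if (any(abs(pA + pB - 1) > tol)) stop("pA + pB must equal 1 within tolerance")
  if (any(T_K <= 0)) stop("temperature must be > 0 K")
  -.RGAS * T_K * log(pB / pA)
}

#' Two-state thermal parameters
#'
#' Lightweight validated container for `(Tm, dH_Tm)`.
#'
#' @param Tm melting temperature, K
#' @param dH_Tm unfolding enthalpy at `Tm`, kJ/mol
#' @return list of class `thermal_params`
#' @export
thermal_params <- function(Tm, dH_Tm) {
  if (!is.finite(Tm) || Tm <= 0) stop("Tm must be finite and > 0 K")
  if (!is.finite(dH_Tm)) stop("dH_Tm must be finite")
  structure(list(Tm = Tm, dH_Tm = dH_Tm), class = "thermal_params")
}

#' Linear-extrapolation-method parameters
#'
#' @param dG_H2O Gibbs energy of unfolding in water, kJ/mol
#' @param m_value denaturant dependence, kJ/(mol M)
#' @return list of class `lem_params`
#' @export
lem_params <- function(dG_H2O, m_value) {
  if (!is.finite(dG_H2O) || !is.finite(m_value)) {
    stop("dG_H2O and m_value must be finite")
  }
  structure(list(dG_H2O = dG_H2O, m_value = m_value), class = "lem_params")
}

#' Folded/unfolded baseline pair
#'
#' Intercepts and slopes of the native and unfolded baselines. For thermal
#' fits the slopes are anchored at `Tm` (signal per K); for chemical fits they
#' are per M of denaturant.
#'
#' @param yN,mN native-state intercept and slope
#' @param yU,mU unfolded-state intercept and slope
#' @return list of class `baseline_pair`
#' @export
baseline_pair <- function(yN, mN, yU, mU) {
  v <- c(yN, mN, yU, mU)
  if (any(!is.finite(v))) stop("all baseline parameters must be finite")
  structure(list(yN = yN, mN = mN, yU = yU, mU = mU), class = "baseline_pair")
}
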