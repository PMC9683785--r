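#' Library of measurement scenarios
#'
#' Named parameter sets for the measurement regimes the package analyses:
#' thermal melts, DSC thermograms, chemical denaturations and CEST exchange
#' regimes of the six KOW domains. Each scenario carries the generating
#' parameters, the default acquisition grid, a realistic noise level, and a
#' `source` string describing the measurement condition it represents.
#'
#' For the DSC scenario the heat-capacity-change parabola is parameterised
#' by its value at `Tm` plus a vertex near 75 degC (where unfolded-state
#' heat capacities flatten); the native baseline is a plausible linear
#' molar baseline.
#'
#' @return named list of scenario definitions
#' @export
#' @examples
#' names(kow_scenarios())
#' kow_scenarios()$EcRfaH_CEST$exchange
kow_scenarios <- function() {
  parab <- function(dcp_Tm, Tm, vertex = 348) {
    c_ <- -3e-5
    b_ <- -2 * c_ * vertex
    a_ <- dcp_Tm - b_ * Tm - c_ * Tm^2
    list(a = a_, b = b_, c = c_)
  }
  cest_scn <- function(pB, kex, src) {
    list(kind = "cest",
         exchange = list(pB = pB, kex = kex),
         spin_defaults = list(R1 = 1.5, R2_A = 8, R2_B = 20),
         nu1_Hz = c(13, 26), Tex_s = 0.5, freq_MHz = 60.81,
         offset_halfwidth_ppm = 8, offset_step_ppm = 0.25,
         sigma = 0.01, source = src)
  }
  ecnusg_dsc <- {
    Tm <- celsius_to_kelvin(87.0)
    pb <- parab(0.800, Tm)
    list(kind = "dsc",
         params = list(a0 = 3.0, b0 = 0.03, a = pb$a, b = pb$b, c = pb$c,
                       Tm = Tm, dH_Tm = 222),
         grid_C = seq(5, 130, by = 0.2), noise_frac_peak = 0.01,
         source = "EcNusG-KOW calorimetric melt, pH 7.0")
  }
  ecrfah_dsc <- {
    Tm <- celsius_to_kelvin(47.3)
    pb <- parab(2.18, Tm)
    list(kind = "dsc",
         params = list(a0 = 3.0, b0 = 0.03, a = pb$a, b = pb$b, c = pb$c,
                       Tm = Tm, dH_Tm = 129),
         grid_C = seq(5, 130, by = 0.2), noise_frac_peak = 0.01,
         source = "EcRfaH-KOW calorimetric melt, pH 7.0")
  }
  list(
    EcRfaH_CD_pH7 = list(
      kind = "thermal",
      params = list(Tm = celsius_to_kelvin(50.3), dH_Tm = 121),
      baselines = list(yN = -4000, mN = 0, yU = -1000, mU = 0),
      grid_C = seq(20, 95, by = 0.5), noise_frac_span = 0.02,
      source = "EcRfaH-KOW far-UV CD thermal melt, pH 7.0"),
    MtNusG_CD_pH7 = list(
      kind = "thermal",
      params = list(Tm = celsius_to_kelvin(76.6), dH_Tm = 193),
      baselines = list(yN = -4000, mN = 0, yU = -1000, mU = 0),
      grid_C = seq(20, 95, by = 0.5), noise_frac_span = 0.02,
      source = "MtNusG-KOW far-UV CD thermal melt, pH 7.0"),
    hSpt5_CD_pH4 = list(
      kind = "thermal",
      params = list(Tm = celsius_to_kelvin(60.5), dH_Tm = 140),
      baselines = list(yN = -4000, mN = 0, yU = -1000, mU = 0),
      grid_C = seq(20, 95, by = 0.5), noise_frac_span = 0.02,
      source = "hSpt5-KOW5 far-UV CD thermal melt, pH 4.0"),
    EcNusG_DSC_pH7 = ecnusg_dsc,
    EcRfaH_DSC_pH7 = ecrfah_dsc,
    VcRfaH_urea_pH7 = list(
      kind = "chemical", axis_kind = "urea",
      params = list(dG_H2O = 14.0, m_value = 2.98),
      baselines = list(yN = -2500, mN = 20, yU = -700, mU = 10),
      grid_M = seq(0, 10, length.out = 25), noise_frac_span = 0.02,
      source = "VcRfaH-KOW far-UV CD urea denaturation, pH 7.0"),
    EcNusG_urea_pH4 = list(
      kind = "chemical", axis_kind = "urea",
      params = list(dG_H2O = 19.8, m_value = 2.51),
      baselines = list(yN = -2500, mN = 20, yU = -700, mU = 10),
      grid_M = seq(0, 10, length.out = 25), noise_frac_span = 0.02,
      source = "EcNusG-KOW far-UV CD urea denaturation, pH 4.0"),
    MjSpt5_GdmCl_pH7 = list(
      kind = "chemical", axis_kind = "GdmCl",
      params = list(dG_H2O = 45.4, m_value = 9.02),
      baselines = list(yN = -2500, mN = 20, yU = -700, mU = 10),
      grid_M = seq(0, 8, length.out = 25), noise_frac_span = 0.02,
      source = "MjSpt5-KOW far-UV CD GdmCl denaturation, pH 7.0"),
    S139_NMR_urea = list(
      kind = "chemical", axis_kind = "urea",
      params = list(dG_H2O = 7, m_value = 3.4),
      baselines = list(yN = 1, mN = 0, yU = 0, mU = 0),
      grid_M = seq(0, 8, length.out = 17), noise_frac_span = 0.02,
      source = "EcRfaH-KOW S139 normalized peak-volume urea titration"),
    EcRfaH_CEST = cest_scn(0.0553, 14.80,
                           "EcRfaH-KOW 15N-CEST global exchange regime"),
    hSpt5_CEST = cest_scn(0.0085, 89.38,
                          "hSpt5-KOW5 15N-CEST global exchange regime"),
    VcRfaH_CEST = cest_scn(0.0043, 74.57,
                           "VcRfaH-KOW 15N-CEST global exchange regime")
  )
}

#' Generate a synthetic thermal unfolding curve
#'
#' Exact two-state melt model plus iid Gaussian noise; identical seed gives
#' identical output, and `sigma = 0` returns the noise-free model.
#'
#' @param params [thermal_params()]
#' @param baselines [baseline_pair()]
#' @param T_grid temperature grid, K
#' @param sigma Gaussian noise standard deviation, signal units
#' @param seed integer RNG seed
#' @param technique recorded detection technique
#' @return an [unfolding_curve()]
#' @export
gen_thermal_curve <- function(params, baselines, T_grid, sigma = 0,
                              seed = 1, technique = "CD_far_UV") {
  if (!length(T_grid)) stop("empty temperature grid")
  if (sigma < 0) stop("sigma must be >= 0")
  y <- predict_unfolding_signal(T_grid, params, baselines)
  noise <- withr::with_seed(seed, stats::rnorm(length(T_grid), 0, sigma))
  unfolding_curve(T_grid, y + noise, axis_kind = "temperature",
                  technique = technique)
}

#' Generate a synthetic chemical denaturation series
#'
#' @param params [lem_params()]
#' @param baselines [baseline_pair()]
#' @param denat_grid denaturant concentrations, M
#' @param sigma Gaussian noise sd, signal units
#' @param seed integer RNG seed
#' @param axis_kind `"urea"` or `"GdmCl"`
#' @param technique recorded detection technique
#' @return an [unfolding_curve()]
#' @export
gen_chem_curve <- function(params, baselines, denat_grid, sigma = 0,
                           seed = 1, axis_kind = "urea",
                           technique = "CD_far_UV") {
  if (!length(denat_grid)) stop("empty denaturant grid")
  if (sigma < 0) stop("sigma must be >= 0")
  y <- predict_unfolding_signal(denat_grid, params, baselines)
  noise <- withr::with_seed(seed, stats::rnorm(length(denat_grid), 0, sigma))
  unfolding_curve(denat_grid, y + noise, axis_kind = axis_kind,
                  technique = technique)
}

#' Generate a synthetic DSC thermogram
#'
#' @param params [dsc_params()]
#' @param T_grid temperature grid, K
#' @param sigma Gaussian noise sd, kJ/(K mol)
#' @param seed integer RNG seed
#' @return a [thermogram()]
#' @export
gen_dsc <- function(params, T_grid, sigma = 0, seed = 1) {
  if (!length(T_grid)) stop("empty temperature grid")
  if (sigma < 0) stop("sigma must be >= 0")
  y <- dsc_model_cp(T_grid, params)
  noise <- withr::with_seed(seed, stats::rnorm(length(T_grid), 0, sigma))
  thermogram(T_grid, y + noise)
}

#' Generate synthetic CEST profiles for a set of residues
#'
#' Simulates the Bloch-McConnell two-state model for every residue at every
#' B1 field and adds iid Gaussian noise on the intensity ratio.
#'
#' @param spins named list of [spin_params()] (names = residue ids)
#' @param exch [exchange_params()] shared by all residues
#' @param nu1_Hz vector of B1 field strengths, Hz
#' @param Tex_s exchange period, s
#' @param offsets_ppm saturation offsets, ppm, shared grid; when `NULL` a
#'   grid of +/- `offset_halfwidth` around each residue's major shift at
#'   `offset_step` spacing is used
#' @param freq_MHz nucleus frequency, MHz
#' @param sigma Gaussian noise sd on I/I0
#' @param seed integer RNG seed
#' @param offset_halfwidth,offset_step per-residue grid parameters, ppm
#' @return named list (per residue) of lists of [cest_profile()]s
#' @export
gen_cest <- function(spins, exch, nu1_Hz = c(13, 26), Tex_s = 0.5,
                     offsets_ppm = NULL, freq_MHz = 60.81, sigma = 0,
                     seed = 1, offset_halfwidth = 8, offset_step = 0.25) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(names(spins))) names(spins) <- paste0("res", seq_along(spins))
  res <- withr::with_seed(seed, {
    lapply(names(spins), function(id) {
      sp <- spins[[id]]
      offs <- if (is.null(offsets_ppm)) {
        seq(sp$delta_A - offset_halfwidth, sp$delta_A + offset_halfwidth,
            by = offset_step)
      } else offsets_ppm
      lapply(nu1_Hz, function(n1) {
        y <- simulate_cest(sp, exch, n1, Tex_s, offs, freq_MHz)
        cest_profile(id, offs, y + stats::rnorm(length(offs), 0, sigma),
                     nu1_Hz = n1, freq_MHz = freq_MHz, Tex_s = Tex_s)
      })
    })
  })
  names(res) <- names(spins)
  res
}

#' Default spin-parameter set for a synthetic CEST study
#'
#' Eight residues with shift differences spread over -4..+4 ppm (all above
#' 1 ppm in magnitude, matching the global-fit inclusion filter) and shared
#' relaxation rates.
#'
#' @param n number of residues (default 8)
#' @param R1,R2_A,R2_B relaxation rates, 1/s
#' @param delta_A_range range of major-state shifts, ppm
#' @return named list of [spin_params()]
#' @export
default_cest_spins <- function(n = 8, R1 = 1.5, R2_A = 8, R2_B = 20,
                               delta_A_range = c(110, 125)) {
  dw <- seq(-4, 4, length.out = n)
  dw <- dw + sign(dw + 1e-9) * pmax(0, 1.2 - abs(dw))  # keep |dw| > 1.2
  dA <- seq(delta_A_range[1], delta_A_range[2], length.out = n)
  sp <- lapply(seq_len(n), function(i) {
    spin_params(dA[i], dw[i], R1, R2_A, R2_B)
  })
  names(sp) <- paste0("res", seq_len(n))
  sp
}

#' Generate the dataset a named scenario describes
#'
#' Dispatches on the scenario `kind` and returns the corresponding
#' synthetic dataset at the scenario's default grid and noise level.
#'
#' @param name scenario name (see [kow_scenarios()])
#' @param seed integer RNG seed
#' @param sigma optional noise override (signal units; for CEST, I/I0
#'   units; `NULL` = scenario default)
#' @return an [unfolding_curve()], [thermogram()] or [gen_cest()] result
#' @export
gen_scenario <- function(name, seed = 1, sigma = NULL) {
  scn <- kow_scenarios()[[name]]
  if (is.null(scn)) stop("unknown scenario: ", name)
  switch(scn$kind,
    thermal = {
      b <- do.call(baseline_pair, scn$baselines)
      span <- abs(scn$baselines$yU - scn$baselines$yN)
      s <- if (is.null(sigma)) scn$noise_frac_span * span else sigma
      gen_thermal_curve(do.call(thermal_params, scn$params), b,
                        celsius_to_kelvin(scn$grid_C), sigma = s,
                        seed = seed)
    },
    chemical = {
      b <- do.call(baseline_pair, scn$baselines)
      span <- abs(scn$baselines$yU - scn$baselines$yN)
      s <- if (is.null(sigma)) scn$noise_frac_span * span else sigma
      gen_chem_curve(do.call(lem_params, scn$params), b, scn$grid_M,
                     sigma = s, seed = seed, axis_kind = scn$axis_kind)
    },
    dsc = {
      p <- do.call(dsc_params, scn$params)
      peak <- p$dH_Tm^2 / (4 * .RGAS * p$Tm^2)
      s <- if (is.null(sigma)) scn$noise_frac_peak * peak else sigma
      gen_dsc(p, celsius_to_kelvin(scn$grid_C), sigma = s, seed = seed)
    },
    cest = {
      sp <- do.call(default_cest_spins, scn$spin_defaults)
      ex <- exchange_params(scn$exchange$pB, scn$exchange$kex)
      s <- if (is.null(sigma)) scn$sigma else sigma
      gen_cest(sp, ex, nu1_Hz = scn$nu1_Hz, Tex_s = scn$Tex_s,
               freq_MHz = scn$freq_MHz, sigma = s, seed = seed,
               offset_halfwidth = scn$offset_halfwidth_ppm,
               offset_step = scn$offset_step_ppm)
    },
    stop("unhandled scenario kind"))
}
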