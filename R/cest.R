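#' Per-residue spin parameters for two-state CEST
#'
#' @param delta_A major-state chemical shift, ppm
#' @param delta_omega minor-minus-major shift difference (signed), ppm
#' @param R1 longitudinal relaxation rate shared by both states, 1/s
#' @param R2_A,R2_B transverse relaxation rates of major/minor state, 1/s
#' @return list of class `spin_params`
#' @export
spin_params <- function(delta_A, delta_omega, R1, R2_A, R2_B) {
  if (R1 <= 0 || R2_A <= 0 || R2_B <= 0) {
    stop("relaxation rates must be > 0")
  }
  structure(list(delta_A = delta_A, delta_omega = delta_omega,
                 R1 = R1, R2_A = R2_A, R2_B = R2_B),
            class = "spin_params")
}

#' Two-state exchange parameters
#'
#' Stores the minor-state population and total exchange rate and derives the
#' microscopic rates `k_AB = pB kex`, `k_BA = pA kex`, the state lifetimes
#' `tau_A = 1/k_AB`, `tau_B = 1/k_BA`, and the Gibbs energy gap at `T_K`.
#' Detailed balance `k_AB pA = k_BA pB` holds exactly by construction.
#'
#' @param pB minor-state population, `0 < pB < 0.5`
#' @param kex total exchange rate `k_AB + k_BA`, 1/s
#' @param T_K temperature for the Gibbs energy, K (default 298.15)
#' @return list of class `exchange_params` with fields `pA, pB, kex, k_AB,
#'   k_BA, tau_A, tau_B, dG, T_K`
#' @export
exchange_params <- function(pB, kex, T_K = .TREF) {
  if (pB <= 0 || pB >= 0.5) stop("pB must be in (0, 0.5)")
  if (kex <= 0) stop("kex must be > 0")
  pA <- 1 - pB
  k_AB <- pB * kex
  k_BA <- kex - k_AB
  kex <- k_AB + k_BA   # kAB + kBA = kex exactly, also in floating point
  structure(list(pA = pA, pB = pB, kex = kex, k_AB = k_AB, k_BA = k_BA,
                 tau_A = 1 / k_AB, tau_B = 1 / k_BA,
                 dG = dG_from_populations(pA, pB, T_K), T_K = T_K),
            class = "exchange_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf("<exchange_params> pB = %.3f%%, kex = %.2f 1/s (kAB = %.3f, kBA = %.2f), tauA = %.2f s, tauB = %.1f ms, dG = %.2f kJ/mol at %.2f K\n",
              100 * x$pB, x$kex, x$k_AB, x$k_BA, x$tau_A, 1000 * x$tau_B,
              x$dG, x$T_K))
  invisible(x)
}

#' A CEST saturation profile for one residue at one B1 field
#'
#' @param residue residue identifier
#' @param offsets_ppm saturation offsets, ppm
#' @param intensity_ratio normalized intensities I/I0 (same length)
#' @param nu1_Hz saturation field strength, Hz
#' @param freq_MHz spectrometer frequency of the observed nucleus, MHz
#'   (converts ppm to Hz)
#' @param Tex_s exchange (saturation) period, s
#' @param nucleus `"N15"` or `"C13alpha"`
#' @return object of class `cest_profile`
#' @export
cest_profile <- function(residue, offsets_ppm, intensity_ratio,
                         nu1_Hz, freq_MHz, Tex_s = 0.5,
                         nucleus = c("N15", "C13alpha")) {
  nucleus <- match.arg(nucleus)
  if (length(offsets_ppm) != length(intensity_ratio)) {
    stop("offsets and intensities must have equal length")
  }
  if (any(!is.finite(offsets_ppm))) stop("offsets must be finite")
  if (any(intensity_ratio < -0.2 | intensity_ratio > 1.2, na.rm = TRUE)) {
    warning("intensity ratios outside [-0.2, 1.2]; check normalization")
  }
  structure(list(residue = residue, offsets_ppm = offsets_ppm,
                 intensity_ratio = intensity_ratio, nu1_Hz = nu1_Hz,
                 freq_MHz = freq_MHz, Tex_s = Tex_s, nucleus = nucleus),
            class = "cest_profile")
}

# 6x6 Bloch-McConnell generator over (Ix, Iy, Iz) of states A and B in the
# rotating frame of the saturation carrier. Relaxation toward zero (the
# standard heteronuclear CEST approximation); B1 along x couples Iy <-> Iz.
bloch_mcconnell_generator <- function(offset_ppm, nu1_Hz, spin, exch,
                                      freq_MHz) {
  wA <- 2 * pi * (spin$delta_A - offset_ppm) * freq_MHz
  wB <- 2 * pi * (spin$delta_A + spin$delta_omega - offset_ppm) * freq_MHz
  w1 <- 2 * pi * nu1_Hz
  one_state <- function(w, R2, R1) {
    matrix(c(-R2,  -w,   0,
              w,  -R2,  w1,
              0,  -w1, -R1), 3, 3, byrow = TRUE)
  }
  I3 <- diag(3)
  L <- rbind(
    cbind(one_state(wA, spin$R2_A, spin$R1) - exch$k_AB * I3, exch$k_BA * I3),
    cbind(exch$k_AB * I3, one_state(wB, spin$R2_B, spin$R1) - exch$k_BA * I3))
  if (any(!is.finite(L))) stop("non-finite Bloch-McConnell generator entries")
  L
}

#' Simulate a two-state CEST intensity profile
#'
#' For each saturation offset, the 6x6 Bloch-McConnell generator over
#' `(Ix, Iy, Iz)` of the two exchanging states (exchange `k_AB`/`k_BA`,
#' relaxation `R1`/`R2`, resonance-offset and B1 terms) is built and the
#' equilibrium magnetization `(0, 0, pA, 0, 0, pB)` is propagated for the
#' exchange period by matrix exponential. The returned intensity ratio is
#' `Iz_A(Tex) / pA`.
#'
#' @param spin [spin_params()]
#' @param exch [exchange_params()]
#' @param nu1_Hz saturation field, Hz
#' @param Tex_s exchange period, s
#' @param offsets_ppm saturation offsets, ppm
#' @param freq_MHz nucleus frequency, MHz
#' @return numeric vector of I/I0, one value per offset
#' @export
simulate_cest <- function(spin, exch, nu1_Hz, Tex_s, offsets_ppm, freq_MHz) {
  w1 <- 2 * pi * nu1_Hz
  # template generator; only the offset terms (elements [1,2],[2,1],[4,5],
  # [5,4]) change across offsets
  L <- matrix(0, 6, 6)
  L[1, 1] <- L[2, 2] <- -spin$R2_A - exch$k_AB
  L[3, 3] <- -spin$R1 - exch$k_AB
  L[4, 4] <- L[5, 5] <- -spin$R2_B - exch$k_BA
  L[6, 6] <- -spin$R1 - exch$k_BA
  L[2, 3] <- L[5, 6] <- w1
  L[3, 2] <- L[6, 5] <- -w1
  L[1, 4] <- L[2, 5] <- L[3, 6] <- exch$k_BA
  L[4, 1] <- L[5, 2] <- L[6, 3] <- exch$k_AB
  if (any(!is.finite(L))) stop("non-finite Bloch-McConnell generator entries")
  vapply(offsets_ppm, function(off) {
    wA <- 2 * pi * (spin$delta_A - off) * freq_MHz
    wB <- 2 * pi * (spin$delta_A + spin$delta_omega - off) * freq_MHz
    if (!is.finite(wA) || !is.finite(wB)) {
      stop("non-finite Bloch-McConnell generator entries")
    }
    L[1, 2] <- -wA; L[2, 1] <- wA
    L[4, 5] <- -wB; L[5, 4] <- wB
    E <- Matrix::expm(L * Tex_s)@x
    # Iz_A(Tex) from the initial condition (0, 0, pA, 0, 0, pB)
    (E[15] * exch$pA + E[33] * exch$pB) / exch$pA
  }, numeric(1))
}

# model I/I0 for one residue across several profiles, given a flat
# parameter vector: (pB, kex, delta_A, delta_omega, R1, R2_A, R2_B)
.cest_residue_model <- function(par, profiles) {
  spin <- spin_params(par[["delta_A"]], par[["delta_omega"]], par[["R1"]],
                      par[["R2_A"]], par[["R2_B"]])
  exch <- exchange_params(par[["pB"]], par[["kex"]])
  unlist(lapply(profiles, function(pr) {
    simulate_cest(spin, exch, pr$nu1_Hz, pr$Tex_s, pr$offsets_ppm,
                  pr$freq_MHz)
  }))
}

# pB and kex are optimized on the log scale: the pB*kex trade-off that
# dominates slow-exchange profiles becomes a straight valley there, which
# the trust-region steps traverse far more reliably
.cest_to_log <- function(par) {
  par[["pB"]] <- log(par[["pB"]]); par[["kex"]] <- log(par[["kex"]])
  names(par)[match(c("pB", "kex"), names(par))] <- c("lpB", "lkex")
  par
}

.cest_from_log <- function(par) {
  par[["lpB"]] <- exp(par[["lpB"]]); par[["lkex"]] <- exp(par[["lkex"]])
  names(par)[match(c("lpB", "lkex"), names(par))] <- c("pB", "kex")
  par
}

# locate major dip and candidate minor dip from the deepest profile,
# after light smoothing so single noisy points are not mistaken for dips
.cest_dip_guess <- function(profiles) {
  pr <- profiles[[which.max(vapply(profiles, function(p) p$nu1_Hz,
                                   numeric(1)))]]
  off <- pr$offsets_ppm; y <- pr$intensity_ratio
  if (length(y) >= 7) {
    ys <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
    ys[is.na(ys)] <- y[is.na(ys)]
  } else ys <- y
  dA <- off[which.min(ys)]
  # secondary dip = deepest local minimum away from the major dip that
  # stands clear of the far-offset plateau (the flank of the major dip has
  # no local minimum, so it can never masquerade as one)
  n <- length(ys)
  is_min <- c(FALSE, ys[2:(n - 1)] <= ys[1:(n - 2)] &
                ys[2:(n - 1)] <= ys[3:n], FALSE)
  cand <- which(is_min & abs(off - dA) > 0.75)
  dw <- NA_real_
  if (length(cand)) {
    i <- cand[which.min(ys[cand])]
    plateau <- stats::median(ys[abs(off - dA) >
                                  0.8 * max(abs(off - dA))])
    noise <- stats::mad(diff(y)) / sqrt(2)
    if (ys[i] < plateau - 3 * noise) {
      dw <- off[i] - dA
    }
  }
  list(delta_A = dA, delta_omega = dw)
}

# coarse (pB, kex) grid search with the remaining parameters held at their
# heuristic values; returns the n_keep best corners as optimizer starts
# (the pB-kex trade-off ridge makes a single start unreliable)
.cest_exchange_grid <- function(profiles, y, base_par, n_keep = 2,
                                pB_grid = c(0.005, 0.02, 0.06, 0.15),
                                kex_grid = c(5, 20, 80, 300)) {
  corners <- list(); devs <- numeric(0)
  for (pB in pB_grid) for (kex in kex_grid) {
    p <- base_par; p[["pB"]] <- pB; p[["kex"]] <- kex
    corners[[length(corners) + 1]] <- p
    devs <- c(devs, sum((y - .cest_residue_model(p, profiles))^2))
  }
  corners[order(devs)[seq_len(min(n_keep, length(corners)))]]
}

#' Fit one residue's CEST profiles to the two-state exchange model
#'
#' Joint least squares across all of the residue's profiles (ideally two B1
#' fields; a single field is accepted but flagged). Floats
#' `pB, kex, delta_A, delta_omega, R1, R2_A, R2_B`. Because the sign of the
#' shift difference is only weakly determined in some regimes, both signs of
#' the starting `delta_omega` are tried and the lower-residual solution is
#' kept; `sign_ambiguous` is set when the two residuals differ by < 5%.
#'
#' @param profiles list of [cest_profile()] for one residue (any number of
#'   B1 fields)
#' @param init optional named starting values
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return list of class `cest_residue_fit` with `spin` ([spin_params()]),
#'   `exchange` ([exchange_params()]), `se`, `converged`, `flags`,
#'   `sign_ambiguous`, `deviance`
#' @export
fit_cest_residue <- function(profiles, init = NULL,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500, maxfev = 100000, ftol = 1e-10, ptol = 1e-10)) {
  if (inherits(profiles, "cest_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile")
  y <- unlist(lapply(profiles, function(p) p$intensity_ratio))

  guess <- .cest_dip_guess(profiles)
  dip_found <- is.finite(guess$delta_omega)
  dw0 <- if (dip_found) guess$delta_omega else 2
  p0 <- c(pB = 0.02, kex = 30, delta_A = guess$delta_A, delta_omega = dw0,
          R1 = 1.5, R2_A = 10, R2_B = 20)
  if (!is.null(init)) {
    p0[names(init)] <- unlist(init)
    starts <- list(p0)
  } else {
    starts <- .cest_exchange_grid(profiles, y, p0)
    if (!dip_found) {
      # the shift-difference sign is unknown: try the mirrored start too
      flip <- starts[[1]]
      flip[["delta_omega"]] <- -flip[["delta_omega"]]
      starts <- c(starts, list(flip))
    }
  }

  lower <- c(lpB = log(1e-5), lkex = log(0.01), delta_A = -Inf,
             delta_omega = -Inf, R1 = 0.01, R2_A = 0.1, R2_B = 0.1)
  upper <- c(lpB = log(0.499), lkex = log(5000), delta_A = Inf,
             delta_omega = Inf, R1 = 50, R2_A = 500, R2_B = 2000)

  run <- function(p_start) {
    try(minpack.lm::nls.lm(
      par = .cest_to_log(p_start),
      fn = function(p) y - .cest_residue_model(.cest_from_log(p), profiles),
      lower = lower, upper = upper, control = control), silent = TRUE)
  }
  fits <- Filter(function(f) !inherits(f, "try-error"), lapply(starts, run))
  if (!length(fits)) {
    return(structure(list(converged = FALSE,
                          message = "optimizer failed from all starts"),
                     class = "cest_residue_fit"))
  }
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  dws <- vapply(fits, function(f) f$par[["delta_omega"]], numeric(1))
  other <- which(sign(dws) != sign(dws[which.min(dev)]))
  sign_ambiguous <- length(other) > 0 &&
    min(dev[other]) - min(dev) < 0.05 * min(dev)

  p <- .cest_from_log(best$par)
  se <- .nlslm_se(best, length(y))
  names(se) <- names(p)
  # delta method back to the natural scale
  se[["pB"]] <- p[["pB"]] * se[["pB"]]
  se[["kex"]] <- p[["kex"]] * se[["kex"]]
  flags <- character(0)
  if (length(profiles) < 2) flags <- c(flags, "single B1 field")
  if (!dip_found) {
    flags <- c(flags, "no resolvable minor dip in data")
  }
  # the shift difference must be determinate for the fit to mean anything;
  # a population pinned at its bounds marks an unresolved pB-kex ridge
  poorly_determined <- !is.finite(se[["delta_omega"]]) ||
    se[["delta_omega"]] > abs(p[["delta_omega"]])
  if (poorly_determined) {
    flags <- c(flags, "minor-state parameters poorly determined")
  }
  if (p[["pB"]] > 0.45 || p[["pB"]] < 2e-5) {
    flags <- c(flags, "population at fit bound")
  }
  if (sign_ambiguous) flags <- c(flags, "delta_omega sign ambiguous")

  structure(list(
    spin = spin_params(p[["delta_A"]], p[["delta_omega"]], p[["R1"]],
                       p[["R2_A"]], p[["R2_B"]]),
    exchange = exchange_params(p[["pB"]], p[["kex"]]),
    se = se, converged = best$info %in% 1:4, flags = flags,
    sign_ambiguous = sign_ambiguous, deviance = best$deviance,
    dw_observed = guess$delta_omega,
    residue = profiles[[1]]$residue, n_obs = length(y)),
    class = "cest_residue_fit")
}

#' @export
print.cest_residue_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<cest_residue_fit> NOT converged\n"); return(invisible(x))
  }
  cat(sprintf("<cest_residue_fit> residue %s: pB = %.3f%% +/- %.3f, kex = %.2f +/- %.2f 1/s, dw = %.2f ppm\n",
              as.character(x$residue), 100 * x$exchange$pB,
              100 * x$se[["pB"]], x$exchange$kex, x$se[["kex"]],
              x$spin$delta_omega))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Global two-state fit of CEST profiles across residues
#'
#' Fits a single shared `(pB, kex)` across all residues whose per-residue
#' shift difference passes the inclusion filter `|delta_omega| > dw_min`
#' (default 1 ppm), with residue-specific
#' `delta_A, delta_omega, R1, R2_A, R2_B`. Per-residue fits seed both the
#' filter and the starting values.
#'
#' @param residue_profiles named list; each element is the list of
#'   [cest_profile()]s (all B1 fields) for one residue
#' @param dw_min inclusion threshold on `|delta_omega|`, ppm
#' @param residue_fits optional precomputed list of [fit_cest_residue()]
#'   results (same names); computed here when absent
#' @param profile_se also compute profile-likelihood standard errors for
#'   `pB` and `kex` (several constrained refits; slower but honest when
#'   the pB-kex valley is flat, as in slow exchange with free minor-state
#'   R2). Reported as `se_profile`; `se` then carries the larger of the
#'   two estimates per parameter.
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return list of class `cest_global_fit` with `exchange`
#'   ([exchange_params()]), `se` (on `pB`, `kex`), `spins` (per-residue
#'   [spin_params()]), `spin_se`, `included`, `excluded`, `converged`
#' @export
fit_cest_global <- function(residue_profiles, dw_min = 1,
                            residue_fits = NULL, profile_se = FALSE,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 100000, ftol = 1e-10, ptol = 1e-10)) {
  if (is.null(names(residue_profiles))) {
    names(residue_profiles) <- vapply(residue_profiles, function(pp)
      as.character(pp[[1]]$residue), character(1))
  }
  if (is.null(residue_fits)) {
    residue_fits <- lapply(residue_profiles, fit_cest_residue)
  }
  dw <- vapply(residue_fits, function(f)
    if (!is.null(f$spin)) f$spin$delta_omega else NA_real_, numeric(1))
  usable <- vapply(residue_fits, function(f) {
    if (is.null(f$spin)) return(FALSE)
    degenerate <- any(grepl("poorly determined|at fit bound", f$flags))
    if (!degenerate) return(TRUE)
    # the per-residue exchange ran onto a ridge; keep the residue only
    # when its fitted shift difference agrees with the dip actually
    # visible in the data (the global fit re-determines everything else)
    is.finite(f$dw_observed) &&
      abs(f$spin$delta_omega - f$dw_observed) < 1.5
  }, logical(1))
  include <- usable & !is.na(dw) & abs(dw) > dw_min
  if (sum(include) < 2) {
    stop(sprintf(
      "global fit needs >= 2 residues with |delta_omega| > %.2f ppm; %d qualify",
      dw_min, sum(include)))
  }
  inc_names <- names(residue_profiles)[include]
  profs <- residue_profiles[include]
  fits <- residue_fits[include]

  y <- unlist(lapply(profs, function(pp)
    unlist(lapply(pp, function(p) p$intensity_ratio))))

  spin_names <- c("delta_A", "delta_omega", "R1", "R2_A", "R2_B")
  # shared exchange parameters on the log scale (see fit_cest_residue),
  # seeded from the well-behaved per-residue fits
  clean <- Filter(function(f)
    !any(grepl("poorly determined|at fit bound", f$flags)), fits)
  if (!length(clean)) clean <- fits
  p0 <- c(lpB = log(stats::median(vapply(clean, function(f) f$exchange$pB,
                                         numeric(1)))),
          lkex = log(stats::median(vapply(clean, function(f) f$exchange$kex,
                                          numeric(1)))))
  lower <- c(lpB = log(1e-5), lkex = log(0.01))
  upper <- c(lpB = log(0.499), lkex = log(5000))
  for (i in seq_along(fits)) {
    s <- fits[[i]]$spin
    v <- c(s$delta_A, s$delta_omega, s$R1, s$R2_A, s$R2_B)
    names(v) <- paste0(spin_names, ".", i)
    p0 <- c(p0, v)
    lo <- c(-Inf, -Inf, 0.01, 0.1, 0.1)
    hi <- c(Inf, Inf, 50, 500, 2000)
    names(lo) <- names(hi) <- names(v)
    lower <- c(lower, lo); upper <- c(upper, hi)
  }

  resid_fn <- function(p) {
    out <- lapply(seq_along(profs), function(i) {
      par_i <- c(pB = exp(p[["lpB"]]), kex = exp(p[["lkex"]]),
                 stats::setNames(p[paste0(spin_names, ".", i)], spin_names))
      .cest_residue_model(par_i, profs[[i]])
    })
    y - unlist(out)
  }

  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                            upper = upper, control = control)
  p <- fit$par
  se <- .nlslm_se(fit, length(y))
  names(se) <- names(p)
  p[["pB"]] <- exp(p[["lpB"]]); p[["kex"]] <- exp(p[["lkex"]])
  se[["pB"]] <- p[["pB"]] * se[["lpB"]]
  se[["kex"]] <- p[["kex"]] * se[["lkex"]]

  spins <- lapply(seq_along(fits), function(i) {
    v <- p[paste0(spin_names, ".", i)]
    spin_params(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]])
  })
  spin_se <- lapply(seq_along(fits), function(i) {
    stats::setNames(se[paste0(spin_names, ".", i)], spin_names)
  })
  names(spins) <- names(spin_se) <- inc_names

  se_out <- c(pB = se[["pB"]], kex = se[["kex"]])
  se_prof <- NULL
  if (profile_se) {
    s2 <- fit$deviance / max(length(y) - length(fit$par), 1)
    prof_one <- function(which_par) {
      # refit with the shared parameter held at offsets around the
      # optimum; the quadratic growth of the deviance along the profile
      # gives the marginal (profile-likelihood) standard error
      se_h <- se[[which_par]]
      if (!is.finite(se_h) || se_h <= 0) se_h <- 0.1
      offsets <- c(-2, -1, 1, 2) * max(se_h, 0.1)
      devs <- vapply(offsets, function(d) {
        par_fix <- fit$par[[which_par]] + d
        keep <- setdiff(names(fit$par), which_par)
        sub_control <- control
        sub_control$maxiter <- 100
        sub <- minpack.lm::nls.lm(
          par = fit$par[keep],
          fn = function(q) {
            full <- c(q, stats::setNames(par_fix, which_par))
            resid_fn(full[names(fit$par)])
          },
          lower = lower[keep], upper = upper[keep],
          control = sub_control)
        sub$deviance
      }, numeric(1))
      qcoef <- unname(stats::coef(stats::lm(c(devs, fit$deviance) ~
                                              I(c(offsets, 0)^2)))[2])
      if (!is.finite(qcoef) || qcoef <= 0) return(NA_real_)
      sqrt(s2 / qcoef)
    }
    se_prof <- c(pB = p[["pB"]] * prof_one("lpB"),
                 kex = p[["kex"]] * prof_one("lkex"))
    se_out <- pmax(se_out, se_prof, na.rm = TRUE)
  }

  structure(list(
    exchange = exchange_params(p[["pB"]], p[["kex"]]),
    se = se_out, se_profile = se_prof,
    spins = spins, spin_se = spin_se,
    included = inc_names,
    excluded = setdiff(names(residue_profiles), inc_names),
    residue_fits = residue_fits,
    converged = fit$info %in% 1:4, deviance = fit$deviance,
    n_obs = length(y)),
    class = "cest_global_fit")
}

#' @export
print.cest_global_fit <- function(x, ...) {
  cat(sprintf("<cest_global_fit> %d residues included (%d excluded by the shift-difference filter)\n",
              length(x$included), length(x$excluded)))
  cat(sprintf("  global pB = %.3f%% +/- %.3f, kex = %.2f +/- %.2f 1/s\n",
              100 * x$exchange$pB, 100 * x$se[["pB"]],
              x$exchange$kex, x$se[["kex"]]))
  invisible(x)
}

#' Exchange thermodynamics from population and rate
#'
#' Convenience wrapper building [exchange_params()] and returning the
#' derived microscopic rates, lifetimes and Gibbs energy gap.
#'
#' @param pB minor-state population
#' @param kex total exchange rate, 1/s
#' @param T_K temperature, K (default 298.15)
#' @return [exchange_params()]
#' @export
#' @examples
#' exchange_thermodynamics(0.0085, 89.38)
exchange_thermodynamics <- function(pB, kex, T_K = .TREF) {
  exchange_params(pB, kex, T_K)
}

#' Minor-species chemical shift
#'
#' `delta_B = delta_A + delta_omega` (signed shift difference convention:
#' minor minus major).
#'
#' @param delta_A major-state shift, ppm
#' @param delta_omega shift difference, ppm
#' @return minor-state shift, ppm
#' @export
minor_species_shift <- function(delta_A, delta_omega) delta_A + delta_omega

#' Compare minor-species shifts to a reference shift set
#'
#' Pairs shifts by residue id and reports the squared Pearson correlation,
#' the root-mean-square difference, and the per-residue differences —
#' the comparison used to decide whether a sparsely populated exchanging
#' species resembles a random-coil (fully unfolded) conformation.
#'
#' @param minor named numeric vector (names = residue ids), ppm
#' @param reference named numeric vector, ppm
#' @return list with `r_squared`, `rmsd`, `n`, and `differences`
#'   (minor - reference, named)
#' @export
compare_to_reference <- function(minor, reference) {
  ids <- intersect(names(minor), names(reference))
  if (length(ids) < 3) stop("need >= 3 paired residues")
  m <- minor[ids]; r <- reference[ids]
  dif <- m - r
  structure(list(
    r_squared = stats::cor(m, r)^2,
    rmsd = sqrt(mean(dif^2)),
    n = length(ids),
    differences = dif), class = "shift_comparison")
}

#' @export
print.shift_comparison <- function(x, ...) {
  cat(sprintf("<shift_comparison> n = %d, R^2 = %.4f, rmsd = %.3f ppm\n",
              x$n, x$r_squared, x$rmsd))
  invisible(x)
}
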