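# shared constants and small builders used across test files

RGAS <- kow_constants()$R
TREF <- kow_constants()$T_ref

# printed thermodynamic reference values (per domain / condition) used by
# the recovery tests: truth for generation, tabulated standard error for
# the "within 2 combined standard errors" checks
ref_thermal_EcRfaH_CD <- list(Tm_C = 50.3, Tm_se = 0.388, dH = 121)
ref_dsc_EcNusG <- list(Tm_C = 87.0, Tm_se = 0.0485, dH = 222, dCp = 0.800)
ref_lem_VcRfaH_urea <- list(dG = 14.0, dG_se = 1.74, m = 2.98)
ref_cest_EcRfaH <- list(pB = 0.0553, pB_se = 0.0046, kex = 14.80,
                        kex_se = 1.31)

# small, fast CEST study: few residues, coarse offset grid
small_cest_spins <- function(n = 3) {
  dw <- c(-3, 2, 3.5, -2.5, 1.8)[seq_len(n)]
  dA <- seq(115, 122, length.out = n)
  sp <- lapply(seq_len(n), function(i) spin_params(dA[i], dw[i], 1.5, 8, 20))
  names(sp) <- paste0("res", seq_len(n))
  sp
}

small_cest_offsets <- function(sp, halfwidth = 6, step = 0.5) {
  seq(sp$delta_A - halfwidth, sp$delta_A + halfwidth, by = step)
}

gen_small_cest <- function(exch, n = 3, sigma = 0, seed = 1,
                           halfwidth = 6, step = 0.5) {
  gen_cest(small_cest_spins(n), exch, nu1_Hz = c(13, 26), Tex_s = 0.5,
           freq_MHz = 60.81, sigma = sigma, seed = seed,
           offset_halfwidth = halfwidth, offset_step = step)
}

# independent Bloch-McConnell evolution by adaptive ODE integration
ode_cest <- function(spin, exch, nu1_Hz, Tex_s, offsets_ppm, freq_MHz) {
  v0 <- c(0, 0, exch$pA, 0, 0, exch$pB)
  vapply(offsets_ppm, function(off) {
    L <- kowtherm:::bloch_mcconnell_generator(off, nu1_Hz, spin, exch,
                                              freq_MHz)
    sol <- deSolve::lsoda(v0, c(0, Tex_s),
                          function(t, y, p) list(as.numeric(L %*% y)),
                          rtol = 1e-11, atol = 1e-13, maxsteps = 1e6)
    sol[2, 4] / exch$pA
  }, numeric(1))
}
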