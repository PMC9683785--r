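---
title: "Thermodynamics and exchange of fold-switching KOW domains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics and exchange of fold-switching KOW domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kowtherm)
```

# The scientific question

A metamorphic protein that interconverts between two folds cannot sit in
a deep free-energy minimum: the fold it must leave has to be marginally
stable, and an unfolded-like state has to be kinetically accessible.
For the KOW domain family (NusG/Spt5/RfaH transcription factors) that
hypothesis is quantifiable: measure the stability of the β-barrel fold
across homologs by thermal and chemical unfolding and by calorimetry,
and probe the exchange between the folded state and sparsely populated
unfolded-like states by CEST NMR. `kowtherm` implements each of those
analyses as a fitted model, and pairs every fitter with a seeded
generator of synthetic data so the whole chain is testable end to end.

# Models

## Two-state spectroscopic unfolding

Thermal melts are fitted with population-weighted linear baselines
anchored at the melting temperature `Tm`:

$$S(T) = f_N\,(y_N + m_N (T - T_m)) + (1-f_N)(y_U + m_U (T - T_m)),$$

with $f_N = 1/(1+K_u)$, $K_u = e^{-\Delta G_u / RT}$ and the van't Hoff
form $\Delta G_u = \Delta H_u(T_m)\,(1 - T/T_m)$. The heat-capacity
difference is deliberately absent here: over the width of a
spectroscopic transition its curvature is absorbed by the fitted
baselines, and only the calorimetric model (below) resolves it.
Anchoring the baselines at `Tm` rather than zero changes the meaning of
the intercept parameters but not the fitted curve; we keep the anchored
parameterization so the intercepts read as signal levels at the
transition.

Chemical denaturation uses the linear extrapolation method (LEM),
$\Delta G = \Delta G(\mathrm{H_2O}) - m\,[\mathrm{denat}]$, evaluated at
the measurement temperature (298.15 K by default), with baselines linear
in denaturant concentration. The transition midpoint is always the
derived ratio $\Delta G(\mathrm{H_2O})/m$ — fitting it independently
would break the identity that the acceptance checks rely on.

Fitting is Levenberg-Marquardt least squares (`minpack.lm`), unweighted.
Without user-supplied starting values a small multi-start is run:
midpoint from the steepest signal change, baselines from the end
quartiles, and a ladder of enthalpy (80/150/250 kJ/mol) or m-value
(1/3/6 kJ/(mol M)) guesses. Standard errors are asymptotic, from the
scaled inverse information matrix of the converged fit.

Reliability is never silent: a fit is flagged when (i) either baseline
is not covered within the scanned range (the folded fraction never
approaches 0 or 1 — the situation in which a melt without an
unfolded-state baseline is not interpretable), (ii) the fitted midpoint
or `Tm` leaves the measured range, or (iii) the fitted transition
amplitude does not stand clear (5x) of the residual noise — the last
guards against the degenerate solution in which both baselines coincide
and a "transition" of zero amplitude fits any featureless series. A
Wald-Wolfowitz runs test on the residual signs (normal approximation,
p < 0.01) raises a separate "multi-state suspected" diagnostic; domains
with genuinely three-state chemical unfolding are reported that way
rather than force-fitted, and only approximate midpoints should be read
off such curves.

## Calorimetry with temperature-dependent ΔCp

The molar heat capacity is modelled as

$$C_p(T) = C_{p,0}(T) + \Delta C_{p,u}(T)\,\frac{K_u}{1+K_u}
          + \frac{\Delta H_u(T)^2}{R T^2}\,\frac{K_u}{(1+K_u)^2},$$

with a linear native baseline $C_{p,0} = a_0 + b_0 T$ (the intercept
absorbs any instrument offset), a parabolic heat-capacity change
$\Delta C_{p,u}(T) = a + bT + cT^2$, and enthalpy/entropy from Kirchhoff
integration of that parabola from `Tm` (the entropy term uses the
natural logarithm). Population fractions are evaluated through
`plogis`, i.e. in log space, so extreme $K_u$ cannot overflow.
Parameters $a_0, b_0, a, b, T_m, \Delta H_u(T_m)$ float; $c$ is held
fixed, supplied either directly or from the group-additivity route:
summed per-residue unfolded-state heat-capacity points at 5-125 °C,
through an OLS quadratic. Two structural identities are enforced by
test: the excess term integrates to $\Delta H_u$ (equivalently to
$\int \Delta H_u\, df_U$) and, with a constant $\Delta C_p$, the excess
peak sits at `Tm` up to the small downward pull of the $1/T^2$
prefactor.

The packaged residue table (`inst/extdata/unfolded_cp_synthetic.tsv`)
is **synthetic**: it reproduces the qualitative shape of published
group-contribution data — contributions rising with temperature and
flattening above ~75 °C — but its values are constructed, not
transcribed from a literature compilation. It exists so the
sequence-based route is runnable and testable; for quantitative work on
real thermograms either supply a literature table in the same layout or
pass the quadratic coefficient `c` directly, which is all the fitting
path actually needs.

Evidence for a transition is again explicit: the fitted model must beat
a plain quadratic baseline by a clear margin, otherwise the thermogram
is flagged as having no resolvable transition (a broad shallow bump that
a smooth baseline explains equally well is not a transition).

## Two-state CEST

Each saturation offset defines a 6×6 Bloch-McConnell generator over
$(I_x, I_y, I_z)$ of the exchanging states: resonance-offset terms
$2\pi(\delta - \Omega)\nu_0$, the B1 coupling $2\pi\nu_1$ between $I_y$
and $I_z$, relaxation $R_1$ (shared between states) and $R_{2,A}$,
$R_{2,B}$, and exchange $k_{AB} = p_B k_{ex}$, $k_{BA} = p_A k_{ex}$.
The equilibrium magnetization $(0,0,p_A,0,0,p_B)$ is propagated for the
exchange period by matrix exponential and the profile is
$I_z^A(T_{ex})/p_A$. Relaxation is toward zero (the standard
heteronuclear approximation; the minor-state longitudinal rate is tied
to the major's because it is unidentifiable at percent-level
populations). Matrix-exponential propagation is verified against
adaptive ODE integration to 1e-8, and the generator's label symmetry
(swap states, read the other z-component) is a regression test.

Per-residue fits float $p_B, k_{ex}, \delta_A, \Delta\omega, R_1,
R_{2,A}, R_{2,B}$ jointly across the residue's B1 fields. Two numerical
choices matter:

* **Log-scale exchange parameters.** Slow-exchange profiles constrain
  the product $p_B k_{ex} \approx k_{AB}$ (dip depth) much more tightly
  than the split between the factors, because the minor dip's width
  lets the free $R_{2,B}$ absorb $k_{BA}$. On the natural scale that is
  a curved, hyperbola-shaped valley; on the log scale it is straight,
  and the trust-region steps follow it reliably. Standard errors are
  mapped back by the delta method, so population uncertainties are
  multiplicative — comparisons "within k standard errors" should be
  made on the log scale.
* **Starting values.** The major dip comes from the smoothed profile
  minimum; a secondary dip must be a *local minimum* away from the
  major dip (the flank of a broad major dip can never qualify) standing
  clear of the far-offset plateau. A coarse grid over
  $(p_B, k_{ex})$ corners supplies the two best starts; the mirrored
  $\Delta\omega$ start is added when no dip is visible, and the
  lower-residual sign wins (an ambiguity below 5% in residual is
  reported as such).

The global fit shares $(p_B, k_{ex})$ across residues with
residue-specific shift and relaxation parameters, seeded by the
per-residue fits. Inclusion follows the shift-difference filter
$|\Delta\omega| > 1$ ppm (configurable); residues whose per-residue
exchange parameters ran onto the ridge (population pinned at a bound,
indeterminate $\Delta\omega$ uncertainty) are kept only when their
fitted shift difference agrees with a dip directly visible in the data,
and excluded otherwise. An optional profile-likelihood standard error
(constrained refits along the shared parameters) is available for the
flat-valley regimes where the curvature-based error is optimistic.

A practical note on precision: at the synthetic study size used
throughout (8 residues, two B1 fields, σ(I/I₀) = 0.01) the single-run
population estimate genuinely carries a relative uncertainty of tens of
percent — the per-residue $R_{2,B}$ parameters absorb most of what
would otherwise pin down $k_{BA}$. Estimates across seeds scatter
accordingly, with standard errors that reflect it. Real studies regain
precision through many more residues; passing recovery tests at this
problem size therefore demonstrates correctness of the estimator, not
the precision attainable on a full dataset.

Derived exchange quantities preserve exact identities:
$k_{AB} + k_{BA} = k_{ex}$ (by construction, including floating point)
and detailed balance $k_{AB} p_A = k_{BA} p_B$; lifetimes are the
reciprocal microscopic rates and the energy gap is
$\Delta G = -RT \ln(p_B/p_A)$ at 298.15 K unless overridden. Note that
recomputing $\Delta G$ from populations printed to two decimals will
differ in the second decimal from a value computed from unrounded fit
output; the package computes, it does not reconcile.

## Secondary shifts and H-bond couplings

Secondary shifts are $\Delta\delta = \delta_{obs} - \delta_{rc} -
\text{(isotope correction)}$, positive Cα/CO meaning helical and
negative extended. Propensity calls use a 3-residue sliding window with
conventional thresholds (0.7 ppm Cα, 0.5 ppm CO) — the call is a
label, not a structure determination, and both the window and the
thresholds are arguments. The packaged random-coil table carries
commonly used reference values and is meant to be replaced by the
user's preferred (e.g. sequence-corrected) reference for quantitative
work.

Through-H-bond couplings $|^{h3}J_{NC'}|$ are compared across
structurally equivalent H-bond groups of the six domains. A group is
flagged *weaker* when at least `k_min = 2` of the reduced-stability
domains with data fall below the minimum over the stable domains with
data, *stronger* by the mirrored rule against the stable maximum. The
strict min/max reading was chosen because it is invariant to row order
and to duplicated records; comparing against the stable mean would be
less conservative and is not order-invariant once missing values enter.
Missing measurements (peak overlap, no HNCO peak, no equivalent
position) are excluded from comparisons and counted in the output,
never imputed. On the packaged table the weaker groups concentrate in
the β1-β2 and β3-β4 sheets plus the β5-β1 seam — the regions that are
disordered in the α-state of the fold-switching domains.

# The synthetic-data generators

`kow_scenarios()` fixes the study conditions: thermal melts on a
20-95 °C grid at 0.5 K with noise at 2% of the baseline separation; DSC
on 5-130 °C at 0.2 K with 1% peak-height noise; denaturation series of
25 points over 0-10 M urea (0-8 M GdmCl) at 2% span noise; CEST with
ν₁ ∈ {13, 26} Hz, T_ex = 0.5 s, offsets ±8 ppm around the major dip at
0.25 ppm steps, σ(I/I₀) = 0.01, at a ¹⁵N frequency of 60.81 MHz. The
parameter sets mirror the measured regimes of the six domains (e.g. a
marginally stable melt at Tm = 50.3 °C, ΔHu = 121 kJ/mol; a
high-stability thermogram at 87.0 °C, 222 kJ/mol, ΔCp(Tm) = 0.800
kJ/(K mol); exchange regimes with pB/k_ex of 5.53%/14.8 s⁻¹,
0.85%/89.4 s⁻¹ and 0.43%/74.6 s⁻¹). For the DSC scenario the ΔCp
parabola is anchored at its value at `Tm` with a vertex near 75 °C,
where unfolded-state heat capacities flatten; the native baseline
(a₀ = 3, b₀ = 0.03 kJ/(K² mol)) is a plausible small-protein molar
baseline. Noise is iid Gaussian on the signal axis — the assumption
under which unweighted least squares is the maximum-likelihood
estimator; heteroscedastic noise, baseline drift, aggregation
exotherms, B1 inhomogeneity and spectral artifacts of real instruments
are deliberately not emulated. Passing recovery tests on these
generators therefore validates the estimators under their own
assumptions; it does not certify performance on pathological real data.

Every generator is deterministic by seed (`withr::with_seed`), returns
the exact model at zero noise, and closes the loop: zero-noise data fed
to the corresponding fitter returns the generating parameters to
optimizer precision. That closed loop is the package's central
correctness property and is tested for all four measurement types.

# Numerical choices

* Energies in kJ/mol, temperatures in K internally; R = 8.314e-3
  kJ/(mol K); user-facing readers accept °C via unit-declaring column
  headers (`T_C`/`T_K`) and refuse ambiguous ones.
* Optimizer: `minpack.lm::nls.lm`, numerical forward-difference
  Jacobians, generous `maxfev`, stopping at ftol/ptol 1e-10 (CEST) or
  1e-13/1e-14 (unfolding/DSC, where model evaluations are cheap and the
  self-consistency tests assert 1e-6 relative recovery).
* Matrix exponential: `Matrix::expm`, called on a template generator
  with only the offset terms rewritten per point; the propagated result
  needs only two entries of the exponential, which keeps a 65-offset
  profile at ~5 ms.
* Degenerate inputs are flagged, not errored: featureless melts,
  all-native denaturation series, peak-free thermograms and
  shift-difference-free CEST profiles all return objects whose
  `reliable`/`flags` fields say what went wrong.

# Problem sizes in the test suite

The spot checks and acceptance-style recoveries run at the full study
conditions above. Repeated-recovery properties use reduced sizes chosen
to keep the suite fast while still estimating the relevant medians: 50
replicates for the thermal and chemical recovery distributions, 20
replicates at 0.5% noise for DSC bias, and 2-3-residue CEST studies on
coarser offset grids (0.5 ppm) for the closed-loop and consistency
properties. These sizes are the package's own choice of simulation
budget; the estimators themselves are identical at every size.

# Known limitations

* Three-state chemical unfolding is diagnosed (runs test) but not
  fitted; only approximate midpoints can be read from such curves.
* The CEST model covers two exchanging sites; triangular three-site
  exchange between folded, intermediate and unfolded states is out of
  scope, as are CPMG/R1ρ dispersion and pulse-sequence effects.
* Asymptotic standard errors understate uncertainty in flat-valley
  regimes; the profile-likelihood option mitigates but does not remove
  this, and single-run CEST population estimates at small residue
  counts are intrinsically imprecise (see above).
* The residue heat-capacity table is synthetic (see above); the
  random-coil table is a convenience default.
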