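---
title: "Mechanics of osmosis: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of osmosis: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoflow)
```

## The problem

Osmosis — the flow of water across a semipermeable membrane from the
low-osmolarity side toward the high-osmolarity side — is often described as
"diffusion of water down its concentration gradient".  That picture fails
quantitatively: membranes with aqueous pores show osmotic permeabilities
`Pf` far above their diffusional permeabilities `Pd`, and the
water-concentration difference between a solution and pure water depends on
the solute's partial molar volume, i.e. on the solute species, whereas
osmotic flow depends on osmolarity alone.  `osmoflow` implements the
mechanical alternative: the membrane exerts a repulsive force on solute
molecules; at the solution-side interface that force is balanced by a
pressure drop of `RT c_s` in the fluid, and water is then driven through
the membrane by an ordinary pressure gradient — for exactly the same reason
it flows under an imposed hydrostatic pressure difference.

The package has five scientific layers, each a module with its own surface:
phenomenological transport laws, continuum interface profiles, a
particle-level stochastic check, a cell-volume (pump–leak) toy model, and
dilute-mixture concentration arithmetic.  A strict-schema YAML config layer
and a small CLI sit on top.

## The phenomenological layer

With differences taken right-minus-left and flux positive rightward:

* van 't Hoff equilibrium: `deltaP = RT deltac_s`;
* Darcy (hydraulic) flow: `Phi_V = -Lp deltaP`;
* the combined law: `Phi_V = -Lp (deltaP - RT deltac_s)`, one coefficient
  `Lp` for both drivers;
* molar form: `phi_w = -Pf (deltaP/RT - deltac_s)` with
  `Pf = RT Lp / v_w0`;
* tracer diffusion `phi_w* = -Pd deltac_w*`, and the same `Pd` governs the
  diffusive response to a pressure difference, `-Pd deltaP/RT`;
* additivity `Pf = Pc + Pd`, so `Pf/Pd - 1 = Pc/Pd` measures the convective
  share (zero for lipid bilayers, huge for porous membranes).

One transcription subtlety: the `Pf`–`Lp` relation is implemented as
`Pf = RT Lp / v_w0` (division by the molar volume of water).  This is fixed
by dimensional analysis (`Pf` must be a velocity) and by requiring the
molar form to reproduce the volume form identically; both are enforced in
tests.  Similarly, the mixture identity is implemented as
`c_w + c_s = (1/v_w) / (1 + X_s (v_s/v_w - 1))`, the form forced by its own
definitions `c_w + c_s = (n_w + n_s)/(n_w v_w + n_s v_s)` and
`X_s = n_s/(n_w + n_s)`; an explicit mole-bookkeeping oracle in the test
suite confirms the reciprocal (not product) form.

The solubility–diffusion model of a bilayer gives `Pf = K D / h` with `K`
the water partition coefficient, `D` the in-membrane diffusion constant,
`h` the thickness; `Pd` is by inspection the same expression, so
`Pf/Pd = 1` exactly — water crosses as independent molecules, with no
convective component.

## Continuum interface model

The membrane acts on solute through a smooth repulsive potential `U(x) >= 0`
spanning `[0, h]`, with force `F = -dU/dx` finite everywhere.  Two shapes
are provided (a flat-topped plateau built from two logistic steps, and a
Gaussian bump); the theory's key prediction is that results do not depend
on this choice.  An idealized infinitely hard membrane is replaced by a
finite barrier with a declared impermeability threshold `U_max >= 30 RT`,
where the Boltzmann exclusion error `exp(-U_max/RT)` drops below 1e-13 —
so "impermeable" is a quantified approximation, not an assumption.

At equilibrium, setting the solute flux (Fickian term plus force drift,
with the Einstein relation `mu = D/RT`) to zero gives the Boltzmann profile
`c(x) = c_r exp(-U/RT)` on the solution side; the solute-free side is
insulated by the barrier and holds `c = 0`.  Mechanical balance of each
fluid slice, `dP/dx = c F`, then integrates to
`P(x) = P_r - RT (c_r - c(x))`: the chamber-to-chamber difference is
`RT c_r (1 - exp(-U_max/RT))`, and every trace of `F` has cancelled.

In the osmotic steady state (both chamber pressures held equal), the
interfaces stay quasi-equilibrated because the chambers are well stirred,
so integrating the flux law across the narrow interface yields a pressure
drop of `RT c_s` just inside the membrane on the solution side; across the
membrane interior, where the solute concentration gradient vanishes, the
pressure falls linearly with slope `-Phi_V/(h Lp)` — an ordinary Darcy
gradient.  The solver is deliberately semi-analytic: Boltzmann interface
factors composed with an exactly linear pressure segment on `[0, h]`
(sharp-interface partition of the pressure drop).  This mirrors the
integral argument itself, makes the interface drop and the interior slope
exact to rounding, and avoids pretending that the solver resolves membrane
microstructure it does not model; a structured membrane could curve the
interior profile, which is out of scope here.  A direct `deSolve::lsoda`
integration of the two balance ODEs is retained as an independent
cross-check and agrees with the closed form to better than 1e-8 of the
bulk concentration.

Numerical choices: the default grid spans each chamber 5 membrane
thicknesses wide with 2001 points; profiles require grid spacing at most
one fifth of the interface width (at least 20 points across the ~4-width
sigmoid transition), and coarser grids are refused with the required size
in the message.  The default interface width is `h/20`.  The solvent-side
pressure is anchored at the attained barrier-top energy `U(h/2)` rather
than the nominal `U_max`; the two differ only for leaky barriers, and using
the attained value keeps the closed form and the numerical integration
consistent to solver precision.

## Particle-level check

The claim that solute–membrane repulsion alone generates the van 't Hoff
pressure is tested with overdamped Langevin (Brownian) dynamics: `N` ideal,
non-interacting particles in a closed 1-D box, advanced by Euler–Maruyama
(drift `mu F dt`, diffusion `sqrt(2 D dt)`), with reflecting outer walls.
The solvent is implicit — it enters only through the mobility and the
noise — because the continuum result being tested lives in the ideal-dilute
limit where the solvent appears nowhere else.  The chamber is one-sided:
the left reflecting wall sits at the barrier midpoint (deep inside the
membrane), so the membrane's solution-side edge is the interface being
pushed on.  The measured observable is minus the time-averaged sum of the
membrane forces on the particles per unit area (Newton's third law), to be
compared with `RT c_b (1 - exp(-U_max/RT))`, where the bulk concentration
`c_b` follows from `N`, the box, and the Boltzmann-accessible length.
Starting positions are drawn from the Boltzmann distribution by rejection
sampling, so equilibration only decorrelates.

Two numerical rules matter and are worth stating plainly:

* **Time step.**  The hard validity bound is
  `mu |F|max dt <= interface_width/10`; beyond it the run is refused with a
  suggested `dt`.  The default is 2.5 times stricter
  (`interface_width/25`), balancing the O(dt) bias that Euler–Maruyama
  imprints on the stationary distribution against covering enough total
  time for honest error bars.
* **Error bars.**  The standard error comes from 20 averaging blocks.
  Blocks are only meaningful if they are longer than the autocorrelation
  time of the summed force, which is set not by the interface width but by
  particle exchange between the interface region and the whole chamber —
  it grows with chamber length.  The default box is therefore compact
  (bulk chamber about one membrane thickness); a pilot study with a 10x
  longer chamber produced standard errors understated by a factor ~3.
  Reduced units (`RT = 1`, lengths in interface widths) are available and
  used throughout the tests; simulation sizes there are N = 800–10000
  particles and 2e4–1e5 steps, which keep the full suite in minutes while
  leaving the van 't Hoff check with a relative standard error near 1%.

What passing these tests shows — and does not show.  The simulations
confirm that an energy-barrier membrane plus thermal motion reproduces the
continuum force balance (the histogram matches the Boltzmann profile; the
wall force matches `RT c_b`, independent of barrier shape).  They do not
model water flux, solvent structure, finite solute size, or single-file
channel dynamics; real membranes add all of these.

## Pump–leak (Donnan) toy cell

A pliant spherical cell exchanges an uncharged permeant A with an infinite
bath by first-order kinetics, `dA_in/dt = k (A_e - A_in) - p`, where `p` is
a constant-rate pump.  The classical statement of this toy model gives the
osmotic constraint and its consequence verbally; the package closes the
system with the minimal volume law consistent with the combined flux law at
negligible pressure difference across a pliant membrane:
`dw/dt = lam (A_in + b/w - A_e - B_e)`, with `b` moles of internal
impermeant and `B_e` an external impermeant.  Kept deliberately literal:
the permeant equation is in concentration form with no dilution term, which
preserves the exact exponential relaxation to `A_e - p/k` and leaves the
qualitative conclusions unchanged.  Fixed points: any volume when `b = 0`
(stable); none when `b > 0` undefended (`w` grows without bound —
`w ~ sqrt(2 lam b t)` after the permeant equilibrates); `w* = b/B_e` with
an external impermeant; `w* = b k/p` with a pump (combined:
`w* = b/(B_e + p/k)`).  `classify_regime()` returns exactly this map; a
pump with `b = 0` is classified "stable" by that map even though the toy
dynamics would shrink such a cell — the corner sits outside the model's
intended regimes and the simulator guards against nonphysical collapse by
stopping with a diagnostic.

Default fixture scales are cell-like: `w0 = 1e-15` m^3 (1 pL), bath
osmolarity 300 mol m^-3, exchange rate `k = 0.05` s^-1, impermeant load
`b = 3e-14` mol (30 mol m^-3 at the initial volume), and
`lam = 1e-16` m^3 s^-1 per mol m^-3, which makes swelling visible within a
few thousand seconds; they are scale choices, not fitted quantities, and
rescaling `lam` rescales time without changing any regime.

## Mixture arithmetic

`concentration_sum()` and `water_concentration_difference()` quantify the
anti-misconception argument: at fixed solute concentration the
water-concentration deficit is `c_s v_s / v_w0`, proportional to the
solute's molar volume — only a solute volumetrically identical to water
(heavy water) gives deficit `c_s`.  If water-concentration differences
drove osmosis, the flow would be species-specific, contradicting both the
van 't Hoff law and the combined flux law.  Partial molar volumes are
treated as composition-independent (dilute ideal regime); the deficit
helper refuses inputs with solute volume fraction above 0.1.

## Configs, fixtures, CLI

Scenario configs are strict-schema YAML (unknown keys rejected with their
path), with explicit unit declarations (`M`/`mM`/`mol/m3`, `atm`/`Pa`)
converted to SI at the boundary; temperature defaults to 298.15 K and every
load logs the resolved SI parameters, seed and package version.
`generate_fixtures()` writes one canonical config per scenario, including
all four Donnan regimes and the reduced-unit particle run.  The
`inst/cli/osmoflow` script is a thin wrapper over `load_config()` and
`run_scenario()`; CSV for profiles and time series, JSON for scalar
summaries.

## Known limitations

One-dimensional geometry; ideal-dilute solutes only (no virial
corrections, no osmotic coefficients, osmolarity and osmolality treated as
identical); fully impermeable solutes only (no reflection coefficients);
uncharged species (no Gibbs–Donnan electroneutrality); linear intramembrane
pressure profile (structured membranes excluded); no explicit-solvent or
single-file channel dynamics.  These follow the scope of the mechanical
theory the package implements, not numerical convenience.
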