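# osmoflow

Mechanical modelling of osmotic water transport across semipermeable
membranes, for membrane biophysicists, physiologists and teachers of
transport physiology.

Osmosis is routinely misexplained as "water diffusing down its
concentration gradient".  Measurements on porous membranes falsify that
picture: the osmotic permeability `Pf` exceeds the tracer-diffusion
permeability `Pd` by orders of magnitude, so most of the flow is
convective, and convection needs a mechanical driver.  `osmoflow`
implements that driver quantitatively: the membrane repels the impermeant
solute with a force `F = -dU/dx`; mechanical balance of the fluid at the
solution-side interface (`dP/dx = c_s F`, with the Boltzmann profile
`RT dc_s/dx = c_s F` from zero solute flux) produces a pressure drop

```
P(solution) - P(just inside membrane) = RT c_s
```

and the water is then pushed through the membrane by an ordinary pressure
gradient — the same physics as pressure-driven (Darcy) flow, which is why
one coefficient governs both in the combined flux law

```
Phi_V = -Lp (deltaP - RT deltac_s),      van 't Hoff at Phi_V = 0:  deltaP = RT deltac_s
```

The package provides:

* **Transport laws** — van 't Hoff, Darcy, the combined flux law,
  `Pf = RT Lp / v_w0`, tracer flux, the `Pf/Pd` convective decomposition,
  and the solubility–diffusion bilayer model `Pf = K D / h` (with
  `Pf/Pd = 1` exactly).
* **Continuum profiles** — closed-form equilibrium and osmotic steady-state
  (`Vegard`) concentration/pressure profiles for plateau or Gaussian
  repulsive barriers, plus an independent ODE integration as a cross-check.
* **Brownian dynamics** — overdamped Langevin particles against an
  energy-barrier membrane (compiled kernel), verifying that the
  time-averaged membrane force per area equals `RT c_b`.
* **Pump–leak toy cell** — Donnan swelling from an impermeant load, and its
  stabilization by external impermeants or active pumping.
* **Mixture arithmetic** — the `c_w + c_s` identity and the
  species-specific water-concentration deficit `c_s v_s / v_w0`.
* **Configs + CLI** — strict-schema YAML scenarios, a fixture generator,
  and a thin command-line interface (`inst/cli/osmoflow`).

## Worked example

A membrane with hydraulic permeability `Lp = 1e-12 m s^-1 Pa^-1` separating
pure water (left) from a 100 mol/m^3 (0.1 osM) solution (right) at 300 K,
equal chamber pressures:

```r
library(osmoflow)

van_t_hoff_delta_p(delta_c = 100, temperature = 300)
#> [1] 249420

pot  <- membrane_potential("plateau", U_max = 30 * R_gas * 300, h = 5e-9)
prof <- steady_state_profile(pot, Lp = 1e-12,
                             left  = solution_state(0,   0, 300),
                             right = solution_state(100, 0, 300))
prof$phi_V        # volume flux, m/s (positive: toward the solution)
#> [1] 2.4942e-07
vegard_drop(prof) # interface pressure drop, Pa
#> [1] 249420
```

The equilibrium pressure difference needed to stop the flow is
`RT deltac = 249,420 Pa` (about 2.5 atm): osmotic gradients are *large*.
The steady-state profile shows the same `RT c_s` drop concentrated at the
solution-side interface and a linear pressure decline across the membrane
interior that drives the flux — `plot(prof)` draws both panels.

The particle-level check (reduced units, `RT = 1`):

```r
cfg <- particle_sim_config(membrane_potential("plateau", U_max = 30,
                                              h = 20, interface_width = 1),
                           N = 10000, D_s = 1, reduced = TRUE,
                           n_steps = 1e5, seed = 1)
res <- run_brownian(cfg)
res
#> Brownian membrane simulation
#>   N = 10000, steps = 100000 (+20000 equilibration), dt = 0.00533333, seed = 1
#>   force/area : 621.034 +/- 3.18591
#>   RT c_b ref : 622.816 (z = -0.56)
```

The mean membrane force per unit area agrees with `RT c_b` within its
standard error: collisions of ideal particles with a repulsive barrier
*are* the osmotic pressure.

From the shell:

```sh
inst/cli/osmoflow fixtures --out configs/
inst/cli/osmoflow profile --config configs/vegard_steady_state.yaml --out results/
inst/cli/osmoflow donnan  --config configs/donnan_pump.yaml --out results/
```

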