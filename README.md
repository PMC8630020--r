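# sedpower

Bioenergetics of nitrifiers in marine oxic sediments: a steady-state
reaction-transport model of the sediment column coupled to the
thermodynamics of nitrification, an ammonia-oxidizing-archaea (AOA)
abundance regression, and the cell-specific power requirement that links
them.

## Who this is for

Geomicrobiologists and biogeochemists who want to go from porewater depth
profiles (O2, NO3-, NH4+, Mn2+, DIC, TOC) to quantitative statements about
the energy economy of the nitrifying community: how fast is nitrification,
how much free energy does it deliver per volume of sediment, how many AOA
cells share that power, and how much does each cell get.

## The model in brief

**Reaction transport.** Five porewater solutes and four solids on a 1-D
finite-volume grid, at steady state. Organic matter is a 3-G mixture
(reactivities `k1 >= k2`, third pool inert) degraded aerobically (R1), by
denitrification (R2, O2-inhibited) and by MnO2 reduction (R3); secondary
bimolecular reactions are nitrification (R4 = phi k_nit [NH4+][O2]),
Mn(II) oxidation (R5) and anammox (R6). Fixed concentrations and fluxes at
the sediment-water interface, zero gradient at the base; damped Newton
with a sparse analytic Jacobian solves the coupled system to a relative
residual of 1e-10.

**Energetics.** For nitrification written with ammonia as substrate,
NH3 + 2 O2 -> NO3- + H+ + H2O,

    dGr = dGr0(T,P) + RT ln Qr,    Qr = a(NO3-) a(H+) / (a(NH3) a(O2)^2)

with extended Debye-Hueckel activity coefficients and
[NH3] = [NH4+] x 10^(pH - 9.3). The volumetric power supply is
Ps = |dGr| * R4, converted to W m-3. Both an 8-electron (stoichiometric)
and a 4-electron-equivalent normalisation of dGr per mol e- are supported.

**Abundance and per-cell power.** The AOA fraction of the community decays
as y = a exp(b x) with relative depth x = z/OPD in the oxic zone; fitted by
nonlinear least squares with heteroscedasticity-robust confidence bands,
it converts total cell counts into AOA abundances, and
P_cell = Ps x 1e-6 / abundance gives W per cell.

A six-preset synthetic-site generator (organic fluxes 1.4e-4 to
0.24 mol C m-2 yr-1, oxygen penetration from ~0.14 m to beyond a 67 m
column) provides fully specified ground truth for every stage.

## Worked example

```r
library(sedpower)
pl <- run_pipeline("AMOR-like", seed = 7)
print(pl)
```

```
<sed_pipeline> AMOR-like
  OPD: 0.899 m
  dG: -42.9 to -41.1 kJ (mol e-)-1 over the oxic zone
  Ps: 6.2e-06 to 9.45e-05 W m-3
  cell-specific power: 2.85e-19 to 1.16e-16 W cell-1
  AOA fit: a = 31.2%, b = -2.64, R2 = 0.70 (n = 40)
```

Reading this: the ridge-flank synthetic core is oxic to 0.90 m;
nitrification there is thermodynamically favourable at about -42 kJ per
mol of electrons (8-electron normalisation) and supplies 6e-6 to 1e-4 W
per m3 of sediment; divided among the AOA estimated from the decay
regression (here fitted to synthetic community data with known truth
a = 22.3%, b = -2), each cell receives on the order of 1e-19 to 1e-16 W.
The building blocks are available individually:

```r
pp  <- make_site_preset("AMOR-like")
fit <- rtm(pp$site, pp$kinetics, grid = pp$grid)  # classed model fit
print(fit)
#> <rtm_fit> AMOR-like
#>   199 cells on [0, 4] m; converged in 22 iterations (residual 1.72e-14)
#>   OPD: 0.8994 m
summary(fit)         # integrated rates, element-budget audit
plot(fit)            # profile panels
coef(fit)            # kinetic parameters + organic flux
```

`rtm()` also calibrates free parameters (`free = c("k1", "F_org",
"k_nit")`) against measured data by weighted least squares, `calibrate()`
and `sensitivity_scan()` expose that machinery directly, and
`read_profile_table()` / `read_run_config()` accept CSV profiles and YAML
run configurations.

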