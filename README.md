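# nltaxis

Simulation and analysis of **nonlocal diffusion–taxis systems**: N
interacting populations on the periodic unit interval that move by
diffusion plus attraction towards, or avoidance of, the locally averaged
density of the other populations. The package is aimed at movement
ecologists and modellers who want to know which between-population
movement responses produce spatial structure — territories, aggregations,
or perpetually shifting distributions — on timescales where births and
deaths are negligible.

The core model for the densities $u_i(x,t)$, each integrating to 1, is

$$\frac{\partial u_i}{\partial t}
  = d_i \frac{\partial^2 u_i}{\partial x^2}
  - \frac{\partial}{\partial x}\Bigl(u_i \sum_{j\neq i} \gamma_{ij}
    \frac{\partial \bar u_j}{\partial x}\Bigr),
  \qquad
  \bar u_j(x) = \frac{1}{2\delta}\int_{x-\delta}^{x+\delta} u_j(z)\,dz ,$$

with periodic boundaries, relative diffusivities $d_i$ ($d_1 = 1$), taxis
coefficients $\gamma_{ij}$ (positive = attraction, negative = avoidance,
$\gamma_{ii}=0$), and a top-hat averaging window of half-width $\delta$
that regularises the otherwise ill-posed local limit.

What the package provides:

- **Model definition** (`taxis_model()`) and the non-dimensional mapping
  from three mechanistic interaction scenarios — direct sensing, scent
  marking, spatial memory (`scenario_params()`, `nondimensionalize()`).
- **Linear pattern-formation analysis**: dispersion relations from the
  eigenvalues of $\kappa^2 M(\kappa,\delta)$, stationary vs oscillatory
  (wave) instability, two-population closed forms and the
  $\gamma_{12}\gamma_{21} > d_2$ criterion, and two-parameter regime maps
  (`dispersion_relation()`, `scan_parameter_plane()`).
- **A conservative PDE solver** (explicit or semi-implicit, compiled):
  exact discrete mass conservation, positivity monitoring, seeded random
  initial conditions (`simulate_model()`).
- **Energy diagnostics** for the symmetric two-population case: descent
  of the energy functional, its lower bound $-4e^{-1} - 1/\delta$,
  steady-state residuals, aggregation/segregation sign structure, and the
  moment-closure curvature analysis (`energy_audit()`,
  `steady_state_residuals()`, `curvature_roots()`).
- **Quasi-continuation bifurcation analysis** for three populations:
  warm-started parameter sweeps, probe-orbit classification by
  peak-height matching, and localisation of the period-doubling cascade
  that leads to irregular, chaos-like dynamics (`continuation_sweep()`,
  `cascade_analysis()`).

A thin command-line interface (`exec/nltaxis`) exposes `dispersion`,
`scan`, `simulate`, `energy-audit`, `bifurcate` and `schematic`
subcommands over JSON configs and CSV outputs.

## Worked example

Two populations that avoid each other ($\gamma_{12}=\gamma_{21}=-2$,
$\delta = 0.1$) segregate into complementary territories:

```r
library(nltaxis)

m <- taxis_model(d = c(1, 1),
                 gamma = rbind(c(0, -2), c(-2, 0)),
                 delta = 0.1)

classify_pair(m$gamma[1, 2], m$gamma[2, 1])
#> [1] "mutual_avoidance"
n2_pattern_criterion(-2, -2, d2 = 1)   # gamma12*gamma21 = 4 > 1
#> [1] TRUE

d <- dispersion_relation(m)
d
#> Dispersion relation over 400 wavenumbers
#>   regime:      stationary
#>   max Re sigma: 81.5307 at kappa* = 13.0326

tr <- simulate_model(m, tau = 1e-5, t_end = 20, n = 100,
                     sample_every = 0.1, seed = 11,
                     stop_when_steady = TRUE, steady_tol = 1e-4)
tr
#> Taxis trajectory: 96 samples on [ 0 , 9.5 ]
#>   grid n = 100 , tau = 1e-05 , scheme = explicit , status = steady
#>   max |mass error| = 2.220446e-14

u <- state_at(tr)$u
cor(u[, 1], u[, 2])
#> [1] -0.8903116
sign_structure(state_at(tr), delta = 0.1)
#> [1] "segregation"

energy_audit(tr)
#> Energy audit over 96 samples
#>   E: 4.000001 -> 2.982864
#>   lower bound: -11.47152 ; closest approach: 2.982864
#>   increases beyond tolerance: 0
```

The linear analysis predicts a stationary instability with a positive
growth band at moderate wavenumbers; the simulation reaches a steady
segregated state (negative spatial correlation between the two
densities) with machine-precision mass conservation, and the energy
functional decreases monotonically from its homogeneous value
$-2\gamma = 4$ while staying far above its theoretical lower bound —
certifying convergence rather than transient coincidence.

For three populations, oscillatory (wave) instabilities become possible.
The bifurcation toolkit sweeps a taxis coefficient through the
oscillatory regime and classifies the attractor at a probe point:

```r
tpl <- taxis_model(d = c(1, 1, 1),
                   gamma = rbind(c(0,  3, -1),
                                 c(1,  0, -2.5),
                                 c(1,  1,  0)),
                   delta = 0.1)
res <- cascade_analysis(tpl, seed = 17)   # several minutes
res$t1   # control value of the first period-doubling of the probe orbit
res$t2   # second doubling (period-2 -> period-4 / loss of period-2)
```

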