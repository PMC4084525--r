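# plateletsim

Three-dimensional multi-scale simulation of deformable platelets tethering
to a vessel wall in shear flow, in R (with Rcpp kernels).

When a vessel is injured, flowing platelets are first caught by transient
GPIbα–vWF bonds: they tether, pause, flip and release on the damaged
surface before any stable adhesion forms. `plateletsim` models this first
step by coupling three scales:

* **cell** — a hybrid membrane: a spring-network cytoskeleton
  (`k = E Δx / 5`) on a closed triangulated oblate spheroid
  (`x²/a² + y²/a² + z²/(λa)² = 1`, a = 1 μm, λ = 0.25, 958 vertices),
  with global/local area and volume penalties and a Helfrich-type bending
  force `F_bend = k₀ (Δ_Σ K + 2K³) A n̂`;
* **bond** — stochastic adhesive dynamics for individual GPIbα–vWF bonds:
  Bell dissociation `k_off(F) = k⁰_off exp(γF/k_BT)`, Dembo association
  `k_on(x) = k⁰_on exp(−σ(x−l_b)²/2k_BT)`, per-step probabilities
  `P = 1 − exp(−k Δt)`, one bond per receptor site, at most four sites per
  vWF;
* **fluid** — a D3Q19 lattice Boltzmann solver (BGK + Guo forcing,
  `ν = c_s²(τ−½)Δt`), periodic sides, moment-exact on-site velocity walls,

coupled by the immersed boundary method (4-point cosine kernel). The
package ships the validation and prediction studies at desk scale: Jeffery
orbit of the tumbling platelet, pause-time statistics with `k_off`
estimation, and reduced-scale experiments on membrane stiffness, receptor
number and platelet–platelet interaction.

## Worked example

```r
library(plateletsim)

p <- platelet_params()                        # published defaults
compute_timestep(1.379, 0.2e-6, p$mu / p$rho) # LBM timestep
#> 1.000009e-08                                 (= the 1e-8 s operating point)
reynolds_number(400, p$rho, p$a, p$mu)
#> 0.0003413                                    (Stokes regime)

mesh <- place_receptors(make_platelet_mesh(), 5344, seed = 1)
mesh
#> <platelet_mesh> 958 vertices, 1912 triangles, 2868 edges
#>   a = 1e-06 m, lambda = 0.25, area0 = 7.061e-12 m^2, V0 = 1.035e-18 m^3
#>   5344 receptor sites (10688 receptors)
sum(mesh$receptors$n_receptors) / (mesh_area_volume(mesh)$area * 1e12)
#> 1513.646                                     (receptors per um^2; ~1500)

kp <- kinetic_params()
bell_off_rate(c(0, 20e-12), kp)               # unstressed and at 20 pN
#> 3.45 106.35                                  (1/s)

# off-rate estimation from pause durations (the flow-chamber estimator)
d <- make_exponential_durations(3.45, 2000, seed = 7)
glance(estimate_koff(d))
#> # A tibble: 1 x 4
#>    koff r.squared n_events degenerate
#> 1  3.47     1.000     2000 FALSE
```

The coupled simulator is assembled with `platelet_simulation()` and
advanced with `sim_step()`; `run_flipping()` reproduces the Jeffery-orbit
validation, `run_adhesion_experiment()` / `run_tether_study()` the
tethering studies, and `detect_pause_events()` + `estimate_koff()` the
pause-time analysis. Results are tibbles with `tidy()`/`glance()`/
`autoplot()` methods. A thin command-line wrapper lives at
`inst/scripts/sim.R`.

See the vignette (`vignettes/platelet-adhesion-model.Rmd`) for the model
equations, parameter table, numerical choices and the limits of the
reduced desk-scale preset.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities from
scratch — it generates the default platelet mesh, places the receptor
field, computes the receptor surface density from the mesh's own area,
evaluates the unstressed Bell off-rate, and reports the mesh vertex count —
and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
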