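# CarbonTransit

Transit-time and age distributions for compartmental models of the
terrestrial carbon cycle.

The time carbon spends in the terrestrial biosphere — from uptake by
photosynthesis to release by respiration — controls how long the land
surface can hold carbon away from the atmosphere. For a linear
compartmental model

$$\dot x = u + B\,x,$$

with input vector $u$ (PgC yr⁻¹) and compartmental matrix $B$ (yr⁻¹),
the equilibrium transit time is a phase-type random variable whose
density, moments and quantiles have closed forms:

$$f_T(\tau) = -\mathbf{1}^\top B\, e^{\tau B} u / \lVert u\rVert,
\qquad
E[T] = \mathbf{1}^\top(-B^{-1})u/\lVert u\rVert
     = \lVert x^*\rVert / \lVert u\rVert .$$

Out of equilibrium the relevant quantity is the **backward transit
time** (BTT): the age of the carbon leaving in the respiration flux at
time $t$. CarbonTransit computes it from the state-transition operator
$\Phi(t,s)$ of the forced system $\dot y = B(t)y + u(t)$, via the
age-resolved mass density
$m(t,a) = \Phi(t, t-a)\,u(t-a)$ (with the equilibrium age structure
carried over for carbon already present at the start), and the
respiration-age density $r(t,a) = -\mathbf{1}^\top B(t)\, m(t,a)$.

The package is aimed at carbon-cycle and radiocarbon modellers. It
provides:

- validated compartmental systems (S4), steady states, and the
  closed-form age/transit-time machinery with moments and quantiles;
- a non-autonomous solver for trajectories, $\Phi(t,s)$, age-mass
  densities and BTT distributions with exact (solver-integrated) totals
  and means;
- the five-pool global terrestrial model of Emanuel *et al.* (1981)
  with idealized twentieth-century CO2 and temperature forcing, and
  three scenario experiments (CO2-only, temperature-only, combined)
  over 1850–2020;
- radiocarbon (Δ¹⁴C) tracer dynamics of pools and of the respiration
  flux, driven by a tabulated atmospheric history or a built-in
  synthetic bomb-spike curve;
- homogeneity diagnostics $h = m_b/(\ln 2\,E_b)$ and $h' = E_b/E_A$,
  and an age-bin aggregation operator for pooling BTT distributions
  across sub-systems;
- synthetic-system generators and an independent Monte-Carlo particle
  oracle (continuous-time Markov chain simulation) used throughout the
  tests.

## Worked example

```r
library(CarbonTransit)

sys <- emanuelModel()
sys
#> CompartmentalSystem with 5 pools
#>   pools: nonwoody_tree, woody_tree, ground_vegetation, detritus, active_soil
#>   total input: 113 PgC/yr
#>   steady-state stock: 1760 PgC

mom <- transitTimeMoments(sys)
qs  <- transitTimeQuantile(sys, c(0.5, 0.95))
sprintf("mean %.1f yr, sd %.1f yr, median %.1f yr, q95 %.1f yr",
        mom$mean, mom$sd, qs[1], qs[2])
#> "mean 15.6 yr, sd 45.0 yr, median 2.3 yr, q95 77.0 yr"
```

Half of the carbon fixed by photosynthesis is respired within 2.3
years, while the mean transit time is 15.6 years (= 1760 PgC / 113 PgC
yr⁻¹) — the distribution is far from exponential, with a long tail of
old soil carbon (h ≈ 0.21 at equilibrium).

Forcing the same model with rising CO2 (productivity) and temperature
(cycling rates):

```r
res <- runScenario("both", by = 10)
res
#> ScenarioResult: both scenario, 18 time steps over [ 1850 , 2020 ]
#>   change since 1850 (% of initial value):
#>   mean median    q95
#>   13.1   19.0   16.9
```

Mean, median and 95% quantile of the backward transit time all drop:
the productivity effect (more young carbon feeding a larger respiration
flux) dominates the temperature effect (which alone would *raise* the
mean by releasing old soil carbon — run `runScenario("temp")` to see
it). `diagnosticsSeries(res)` adds the mean system age and the
homogeneity ratios; `distributionDifference(res, 2020)` shows where in
age the 2020 respiration flux differs from equilibrium.

Pipelines (`runEquilibriumPipeline()`, `runScenarioPipeline()`,
`runRadiocarbonPipeline()`) write tidy CSV/JSON output; a thin
command-line wrapper lives at `inst/cli/carbon-transit.R`.

## Vignette

`vignettes/transit-times.Rmd` documents the model and its assumptions,
the numerical design (age-adjoint integration of the state-transition
operator, exact moment accumulation, grid and tolerance choices) and
the known limitations.
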