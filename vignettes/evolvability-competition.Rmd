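---
title: "Competing evolvabilities: model, scenarios and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing evolvabilities: model, scenarios and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evodyn)
```

## The model

`evodyn` simulates two (or more) competing species that are identical in
every ecological respect but differ in *evolvability* — the rate constant
`k` that converts a selection gradient into strategy change.  The
per-capita growth rate of a rare focal individual with strategy `v` in a
community with resident strategies `u_j` and densities `x_j` is the
fitness-generating function

$$G(v, \mathbf u, \mathbf x) \;=\; \frac{r}{K(v)}\Bigl(K(v) -
\sum_{j} a(v, u_j)\, x_j\Bigr) \;-\; d\,k,$$

a Lotka–Volterra competition model with two Gaussian kernels and a linear
cost of evolvability:

* **Carrying capacity** $K(v) = K_m \exp\!\bigl(-(v-\gamma)^2 / 2\sigma_k^2\bigr)$:
  resources peak at the environmental optimum $\gamma$, which the
  environment schedules move over time.
* **Competition** $a(v,u) = \exp\!\bigl(-(v-u)^2/2\sigma_a^2\bigr)$: like
  competes most with like; $a = 1$ at $v = u$.  A *bounded* variant
  $a = 0.05 + 0.95\exp(\cdot)$ keeps residual competition between
  arbitrarily distant strategies and is the default in the
  adaptive-radiation scenario, where $\sigma_a^2 < \sigma_k^2$ would
  otherwise permit unlimited niche packing.
* **Cost of evolvability** $d\,k$: producing heritable variation is
  penalised in proportion to the rate at which it is produced.  The cost
  uses the *focal* species' own `k`, which is what places the slow
  evolver's adaptive landscape exactly $d(k_1 - k_2)$ above the fast
  evolver's at every strategy.

Each species' density and mean strategy follow

$$\frac{dx_i}{dt} = x_i\, G\rvert_{v=u_i}, \qquad
  \frac{du_i}{dt} = k_i \,\frac{\partial G}{\partial v}\Big\rvert_{v=u_i},$$

so a large `k` buys speed along the adaptive landscape at a constant
fitness toll.  The competition sum runs over *all* extant species,
including every daughter lineage created during a radiation — without
that, multi-species coexistence at distinct minima could not feed back on
the landscape.

With a single resident the eco-evolutionary equilibrium is closed form:
`u* = gamma` and `x* = K(u*) (1 - d k / r)`; under the default parameters
(`r = 0.25, Km = 100, d = 0.05`) that is `x* = 96` for the slow evolver
(`k = 0.2`) and `90` for the fast one (`k = 0.5`).  These exact values
anchor the unit tests.

```{r equilibrium}
p <- model_params()
equilibrium_single_species(k = 0.2, gamma = 0, params = p)
```

## Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `r` | intrinsic growth rate | 0.25 | 1/time |
| `Km` | maximum carrying capacity | 100 | density |
| `d` | cost of evolvability | 0.05 | fitness per unit `k` |
| `sigma_k2` | resource-kernel variance | 12.5 | strategy² |
| `sigma_a2` | competition-kernel variance | 100 (2 in radiation) | strategy² |
| `k_fast`, `k_slow` | founder evolvabilities | 0.5, 0.2 | strategy²/time per gradient |
| `extinction_threshold` | density below which a species is removed | 1 | density |
| `x0` | founder density | 10 | density |

The deterministic ODE model never reaches zero density on its own; the
threshold of one individual per unit area stands in for demographic
stochasticity and Allee effects.  It is checked *strictly below* at every
recorded sample (`record_dt = 1` by default), after which the species'
density is fixed at 0, its strategy frozen, and it leaves all competition
sums; extinction is absorbing.

Founder densities are a modelling choice the model itself does not fix.
The package default `x0 = 10` per founder was set once, up front; under
it the clade-initiation extinction times come out at 315, 1022 and 11
time units for the close, medium and far starts, and the early- and
middle-disturbance rescue extinctions at 665 and 910 — the reference
values the acceptance checks assert.  Every output header records the
value used.

## Environment schedules

The environment acts only through `gamma(t)`, the position of the
carrying-capacity peak (the competition kernel never sees it):

* `env_constant()` — clade initiation and radiation.
* `env_stochastic()` — piecewise-constant `gamma` redrawn uniformly from
  `[-2, 2]` every 5 time units.  `gamma(0) = 0` is held until the first
  redraw at `t = 5`; the alternative reading (a draw already at `t = 0`)
  shortens far-start extinction times by roughly a quarter but stays well
  inside the replicate spread.  Draws consume a dedicated RNG stream, so
  community events cannot shift the realised environment.
* `env_sinusoidal()` — `gamma(t) = sin(t/50)` by default.
* `env_steps()` — explicit `(time, gamma)` jumps for the rescue and
  disturbance-regime experiments.

The integrator (lsoda via `deSolve`, `rtol = 1e-8`, `atol = 1e-10`) is
hard-restarted at every schedule discontinuity so no internal step
straddles a jump in `gamma`; sub-`record_dt` step times become extra
samples.  Integration failures raise errors rather than truncating
silently.  Densities are clipped at zero against sub-tolerance overshoot.

## Scenarios

**Clade initiation** (`run_clade_initiation`): both founders start at the
same strategy in a constant environment.  Far from the optimum the fast
evolver climbs first and the slow evolver dies (11 time units from
`u0 = 10`); close to the optimum the fast evolver pays its cost for
nothing and dies (315 time units from `u0 = 0.5`; 1022 from `u0 = 4`).

**Evolutionary tracking** (`run_tracking`): under the stochastic
schedule, 100 replicates per case; the summary reports, per species, how
many replicates lost it and the mean ± sample SD of the extinction times
over those replicates.  Under the sinusoidal schedule both strategies
oscillate — the fast evolver with the larger amplitude — and the winner
ordering mirrors clade initiation from close starts.

**Evolutionary rescue** (`run_rescue`): from the medium start, a step of
`gamma` to −4 at 600, 750 or 900 time units.  The fast evolver reaches
the new optimum in time in all three cases; the slow evolver dies shortly
after the early and middle disturbances and survives — then recovers and
ultimately prevails, thanks to its lower cost — after the late one.

**Disturbance regimes** (`run_disturbance_regime`): explicit step trains;
the outcome is classified from the extant founders at the horizon.
Because coexistence in this model is *transient* (one species eventually
outcompetes the other even in the "balanced" regime — the fast evolver
in the intermediate regime dies around t = 2675), the classification
horizon matters: the default `t_end = 2500` matches the span over which
the three canonical regimes (second shift at 1800 / 1700 / 1600) yield
fast-extinct / both-persist / slow-extinct.  Fixture configurations for
all printed schedules, including the transient-disturbance variants and a
qualitative periodic train, ship under `inst/extdata/configs/`.

**Adaptive radiation** (`run_adaptive_radiation`): bounded kernel,
`sigma_a2 = 2`.  The two-resident equilibrium places each founder on a
*convergent-stable minimum* of its landscape — an evolutionary branching
point — and is independent of the founding strategy (a property of the
uncapped ODE flow; from far starts the transient dips below the usual
extinction threshold, so that comparison is run with a negligible
threshold).  The speciation loop then:

1. recomputes the singular points of the current landscape after every
   recorded step (their locations are shared across `k`, since the linear
   cost drops out of all derivatives);
2. triggers speciation when an extant species *newly approaches* within
   0.02 of a convergent-stable minimum — the species must have left the
   0.02 neighbourhood since its last branching, and be past a 5-unit
   refractory.  Edge-triggering matters: a parent *sitting at* a minimum
   would otherwise re-trigger every refractory period.  Equally,
   requiring convergence stability screens out the transient minimum that
   chases the slower resident early in the race, which is a minimum of
   the landscape but not an attractor of the strategy dynamics;
3. gives the daughter its parent's `k`, strategy `u ± 0.02` (uniform on
   the interval by default; a two-point draw is available) and density 1.

A daughter is born exactly at the extinction threshold and necessarily
dips a few percent below it for tens of time units before disruptive
selection carries it into its own niche.  A threshold meant to proxy
demographic stochasticity in established populations would cull every
branch at birth and make the procedure inconsistent, so the loop applies
the threshold only to *established* lineages — those whose density has
exceeded it at least once (founders qualify at birth).  Under this rule
the radiation reproduces the expected asymmetry: every speciation event
has a fast-evolving parent, and the slow lineage never branches first and
never goes extinct — it is simply pushed to ever more extreme strategies.

The lineage tree is returned as a phylogeny and serialises to Newick with
branch lengths in simulation time units and internal node labels equal to
lineage ids.

```{r radiation, eval = FALSE}
rad <- run_adaptive_radiation(scenario_config("adaptive_radiation",
                                              t_end = 1500,
                                              max_species = 8, seed = 7))
as_newick(rad$phylogeny)
```

## Numerical choices

* **Derivatives** of `G` are analytic (closed-form kernel derivatives),
  cross-checked in the tests against central finite differences
  (`h = 1e-4` for the gradient; `h = 1e-3` for the curvature, where
  smaller steps lose accuracy to cancellation) to better than `1e-6`
  relative error on randomised configurations.
* **Singular points**: sign-change scan of the gradient on a `0.01` grid
  over `[-20, 20]`, bisection refinement to `1e-8`, classification by
  curvature sign plus a convergence-stability test (the resident nearest
  the root is moved onto it and the derivative of its own gradient with
  respect to its position must be negative).  An empty community has a
  flat landscape, so the analysis places a phantom resident at its
  single-species equilibrium and reports the carrying-capacity peak.
* **Extinction-time discretisation**: times are reported on the
  `record_dt` grid; halving `record_dt` while tightening tolerances
  tenfold moves the close-case clade-initiation extinction time by well
  under 1%.
* **Seeds**: one master seed per run.  Tracking replicates draw
  per-replicate seeds from it; the stochastic environment and the
  speciation offsets consume separate streams, and the caller's RNG state
  is restored afterwards, so runs are bit-reproducible.
* **Ties**: simultaneous speciation candidates are resolved
  closest-to-minimum first, then community order; simultaneous threshold
  crossings are marked extinct at the same sample.

## Problem sizes used by the tests

Deterministic scenario checks integrate single runs of 400–3000 time
units (seconds each).  The stochastic-tracking checks use the full 100
replicates per case at a 600-unit horizon.  The radiation checks use a
1500-unit horizon capped at 8 species, enough for several branching
events.  The two-resident equilibrium comparison runs to 12 000 units at
a 5-unit recording interval.

## What the simulations do and do not show

Everything here is a deterministic (or seeded) ODE world: no demographic
stochasticity, no Allee dynamics beyond the extinction cutoff, no spatial
or stage structure, evolvability itself never evolves, and "speciation"
is an imposed procedural rule at branching points rather than an emergent
splitting of a trait distribution.  Strategy variances are implicit in
`k`; the model tracks only population means.  Passing tests demonstrate
that the implementation reproduces the model's documented behaviour — the
reference extinction times, the winner orderings, the branching
asymmetry — not that real communities behave this way.  The medium-start
cases are the most sensitive to the founder-density choice and deserve
the most caution when varied.
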