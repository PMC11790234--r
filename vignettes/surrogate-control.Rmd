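---
title: "ODE surrogate models for controlling agent-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ODE surrogate models for controlling agent-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Agent-based models (ABMs) describe populations of discrete, rule-following
agents on a spatial grid. They are natural models for ecological and
biochemical systems but awkward objects for optimal control: their state is
high-dimensional and their dynamics emerge from stochastic rules rather than
equations. `abmctrl` implements a surrogate-modeling pipeline around this
obstacle:

1. simulate a replicate ensemble of the ABM (optionally under several levels
   of control),
2. calibrate a low-dimensional ODE system — the *surrogate* — to the
   ensemble means by least squares,
3. solve the control problem on the surrogate with standard continuous
   methods,
4. discretize the solution back into per-step probabilities and validate it
   on the ABM with a replicate-averaged grid search.

This vignette records the modeling decisions behind each stage: the model
forms, the tunable parameters and their defaults, the numerical choices, and
what the desk-scale experiments do and do not demonstrate.

## The two reference ABMs

### Sheep, wolves and grass

A toroidal lattice predator-prey model. Sheep and wolves carry an energy
budget: each step every animal turns by at most one octant and moves one
cell (a persistent-heading walk, the lattice analogue of the classic
wiggle-and-step movement; a memoryless 8-neighbour walk mixes measurably
worse and starves the predators at small world sizes), paying `move_cost`
energy (default 1). A sheep standing on fully grown grass eats it, gaining
`sheep_gain = 4` energy and starting that cell's 30-step regrowth countdown;
a wolf sharing a cell with a sheep eats one, gaining `wolf_gain = 20`. Each
animal reproduces with probability 4% (sheep) or 5% (wolves) per step,
splitting its energy evenly with the offspring; an animal whose energy
reaches zero dies. The scheduler order within a step is fixed: move, eat,
reproduce, die, scheduled control removal, grass regrowth.

The reference configuration is a 255 x 255 world with 2,500 sheep, 1,250
wolves and 50% initial grass cover. All desk-scale work uses the
density-preserving `scale = 5` configuration (51 x 51, 100 sheep, 50
wolves), which sustains the predator-prey oscillation (grass ~950, sheep
~165, wolves ~80 at the noisy steady state) with no wolf extinctions over
2,000-step horizons.

```{r}
library(abmctrl)
model <- sheep_wolves_params(scale = 5)
traj <- run_simulation(model, 2000, seed = 1)
plot_trajectory(traj)
```

### An elementary-step enzymatic pathway

Five metabolites and four enzymes on a small lattice, with every reaction
resolved at the elementary level: substrate S is converted through
intermediates A and B into the branch products R and T
(S -> A by E1, A -> B by E2, B -> R by E3, B -> T by E4; all catalytic steps
irreversible). Molecules are individual agents; metabolites take ten
movement substeps per enzyme step, and a metabolite landing on a cell with a
binding-competent partner binds with the pair's probability. Complexes may
dissociate at any step. Two regulatory interactions couple the branches in
mixed-inhibition form: product T binds E3 (free or loaded: complexes E3T,
E3BT) and R binds E4 (E4R, E4BR), blocking catalysis while bound. With the
four enzyme-substrate and four enzyme-product complexes this gives the 12
enzyme-containing complex species of the reference topology. The
interaction tables are plain data (`metabolic_params()` builds them), so
alternative topologies can be declared without touching the engine.

In continuous mode the vessel behaves like a constant-volume stirred tank:
S flows in at `inflow` expected molecules per step (a Bernoulli one-molecule
insertion, which keeps agents integer and is unbiased for fractional rates)
and every free metabolite independently leaves with probability
`outflow = 0.0005` per step; enzymes and complexes never leave.

The lattice size (16 x 16), molecule counts (400 S; 40/40/20/20 enzymes)
and event probabilities are desk-scale choices: the published experiment
this pathway emulates is not accompanied by its full interaction/probability
table, so the defaults here are a declared stand-in chosen for clean batch
behaviour (substrate depletes over roughly 10^4 steps through visible
intermediate waves) and stable continuous-mode operation. Two exact
invariants hold by construction and are enforced in the tests: each
enzyme's total count (free + complexed) is constant, and in batch mode the
total number of metabolite moieties (free + bound) is conserved.

## The surrogate families

All surrogates share one contract: an evaluable right-hand side, a packed
parameter vector (`surrogate_params()` / `set_params()` are exact inverses),
a linear control term, and integration with stiff fallback.

* **Mechanistic** (`mechanistic_model()`): processes with declared
  functional forms tied to a signed stoichiometric matrix. The
  sheep-wolves reduction is the logistic-plus-Lotka-Volterra system
  `dX/dt = k1 X - k2 X^2 - k3 X Y`, `dY/dt = k4 X Y - k5 Y - k6 Y Z`,
  `dZ/dt = k7 Y Z - k8 Z` (X grass, Y sheep, Z wolves); the pathway's
  mean-field model is four irreversible Michaelis-Menten rates over free
  metabolite counts with competitive inhibition factors `ki/(ki + I)` for
  the two regulatory interactions.
* **Generalized mass action** (`gma_model()`): every process is a power law
  `alpha_j * prod_k X_k^(g_jk)` in all state variables; only the
  stoichiometry is assumed. The sheep-wolves GMA uses seven processes
  (the logistic pair collapses into one net-growth power law), hence
  `7 * (1 + 3) = 28` free parameters.
* **Taylor expansions at the steady state** (`taylor_model()`): order 1
  treats the Jacobian entries as free parameters (`n^2` of them); order 2
  adds symmetric Hessians per coordinate (`(3n^2 + n^3)/2` total). The
  expansion point is the tail average of the uncontrolled ensemble
  (`estimate_steady_state()`, trailing 25% by default).
* **S-system** (`ssystem_model()`): each equation is an aggregate influx
  minus an aggregate efflux power law, `2(n + n^2)` parameters.

Power laws define `0^0 = 1`; a zero state raised to a negative kinetic
order raises a domain error rather than being clamped — silent clamping
would mask calibration pathology.

## Calibration

`fit_parameters()` minimizes the unweighted squared deviation between the
dataset means and the surrogate integrated from each dataset's initial mean
state under that dataset's control level, residuals concatenated over all
datasets (an optional per-variable `1/max` scaling exists for badly scaled
systems, off by default). Optimization is bounded Levenberg-Marquardt from
multiple starts: the time-course slope guess (central-difference derivatives
regressed one scalar rate at a time onto the process terms), Latin-hypercube
perturbations of it, and — for the power-law families — a warm start
obtained by locally collapsing a fitted mechanistic model into power laws at
the data's mean state (matching value and logarithmic derivatives; a
Michaelis-Menten rate contributes kinetic order `Km/(Km+S)` in its substrate
and `-I/(Ki+I)` in its inhibitor). The warm start is a numerical device:
it changes where optimization starts, never what the family can express.

Family-specific fitting practice for the reference experiments
(`fit_reference_surrogate()`): the linear expansion is fitted only to the
uncontrolled baseline ensemble (its validity region cannot span several
initializations — the full-scale experiment handled it the same way); the
quadratic is fitted only to datasets sharing its expansion point's
initialization; both Taylor families use the per-variable `1/max` residual
scaling (populations span 950 grass cells vs 80 wolves, and unscaled
residuals would let the grass equation dominate a local expansion).

Defaults that matter:

* bounds: rate constants in `(1e-9, 1e9]`, kinetic orders in `[-4, 4]`,
  Taylor entries unbounded. The rate upper bound must accommodate power
  laws with negative kinetic orders at count scales of 10^3 (a rate
  `f * X^2` with `X ~ 1000` is of order 10^8), which is why it is far above
  any per-capita rate.
* the L1 penalty `lambda * sum |kinetic orders|` applies to kinetic orders
  only; sparsifying orders performs variable selection while rate constants
  stay free. It is implemented by appending `sqrt(lambda * |g|)`
  pseudo-residuals; orders below `zero_tol = 1e-4` are reported as zero in
  the sparsity mask.
* integration during fitting uses `lsoda` with a capped internal step
  budget, so pathological parameter proposals fail fast instead of
  stalling the optimizer.
* `fit_quadratic_with_root_constraint()` re-runs the multi-start fit and
  rejects any candidate whose right-hand side has a root other than the
  expansion point inside the control problem's region of interest (found by
  `find_roots()`, a multi-start damped least-squares search from a start
  lattice, deduplicated at 1e-6 per coordinate). The default region is
  40%-160% of the baseline steady state: quadratic expansions routinely
  acquire spurious steady states further out, and it is the operating
  region that the control trajectory must cross that has to be clean.

## The two control problems

**Steady-state transfer (sheep-wolves).** Input matrix `diag(0, 1, 1)`,
control `u = (0, -kappa2 Y, -kappa3 Z)`: find constant per-step removal
rates that move the system to a new steady state with 10% more sheep and
50% fewer wolves, minimizing the total number of animals removed.
`solve_transfer_on_surrogate()` root-finds the two rates against the two
target conditions with a damped box-constrained Newton iteration (explicit
finite-difference steps of 1e-4: the residual comes out of an ODE solve
whose discretization jitter defeats machine-epsilon difference steps); the
controlled steady state is obtained by long-horizon integration plus a
damped-Newton polish (controlled power-law systems lack closed forms).
Among candidates matching within tolerance, the one with the smallest
removal integral wins. Removal rates are capped at the training control
levels (2% sheep, 1.5% wolves per step): training deliberately applies more
control than the expected optimum, so keeping solutions inside that range
makes control solving an interpolation rather than an extrapolation. Rates transfer to the ABM
one-to-one (`transfer_to_abm()`): the ODE time unit is one ABM step, so a
rate is a per-step Bernoulli removal probability; a rate above 1 cannot be
a probability and is an error.

**Inflow optimization (metabolic).** Minimize the cumulative
substrate-to-product loss `sum_k S_k / (R_k + T_k)` over the horizon as a
function of the constant substrate inflow `Q` in `[0, 1]`.
`solve_inflow_on_surrogate()` scans a dense grid, reports the integrable
sub-domain when the surrogate cannot be integrated everywhere (a routine
occurrence for stiff power-law fits), flags the absence of an interior
minimum, and refines an interior best point by local 1-D minimization.

Steps where `R_k + T_k = 0` make the loss undefined. Two policies exist:
`"skip"` (default for descriptive use: such steps are omitted and counted)
and `"strict"` (an error). The grid-search validation uses the strict
policy, mapped to an infinite loss for the affected run: under the skip
policy the degenerate strategy of starving the reactor (`Q = 0`) is rewarded
— the numerator dies and the undefined steps are silently discounted — so
the optimum collapses to zero inflow, which answers a different question
than the control problem poses.

## Grid-search validation

`grid_search_abm()` evaluates the objective on seeded replicates at every
grid point (replicate seeds derive from the root seed and the point index
and are recorded), stores per-point means and standard deviations, and
breaks ties lexicographically. `suboptimal_band()` returns the points whose
mean outcome lies within one standard deviation of the target, boundary
inclusive — the set of solutions indistinguishable from the target at the
ABM's intrinsic noise level.

## Problem sizes used by the test suite

The packaged experiments are desk-scale reproductions; the full-size
configurations (255 x 255 world, 100-replicate ensembles, 50,000-step
pathway horizons, removal grids at 0.0001 resolution) are expressible with
the same functions.

* Sheep-wolves: 51 x 51 world, 2,000-step runs, control from step 1,000,
  10-replicate training ensembles (datasets I-V: two initializations
  uncontrolled, then 2% grass, 2% sheep, 1.5% wolves removal), removal grid
  at step 0.005 over `[0, 0.03]^2` with 10 replicates per point. A finer
  development run (step 0.0025, 20 replicates) places the ABM's best point
  at `(0.0100, 0.0025)`.
* Metabolic: 10,000-step horizon, inflow grid `0, 0.1, ..., 1` with 3
  replicates per point; training datasets I/II as single runs and III-V as
  3-replicate averages.

What passing desk-scale tests show: that the pipeline — simulate, average,
calibrate, solve, transfer, validate — is internally consistent, that the
scaled grid search recovers the removal optimum near the full-scale value,
and that the mechanistic and GMA surrogates propose controls whose ABM
outcomes lie within one intrinsic-noise standard deviation of the target
(the band width is the populations' pooled fluctuation about the
uncontrolled steady state). What they also show, honestly: every surrogate
overestimates the wolf-removal rate roughly twofold — the small ABM's wolf
population responds to sustained removal more steeply than any fitted
deterministic model — which leaves the S-system proposal marginally outside
the band and the quadratic clearly outside (its extrapolated wolf response
is the least trustworthy, consistent with it being the family that needs
the root constraint at all).

What desk-scale tests cannot show: agreement with full-scale printed values
wherever the underlying system changes qualitatively with size. The
clearest case is the pathway's inflow problem: the desk-scale strict-policy
loss landscape has its feasibility edge at low inflow rather than an
interior optimum near 0.7 — product pools of a 16 x 16 vessel are tens of
molecules, so the zero-denominator elimination boundary (which moves by one
e-fold per product molecule) cannot be placed sharply, and the homogeneity
of the loss (both `S*` and `R*+T*` scale linearly with `Q`) leaves no
deterministic interior minimum to fall back on. The corresponding
acceptance check is left failing rather than weakened.

## Known limitations

* The surrogate state is the ensemble mean; replicate variance is used only
  for the suboptimal band, not propagated through the fits.
* Power-law families inherit their classical inability to saturate;
  Michaelis-Menten behaviour is approximated only locally.
* The transfer solver assumes the targeted variables are the controlled
  ones (square root-finding problem), which matches the reference input
  matrix but not arbitrary under-actuated problems.
* Trajectory calibration uses a thinned time grid (every 40th step by
  default) — adequate for the slow dynamics here, too coarse for systems
  with fast transients between samples.
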