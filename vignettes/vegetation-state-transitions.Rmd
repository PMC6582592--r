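---
title: "Simulating vegetation dynamics as state transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating vegetation dynamics as state transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`vegtrans` simulates vegetation dynamics on a raster of 100 m (1 ha)
cells with an annual time step, following the state-and-transition
tradition but with a state space fine enough (10^3^–10^6^ classes) that
transition rules cannot be hand-parameterized and must instead be
learned from data.

**States.** A vegetation state combines three axes:

* *composition* — either bare ground, a single species holding more
  than 66% of biomass ("dominated"), or the set of species each holding
  more than 20% ("mixture"; at most four species can each exceed 20%);
* *structure* — the dominant canopy height, binned into 4 m classes,
  by default 26 classes covering 0–100 m with an open-ended top bin;
* *functioning* — leaf area index in three classes: LAI ≤ 2,
  2 < LAI ≤ 4, and LAI > 4 (boundaries belong to the lower class).

Shares passed to the composition classifier are treated as *relative*
biomass and normalized before thresholding, so classification is
invariant to rescaling all shares by a positive constant; the only
exception is the all-zero vector, which is bare. Two consequences of
the thresholds are worth stating: a species holding between 20% and 66%
with no co-dominant forms a *singleton mixture*, distinct from a
dominated stand; and the bare class pins height and LAI class to zero.
With a 20-species pool and the rule as implemented, the composition
axis enumerates to `1 + 20 + sum(choose(20, 1:4))` classes.
`enumerate_state_space()` also accepts an explicit composition-class
override so that externally published per-axis factors (6,597 × 26 × 3
= 514,566) reproduce exactly; the published composition factor is not
derivable from the two thresholds alone, and we enumerate honestly from
our rule rather than reverse-engineer it.

**Transitions.** Each cell carries a residence time *R*, the years
spent in its current state; the process is semi-Markov — the hazard of
leaving depends on *R*, not only on the state. A two-headed classifier
predicts, from a cell's context, (1) a categorical distribution over
*when* the cell leaves its state within a 10-year horizon (classes
1–10, plus a censored "not within the horizon" class), and (2) a
distribution over the *target state* entered at the transition.
Predictors are: the state (one-hot; state spaces beyond 1,024 states
would need an embedding input and are rejected), residence time, soil
depth and fertility, monthly mean temperature and precipitation for the
next 10 years, species shares in two neighbourhood tiers (the 8
adjacent cells, and all cells within 300 m of the focal cell excluding
those — 20 cells), and the distance to the edge of the simulated area
(Chebyshev distance in cells × 100 m, capped at 1,000 m). Tier shares
proxy seed input: a dominated cell contributes weight 1 for its
dominant, a k-species mixture 1/k per member, bare nothing;
out-of-area cells contribute zero but stay in the denominator, so seed
pressure genuinely falls off at edges.

**Attributes.** Ecosystem attributes (live tree carbon, tC/ha; tree
species diversity as the first-order Hill number, the exponential of
Shannon entropy) are not predicted by the classifier. They are attached
to (state × residence-time) classes through an empirical database of
sample vectors and drawn uniformly from the matching vector during
simulation — a deliberately nonparametric treatment. Residence times at
or above a cap (default 50 years, by which time the attributes of a
state have plateaued) share one pooled class. Querying an unstored
residence key falls back to the nearest stored key of that state. We
adopt the convention D = 0 for bare cells even though exp(H) ≥ 1 for
any non-empty community; the zero unambiguously flags absent
vegetation.

## The simulation loop

The engine holds per cell: state, residence time, an optional scheduled
transition year, and the year of the last timing query. The annual step
advances the landscape to year *t* as follows:

1. Neighbourhood shares are computed once from the start-of-year
   snapshot; all cells then update synchronously, so per-cell update
   order cannot create artifacts (this replaces explicit random update
   ordering, which would matter only under sequential updates).
2. Cells whose scheduled year is *t* draw a target state from the state
   head, using features current at *t* (climate and neighbourhood may
   have drifted since scheduling); their residence time resets to 0.
   All other active cells advance R by one year.
3. Cells that just transitioned draw a fresh timing schedule; a draw of
   k schedules year *t + k*, the censored class schedules nothing and
   the cell is re-queried ten years later. Cells whose censored window
   expired at *t* are re-queried the same way. Timing is therefore
   sampled once per state entry, not annually — with hazards expressed
   through the timing distribution the two are equivalent in law, and
   one draw per sojourn is far cheaper.
4. If an attribute database is attached, attributes are refreshed for
   every active cell from its (state, R) class.

Randomness is organized as named independent streams (scheduling,
target draws, attribute sampling) derived from one master seed via
L'Ecuyer-CMRG substreams: toggling attribute sampling does not perturb
the transition sequence, and identical seeds give bit-identical
rasters.

## The synthetic world

Real training data for such a model comes from a process-based
simulator. The package replaces that dependency with a transparent
surrogate: a truth kernel with fully known coefficients.

* *Hazard*: `base × plogis(steepness × (R − midpoint)) +
  temp_effect × (T − temp_ref)`, clamped to [0, 1] — logistic in
  residence time (young stands persist, old stands turn over), with an
  additive annual-temperature term. At `R = midpoint` and the reference
  temperature the hazard is exactly `base/2`, which gives tests a
  closed form.
* *Targets*: a softmax over the successor support (height class may
  rise by at most one per transition; any decrease is allowed; no self
  transitions) of base log-weights plus a seed-pressure bonus
  (`neigh_coef ×` the successor's member shares averaged over the two
  tiers) minus a thermal penalty (`therm_sel × |T − optimum|` of the
  successor's members).

The trajectory generator applies this kernel cell by cell, year by
year; the extractor then emits one training example per cell-year with
at least a horizon of future trajectory, labelling time-to-next-change
(censored beyond 10 years) and the state entered. Monthly climate is
generated as region mean + seasonal sine + monthly noise + a shared
interannual year effect and an optional linear warming trend; only the
classifier sees monthly resolution while the kernel consumes annual
means, which builds realistic predictor redundancy into training.

What the generator does *not* emulate: disturbance and management
pathways, physiological detail (light, water, nutrient budgets),
spatially autocorrelated soils, dispersal kernels beyond the two fixed
tiers, and observation error. A green test therefore establishes that
the pipeline recovers a known semi-Markov data-generating process at
desk scale — not that it reproduces any particular real landscape.

Two oracles make the kernel checkable end to end. `analytic_stationary()`
power-iterates the exact Markov chain on (state, residence) pairs
(residence capped, default 150 years, far beyond hazard saturation) and
returns the long-run state occupancy. `tabulate_kernel()` turns the
kernel into an exact lookup model over (state, R), using the product
form P(leave in year k) = Π~j<k−1~(1−h(R+j)) · h(R+k−1); driving the
engine with it must reproduce the analytic occupancy, which ties the
scheduling semantics of the engine to the per-year hazard chain with no
learning error in between.

## The classifier

The neural model is a multilayer perceptron written directly on R's
BLAS primitives (no deep-learning framework is required at desk scale):
ReLU trunk, two softmax heads, joint cross-entropy loss with the
target-state term masked on censored rows, inverted dropout, L2,
minibatch Adam with optional per-epoch decay, seeded and reproducible.
The default architecture (4 × 256, dropout 0.2) suits large synthetic
spaces; the validation experiments use smaller, explicitly configured
nets. Two open design choices deserve a note:

* *One network or two.* Both heads can share one trunk (default) or
  train separate trunks (`two_networks = TRUE`). The shared trunk is
  cheaper; the separate target-state trunk learns to ignore predictors
  irrelevant to that head much more readily, which matters when the
  evaluation is distributional (total variation) rather than top-1.
* *Climate encoding.* 240 raw monthly values (default) or 24 decadal
  monthly means. At 2 × 10^5^ examples the 240 raw columns are mostly
  noise dimensions that a desk-scale net partially memorizes; the
  recovery experiment therefore uses the decadal encoder, and we treat
  the monthly encoder as the right default only for datasets orders of
  magnitude larger.

The empirical baseline, `fit_tabulated()`, stores exact conditional
class frequencies over discretized keys with optional Laplace smoothing
and marginal backoff for unseen keys. Keyed on the kernel's true inputs
it converges to the Bayes classifier, which is what the neural model is
judged against.

## Validation experiments and their design choices

Four standing experiments (`R/experiments.R`) are run both by the test
suite and by `scripts/acceptance.R`:

1. **Oracle equivalence** — engine + exact tabulated kernel vs analytic
   stationary occupancy on 5,000 cells × 300 years; agreement within
   ±0.02 absolute per state.
2. **Parameter recovery** — an 8-state kernel whose *timing* is
   temperature-dependent, three climate scenarios differing in warming
   trend, the middle trend held out entirely (as one holds out a
   climate-model trajectory; ranges overlap, levels differ). The
   network must match the tabulated Bayes oracle's top-1 accuracy on
   both heads within 5 points, read one-sidedly: the network may not be
   *worse*. On a held-out scenario the lookup table is handicapped by
   key coverage, so capping how much the network may *exceed* it would
   be meaningless. Target-state distributions must be within 0.05 mean
   total variation of the kernel truth; this comparison is only
   well-posed when an example's target distribution is determined by
   its predictors at query time, which is why this kernel keeps targets
   state-dependent and expresses temperature through timing (thermal
   target selection is exercised by experiments 4 and the ablation
   instead).
3. **Spatial-context ablation** — a kernel with species-symmetric base
   weights and strong seed-pressure feedback, so local dominance is
   decided purely by neighbourhood history; networks trained with and
   without tier shares, the share-aware network must be strictly more
   accurate on a held-out cell block.
4. **Gradient zonation** — 200 × 50 cells, a linear 5.5 °C cold-to-warm
   gradient down the rows, three species with optima 6, 8.25 and
   10.5 °C spanning the gradient, random initial states, 300 years
   under the exact kernel model. Vegetation must self-organize into
   ordered bands: Spearman correlation ≥ 0.9 between row index and the
   thermal optimum of the row's modal dominant species.

Numerical conventions: probability rows are renormalized defensively
before inverse-CDF draws and the final cumulative value is forced to 1;
argmax ties break to the first (pool-order) candidate; constant feature
columns receive unit scale; NaN training loss aborts with diagnostics
rather than continuing silently.

## Tunable parameters that matter

| Parameter | Default | Unit | Why this value |
|---|---|---|---|
| height class width | 4 | m | standard canopy-height binning |
| LAI class bounds | 2, 4 | – | sparse/moderate/dense functional split |
| dominance threshold | 0.66 | share | single-species dominance |
| mixture threshold | 0.20 | share | membership in a mixture |
| prediction horizon | 10 | yr | cumulative climate effects; one query per sojourn |
| tier-1 / tier-2 | 8 cells / 20 cells | – | adjacent ring; ≤ 300 m of centre distance |
| edge-distance cap | 1,000 | m | beyond ten cells edge effects are immaterial |
| attribute R cap | 50 | yr | attribute distributions plateau within a state |
| residence cap (oracles) | 150 | yr | hazards saturate far earlier |
| cell size | 100 | m | 1 ha grain of all rasters |

## Known limitations

* No disturbance or management pathway; succession only.
* One-hot state input limits the classifier to ≤ 1,024 realized states;
  an embedding input would be required beyond that.
* GeoTIFF is not read or written (no GDAL dependency); ESRI ASCII grids
  are the raster exchange format.
* The attribute database samples cells independently; spatial
  correlation of attributes within a state is not represented.
* The exact kernel model assumes the current annual temperature
  persists over the prediction horizon; under strong trends its timing
  distributions are approximate.
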