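---
title: "Surrogate-assisted multiobjective optimization of pedicle screw geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted multiobjective optimization of pedicle screw geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design problem

A spinal pedicle screw must resist two distinct failure modes at once:
fatigue fracture under cantilever bending (screw breakage) and loss of
axial holding power in weak, osteoporotic bone (screw loosening). Both are
governed by the screw's thread geometry, and they conflict: geometry that
stiffens the core against bending tends to reduce the thread engagement
that resists pullout. `screwopt` treats this as a biobjective optimization
over six structural variables of a conical-core screw with a fixed 7 mm
outer diameter:

| variable | meaning | range | units |
|---|---|---|---|
| `bp` | beginning position of the conical angle | 0–36 | mm |
| `id` | inner (core) diameter at the screw tip | 3.8–5.5 | mm |
| `prr` | proximal root radius | 0.4–1.0 | mm |
| `p` | thread pitch | 2.6–4.0 | mm |
| `pha` | proximal half angle | 5–20 | degrees |
| `tw` | thread width | 0.1–0.3 | mm |

Bending performance is proxied (inversely) by the maximum tensile stress
MTS (MPa) at the proximal thread root under a cantilever load; pullout
performance by the total axial reaction force TRF (N) under a small axial
displacement in foam-like bone. The packaged data
(`load_table1()`) contain 35 designs with both responses from
finite-element analysis: a 25-run orthogonal array (`l25_array()`), which
balances five levels of each variable, used as the learning set, and 10
random designs used as the testing set.

## Neural surrogates

Finite-element evaluation is far too slow to sit inside an optimizer, so
each response is replaced by a small feed-forward network: 6 normalized
inputs, one hidden layer of 3 sigmoid neurons, one sigmoid output
(`init_network()`, `train_network()`). Inputs are mapped linearly to
[-1, 1] over the design box; the response is mapped to [0, 1] against the
learning-set range widened by a 10% margin on each side, which keeps
optimizer queries beyond the training range inside the sigmoid's
responsive region.

Training is gradient descent with momentum on the squared error
`E = 0.5 * sum((y - t)^2)`, learning rate 0.5 and momentum coefficient 0.5,
with all weights and biases initialized uniformly on (-1, 1). One
iteration is one batch pass over the 25 learning records (an online
per-record mode is available via `update_mode`; at these budgets the batch
mode reaches lower errors on both targets). The iteration budget is 10000
for the bending target and 5000 for pullout. Training is restarted from
100 random initializations and the restart with the least testing-set
error is kept (`multi_restart_train()`).

Two numerical choices deserve explanation:

* **Error scaling.** The loss is summed, not averaged, over the batch.
  With the stated learning rate, a mean-scaled gradient moves the weights
  roughly 25 times more slowly and visibly underfits within the iteration
  budgets; the summed form reaches testing errors consistent with the
  surrogate accuracies the packaged table itself records in its
  `*_ann` columns.
* **Stopping rule.** The iteration budgets are read as the point at which
  the testing error has bottomed out, and the final iterate is returned
  (`stopping = "final"`, the default). The alternative — returning the
  intermediate snapshot with the smallest testing error ever seen
  (`stopping = "best_test"`) — sounds safer but behaves worse here: with
  momentum at this step size the early testing-error trace is noisy, its
  global minimum typically occurs within the first few hundred iterations,
  and the returned model is undertrained (learning error 2–3x higher, and
  downstream optima that sit at qualitatively wrong pitch and core
  diameter). Both rules are exposed; all reported results use the default.

With the default schedule the best-of-100 surrogates reach mean absolute
errors of roughly 0.8% (bending) and 0.3% (pullout) on the learning set
and 1–3% on the 10 testing designs, the same order as the `*_ann` columns
shipped with the data (1% / 1.64% and 0.4% / 0.78%).

## Genetic algorithm and scalarization

The two surrogate responses are turned into normalized, larger-is-better
objectives

```
F_bending = (MTS_max - MTS) / (MTS_max - MTS_min)
F_pullout = (TRF - TRF_min) / (TRF_max - TRF_min)
```

where the min/max references are the surrogate extremes over a seeded
100,000-point uniform sample of the box, computed once per
`fitness_context()` and frozen. Freezing matters: every weight of the
sweep, the knee criterion, and the dominance validation must score designs
on one common scale.

A binary genetic algorithm (`run_ga()`) maximizes the weighted sum
`F = w * F_bending + (1 - w) * F_pullout`. Chromosomes are 42 bits — six
7-bit fields decoded linearly onto each variable's range (`decode()`), so
every chromosome is inside the box by construction. Defaults follow the
study settings: population 40, roulette-wheel selection, single-point
crossover at rate 0.90, per-bit mutation at rate 0.01. Designs violating
the geometric feasibility rules (`check_constraints()`: positive thread
depth, root radius fitting within a pitch) receive fitness 0. One elite is
copied unchanged into each generation, which makes the best-fitness trace
non-decreasing and gives the convergence test a well-defined quantity: the
run stops when the best fitness improves by less than 1e-4 over 50
consecutive generations (or at 1000 generations). Runs typically terminate
after 150–300 generations. Widening the window delays termination without
changing the answer; the residual imprecision (about 1–2% in fitness, and
more in coordinates the objective is nearly flat in) is intrinsic to a
40-member roulette GA at this mutation rate.

## Pareto front, knee, and validation

`weight_sweep()` runs one seeded GA per weight on a 0.01-step grid and
archives, besides each run's final solution, every per-generation elite:
these points were already evaluated, and they densify the front at no
cost. `nondominated_filter()` reduces the archive to the Pareto set (weak
dominance; exact ties kept), `knee_region()` extracts the balanced part of
the front where `|F_bending - F_pullout| < 0.02`, and
`dominance_validation()` checks that uniformly random designs (10,000 by
default) are dominated by the front. `score_reference_screws()` projects
the packaged commercial reference geometries onto the same objective
plane, by default through their recorded finite-element responses: most of
those geometries lie outside the design box (cylindrical cores, root radii
of 3 mm), where surrogate extrapolation would be meaningless; surrogate
scoring remains available and flags such screws as extrapolated.

On the packaged data the knee solutions hold both normalized objectives
above 0.92, pin the taper start near 0 mm, root radius near 0.4 mm, half
angle near 5 degrees and thread width near 0.1 mm, with core diameter
about 4.0–4.3 mm and pitch about 3.2–3.5 mm, and the front dominates
essentially all random designs. These are the quantities
`scripts/acceptance.R` recomputes.

## The pseudo-FE generator

`pseudo_bending()` / `pseudo_pullout()` are closed-form stand-ins for the
finite-element stage, so the whole pipeline can be exercised against known
ground truth. Each is a sum of affine terms plus one quadratic term (root
radius for bending, pitch for pullout) and one bilinear interaction
(taper-start x core diameter; core diameter x pitch) — the simplest family
that is nonlinear enough to need the hidden layer yet has box optima on a
small closed-form candidate set (`pseudo_optimum()`). Default coefficients
are least-squares fits to the 25 array rows, frozen as package constants
(derivation in `inst/scripts/fit_pseudo_fe.R`). The bending fit is
sign-constrained so stress strictly increases with taper start and
strictly decreases with core diameter and root radius over the whole box;
the array data leave the weak core-diameter main effect confounded enough
that the unconstrained fit points the wrong way at zero taper. The fits
explain about 81% (bending) and 93% (pullout) of the response variance.
`generate_dataset()` labels the array plus uniform random designs with
these surfaces and optional multiplicative Gaussian noise
(`noise_sd`; 0 gives a deterministic generator).

What the generator does not emulate: finite-element discretization error,
contact nonlinearity, or any local response structure beyond one quadratic
and one interaction term per response. Passing the recovery tests
therefore shows the pipeline's statistical machinery is sound, not that a
3-neuron surrogate can reproduce arbitrary FE response surfaces.

## What a 25-point surrogate can and cannot localize

Two honest limitations surfaced repeatedly during testing and are worth
stating as findings:

* **Flat directions are unidentifiable.** Near a box-corner optimum the
  surfaces are nearly flat along several coordinates (the sign-constraint
  margins are small by construction). No optimizer can recover such
  coordinates to tight tolerances; recovery tests therefore check the
  response value and the well-identified coordinates, not all six.
* **Knee location inherits surrogate shape error.** The knee of the
  front — both its weight interval and its core-diameter/pitch values —
  shifts by the order of 0.05–0.15 (on the weight scale) across
  surrogate training seeds, and a surrogate trained on 25 noise-free
  pseudo-FE points places the knee of the true surface only approximately.
  The structural pattern at the knee (taper start 0, root radius 0.4 mm,
  half angle 5 degrees, thread width 0.1 mm, mid-range pitch) is robust;
  the exact interval endpoints are not. Stability tests assert what is
  stable: overlapping intervals and lower-endpoint agreement across
  optimizer seeds at fixed surrogates.

## Problem sizes and runtime

All defaults run on a laptop-class single core: 100-restart training takes
seconds per target (the inner loop is compiled), the 101-weight sweep with
10,000-design validation under a minute. The test suite trains full-scale
surrogates once and reuses them across test files; synthetic-data tests
use 26–51-weight sweeps and 30-restart training where full scale adds
nothing to the property under test.
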