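# screwopt

Surrogate-assisted multiobjective design optimization of spinal pedicle
screws.

Pedicle screws anchoring short-segment spinal instrumentation fail in two
conflicting ways: fatigue fracture under bending loads, and loosening
(pullout) in osteoporotic bone. Both depend on the same six structural
variables of a conical-core screw — taper start (BP), core diameter (ID),
proximal root radius (PRR), pitch (P), proximal half angle (PHA) and
thread width (TW) — and improving one performance tends to degrade the
other. `screwopt` is for implant-design engineers and biomechanics
researchers who want the full trade-off picture rather than a single
compromise design.

The pipeline:

1. **Neural surrogates.** Two 6–3–1 sigmoid feed-forward networks are
   trained by error backpropagation with momentum (learning rate 0.5,
   momentum 0.5, 100 random restarts, least-testing-error model kept) to
   map the normalized structural variables to the finite-element bending
   response (maximum tensile stress, MPa) and pullout response (total
   reaction force, N). Training data — a 25-run L25 orthogonal array plus
   10 random testing designs — ship with the package.
2. **Weighted-sum genetic algorithm.** Both responses are normalized to
   larger-is-better objectives on [0, 1] and aggregated as
   `F = w·F_bending + (1−w)·F_pullout`. A binary GA (42-bit chromosomes,
   population 40, roulette selection, 90% crossover, 1% mutation,
   elitist) maximizes `F` at each weight of a 0.01-step sweep.
3. **Pareto front and knee.** The nondominated set of all evaluated
   elites forms the front; the *knee* — the balanced designs with
   `|F_bending − F_pullout| < 0.02` — is the recommended operating
   region. The front is validated by dominance against 10,000 random
   designs, and packaged commercial screw geometries are projected onto
   the same objective plane for comparison.

A closed-form pseudo finite-element generator with known optima
(`pseudo_bending()`, `pseudo_pullout()`, `generate_dataset()`) makes every
stage testable end-to-end without an FE solver.

## Worked example

```r
library(screwopt)

surr <- fit_surrogates(seed = 1)           # two nets, 100 restarts each
surr$mae
#>    target learning testing
#> 1 bending    0.805    2.67
#> 2 pullout    0.327    1.25

ctx <- fitness_context(surr$bending, surr$pullout)
opt <- optimize_designs(ctx, ga_cfg = ga_config(seed = 1001))
str(opt$knee_summary)
#> List of 8
#>  $ n     : int 42
#>  $ weight: num [1:2] 0.42 0.68
#>  $ bp    : num [1:2] 1.42 5.1
#>  $ id    : num [1:2] 4.11 4.27
#>  $ prr   : num [1:2] 0.4 0.405
#>  $ p     : num [1:2] 3.23 3.51
#>  $ pha   : num [1:2] 5 5.35
#>  $ tw    : num [1:2] 0.1 0.106

opt$validation$fraction
#> [1] 0.9999
```

The mean-absolute-error table says the bending surrogate reproduces the
25 finite-element learning responses to 0.8% and generalizes to the 10
held-out designs to 2.7% (pullout: 0.3% / 1.2%). The knee summary is the
answer to the design question: the balanced optima use a fully conical
core starting near the screw tip (BP small), the smallest root radius
(0.4 mm), half angle and thread width at their lower bounds (5°, 0.1 mm),
a core diameter around 4.1–4.3 mm and a pitch around 3.2–3.5 mm, and they
arise for aggregation weights of roughly 0.4–0.7. Virtually all of 10,000
random designs are dominated by the computed front.

Comparing against the packaged commercial reference screws:

```r
compare_reference_screws(ctx, opt$knee)[, c("name", "f_bending",
                                            "f_pullout", "dominated_by_knee")]
#>             name f_bending f_pullout dominated_by_knee
#> 1        Synthes      0.00      1.00             FALSE
#> 2        A-Spine      0.55      1.00             FALSE
#> 3     Moss Miami      0.00      0.51              TRUE
#> 4          Viper      0.00      0.55              TRUE
#> 5 Optimal design      0.92      0.94              TRUE
```

The cylindrical-core screws (Moss Miami, Viper) are dominated by the knee
designs in both objectives; the small-pitch screws (Synthes, A-Spine)
reach maximal pullout scores at a severe bending penalty. The knee-region
optimal design holds both objectives above 0.92.

`run_pipeline(out_dir, seed)` runs all of the above and writes the
serialized surrogate models, the front CSV, a JSON knee summary and the
reference-screw report into `out_dir`; `plot_pareto_front()` draws the
front, knee, reference screws and validation cloud.

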