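# fraudgame

Evolutionary game dynamics of doctor–patient health-insurance fraud.

Health-insurance fraud is rarely a one-sided crime: doctors can
over-prescribe and bill for fraudulent treatment, patients can
exaggerate conditions and falsify claims, and the two can collude —
sealed by a bribe — to extract a joint surplus from the insurer.
`fraudgame` implements a two-population evolutionary game for analysts
of insurance governance who want to know which levers (fraud costs,
penalties, rewards, moral hazard, bribery) move such a system toward
honesty, and how fast.

## The model

A fraction *x* of doctors and *y* of patients play a *fraud* strategy.
The 2×2 asymmetric payoff matrix is built from 17 constants — honest
and fraudulent payoffs (*K₀ < K₁*, *N₀ < N₁*), fraud costs *C₁, C₂*,
moral-hazard coefficients *f, g* ∈ (0,1), penalties *P₁, P₂*, rewards
*R₁, R₂*, risk coefficients *β₁, β₂*, bribe *H*, collusion surplus *M*
split *α* : 1−*α*. The frequencies evolve under two-population
replicator dynamics

    dx/dt = x(1−x)(−A₁ + y·B₁),   dy/dt = y(1−y)(−A₂ + x·B₂),

where the condition values A₁, B₁, A₂, B₂ are closed-form combinations
of the constants (see `?condition_values`). The package enumerates the
equilibria (the four corners plus, when it lies inside the unit
square, the interior point *P(x\*, y\*)* = (A₂/B₂, A₁/B₁)), classifies
their stability from the Jacobian determinant and trace, identifies
which of three inequality-defined regimes the parameters occupy
(honesty-dominant, fraud-dominant, or bistable), predicts the long-run
attractor in the bistable regime from the saddle position via a
quadrilateral-area rule, integrates the dynamics (fixed-step RK4),
maps basins of attraction, and scripts the nine built-in
single-parameter sweep experiments. A seeded generator samples
synthetic parameter sets from each regime.

## Worked example

```r
library(fraudgame)
p <- baseline_params()   # the reference parameter set of the study
analyze_game(p)
#> Regime: case3  (A1 = 4.4, B1 = 9.1, A2 = 3.3, B2 = 7.9)
#> Equilibrium (0, 0): det = 14.52, trace = -7.7 -> ESS
#> Equilibrium (0, 1): det = 15.51, trace = 8 -> unstable
#> Equilibrium (1, 0): det = 20.24, trace = 9 -> unstable
#> Equilibrium (1, 1): det = 21.62, trace = -9.3 -> ESS
#> Equilibrium (0.417722, 0.483516): det = -4.3667, trace = 0 -> saddle
#> Saddle at (0.4177, 0.4835); area toward E = 0.4506, toward K = 0.5494 -> K(1,1)
```

The baseline is bistable: both the honest corner E(0,0) and the
collusion corner K(1,1) are evolutionarily stable, separated by the
interior saddle at (0.418, 0.484). Because the saddle sits below the
centre of the square, the collusion basin is the larger one
(area 0.549) and an agnostic population starting at (0.5, 0.5) drifts
into full fraud:

```r
integrate_replicator(p, c(0.5, 0.5))
#> Replicator trajectory: 239 steps (dt = 0.01), status: converged
#>   converged to K(1,1)
#>   final state (0.999289, 0.999305), max clamp 0
```

Raising the doctor's fraud cost from 3 to 7 moves the saddle up
(y\* = 0.923), shrinks the collusion basin, and the same initial
population now converges to honesty:

```r
integrate_replicator(update_params(p, C1 = 7), c(0.5, 0.5))
#> Replicator trajectory: 249 steps (dt = 0.01), status: converged
#>   converged to E(0,0)
#>   final state (0.000000, 0.000983), max clamp 0
```

The built-in sweeps reproduce the study's comparative statics — for
example the bribery reversal, where a small bribe sustains collusion
but a large one destroys it:

```r
sw <- run_sweep(builtin_figures()$fig10)
sw[, c("value", "predicted", "terminal_x", "terminal_y")]
#>   value predicted terminal_x terminal_y
#> 1     2    K(1,1)  0.9992894  0.9993053
#> 2     3    K(1,1)  0.9999672  0.9990015
#> 3     4    K(1,1)  0.9999999  0.9990102
#> 4     5    E(0,0)  1.0000000  0.9990038
#> 5     6    E(0,0)  0.0005236  0.0008137
```

(H = 5 is also a worked warning: the area rule's margin there is under
0.02, and the simulated trajectory — the ground truth — still reaches
collusion.)

A thin command-line front end over the same functions lives at
`inst/cli/fraudgame.R` (subcommands `classify`, `simulate`, `basins`,
`sweep`, `scenario`).

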