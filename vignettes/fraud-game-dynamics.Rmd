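---
title: "Modelling doctor-patient health-insurance fraud as an evolutionary game"
author: "fraudgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling doctor-patient health-insurance fraud as an evolutionary game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraudgame)
```

## The model

Health-insurance fraud involves two interacting populations with bounded
rationality: doctors, a fraction $x$ of whom play a *fraud* strategy
(over-prescription, fraudulent treatment), and patients, a fraction $y$
of whom play fraud (exaggerated conditions, falsified claims). When both
sides defraud together they collude, unlocking a joint surplus extracted
from the insurer, enabled by a bribe from patient to doctor.

The stage game is a $2 \times 2$ asymmetric matrix built from 17
constants. Writing $K_0 < K_1$ for the doctor's honest/fraudulent payoff
and $N_0 < N_1$ for the patient's, the four cells are:

| doctor \\ patient | fraud ($y$) | non-fraud ($1-y$) |
|---|---|---|
| **fraud** ($x$) | $-C_1 + H + \alpha M + K_1 - \beta_1 K_1 - P_1$, <br> $-C_2 - H + (1-\alpha) M + N_1 - \beta_2 N_1 - P_2$ | $-C_1 + f N_0 + K_1 - P_1 - \beta_1 K_1$, <br> $N_0 + R_2 - f N_0$ |
| **non-fraud** ($1-x$) | $K_0 + R_1 - g K_0$, <br> $-C_2 + g K_0 - P_2 - \beta_2 N_1 + N_1$ | $K_0$, $N_0$ |

Here $C_i$ are fraud costs, $P_i$ penalties, $R_i$ honesty rewards,
$\beta_i$ risk coefficients, $H$ the bribe, $M$ the collusion surplus
split $\alpha : 1-\alpha$, and $f, g \in (0,1)$ the moral-hazard
coefficients: the fraction of the counterpart's honest payoff a
fraudulent party extracts under information asymmetry. Note that the
bribe $H$ enters the collusion cell with opposite signs for the two
roles — the patient pays it, the doctor receives it — and that rewards
are granted to the honest party exactly when the counterpart frauds,
as the matrix above states; we deliberately do not extend them to the
mutual-honesty cell.

## Replicator dynamics

Each strategy's frequency grows in proportion to its payoff advantage
over its own population's mean. With $U_{11}, U_{12}$ the expected
payoffs of a fraudulent/honest doctor against the patient mixture (and
$U_{21}, U_{22}$ the patient analogues), the two-population replicator
system is

$$\frac{dx}{dt} = x(1-x)\,(U_{11} - U_{12}) = x(1-x)\,(-A_1 + y B_1),$$
$$\frac{dy}{dt} = y(1-y)\,(U_{21} - U_{22}) = y(1-y)\,(-A_2 + x B_2),$$

with the four *condition values*

$$A_1 = C_1 - f N_0 - K_1 + P_1 + \beta_1 K_1 + K_0, \quad
  B_1 = H + \alpha M - R_1 + g K_0 - f N_0,$$
$$A_2 = C_2 - g K_0 - N_1 + P_2 + \beta_2 N_1 + N_0, \quad
  B_2 = -H + (1-\alpha) M - R_2 - g K_0 + f N_0.$$

A subtle but load-bearing point: the *patient* bracket depends on $x$,
the doctors' fraud frequency, not on $y$ — whether fraud pays for a
patient hinges on how likely the doctor is to collude. The package
computes the field both ways (bracket constants, and utility
differences assembled from the payoff matrix) and the test suite pins
their equivalence to $10^{-10}$.

```{r}
p <- baseline_params()
condition_values(p)
replicator_rhs(p, 0.5, 0.5)
```

## Equilibria, stability and the three regimes

The four corners of $[0,1]^2$ are rest points for every parameter set;
the interior point $P(x^*, y^*) = (A_2/B_2,\; A_1/B_1)$ joins them when
it lies strictly inside the square. Stability follows the planar
determinant/trace rule applied to the analytic Jacobian: $\det J > 0$
with $\operatorname{tr} J < 0$ is an asymptotically stable node — an
evolutionarily stable strategy (ESS) of the game; $\det J > 0$ with
positive trace is unstable; $\det J < 0$ is a saddle whatever the
trace; the interior point always has zero trace and negative
determinant when present, hence is a saddle. Sign tests use a
tolerance of $10^{-9}$; boundary hits are reported as
`indeterminate`/`other` rather than forced into a class.

Three inequality regimes on $(A_1, B_1, A_2, B_2)$ organise the phase
portrait:

* **case 1** ($0 < B_i < A_i$): honesty dominates; $E(0,0)$ is the
  unique ESS and every interior trajectory reaches it.
* **case 2** ($A_i < 0 < B_i$): fraud dominates; $K(1,1)$ is the unique
  ESS.
* **case 3** ($0 < A_i < B_i$): bistable; $E$ and $K$ are both ESS and
  the interior saddle's stable manifold separates their basins.

```{r}
analyze_game(p)
```

## Predicting the attractor: the quadrilateral-area rule

In the bistable regime a useful closed-form heuristic replaces the
separatrix by the straight lines through the saddle: the basin of
$E(0,0)$ is approximated by the quadrilateral $S(0,1), E(0,0), N(1,0),
P(x^*,y^*)$, whose shoelace area is $(x^* + y^*)/2$. The corner with
the larger area wins; equality (within $10^{-9}$) is reported as
`undetermined`. The rule is exact in its ordering claim when both
coordinates sit on the same side of $1/2$ and we extend it
continuously in between by comparing $(x^* + y^*)/2$ with $1/2$.

Its accuracy as an *area* estimate is good when the saddle is central
(at the baseline the $21 \times 21$ basin fraction differs from the
predicted area by about 0.03) but degrades when the saddle sits near
an edge of the square, where the separatrix curves strongly; the test
suite therefore checks the rule three ways — as an area estimate at
the baseline, as a rank correlation across bistable scenarios
(Spearman $\rho > 0.9$ at grid $n = 21$ over 50 generated games), and
as a corner predictor against simulation whenever the predicted margin
$|(x^*+y^*)/2 - 1/2|$ exceeds 0.05 — rather than as a uniform
quantitative bound.

```{r}
predict_attractor(p)
```

## Numerical integration

The replicator clock has no empirical units — nothing calibrates a
time step to days or claim cycles — so absolute time is not meaningful
anywhere in this package; only limits, orderings and monotone
relations are. We integrate with classical fixed-step RK4,
`dt = 0.01`, up to `1e5` steps. The replicator field is a smooth cubic
polynomial on the unit square and the edges are invariant lines, so
RK4 at this step keeps the per-step clamping to $[0,1]^2$ below
$10^{-9}$ — exceeding that raises an accuracy error advising a smaller
step rather than silently projecting. A trajectory terminates when it
comes within `convergence_tol = 1e-3` (euclidean; necessarily
$< 0.5$ so the corner is unique) of a corner, when the velocity norm
drops below `stall_tol = 1e-10` in the interior (e.g. started exactly
on the saddle), or at the step cap. Halving `dt` changes no terminal
corner across generated bistable games, which the suite checks.

Single runs and all sweep experiments start from $(0.5, 0.5)$ — the
maximally uninformative prior over both populations' strategies, and
the natural common anchor for comparing sweep outcomes. Basin maps integrate from an $n \times n$ uniform *interior*
grid: points exactly on the boundary lie on invariant lines and would
never leave them, biasing the fractions.

```{r}
tr <- integrate_replicator(p, c(0.5, 0.5))
tr
basin_map(p, n = 11)
```

## The sweep experiments

`builtin_figures()` scripts the nine single-parameter sweeps of the
numerical study, each varying one parameter over its printed list with
everything else held at the baseline (`C1` 3–7, `C2` 2–4, `f` 0.8–0,
`g` 0.6–0, `P1` 5–7, `P2` 3–7, `R1` 5–9, `R2` 3–7, `H` 2–6). Terminal
fraud frequency is the relevant coordinate of the converged corner.
Deterrents (costs, penalties, rewards) push monotonically toward the
honest corner and larger penalties shorten the time to reach it; the
moral-hazard coefficients push the other way; bribery is
non-monotone in its effects — a small bribe cements collusion, a
large one makes the patient's side of collusion too expensive and the
system flips to honesty.

The moral-hazard lists include the endpoint 0, which violates the
strict open interval $f, g \in (0,1)$ the validator enforces; the
built-in specs are therefore constructed with `allow_boundary = TRUE`,
a relaxation that is local to them — user configurations keep the
strict bound unless they opt in.

```{r}
sw <- run_sweep(builtin_figures()$fig10)
sw[, c("value", "x_star", "y_star", "predicted", "terminal_x", "terminal_y")]
```

## Synthetic scenarios

`sample_params()` draws parameter sets from uniform boxes bracketing
the baseline values (`K0, N0 ~ U(1,5)` with fraud payoffs exceeding
them by `U(1,10)`; costs, penalties, rewards `~ U(0,10)`; `H ~ U(0,8)`;
`M ~ U(5,40)`; unit-interval coefficients `~ U(0.05, 0.95)`) and keeps
draws whose regime label matches the target — plain rejection
sampling, exactly uniform on the feasible region within the box, with
a seeded private stream that leaves the session RNG untouched. All
three regimes have workable acceptance rates under these boxes (the
fraud-dominant regime is the rarest, at roughly a quarter of a percent).
The generator and the analyzer share no code path beyond the validated
parameter object, so the suite's cross-validation — every generated
regime sample must reproduce the full determinant/trace sign pattern
of its regime — is a genuine two-sided check.

What the generator does *not* emulate: real claims data, empirical
parameter calibration, heterogeneity within the populations, or any
temporal variation in the constants. Passing tests show the analysis
machinery is correct on the model's own terms, not that the model
describes any particular health-insurance system.

## Problem sizes and limitations

The suite and the acceptance script run at desk scale: basin maps on
$11^2$–$21^2$ grids, 50–200 generated scenarios per property, 100 per
regime for the generator/analyzer cross-validation. Known limitations:
strictly two populations and two strategies; deterministic dynamics
(no finite-population or stochastic replicator variants); no insurer
as a third strategic player; single-parameter sweeps only; and the
area rule's quantitative accuracy caveat above.
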