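---
title: "Controlling program growth in geometric semantic GP with elitist replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling program growth in geometric semantic GP with elitist replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsgpr)
```

## The model

Geometric semantic genetic programming (GSGP) identifies a regression
program with its *semantics*: the vector of its outputs on the training
instances. The two variation operators act geometrically in that space.
Crossover of parents $T_1, T_2$ under a random function $T_R$ with outputs
in $[0,1]$ produces

$$T_{XO} = (T_1 \cdot T_R) + ((1 - T_R) \cdot T_2),$$

so every output coordinate of the child is a convex combination of the
parents' coordinates. Mutation with step $ms > 0$ and two random $[0,1]$
functions produces

$$T_M = T + ms \cdot (T_{R1} - T_{R2}),$$

a ball mutation perturbing each coordinate by at most $ms$. For any
error-to-target fitness (here RMSE) these operators induce a unimodal
landscape, which is what makes GSGP attractive for hard symbolic
regression such as QSAR/pharmacokinetic endpoint modelling
(oral bioavailability, LD50, plasma protein binding).

Their structural cost is severe: the crossover offspring contains a full
copy of both parents plus **two** copies of $T_R$'s genotype plus 5
combiner nodes; mutation adds the two random genotypes plus 4 nodes (the
step constant counts as one). Sizes therefore grow exponentially. With
event probabilities $p_{xo} + p_m + p_r = 1$ and random trees budgeted at
$2^D$ nodes (the binary-primitives convention for a depth-$D$ tree), the
average size obeys

$$S^{(g)} = p_{xo}\,(2 S^{(g-1)} + 2 \cdot 2^D + 5)
          + p_m\,(S^{(g-1)} + 2 \cdot 2^D + 4)
          + p_r\, S^{(g-1)},$$

implemented by `size_growth_bound()`. The asymptotic growth ratio is
$1 + p_{xo}$: exponential whenever crossover is used. A model is
conventionally *manageable* while it fits the depth-17 node budget
$2^{17} = 131072$ (Koza's standard depth limit under binary primitives);
`first_unmanageable_generation()` locates the horizon where a size
summary crosses that budget. Note the $2^D$ convention undercounts a true
full binary tree ($2^{D+1}-1$ nodes); `size_growth_bound()` exposes both
conventions (`"paper"` and `"strict"`) plus an explicit `tree_budget`
override, and the bound-domination test uses the strict budget including
the squashing wrapper node.

## Elitist replacement

The package implements two systems sharing one generational loop
(`run_gsgp()`):

* **standard** — every offspring enters the new population;
* **elitist** — a crossover child is accepted only if its training RMSE
  is *strictly* lower than both parents', a mutation child only if
  strictly lower than its parent's; otherwise a parent is copied (for
  crossover, the better parent by default, or a uniformly random one via
  `surviving_parent = "random"`; the choice has little effect on
  performance).

Ties reject the child: keeping the equal-fitness parent keeps the smaller
model, which is the point of the method. Acceptance uses training fitness
only; test-partition semantics are propagated through the same operator
formulas so test RMSE is observable every generation without ever
reconstructing a model. Both systems record per-generation operator
*success rates* — the fraction of crossover events beating both parents
and of mutation events beating their parent — because the method's
leverage comes precisely from crossover succeeding rarely (so it is
replaced by reproduction most of the time) while mutation succeeds often.

## Representation and cost

Materialising offspring syntax is hopeless at these growth rates, so an
individual stores only its train/test semantics, its fitness, its *exact*
node count and a lineage record (parents, random-tree references, ms).
Genesis and random trees live in an append-only pedigree store. Evolving
$n$ individuals for $g$ generations costs $O(ng)$ vector operations;
`evaluate_unseen()` scores a new instance in time linear in the lineage,
not in model size. `reconstruct_expression()` expands a lineage back into
syntax on demand and refuses (with the exact size in the error) any model
over the `size_guard` (default $2^{17}$).

Sizes are carried as arbitrary-precision integers (`big_int()`): median
final sizes of standard GSGP reach $10^{20}$–$10^{50}$ nodes, far beyond
exact double range, and the size–reconstruction identity
`node_count(reconstruct_expression(ind)) == ind$size` is asserted exactly
wherever reconstruction is feasible.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 50 | individuals per generation |
| `generations` | 200 | generational steps |
| `p_xo, p_m, p_r` | 0.7 / 0.25 / 0.05 | event probabilities, sum to 1 |
| `ms` | 1 | mutation step, units of the target variable |
| `tournament_size` | 4 | selection pressure |
| `elitist` | FALSE | elitist replacement on/off |
| `surviving_parent` | "best" | rejected-crossover survivor policy |
| `best_survives` | TRUE | copy the incumbent best each generation |
| `rt_max_depth` | 4 | random-tree depth `D` (grow method) |
| `init_depths` | 2–6 | ramped half-and-half initial population |
| `constant_range` | [-1, 1] | ephemeral constants |

The reference experimental protocol fixes the study conditions this
package emulates: RMSE fitness, 30 independent runs, a fresh uniform
70/30 train/test split per run, per-generation medians of the best
individual, mutation steps $\{0.01, 0.1, 1\}$, and $\alpha = 0.1$ for
both the Shapiro–Wilk normality gate and the two-sided Mann–Whitney
comparison of final model sizes. It does not print the population size,
selection scheme, operator rates or initialisation; the defaults above
are this package's own documented choices, exposed in `run_config()` so
every experiment states them explicitly. Tournament selection draws `k`
distinct individuals uniformly, so `k = 1` is a uniform draw and
`k = pop_size` is deterministic truncation to the best.

## Synthetic benchmarks

The five study datasets (three proprietary drug-discovery matrices, a
concrete-strength table and a Parkinson voice-symptom table) are not
redistributable, so `synth_dataset()` emulates their *shapes* with known
ground truth: features uniform in $[-1,1]$, target
$y = \mathrm{offset} + \mathrm{scale}\cdot f(x) + \mathcal N(0,
\sigma)$ with $f$ a small nonlinear expression inside the GP search
space. Presets (`synth_presets()`):

```{r presets}
synth_presets()
```

Offsets and scales place each target on its endpoint's natural range
(percent bound/bioavailable on 0–100, LD50 on an mg/kg scale, MPa,
UPDRS-like score) so that the study's mutation steps keep the same
meaning relative to target scale; $\sigma$ is roughly 5–10% of the
signal's spread. What the generator deliberately does *not* emulate:
correlated molecular descriptors, heavy-tailed or censored endpoints, and
targets outside the closure of the primitive set. Passing tests on these
benchmarks therefore demonstrates the *mechanics and the direction of
effect* (comparable fitness, drastically smaller models), not predictive
performance on real pharmacokinetic data.

## Numerical choices and degenerate inputs

* **Protected division** `a /p b` returns 1 when $|b| \le 10^{-6}$, the
  standard GP guard; evaluation is finite on finite input.
* **[0,1] codomain**: random trees are wrapped in a logistic squashing
  node $1/(1+e^{-t})$, counted as one node, preserving diversity while
  guaranteeing the codomain (matching the reference GSGP implementation's
  approach). Operators validate the codomain and raise a contract error
  otherwise.
* **Tie-breaks**: "better" always means strictly lower training RMSE;
  fitness ties are broken by smaller exact size, then lower id, making
  runs fully deterministic under a seed.
* **Mann–Whitney**: `stats::wilcox.test`, exact distribution for untied
  samples with $n+m < 50$, normal approximation with tie correction
  otherwise; the Shapiro–Wilk gate is recorded, never branched on — the
  rank test always decides, and degenerate all-identical samples are
  rejected.
* **Determinism**: one seed drives dataset generation, splitting,
  initialisation and evolution; a run, an experiment and their artifact
  files reproduce byte-for-byte.

## Scale of the shipped experiments

The packaged tests run a desk-scale analogue of the full protocol: the
plasma-protein-binding-like preset, population 50, 200 generations, 10
runs per system at $ms = 1$, paired splits. At this scale the elitist
system's median final best-model size is orders of magnitude below the
standard system's (the Mann–Whitney test at $\alpha = 0.1$ separates
them) while median final training RMSE stays within a few percent —
the central claim, reproduced in direction rather than in the magnitudes
of the full 30-run, 1000-generation study, which additionally depends on
the external datasets.

```{r example, eval = FALSE}
ds <- synth_dataset(preset = "ppb", seed = 1)
sp <- experiment_spec(ds, ms = 1, systems = c("standard", "elitist"),
                      n_runs = 10, config = run_config(), seed = 101)
exp <- run_experiment(sp)
glance(exp)
autoplot(exp, type = "size")
exp$comparisons[["1"]]
```

## Known limitations

* Reconstructed expressions are returned verbatim; no algebraic
  simplification or compression is attempted.
* The elitist monotonicity guarantee is stated for the default
  `best_survives = TRUE`; with it off, the best can be lost to selection.
* Only binary arithmetic primitives are supported — no unary operators
  (beyond the internal squashing wrapper), Boolean domains or
  classification operators.
* `as.numeric()` on an exact size saturates to `Inf` past ~$10^{308}$;
  ranking final sizes through doubles is safe at the shipped scales but
  exact comparison operators on `big_int` are available where it is not.
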