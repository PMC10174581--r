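---
title: "Methods: cascades, tabu search and robustness metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascades, tabu search and robustness metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keystone)
library(dplyr)
```

This vignette documents the model implemented by `keystone`, the choices made
where the method leaves room, and what the synthetic test bed does and does
not establish about real webs.

## The cascade model

A quantitative food web is a directed network whose link from prey $i$ to
consumer $j$ carries an energy flux $w_{ij} \ge 0$ (carbon flow in
gC\,m$^{-2}$\,day$^{-1}$ in the empirical webs this model is aimed at).
Besides inter-species flows, each species exchanges energy with the external
environment: imports (environment $\to$ species), exports and respiration
(species $\to$ environment). `augment_web()` materialises the environment as
a virtual node with exactly those edges and caches each species' baseline
inflow $b_i = \mathrm{imports}_i + \sum_j w_{ji}$ in the intact web $G_0$.

Given a primary removal set and an extinction threshold $t \in [0,1]$, the
cascade runs in synchronous rounds. A dead species loses **all** incident
edges. Each round recomputes, for every surviving species,

$$P(i) \;=\; \frac{\mathrm{imports}_i + \sum_{j\,\text{alive}} w_{ji}}{b_i},$$

and kills every species with $P(i) \le t$. The survivor count is
$f(G) = \sum_i I(P(i))$ with $I$ the indicator of survival, and the
disintegration of a removal strategy $X$ with $n$ removals is
$F(X) = f(G_0) - f(G) = N - f(G)$, so $F \ge n$ always.

Choices worth stating explicitly:

* **Boundary rule.** Extinction uses $P(i) \le t$: a species sitting exactly
  at the threshold dies. `strict_less = TRUE` switches to $P(i) < t$ for
  sensitivity checks; at $t = 0$ the default rule reproduces the
  conventional topological criterion (extinct when all energy inflow is
  lost), while the strict rule would never kill anything at $t = 0$.
* **Synchronous rounds.** The kill rule is monotone — removing a species can
  only lower other species' inflows — so the fixed point is unique and
  independent of update order. Synchronous updating is chosen for speed and
  determinism; the test suite verifies agreement with an independent
  asynchronous one-at-a-time oracle on 100 random webs.
* **Environment edges.** Imports are never severed (the environment cannot
  die), so a species drawing at least $(1-t)\,b_i$ of its baseline from
  imports is uninvadable by the cascade. This is intended behaviour, not an
  edge case.
* **Degenerate species.** A species with $b_i = 0$ has $P(i)$ defined as 0
  and dies the moment a cascade is evaluated. Such species are flagged with
  a warning at augmentation time rather than rejected.
* **At $t = 1$** every species has $P \le 1$, so any evaluation kills the
  entire web. This extreme is permitted (and used as a test), although the
  analysis grid stays inside $(0, 1)$.

## The optimisation problem and tabu search

Keystone identification is cast as network disintegration: find the removal
set $X$ of size $n$ maximising $F(X)$. Exhaustive enumeration costs
$\binom{N}{n}$ cascade evaluations and is hopeless beyond toy sizes (it is
retained as `brute_force_optimal_removal()`, the ground-truth oracle for
small webs). `tabu_search()` implements the metaheuristic:

1. start from a uniform random $n$-subset;
2. each iteration, draw up to `n_can` candidate neighbours of the current
   solution, each obtained by one swap (restore one removed species, remove
   one kept species), rejecting swaps already drawn this iteration or
   present in the tabu list;
3. move to the candidate with the largest $F$ (first drawn wins ties);
4. if the move improves on the historical best, record it and **clear** the
   tabu list (aspiration); otherwise append the accepted swap to the FIFO
   tabu list of length `tabu_length`;
5. stop after `t_max` iterations and return the historical best.

Swaps are stored as unordered pairs, so reversing a recent move is forbidden
for `tabu_length` insertions — this is what lets the search walk through
temporary deteriorations instead of cycling around a local optimum. If
candidate generation exhausts `retry_cap` draws without finding a legal swap
and has none in hand, the oldest tabu entry is evicted and drawing continues;
this guarantees progress when the neighbourhood is small relative to the
tabu list.

**Defaults.** `t_max = 100`, `n_can = 20`, `tabu_length = 7`. There are no
canonical values for these constants, so the defaults are this package's own
choice: large enough that, on webs of 8–10
species, the optimiser reaches the exhaustive optimum in well over 95% of
seeded runs (tested), while staying cheap on webs of a hundred species. All
three are exposed everywhere a search is run.

**Determinism.** Every stochastic path is a pure function of the seed in
`tabu_config()`. Replicate $r$ of an experiment uses `base_seed + r`; the
per-budget searches inside a removal curve use `xor(seed, p)`.

## Removal protocols and metrics

`sequential_removal()` runs the five centrality baselines as remove-1,
cascade, repeat protocols. Scores are recomputed on the current surviving
web at each step (`mode = "dynamic"`, the default) because that is the
natural reading of "greatest in-degree at each step"; `mode = "static"`
ranks once on the intact web for comparison. Ties go to the lowest species
index so runs are reproducible. Degree scores include environment edges by
default (`include_env = FALSE` excludes them). Eigenvector scores are the
dominant eigenvector of the transposed alive flow matrix (a species matters
when it receives energy from important species), by power iteration with L1
normalisation, tolerance $10^{-10}$, $10^4$ iteration cap; on an acyclic
sub-web — where the matrix is nilpotent and no dominant eigenvector exists —
the last non-zero iterate is returned, and an all-zero sub-web falls back to
uniform scores. This convention is isolated in `eigenvector_scores()`.

`tabu_removal_curve()` optimises each budget $p = 1 \dots N$ independently,
which matches the set-based objective (the best 5-set need not contain the
best 4-set). Under a finite iteration budget an unlucky larger-budget search
could report less damage than a smaller one, so the curve takes the running
maximum; the true optima are monotone in $p$, and the envelope merely
enforces that known fact on the estimates. Computation stops at the first
budget achieving total collapse and the series is padded with $N$.

The curve metrics are computed literally:

* $\mathrm{SEA} = \sum_p N_p / N^2 - 0.5$, the discrete area between the
  extinction curve and the 1:1 line. Its maximum 0.5 is attained at
  immediate total collapse. Note the discrete sum gives $1/(2N)$, not
  exactly 0, for a cascade-free curve — the "zero at no secondary
  extinction" reading is asymptotic in $N$; the literal formula is used
  everywhere.
* $R_{50} = \min\{p : N_p \ge N/2\}/N$. A count hitting exactly $N/2$
  qualifies (ceiling semantics on "cause 50% to become extinct").

`threshold_sweep()` evaluates either metric over the 19-point grid
$t = 0.05, 0.10, \dots, 0.95$. For a *fixed* removal set $F$ is
non-decreasing in $t$, and on the hand-built fixtures $R_{50}(t)$ is
non-increasing for every strategy (asserted in the tests). For dynamic
greedy protocols on arbitrary webs this monotonicity is a strong empirical
tendency, not a theorem — the greedy order itself can change with $t$ — and
occasional single-step reversals do occur on random webs.

## Comparison statistics

`run_comparison()` produces one row per (web, strategy, replicate) with SEA
and $R_{50}$ at $t = 0.5$, the conventional mid threshold. Statistical
comparisons operate on *web-level* values (replicate averages, one value per
web and method, via `web_level_means()`): with 12 webs and 6 methods the
one-way ANOVA has $df = (5, 66)$, which is the design the published
benchmark's interval widths imply. `one_way_anova()` is the classical
between/within decomposition via `stats::aov()`; the dispersion summary
reports both SD and SEM, since "±" values in the literature are sometimes
one and sometimes the other (the benchmark's printed ±0.030 for the tabu
column is its SD across webs; its SEM is 0.0087). `dunnett_vs_control()`
wraps `multcomp::glht()` many-to-one contrasts with the tabu strategy as
control; the simultaneous multivariate-$t$ quantile is evaluated by Monte
Carlo integration under a fixed internal seed, so confidence limits are
reproducible to numerical tolerance, and in a balanced design all five
intervals share a single half-width.

One caveat the regression tests document: the benchmark's published ANOVA
$F$ (12.676) cannot be regenerated from its own printed three-decimal SEA
table — exact arithmetic on the printed values gives $F = 12.717$ — so the
published statistic was evidently computed on unrounded values. The package
asserts its implementation against an independent hand decomposition and
records the printed-table value.

## The synthetic test bed

`generate_niche_web()` supplies webs for testing and simulation studies in
the empirical range (the benchmark webs span $S = 21$–$125$ species and
binary connectance $0.086$–$0.366$):

* **Topology** from the niche model: species get niche values
  $\eta_i \sim U(0,1)$ and consume every species inside a diet interval of
  width $\eta_i \cdot \mathrm{Beta}(1, 1/(2C) - 1)$; the species with the
  smallest niche value is forced basal. Webs are resampled until realized
  connectance is within `tol = 0.03` of the target, the usual practice for
  fixed-connectance generation. Cycles and cannibalism arise naturally and
  are kept.
* **Weights** are lognormal (mean-log 0, sd-log 1 by default): positive and
  right-skewed, the qualitative shape of empirical carbon-flow
  distributions.
* **Environment vectors**: every basal species receives an import (so all
  baseline inflows are positive); consumers additionally receive one with
  probability `import_fraction = 0.1`; exports and respiration are small
  positive lognormals.

What the generator does *not* emulate: mass balance (inflow = outflow at
every node), allometric scaling of fluxes, trophic-level coherence of flow
magnitudes, and the empirical preponderance of detritus compartments with
enormous throughput. Tests passing on these webs therefore establish the
*algorithms* — cascade fixed points, optimiser correctness against
enumeration, metric arithmetic, statistical machinery — not ecological
claims about any particular real system. Replicating published per-web
numbers requires the original flux data, which are read through
`read_foodweb_json()`/`read_s1_foodweb()` when available.

Four hand-computable fixtures (`fixture_web()`) anchor the arithmetic:
a three-species chain whose basal removal collapses everything, a two-prey
consumer sitting at $P = 3/4$ after losing its minor prey, an import-only
web immune to secondary extinction below $t = 1$, and a web whose in-degree
ranking swaps once the top species is removed (separating dynamic from
static scoring).

## Problem sizes in the checks

The bundled verification runs are sized for minutes, not hours: optimiser
validation uses 30 webs of 8–10 species with budgets 2–3 against exhaustive
enumeration ($T_{max} = 200$, $n_{can} = 10$, $L = 3$); cascade
order-independence uses 100 random webs of 10–20 species; threshold
monotonicity uses the full 19-point grid on the four fixtures for all six
strategies. Scaling beyond that is linear in `t_max`, `n_can` and the number
of budgets, and quadratic in $S$ per cascade round.

## Known limitations

* No flow rerouting or prey switching: lost inflow is never compensated, so
  the model overstates fragility relative to adaptive-foraging dynamics.
* Static topology and fluxes: no population dynamics, no bioenergetics.
* The weighted connectance `C_w` is a descriptive statistic whose exact
  published formula varies by source; this package uses the entropy-based
  effective-links definition (per-species $2^H$, averaged over inflows and
  outflows, divided by $S$), which reduces to the binary connectance for
  uniform weights. It feeds no algorithm.
* Independent per-budget optimisation makes the tabu removal curve
  embarrassingly parallel but costs $N$ searches per curve; no warm-start
  scheme is used by default because it couples budgets and changes the
  estimand.
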