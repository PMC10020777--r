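---
title: "Red piranha optimization: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Red piranha optimization: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpo)
```

## The model and its assumptions

RPO is a population metaheuristic organized as three *sequential* phases
rather than the interleaved exploration/exploitation of most swarm
optimizers. The iteration budget `Z` is split as
`Z_srch = Z_enc = floor(Z/3)` with the attacking phase absorbing the
remainder — so the exploration budget is fixed a priori, not adapted.
The phases assume:

- **Searching** relies on pure randomness for exploration: scouts are
  redrawn uniformly every iteration, and the coefficient
  `A = r1(-2 + r2) + (1 - r1)(1 + r3)` has support `[-2,-1) U (1,2]` by
  construction, so a non-scout always takes a long step relative to its
  scout. Agents may (and do) wander to worse positions; the end-of-phase
  greedy selection is what makes the phase safe.
- **Encircling** assumes the mean of the `k` current best agents is a
  useful surrogate for the optimum ("prey"). That is reasonable for
  unimodal basins and a mild assumption elsewhere since the prey is
  recomputed every iteration from the current ranking.
- **Attacking** assumes the neighborhood of the prey is worth exploiting:
  steps shrink linearly (`a = 2 - 2t/Z_att` down to 0) and are per-step
  greedy, so the phase can only refine, never lose, each agent's best.

The optimization sense is an explicit parameter of `objective_spec()`
(default minimize); "best" always means best under that sense, which
resolves the source material's mixed language about "maximum verification"
in a minimizing example.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `n` | agents | 10 | size of the worked example; raise for harder problems |
| `Z` | iterations (unitless) | 50 | enough for the 2-d benchmark to reach its basin |
| `xi` | scout scaling, `lambda = ceil(n/xi)` | 4 | the worked example's value (3 scouts for n = 10) |
| `k` | alpha agents defining the prey | `min(3, n)` | the worked example uses 3; the stated bound `k <= n/10` is not enforced because the example itself violates it (k = 3, n = 10) — validation is `1 <= k <= n` |
| `b` | spiral shape | 1 | worked-example value; larger b tightens the spiral contraction |
| `delta` | safety-shield half-width (position units) | 0 | collisions off unless requested; `2*delta` is the collision distance |
| `n_ck` | checkpoints | 0 | collision checks only at `floor(Z_att/n_ck)*i - 1` |
| `early_stop_tol` | plateau tolerance | 1e-7 | the stated stop rule threshold |

## Numerical choices

- **Bounds**: every update is clamped componentwise to the violated bound
  (not reflected or resampled), matching the worked example's treatment of
  out-of-range coordinates.
- **Coefficient granularity**: one scalar `(A, C)` pair per agent per
  iteration, broadcast over components. The printed tables show scalar
  pairs; per-component vectors would change the distribution of steps.
- **Ties**: ranking ties (prey alphas, greedy selection, collisions) break
  toward the lower agent index / earlier history entry, making runs
  deterministic given the seed.
- **Degenerate inputs**: `Z < 3` is a configuration error (each phase must
  run at least once); an empty attacking or encircling phase is skipped
  cleanly when a schedule field is 0 (possible only through direct calls,
  not through `rpo_config`).
- **RNG**: a single seed set at run start; draw order is documented in
  `?run_rpo` (initialization agent-by-agent, then scout draws, then
  per-agent coefficients in index order), so fixture injection and replay
  are exact. Identical seeds give bit-identical traces.
- **Early stop**: the stop rule `|best(t) - best(t+1)| < 1e-7` is
  evaluated at *phase boundaries* (after the greedy selection closing a
  phase), comparing the global best before and after the phase. A
  per-iteration check would abort almost immediately whenever one
  iteration fails to improve the best — under per-step greedy the best
  changes rarely — while the phase-boundary reading preserves the intended
  "plateau" semantics. Default off for the continuous optimizer, on for
  the binary variant, where the realized iteration count `z_o` feeds the
  cost metric `n * z_o`.

## The binary variant

Bit vectors are used directly as 0/1 reals in the update equations; there
is no persistent continuous shadow state because the method re-binarizes
every iteration. The virtual prey is the real-valued mean of the `k` best
bit vectors when it enters the update equations (magnitudes matter there)
and is binarized only for reporting — the source describes binarizing it
but the update formulas are meaningless on a binarized mean; this is a
documented package decision, not a claim about the authors' intent.

The printed transfer rule `bit = 1 iff rand >= sigmoid(x)` *inverts* the
conventional direction: larger continuous components make a 1 less
likely. It is implemented as printed (default) with the conventional rule
available (`transfer = "conventional"`), and the test-suite pins the
empirical bit probabilities of both (`1 - sigmoid(x)` and `sigmoid(x)`
respectively). Under the printed rule, selection pressure comes from
greedy retention rather than from the transfer direction.

Empty subsets cannot be scored, so an all-zero binarization has one
uniformly chosen bit set. Collision detection is off by default in binary
space (the source assumes the condition is never met); an experimental
Hamming-distance variant (`collision iff Hamming < 2*delta`) is provided.
Fitness values are cached by bit pattern.

## Wrapper feature selection

The fitness is the percent test-set accuracy of a Gaussian Naive Bayes
(variance floor 1e-9) trained on the selected columns. The classifier
variant is a package choice — the source says only "classical Naive
Bayes" — and Gaussian-on-imputed-numeric is the natural reading for
laboratory panels. The train/test protocol is a stratified 70/30 split
with its own seed, created once per run so that fitness values are
comparable across agents; per-call resplitting would turn the fitness into
a noisy objective. Class imbalance is left as-is (no resampling). The
F-measure is the harmonic mean of macro precision and macro recall (also a
documented choice; the definition is unstated in the source). Micro
precision = micro recall = accuracy/100 holds identically for single-label
classification and is asserted on every report.

## The synthetic generator: what it does and does not emulate

`generate_clinical()` emulates the *shape* of the motivating clinical
dataset: 5644 rows, 110 mixed-type features, positive fraction 559/5644,
heavy missingness. Defaults chosen where the shape description is silent:
10 informative features, effect size 1.0 (a clearly detectable but not
trivial univariate signal: single-feature Bayes accuracy
`pnorm(0.5) = 0.69` on balanced classes), missing rate 0.6 (heavy, in the
spirit of sparse laboratory panels while keeping median imputation
usable), categorical fraction 0.2. Informative features are
class-conditional unit-variance Gaussians shifted by the effect size;
noise features are class-blind; categorical columns are quartile-coded
(noise columns are discretized first so the configured effect size is not
silently eroded); missingness is uniform.

What it deliberately does **not** emulate: the covariance structure of
real laboratory panels, informative missingness (in real clinical data
*which* tests were ordered is itself predictive), measurement scales, or
the clinical meaning of the 110 named tests. Consequently a green
synthetic test establishes that the selection machinery recovers planted
univariate signal under class imbalance and missingness — it does not
establish the headline accuracies reported for the external dataset,
which depend on that dataset and on unstated preprocessing and are out of
scope by design.

## The worked-example replay and its anchoring

The printed worked example is shipped as plain-text fixtures and replayed
through the package update rules (`replay_worked_example()`; exposed on
the command line as `repro-example`). Three anchoring decisions, each
forced by internal inconsistencies of the printed tables and all visible
in the replay report rather than silently absorbed:

1. **Objective cells are checked at the printed coordinates.** The printed
   objective values are consistent with the *rounded* printed coordinates;
   recomputing positions exactly and then evaluating can differ by up to
   ~1e-2 through rounding amplification. The replay therefore asserts
   positions (recomputed vs printed) and objectives (evaluated at printed
   coordinates vs printed) separately, each within 5e-3.
2. **Encircling coordinates are excluded.** The printed updated
   coordinates imply a spiral factor of about +1.136 at `l = 1/3`,
   `b = 1`, where the update formula gives about -0.698; the two are
   irreconcilable as printed (the acceptance suite computes both). The
   replay checks distance vectors, prey means, `l` values, objective
   evaluations and the greedy table, chaining on the printed coordinates.
3. **Attacking rows carry their own starting state.** The printed
   attacking arithmetic mostly chains from raw candidates even when the
   per-step greedy rule rejected them, but not always; each fixture row
   stores the position the printed computation actually started from.
   `run_rpo` itself implements strict per-step greedy movement. Similarly,
   the printed end-of-encircling greedy table drops the position each
   agent entered the phase with (losing a better solution than anything
   the phase found); `run_rpo` includes the entering position, which is
   required for the monotone-best invariant, while the replay mirrors the
   table.

A handful of garbled printed coefficients are stored with the reading that
reproduces the adjacent printed results (e.g. `-1.89.45` as -1.8945,
`1.689.4` as 1.689, `0.89.41` as 0.89); one encircling distance cell is a
visible misprint (it repeats the neighboring agent's value) and is flagged
unchecked in the fixture rather than asserted.

## Known limitations

- The uniform phase split cannot adapt to problems needing more (or less)
  exploration; `Z` is the only lever.
- The prey-mean surrogate can sit in a poor region when the `k` best
  agents straddle separate basins.
- With the printed transfer rule the binary searching phase drifts toward
  dense subsets (0-bits flip to 1 with probability 1/2, 1-bits stay with
  probability ~0.27 before greedy retention); the conventional rule
  behaves symmetrically. Both are exposed; neither is "fixed" silently.
- The Naive Bayes fitness inherits NB's independence assumption; strongly
  correlated informative features can be under-selected.
- The nominal cost metric `n * z` counts iterations, not classifier
  trainings; with caching the number of distinct subsets scored (reported
  as `evaluations`) is the better effort measure.
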