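---
title: "Simulating the evolution of gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the evolution of gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnevolve)
```

## The model

`grnevolve` simulates, forward in time, a haploid Wright–Fisher population in
which the heritable unit is a gene regulatory network (GRN) rather than a set
of independent loci. Each individual carries `n` genes, and each gene `i` two
binary regulatory regions of length `L`: a *cis* region `R_ic` (the sequence
upstream of the gene on which other genes bind) and a *trans* region `R_it`
(the sequence through which the gene regulates others). Positions `1..L-1` of
a region are **strength bits**; position `L` is the **type bit**.

The signed interaction of gene `j` on gene `i` is

```
I(R_ic, R_jt) = 0                            if R_ic[L] = 0
              = + pc(R_ic[1:L-1] & R_jt[1:L-1]) / L   if R_ic[L] = R_jt[L] = 1
              = - pc(R_ic[1:L-1] & R_jt[1:L-1]) / L   if R_ic[L] = 1, R_jt[L] = 0
```

where `pc` counts the strength-bit positions set in *both* regions. A closed
cis gate (`R_ic[L] = 0`) silences the whole row: the gene accepts no
regulation from anyone. The denominator is `L` (not `L-1`), so the largest
attainable magnitude is `(L-1)/L`. Self-regulation (`i = j`) follows the same
rule; nothing in the model singles out the diagonal. All `n^2` interactions
are held in the matrix `M` with `M[i, j] = I(R_ic, R_jt)` — row `i` is
"everything regulating gene `i`", column `j` is "everything gene `j`
regulates".

### Maturation: from genotype to phenotype

A newborn starts from a constant binary expression vector (all-ones by
default; see *Design choices*) and iterates the synchronous update

```
E(t+1)[i] = 1  if  sum_j M[i, j] * E(t)[j] > 0,   else 0
```

until the trajectory revisits a state. Three outcomes are possible: a **fixed
point** (period 1), a **cycle** of period `k >= 2` — viable here, and scored
below — or, if no state repeats within `step_cap` steps (default 10000), the
individual is declared **non-viable**. Because the state space has `2^n`
states, a deterministic trajectory must repeat within `2^n + 1` steps; for
`n <= 13` genes non-viability is therefore impossible, and the cap only binds
for large networks.

### Fitness and selection

Fitness compares the matured expression vector with an optimum `E_opt` over
the genes under selection:

```
F(E) = exp( -||E - E_opt|| / sigma^2 )
```

with the Euclidean norm, so for binary vectors `||E - E_opt|| = sqrt(k)` with
`k` the number of mismatched selected genes. Entries of `E_opt` set to `NA`
mark *neutral* (free) genes that never enter the distance; an all-`NA`
optimum makes every viable individual equally fit and the run is pure drift.
Fixed points are scored on their single state; cyclic individuals receive the
**minimum** fitness over one full period (the transient before the cycle does
not contribute); non-viable individuals get fitness 0. Parents are drawn
i.i.d. proportionally to fitness; generations do not overlap and the
population size `N` is constant.

An important consequence of binary expression is the **fitness ladder**: the
attainable fixed-point values are exactly `exp(-sqrt(k)/sigma^2)` for
`k = 0..n_selected` (`fitness_ladder()`), so mean-fitness trajectories move
between discrete plateaus rather than smoothly.

### Mutation

The number of mutations per offspring genome is Poisson(`mu`). Each event
picks one of the `2n` regions uniformly, then a position within it: the type
bit with that region kind's type-bit probability, otherwise a uniform
strength bit. The defaults differ by region kind
(`type_bit_prob = c(cis = 1/L, trans = 0.01)`): cis mutations fall uniformly
over the whole region — opening or closing a promoter is an ordinary
mutational event — while trans type-bit hits are held to 1%, encoding that a
mutation converting a gene from activator to repressor of *everything* it
regulates is far rarer than one nudging a single interaction's strength.
(Applying the 1% gate to cis regions as well cuts the supply of
gate-opening mutations threefold; under the default study conditions that
variant never reaches the optimum within the simulated horizon, which
contradicts the adaptive behaviour this simulator is built to reproduce —
hence the asymmetric default; both knobs are exposed.) After a cis flip only
one matrix row can change, after a trans flip only one column; the engine
refreshes exactly that slice, and the test suite holds the incremental
matrix to bit-identity against a from-scratch rebuild.

### Recombination

Two models, selected by `recombination_model`:

* `"wagner"` — cis swapping: the child takes all trans regions from parent 1
  and, independently per gene, its cis region from parent 2 with probability
  1/2. The classical row-swapping scheme kept the donor's interaction values;
  here the matrix is re-derived from the child's own regions, because a
  swapped-in cis region meets a different set of trans regions.
* `"r1r2"` — a single breakpoint `j` uniform on `{1..n-1}`: genes `1..j`
  inherit both regions from parent 1, genes `j+1..n` both regions from
  parent 2, and the cross-block interactions are recomputed.

An offspring has two parents with probability `recombination_prob` (default
0.5 once a model is enabled, a free parameter of the experiment design).

### Generation 0

Founders have all cis type bits 0 and all trans type bits 1 (all-activator,
nothing-accepts): every founder matrix is zero and every founder matures to
the all-zero expression vector, fitness `exp(-sqrt(10)/5) ~ 0.5313` under the
default all-ones optimum. Founder *strength* bits are not pinned down by the
model; the default draws them i.i.d. uniform per individual (options
`"zeros"`, `"ones"`), which supplies standing variation in interaction
magnitudes without opening any interaction.

## Design choices made where the design was open

**The update nonlinearity and the birth state.** The update rule iterates
`E(t+1) = M E(t)` on a binary vector, which leaves the nonlinearity and the
birth vector to be fixed. We use the literal product over `{0,1}` states with
a strict positive threshold (zero or net-repressive input silences a gene)
and an all-ones birth vector. The alternatives fail structurally: an all-zero
birth vector is absorbing under a plain product (`M·0 = 0`, so no network
could ever express anything), and a ±1 "spin" convention makes every open cis
row receive strictly negative input while genes are off — founder trans
regions are all activators — so the all-off phenotype could never be left and
no adaptation would occur at all. Under the implemented rule a single cis
type-bit flip lets a gene self-activate from the all-ones birth state, which
is precisely the elementary step behind the ladder-like fitness trajectories
the simulator is built to study. With zero founder matrices the first update
silences everything, so generation-0 phenotypes are all-zero, as they should
be.

**Cyclic phenotypes in statistics.** Where a single expression vector per
individual is needed (per-generation statistics, robustness identity), a
cyclic individual is represented by the minimum-fitness state of its cycle —
the state that defines its fitness — with the first such state in cycle order
as tie-break.

**Reaching the optimum.** `time_to_optimum()` offers two readings: the first
generation at which *some* individual has fitness 1 (`"individual"`), and the
first at which *every* individual does (`"population"`, i.e. mean fitness
exactly 1). The buffering experiment uses the population reading: with few
genes a single lucky individual touches the optimum quickly at any mutation
rate, so the phenomenon of interest — whether the optimal genotype can be
*transmitted intact* under mutation pressure — is only visible at the
population level.

**Genotype identity.** The distinct-genotype statistics treat two individuals
as the same genotype when their full `2nL`-bit genomes are identical
(`genotype_identity = "genome"`); counting distinct raw interaction matrices
(`"matrix"`, under which mutations in gated-off regions are invisible) or
distinct sign-discretized matrices (`"matrix_sign"`) is also available.

**Randomness.** All randomness — including the C++ engine's — flows from R's
global RNG, so `set.seed()` (or `config$seed`) makes runs bit-reproducible.
Experiment probes run under `with_preserved_seed()`, which saves and restores
`.Random.seed`; a probed run therefore follows exactly the trajectory of the
unprobed run, which the test suite checks bit-for-bit.

**All-zero fitness.** With `n >= 14` a whole generation can in principle be
non-viable; the default policy aborts with a diagnostic
(`on_zero_fitness = "error"`), with a uniform-choice fallback available for
deliberately lethal-heavy explorations.

## The experiment harnesses

**Robustness probing** (`run_simulation(robustness_interval = ...)`,
`branch_and_probe()`): at fixed intervals the population is cloned; every
clone receives a fixed number of extra mutations (default 15, same placement
law as the mutation model); both copies mature; and two identities are
recorded — the fraction of genes with equal binary expression (*expression
robustness*) and the fraction of matching entries of the sign-discretized
matrices (*topology robustness*). Discretization means the comparison is of
network topology, not of magnitudes; `raw_topology = TRUE` adds the
undiscretized comparison for sensitivity analysis. Probes are classified into
trajectory phases by `robustness_phases()`: *initial* (before the first
fitness improvement, where robustness is trivially high because founders
admit no interactions), *ascent*, and *plateau* (from the first attainment of
the run's maximum mean fitness, within `1/N`).

**Neutral genes** (`cross_partition_interactions()`): with a mixed optimum
the per-generation statistics include the mean number of nonzero sign-matrix
entries linking a neutral and a selected gene (both directions counted).

**The regulation-free baseline** (`run_grnless()`): the same Wright–Fisher
orchestration — the two models literally share the run loop, differing only
in the injected genotype-to-offspring map — but the genotype *is* the
expression vector and a mutation flips a gene state directly. Every mutation
is immediately phenotypic, so the contrast with the full model isolates what
the regulatory layer buffers. `run_buffering()` scans a mutation-rate grid
and records per-replicate population-level times to the optimum for both
models.

## What the generator emulates, and what it does not

Runs under the default configuration emulate the study conditions: `N = 100`,
`n = 10`, `L = 30`, `mu = 0.005`, `sigma2 = 5`, all-ones optimum, 15000
generations. The model is haploid, with non-overlapping generations, constant
population size, no demography or spatial structure, fixed-length regions (no
duplication, deletion or indels), binary expression (no intermediate levels),
synchronous updates, and no non-genetic inheritance. Passing tests therefore
say nothing about diploid dominance, quantitative expression, or asynchronous
regulatory dynamics — they validate the discrete model above and the
population-genetic machinery around it.

## Scales used by the test suite

The per-generation cost is dominated by maturation, so the checked
experiments run at reduced scale; sizes were chosen once, as part of the
experiment design, to keep each check in minutes while preserving the
phenomenon under test:

* distinct-genotype exploration: the full study conditions (`N = 100`,
  `mu = 0.005`, 15000 generations), four replicates per arm — a selected
  population with breakpoint recombination versus pure drift (all genes
  free, mutation only). The arms differ in recombination as well as
  selection because cumulative distinct-genotype counts under genome-bit
  identity are driven by two sources, mutation events (present in both arms
  at identical rates) and recombinant novelty; a drift-only arm isolates the
  former. Compressed-time surrogates were examined and rejected: raising
  `mu` to fit a 2000-generation window inflates neutral standing variation
  (`2*N*mu` grows) until recombinant novelty swamps both arms and the
  contrast disappears.
* ladder plateaus: one full-scale default run; a plateau is at least 200
  consecutive generations with range below `1.5/N`, and its level must sit
  within `1/N` of a ladder value. The tolerance is deliberately smaller than
  the closest ladder gap (`exp(-3/5) - exp(-sqrt(10)/5) ~ 0.0175`), so a slow
  sweep between adjacent rungs cannot masquerade as a plateau.
* robustness: `N = 50`, 3000 generations, probes every 250 generations, 15
  branch mutations, `mu = 0.02`.
* buffering: `mu` grid `{0.01, 0.1, 1.0}` (two orders of magnitude), `N = 50`,
  20 replicates per cell, 5000-generation cap, censored medians.
* neutral genes: 5 selected / 5 neutral, `N = 50`, `mu = 0.05`, 6000
  generations, pooled over three replicates; the higher rate lets the
  5-gene optimum actually be reached within the run.
* neutral drift: `N = 20`, two genotype labels at frequency 0.25/0.75,
  `mu = 0`, all genes free, 2000 replicates against the binomial fixation
  law.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(N = 50, generations = 3000, mu = 0.02,
                  recombination_model = "r1r2", seed = 42)
sim <- run_simulation(cfg, robustness_interval = 500)
summary(sim)
plot(sim)                 # mean fitness with the ladder as guides
head(robustness_phases(sim))
```

## Known limitations

* The maturation nonlinearity is a modelling commitment (see *Design
  choices*); results for networks balanced exactly at zero input depend on
  the strict-threshold convention.
* Two second-order phenomena are weak or absent at the simulated population
  sizes, and the corresponding study-level checks in the test suite record
  that honestly: probe robustness does not rise again once the optimum is
  reached (as adaptation opens cis gates, a larger fraction of random
  mutations becomes phenotypically visible, and no canalizing pressure
  strong enough to reverse that exists at `N` of order 100), and
  neutral-selected cross-partition interactions are not pruned after the
  optimum (a load-bearing interaction cannot be removed without flipping
  the regulated gene's state, and selection against mutational target size
  is of order `mu` times the effect — invisible at these scales).
* Statistics for cyclic individuals hinge on the minimum-fitness
  representative state; other summaries of a cycle (first state, majority
  state) are defensible and would change robustness numbers slightly.
* The distinct-genotype counter treats every bit as identity-relevant;
  synonymous genotypes (identical matrices from different bit patterns) are
  counted as distinct under the default identity.
* Large gene counts (`n > ~20`) make exhaustive state-space arguments
  inapplicable and maturation cost grows with cycle lengths; the engine is
  tuned for the tens-of-genes regime the model was designed around.
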