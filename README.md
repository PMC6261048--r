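# evofix

Exact fixation probabilities and selection regimes of the Moran process
on undirected graphs.

## The problem

When a population lives on a graph — each individual on a vertex,
offspring replacing neighbours — its structure changes the fate of a
mutant.  Under Birth-Death updating with uniform initialisation, a single
mutant of fitness *r* placed uniformly at random fixes with probability
Φ(*r*), to be compared with the homogeneous-population baseline

    Φ0(r) = (1 − r⁻¹) / (1 − r⁻ᴺ).

A graph is an **amplifier** of selection where Φ(*r*) > Φ0(*r*), a
**suppressor** where Φ(*r*) < Φ0(*r*), and **isothermal** (Φ ≡ Φ0)
exactly when it is regular.  Because Φ(*r*) is a rational function of
*r*, a graph can switch regime at critical fitnesses *r_c* where
Φ − Φ0 changes sign — and such **regime transitions** cannot be
established by simulation or by any finite fitness scan alone.

`evofix` is for researchers in evolutionary graph theory / structured
population genetics who need *certified* answers at small order: exact
rational arithmetic end to end, exact rational-function fixation curves,
and exact isolation of every transition on (1, ∞).

## What it does

* **Graphs**: constructors for the families central to suppression
  mechanisms (ℓ-graphs, friendship cycles/stars/ribbons, stars, cycles,
  cliques, complete bipartite), graph6 and edge-list I/O, canonical
  64-bit identifiers, exhaustive enumeration of connected graphs up to
  isomorphism (order ≤ 8), and cycle-index class counting to order 10.
* **Solvers**: the fixation linear system with degree-one polynomial
  entries, solved in float, exact-rational (GMP), or 50-digit decimal
  rendering; automorphism-orbit reduction with exact equivalence.
* **Symbolic curves**: Φ(*r*) = Φ′(*r*)/Φ″(*r*) as an exact, coprime
  rational function, recovered from exact solves at the fitnesses
  1, …, d+1, 1/2, …, 1/d.
* **Regimes**: classification into isothermal / amplifier / suppressor /
  transition patterns by exact real-root isolation of Φ − Φ0, plus an
  *apparent* numeric-scan mode on fitness grids up to r = 2000.
* **Census**: a checkpointed, resumable pipeline classifying every graph
  of a given order, with summary tables and regime "barcode" exports.
* **Simulation**: a Monte-Carlo trajectory sampler used as an
  independent stochastic check of the solvers.

## Worked example

The balanced ℓ-graph ℓ₆ (a 4-clique plus two adjacent extra vertices,
each joined to its own pair of clique vertices) is the unique order-6
graph that suppresses selection at every fitness r > 1:

```r
library(evofix)
ell6 <- graph_ell(6, 2, 2)
classify(ell6)
#> <regime_profile> order 6: suppressor (method: exact)

solve_fixation(ell6, "2", mode = "exact")$average_frac
#> [1] "290563457033894472128/573017130923792511951"
```

The average fixation probability at r = 2 is the exact fraction above,
about 0.5070764 — strictly below the homogeneous baseline
`phi0(6, 2)` = 32/63 ≈ 0.5079365, and the exact classification certifies
the inequality for *every* r > 1, not just the ones evaluated.  One
order up, the balanced ℓ-graph stops suppressing at a critical fitness:

```r
p <- classify(graph_ell(7, 2, 2))
p
#> <regime_profile> order 7: S/A (method: exact)
#>   transition S/A at r_c ~ 5.17
p$transitions$r_c
#> [1] 5.176118
```

A full order census reproduces the published distribution:

```r
cen <- run_census(6)
summarize_census(cen)
#> Regime census summary (percentages recomputed):
#>   N=6  #112  iso 5 (4.46%)  sup 1 (0.89%)  S/A 6 (5.36%)  A/S 0 (0.00%)  S/A/S 0 (0.00%)  amp 100  [confirmed]
```

(112 connected graphs of order 6: 5 isothermal, the single global
suppressor ℓ₆, 6 suppressors that become amplifiers, 100 amplifiers.)

A command-line front end for shell use ships in `inst/cli/evofix.R`:

```sh
Rscript inst/cli/evofix.R classify --family ell --N 7 --n 2 --m 2
Rscript inst/cli/evofix.R census --order 6 --out order6.tsv
```

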