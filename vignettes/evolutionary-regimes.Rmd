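---
title: "Exact evolutionary regimes of the Moran process on small graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact evolutionary regimes of the Moran process on small graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evofix)
```

## The model

A population of $N$ individuals occupies the vertices of an undirected,
connected, simple graph $G$.  One vertex, chosen uniformly, initially
carries a mutant of fitness $r > 0$; residents have fitness 1.  Each step
of the Birth-Death Moran process selects a reproducing individual with
probability proportional to fitness and copies it onto a neighbour chosen
with weight $w_{ij} = 1/d_i$, where $d_i$ is the degree of the reproducer.
The mutant set $S \subseteq V$ is a Markov chain with two absorbing
states, $\emptyset$ (extinction) and $V$ (fixation).  With
$w_S(r) = r|S| + N - |S|$ the total reproductive weight, the transition
probabilities are

* gain of $j \notin S$: $\;r \sum_{i \in S} w_{ij} / w_S(r)$,
* loss of $j \in S$: $\;\sum_{i \in V \setminus S} w_{ij} / w_S(r)$,
* no change: the complementary self-loop mass.

The fixation probabilities $\Phi_S(r)$ solve the absorbing-chain hitting
system; the headline quantity is the average over uniform single-mutant
starts, $\Phi(r) = \frac1N \sum_i \Phi_{\{i\}}(r)$.  For the homogeneous
(complete-graph) population,

$$\Phi_0(r) = \frac{1 - r^{-1}}{1 - r^{-N}},$$

and the Isothermal Theorem states $\Phi \equiv \Phi_0$ exactly when all
vertex temperatures $T_i = \sum_{j \sim i} 1/d_j$ coincide — for
undirected graphs, exactly the regular graphs.  A non-isothermal graph is
an *amplifier* of selection where $\Phi(r) > \Phi_0(r)$ and a *suppressor*
where $\Phi(r) < \Phi_0(r)$; a fitness $r_c > 1$ where the sign of
$D(r) = \Phi(r) - \Phi_0(r)$ changes is a *regime transition*.  All
classification in this package is restricted to the advantageous domain
$r > 1$; values for $r < 1$ are computed and stored but never labelled.

## Exact linear algebra

Multiplying each hitting equation by $w_S(r)$ clears every denominator
except the vertex weights, and scaling rows by $L = \mathrm{lcm}_i\, d_i$
clears those: the result is a square system $(A_0 + r A_1)\,\Psi = c_0 +
r c_1$ whose coefficients are small integers.  Three solution modes share
this assembly:

* **float** — LAPACK LU at a numeric $r$; used by the census scan.
* **exact** — for rational $r = p/q$, the integer system
  $(qA_0 + pA_1)\Psi = qc_0 + pc_1$ is solved by fraction-free Bareiss
  elimination with exact rational back-substitution (GMP integers, no
  rounding anywhere).
* **highprec** — the exact solution rendered to a requested number of
  significant decimals (default 50); this realises the high-precision
  escalation path without a separate floating-point type, so escalation
  can never disagree with the exact authority.

The automorphism group of $G$ (computed via igraph/BLISS) acts on mutant
configurations; vertex permutations commute with the kernel, so the chain
is lumpable over subset orbits and the system may be assembled on orbit
representatives.  Reduced and full solves agree exactly (this is a tested
invariant, not an approximation), and the orbit count also bounds the
degree of the fixation curve below.

## Exact fixation curves

By Cramer's rule on the degree-one polynomial system, $\Phi(r) =
\Phi'(r)/\Phi''(r)$ is a rational function with rational coefficients of
degree $d$ at most the number of non-absorbing orbit rows (hence at most
$2^N - 2$).  Since $\Phi \to 1$ as $r \to \infty$, both leading
coefficients can be pinned to 1, leaving $2d$ unknowns determined by
exact solves at the sample fitnesses $1, \dots, d+1$ and $1/2, \dots,
1/d$.  If numerator and denominator share a factor the interpolation
system is rank-deficient; a deficiency of $k$ means the canonical coprime
degree is $d - k$, so the bound is lowered and the system rebuilt until
the solution is unique.  The resulting curve is normalised to coprime
form with a monic denominator and validated against a fresh exact solve
at a held-out fitness.

The interpolation system itself has huge integer entries (powers up to
$(d+1)^d$), so it is solved modulo a stream of 61-bit primes with CRT
combination and rational reconstruction of the coefficients; every
candidate is verified against the system modulo a fresh prime, and the
held-out validation provides an end-to-end exact check.  Rank deficiency
is likewise detected modulo two independent primes — a wrong rank (an
event of negligible probability) would surface as an inconsistent or
non-validating retry, not as a wrong curve.

## Regime classification

**Exact method.**  Regularity is checked first and certifies the
isothermal class with no computation.  Otherwise the sign of $D = \Phi -
\Phi_0$ on $(1, \infty)$ is governed by its numerator $M(r)$ (the
denominator is positive there; the code verifies it has no positive
roots).  $M$ is reduced to its square-free radical and all real roots in
$(1, \infty)$ are isolated by Descartes'-rule bisection
(Vincent–Collins–Akritas with exact Taylor shifts), then refined to
intervals narrower than $10^{-6}$.  The sign of $M$ is evaluated exactly
on every gap between consecutive roots: roots without a sign change are
tangencies, not transitions — the regime sequence and its critical
fitnesses follow.  Exact classifications are certified for **all**
$r > 1$, including beyond any scan range.

**Numeric scan.**  $D$ is evaluated on a fitness grid: the standard grid
$0.25, 0.5, \dots, 10$, a refinement near 1
($1.0005, \dots, 1.015$, then steps of $0.02$ to $1.2$ and $0.1$ to $4$)
because transitions occur arbitrarily close to $r = 1$ (the order-7
census contains one at $r_c \approx 1.013$), and an extended grid to
$r = 2000$ (steps of $0.5$ to 30, $2.5$ to 100, then log-spaced — the
extended range exists to catch late transitions such as the order-7 ones
near $r \approx 25$ and $r \approx 80$, and bisection after detection
makes the step size uncritical).  Grid values with $|D| < 10^{-9}$ are
ties, never silently signed.  Scan classifications are flagged *apparent*:
sign excursions between grid points or beyond the range cannot be
excluded, which is precisely why the exact path exists.

**Hybrid census.**  The census classifies each graph by: (i) regularity;
(ii) full symbolics whenever the orbit-reduced system has at most 16 rows
(symmetric graphs are both the cheap and the interesting cases); (iii)
otherwise the scan, with exact rational confirmation of the sign of $D$
on both flanks of every detected transition, at six representative
fitnesses ($3/2$ to $1000$) for every graph whose scan shows suppression
anywhere, at one interior fitness for pure amplifiers, and an exact
re-decision of every tie; any disagreement escalates the graph to full
symbolics.  This reproduces the published order-6 and order-7 tables
exactly at desk scale (about 3 s and 90 s of classification
respectively, after roughly 20 s of enumeration).

Critical fitnesses are displayed truncated (not rounded) to two decimals,
matching the convention evident in the published values (e.g. an exact
root at $5.1761$ printed as $5.17$, and $24.797$ as $24.79$); full
precision and the exact isolating intervals stay in the objects.

## Enumeration, identifiers and counting

Every connected graph on $N$ vertices arises from a connected graph on
$N - 1$ vertices by deleting a spanning-tree leaf, so augmenting each
order-$(N-1)$ representative with a new vertex joined to every non-empty
subset, and deduplicating by BLISS canonical form, enumerates all classes
(practical to $N = 8$; 11,117 classes).  Canonical identifiers encode the
canonically labelled adjacency matrix behind a sentinel bit, decode back
to the edge list, and are *not* comparable to identifiers of external
databases, whose bit layout is unspecified.  Class counts up to $N = 10$
come independently from orbit counting over the pair action of the
symmetric group (cycle index) followed by the inverse Euler transform —
enumeration and counting cross-validate each other where both apply.

## Graph families

The `ell` family $\ell_N^{n,m}$ (clique $K_{N-2}$ plus two adjacent extra
vertices attached to disjoint sets of $n$ and $m$ clique vertices) is
constructed directly from its definition.  The friendship families are
under-determined by their schematic descriptions, so their conventions
were fixed by calibration against the independently classified order-7
census: the friendship cycle $FC_N^m$ spaces its $m$ centre-attached
cycle edges as evenly as possible ($FC_7^2$ is then exactly the census
graph losing amplification at $r_c \approx 4.98$); the friendship star
$FS_N^m$ glues $m/2$ "diamonds" (two 3-cliques on a shared base edge) at
one common apex ($FS_7^4$ is exactly the census graph with
$r_c \approx 24.79$); the friendship ribbon $FR_N^m$ chains the same
diamonds through distinct shared apexes, so no vertex lies in more than
two 3-cliques.  Star and ribbon coincide for $m = 4$ and diverge from
$m = 6$; both give order 10 at $m = 6$.  Beyond the calibrated cases the
star/ribbon conventions remain provisional: a future checkable value that
disagreed would falsify the convention, not the solver.

## Monte-Carlo check

The simulator realises the same kernel by construction — reproducer
sampled by fitness class then uniformly within it, neighbour by $w_{ij}$ —
and serves exclusively as an independent stochastic check of the solvers
(binomial agreement within $3.29$ standard errors at $10^5$ runs).  It
uses R's RNG, so `set.seed()` (or the `seed` argument) makes runs
reproducible.  A hard cap of $10^8$ steps per trajectory turns any
non-absorbing loop (impossible for a correct kernel) into a diagnostic
rather than a hang.  Simulation is never used to classify regimes: a
scan of finitely many fitnesses cannot certify a regime, and a sampled
estimate is strictly weaker still.

## Problem sizes and limitations

The shipped tests and the acceptance script work at desk scale: full
censuses of orders 6 and 7 (112 and 853 graphs), symbolic curves for the
ell-graphs to order 10 and friendship graphs of order 7, counting to
order 10.  An order-8 census (11,117 graphs) runs with the same code in
roughly an hour but is not part of the default runs; orders 9–10 are
counted, not enumerated.  Exact classification certifies all $r > 1$;
scan results are always labelled with their range.  The dense solvers
stop at 4096 states/orbits and direct the user to orbit reduction or the
scan.  Within the exact arithmetic there are no tolerances to tune: the
only numerical knobs are the scan grids, the $10^{-9}$ tie threshold and
the $10^{-6}$ isolation width documented above.
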