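---
title: "Computing minimum metabolic subnetworks with minsubnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing minimum metabolic subnetworks with minsubnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minsubnet)
```

## The problem

Genome-scale metabolic reconstructions routinely contain thousands of
reactions, which puts several useful constraint-based analyses (elementary
flux modes, minimal cut sets, exhaustive intervention screens) out of
computational reach. A common remedy is to *reduce* the model: find a
subnetwork that is much smaller but still able to do everything the analyst
cares about. `minsubnet` computes subnetworks that are **provably minimum
in the number of active reactions** subject to four kinds of user
requirements:

1. a set of *protected metabolites* that must stay connected,
2. a set of *protected reactions* that must be able to carry flux,
3. a list of *protected functionalities*, each a system of linear flux
   conditions $D_f v \le d_f$ (for example "at least 99.9% of maximal
   growth, with the oxygen exchange closed"),
4. a minimum number of *degrees of freedom* for the reduced network.

Greedy pruning heuristics satisfy the same requirements but can terminate
in subnetworks that are larger than necessary, because the order in which
reactions are probed matters (the `make_branch_toy()` fixture is the
canonical trap: probing the direct branch first strands you with the
two-step detour). Formulating the problem as a mixed-integer linear
program removes the order dependence and, as a side benefit, allows
enumerating *all* minimum subnetworks.

## The flux space and activity variables

The model is the steady-state flux space
$C = \{ v \in \mathbb{R}^{\mathrm{Rxn}} \mid S v = 0,\; l \le v \le u \}$
with the irreversible reactions $\mathrm{Irrev} = \{ i : l_i \ge 0 \}$.
Activity of a reaction is encoded by a binary $a_i$ with the intended
semantics $a_i = 0 \iff v_i = 0$. Exact zero/nonzero logic is not
MILP-representable, so a positive activity threshold $\delta$ is
introduced: an active reaction must carry at least $\delta$ flux. For an
irreversible reaction,

$$\delta\, a_i \le v_i \le M a_i,$$

and for a reversible one, with a second binary $\bar a_i$ for the
backward direction,

$$\delta\, a_i - M \bar a_i \le v_i \le M a_i - \delta\, \bar a_i,
  \qquad a_i + \bar a_i \le 1 .$$

`delta` defaults to `1e-04`, the upper end of the range we consider
numerically safe (`1e-06`–`1e-04`); values outside that range are accepted
with a warning. The big-M constant defaults to
`max(1000, largest finite |bound|)` and must dominate every finite bound.

### Single copy: `build_minnw0()`

When all functionalities are mutually compatible, one flux vector can
witness everything at once; the objective
$\min \sum_i a_i + \sum_{k \in \mathrm{Rev}} \bar a_k$ counts active
reactions because $a_i + \bar a_i \le 1$. Protected reactions enter as
$a_i = 1$ (irreversible) or $a_i + \bar a_i = 1$ (reversible). A protected
metabolite $m$ needs its own constraint only when no protected reaction
touches it:

$$\sum_{i \in \mathrm{Rxn}_m} a_i + \sum_{i \in \mathrm{Rev}_m} \bar a_i \ge 1 .$$

### One copy per functionality: `build_minnw()`

Functionalities are often *conflicting*: growth with oxygen uptake and
growth without oxygen uptake cannot be shown by the same flux vector,
since that vector would need $v_{o_2} \ge \delta$ and $v_{o_2} = 0$
simultaneously. The multi-copy formulation therefore carries one flux
vector $v^j$ (with its own binaries $a_i^j,\bar a_i^j$) per functionality
$j = 1 \dots |\mathcal F|$, plus a copy $j = 0$ for the protected sets.
Aggregated binaries tie them together,

$$a_i \le \sum_{j=0}^{|\mathcal F|} a_i^j \le (1+|\mathcal F|)\, a_i
 \qquad\text{(and the $\pm$ analogue for reversible reactions)},$$

and the objective $\min \sum_i a_i$ counts reactions that are active in
*any* copy. The `make_dual_condition_toy()` fixture shows why this is
worth the extra variables: minimizing each functionality separately and
taking the union can cost 7 reactions, the joint minimum needs only 6.

Protected sets bind the $j=0$ copy only. One might biologically expect
the functionality copies to also respect protected-reaction activity;
the formulation deliberately does not require that — each copy witnesses
exactly its own requirement, and the union objective handles the rest.

### Coupling classes: `build_minnw_rep()`

Over the sign cone
$C_0 = \{ v \mid Sv = 0, v_i \ge 0\ \forall i \in \mathrm{Irrev}\}$, two
unblocked reactions are *partially coupled* ($r \Leftrightarrow s$) when
$v_r = 0 \iff v_s = 0$ for every $v \in C_0$. This is an equivalence
relation, and its classes behave like enzyme subsets: all-or-nothing
groups. One binary per class, weighted by class size in the objective,
preserves the optimum while cutting the binary count — on genome-scale
models typically by about half.

Classes may mix reversibilities. We choose an irreversible representative
whenever one exists (avoiding spurious sign freedom) and treat the class
as reversible only if the representative is reversible. A member whose
reversibility disagrees with its class gets a sign-free activity gate
(`0` when the class is off, its own bounds when on) rather than the
$\delta$-floored rows; coupling guarantees such a member carries flux
whenever its class does, but the solver is not forced to push it past
$\delta$. The class rows also assume that coupled reversible members run
in a coherent orientation; networks where partially coupled reversible
reactions must run in opposing sign patterns would need per-member
direction binaries, which we deliberately avoid.

## Preprocessing

Blockedness and coupling are *structural* properties: they are decided
over $C_0$, which ignores the finite bounds, so preprocessing does not
depend on the bound values. The LPs are solved over $C_0 \cap [-1,1]^n$,
which is equivalent by scale invariance of the cone. Dead-end metabolite
removal (`find_dead_end_metabolites()`) runs first purely as a
combinatorial speed-up — every reaction touching a dead end is blocked
anyway, and the final unblocked set is identical with or without it. The
coupling partition is seeded by grouping proportional rows of a nullspace
basis of $S$ (proportionality in the nullspace implies coupling on the
cone) and refined by pairwise LPs between group representatives.

## Enumeration and degrees of freedom

After each solve, the found activity pattern $Z^k$ is excluded by the
integer cut

$$\sum_{i:\,Z^k_i=0} a_i + \sum_{i:\,Z^k_i=1} (1 - a_i) \ge 1,$$

(or its class-space analogue), which removes exactly that 0/1 assignment.
Because cuts only remove already-found patterns, the first re-solve whose
optimum strictly exceeds the minimum size proves that the enumeration is
complete; `enumerate_minimum_subnetworks()` reports this as
`exhausted = TRUE`. Cuts act on activity patterns, so two solutions that
differ only in their witness fluxes are one solution. Solutions are
canonicalized (lexicographic active-set order) so output order does not
depend on the solver's tie-breaking.

Degrees of freedom are $|A| - \mathrm{rank}(S_A)$ for active set $A$.
With the default `dof_min = 1` the requirement is vacuous whenever
anything is protected (forced flux implies a nonzero nullspace vector).
For `dof_min > 1`, solutions failing the check are excluded by a cut but
*not counted*; the reported minimum size is the smallest dof-passing
size. This is the one place where the returned "minimum" can exceed the
unfiltered MILP optimum.

## Encodings and the solver backend

Two activity encodings are available and are required to agree on every
fixture (the test suite asserts this):

* **`bigM`** emits the constraints above literally, with infinite model
  bounds capped at $\pm M$ *inside the encoding only* — the network
  object keeps its infinities.
* **`indicator`** expresses the implications $a = 0 \Rightarrow v = 0$
  and $a = 1 \Rightarrow v \ge \delta$ without a global constant, by
  compiling them into linearizations that use each reaction's own finite
  bounds (e.g. $v_i \le u_i a_i - \delta \bar a_i$). This is exact
  whenever the bounds are finite and avoids the numerical trouble that a
  large shared $M$ invites. A reaction with an infinite bound cannot be
  linked this way; `encode()` then raises a capability error suggesting
  the big-M fallback.

All LPs and MILPs are solved by **HiGHS**, reached through a small
bundled Python worker (`scipy.optimize.milp`); the worker is a persistent
subprocess spoken to over a local socket so that the many small LPs of
flux variability, blockedness scans and the brute-force oracle cost one
round trip per batch. The MIP gap is set to `1e-9` (prove optimality),
and solutions are post-validated: activity flags are re-derived from the
witness fluxes (active iff some copy carries more than $\delta/2$) and
cross-checked against the solver's binaries; steady state and every
functionality row must hold within `1e-06`. A mismatch is an error, not
a silent repair — MILP integrality tolerances can otherwise corrupt
active sets unnoticed.

## The synthetic fixtures and the oracle

`random_feasible_network()` builds small sparse integer-stoichiometry
networks around a guaranteed-functional backbone (import → conversion
chain → export), with bounds $[0,10]$ or $[-10,10]$; by default the test
suites use 8 metabolites, 12 reactions, 30% reversible, and two
functionalities per scenario — small enough for exhaustive verification,
large enough to produce branching, blocked reactions and nontrivial
coupling classes. What these fixtures do **not** emulate: realistic
biomass compositions, thermodynamic constraints,
gene–protein–reaction structure, and the numerical pathologies of
genome-scale bounds (e.g. $\pm 1000$ defaults mixed with tiny
coefficients). Passing tests therefore validate the *formulations and
algorithms*, not solver robustness at genome scale.

`brute_force_minimum_subnetworks()` is the independent ground truth: a
subset of reactions is feasible when plain LPs (everything outside the
subset clamped to zero) witness every functionality and the protected
requirements, and the oracle returns all feasible subsets of minimum
cardinality. Before enumerating, the search space is reduced by two sound
arguments: a reaction whose clamping makes some requirement infeasible is
in every feasible subset, and a reaction that cannot reach $\delta/2$
under any requirement is in no *minimal* one. Disjunctive requirements
(the sign of a reversible protected reaction; which reaction keeps a
protected metabolite) are expanded into variants. One caveat is inherent:
the oracle's LP witnesses are not $\delta$-quantized, so a subset could in
principle be LP-feasible only via fluxes in $(0, \delta)$ that the MILP
would reject. With $\delta = 10^{-4}$ and integer stoichiometries in
$[-2, 2]$, basic solutions have entries orders of magnitude above
$\delta$, so the gap is immaterial at the fixture scale; it is the reason
$\delta$ sits at the top of its recommended range by default.

## Worked example

```{r example, eval = FALSE}
toy <- make_dual_condition_toy()
res <- enumerate_minimum_subnetworks(toy$network, toy$scenario)
res
#> Enumeration result: 2 minimum subnetwork(s) of size 6 (exhaustive)
#>   core: 5 reaction(s), union: 7 reaction(s)
compare_subnetworks(res)
#> Subnetwork comparison across 2 solution(s):
#>   core 5 / union 7 reactions; 1 mutually exclusive pair(s),
#>   0 always-together pair(s)
```

The two minima swap the interchangeable transport steps `t1`/`t2` — a
mutually exclusive pair, the small-scale analogue of isoenzyme pairs in
real reductions.

## Known limitations

* Minimality is fundamentally at odds with preserving flux variability:
  a minimum subnetwork keeps one witness per functionality, not the full
  range of behaviors.
* Enumeration cost grows with the number of alternative optima; the
  `max_solutions` / `time_limit` guards (with `exhausted = FALSE`)
  exist for scenarios with combinatorially many minima.
* Elementary-flux-mode level co-occurrence analysis of the reduced
  networks is out of scope; `compare_subnetworks()` works at the level
  of activity patterns only.
* The indicator encoding requires finite bounds on linked reactions; use
  big-M (or finite bounds) for models with unbounded exchanges.
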