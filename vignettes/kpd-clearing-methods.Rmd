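---
title: "Clearing kidney paired donation pools: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clearing kidney paired donation pools: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpdclear)
```

## The clearing problem

A kidney paired donation (KPD) pool is a directed graph. Nodes are
incompatible donor–patient pairs plus altruistic donors; an arc
`i -> j` with weight `w_ij > 0` states that the donor of node `i` can
give to the patient of node `j` (ABO-compatible and expected to pass
crossmatch). Exchanges are bounded-length structures in this graph:
simple cycles over pairs (a cycle of L pairs yields L transplants) and
chains rooted at an altruistic donor (L nodes yield L − 1 in-pool
transplants; the terminal pair's donor bridges to the deceased-donor
waiting list). Because all operations of an exchange are performed
simultaneously, length is capped at `k` (default 3, matching common
hospital practice).

After enumerating the exchange set `M`, clearing is weighted set
packing: select a subset of `M`, pairwise node-disjoint, maximizing
total arc weight. With unit weights the objective is the number of
transplants; non-unit weights let a registry prioritize hard-to-match
patients. The package keeps that as the only prioritization mechanism —
weights are data, not a separate rule system.

## Pool representation and enumeration

`kpd_pool()` validates the structural invariants (unique ids, altruistic
nodes carry no patient and can never receive, no self-arcs — a pair that
could self-match would never enter a KPD pool, no duplicate arcs).
`build_compat_matrix()` lays the square utility matrix out pair-nodes
first, then altruistic donors, each in ascending id order. The fixed
order matters: exchange enumeration scans it deterministically, so the
index order of `M` — the coordinate system of every optimizer — is
reproducible across runs.

`extract_chains()` is a depth-first search over simple paths from each
altruistic root, emitting every prefix of length 2..k nodes (a shorter
chain is a valid exchange on its own). `extract_cycles()` roots a search
at each node and only descends into larger ids, which yields every
simple cycle of 2..k pairs exactly once and already in its canonical
rotation (minimum id first); the canonical form is needed because a
cycle has no distinguished starting node. `enumerate_exchanges()`
concatenates chains before cycles, each group sorted by (length, node
sequence). Equivalence with an independent exhaustive search (igraph
simple paths; subset-times-rotation enumeration for cycles) is asserted
over randomized digraphs in the test suite.

## The penalized objective

A candidate solution is a binary mask `Y` over `M`. Its fitness is

```
f(Y) = sum of w_ij over arcs of selected exchanges  -  (E1 + E2) * lambda
```

where `E1` counts nodes donating more than once across the selected
exchanges, `E2` nodes receiving more than once, and `lambda` is a
penalty weight far above the pool size (`run_round()` passes
`10 * pool size`; solvers default to ten times the number of distinct
nodes in `M` when the pool is out of view). Whenever `lambda` exceeds
the total utility of `M`, every infeasible mask scores strictly below
every feasible one, so the penalty never distorts the feasible ranking.

Two conventions needed pinning down, and the worked instance
(`make_worked_instance()`) fixes both:

* **Every node of a selected exchange donates.** Cycle members donate to
  their successor; a chain's altruistic root starts it; interior pairs
  donate onward; and the terminal pair of a chain donates to the
  waiting list as a bridge donor. Selecting a 2-node chain therefore
  occupies its pair's donor as well as its patient, which is what makes
  that chain conflict with a cycle containing the same pair *as a
  donor* — the worked instance's mask `[1,1,0,1]` has `E1 = 1, E2 = 0`
  and fitness `6 - 50 = -44`.
* **A conflicted node is penalized once.** `E1`/`E2` count violating
  nodes (donor-side first), not violation multiplicity, so a node used
  three times still contributes one unit to `E1`.

### Graded search penalty

The node-counted penalty has a search-topology flaw: once a node is
used three or more times, dropping one of its exchanges leaves the node
still conflicted — the penalty is unchanged and utility falls, so *no
single bit-flip improves an infeasible mask* in that region. Empirically
the bit-flip ALO then stalls at infeasible plateaus on instances with
|M| in the dozens (the elite stayed infeasible for 150+ generations
while the whole colony collapsed onto it). The solvers therefore search
on a *graded* penalty, `lambda` per excess use per node. The two forms
agree exactly wherever no node is used more than twice — in particular
on every feasible mask, every single-conflict mask, and the worked
instance — but the graded form always rewards shedding an over-used
exchange, restoring a strict descent direction to feasibility. Reported
solutions are re-evaluated with the node-counted breakdown
(`evaluate_selection()`), so printed `E1`/`E2` keep their published
meaning.

## Binary Ant Lion Optimization

The continuous ALO explores with cumulative random walks, which cannot
preserve a binary encoding, so this variant substitutes discrete
operators while keeping the ALO control flow:

* **Initialization**: each individual is the great-value-priority (GVP)
  binarization of a uniform vector on `[0,1]^d` — bit `i` is set when
  the descending rank permutation satisfies `P[i] >= P[i+1]` (ties break
  toward the lower index; the last bit, with no successor, is 0). GVP
  maps continuous positions to priority-ordered masks; its exact
  permutation convention only affects initialization diversity.
* **Per generation, per ant**: roulette-wheel selection (on fitness
  shifted by `-min + 1e-9`, since penalized fitness is routinely
  negative) picks a trap-owning ant lion; the selected ant lion and the
  elite are each mutated by one uniformly chosen bit flip; the ant takes
  each bit from the mutated elite with probability 1/2, else from the
  mutated ant lion.
* **Catch and rebuild**: an ant strictly fitter than its selected trap
  owner replaces it. The replacement target is the roulette-selected
  ant lion ("its corresponding ant lion"); the stored elite copy is
  updated only when some ant lion strictly beats it, so the elite trace
  is non-decreasing by construction.

Defaults follow the published settings: 200 generations and population
200 (used for both colonies, since a single population size is
published; both are configurable). The mutation guide is re-drawn per
ant rather than per generation — the natural reading of the per-ant
update loop.

## Post-processing

Metaheuristic output is repaired by `postprocess_solution()`: one
augmentation pass adds every exchange node-disjoint from the growing
solution; one swap pass replaces a selected exchange by a strictly
higher-utility unselected one when disjoint from the rest; and a final
augmentation pass runs because a successful swap can shrink the used
node set (that last pass is a deliberate extension of the single sweep;
`final_augment = FALSE` restores the literal two-phase form). Both
phases scan in descending utility, ties by index, making the repair
deterministic; utility never decreases and feasibility is preserved.
The trial count is bounded by `|M| + |M| * |solution|` per pass, versus
`2^|M|` for exhaustive search. If a solver ends infeasible,
`kpd_solve()` first strips the mask to a feasible subset greedily and
then repairs.

## Baselines

* `solve_exact()` solves the set-packing model exactly as a
  maximum-weight independent set on the exchange conflict graph by
  depth-first branch and bound (descending-utility order, suffix-sum
  bound). No integer-programming solver is required; equivalence with
  the `2^|M|` optimum is asserted on 30 randomized instances in the
  suite. It is the optimality oracle for every heuristic claim.
* `ga_solve()` is a generational binary GA with the published baseline
  settings (population 800, 100 generations, crossover 0.8, mutation
  0.2, roulette parents with the same fitness shift, one elitist
  carry-over; single-point crossover by default, uniform as an option —
  the published account does not fix the operator). It shares the
  search fitness with ALO so the comparison isolates the search
  dynamics. In benchmarking, the repair stage belongs to the proposed
  ALO pipeline; the GA reports raw output and an infeasible GA run
  counts as zero transplants.

## Synthetic pools

`generate_kpd_pool()` follows the Saidman-generator scheme: donor and
patient ABO groups are drawn from population frequencies (O 48.14%,
A 33.73%, B 14.28%, AB 3.85%); each patient receives a sensitization
level — the probability that an ABO-compatible donor still fails
crossmatch; couples are resampled until internally incompatible, since
compatible couples transplant directly and never register; arcs are
ABO-compatibility times an independent Bernoulli crossmatch draw per
(donor, patient). Altruistic donors default to 5% of the pair count.

The sensitization mix defaults to levels (0.05, 0.85, 0.98) with
prevalences (0.10, 0.20, 0.70). This models a *registry* pool, which is
dominated by highly sensitized, hard-to-match patients because
easy-to-match pairs clear quickly and leave: it reproduces the
compatibility-arc density characteristic of registry-fitted KPD
simulations (about 4–6% of ordered node pairs, e.g. ~50 arcs at 30
pairs and ~2000 at 200 pairs at the defaults). The classical community
mix (levels 0.05/0.45/0.90 with prevalences 0.70/0.20/0.10) yields
~30% arc density — an unrealistically easy pool — and remains available
through `saidman_params()`.

What the generator does *not* model: allele-level HLA typing (collapsed
into the sensitization probability), correlations between blood group
and sensitization, arrival-time dynamics within a round, and pair
withdrawal. Tests passing on these pools show the pipeline clears
realistic compatibility structures correctly; they do not certify
performance on any particular registry's case mix.

## Numerical and design choices

* Node ids are 0-based and contiguous in generated pools; after
  `remove_matched()` ids keep their identity (gaps allowed).
* Roulette shift epsilon is `1e-9`: the worst individual stays
  selectable without distorting proportionality.
* The exact solver breaks utility ties toward the lower dimension
  index; enumeration order makes this reproducible.
* Seeds: every stochastic entry point takes an explicit seed;
  `derive_seed()` mixes a top-level seed with (size, solver, repeat)
  labels so that adding a solver to an experiment does not perturb the
  streams of the others. All derived seeds stay below 2^31.
* Degenerate inputs: an empty exchange set yields the empty solution
  with fitness 0; a pool without relations clears zero transplants and
  is returned unchanged.
* Problem sizes in the shipped tests — pools of 30–75 pairs, exchange
  sets up to ~100 dimensions, 10 seeds per pool — were chosen so the
  whole suite exercises every claim at desk scale in about a minute.

## Known limitations

* The swap phase exchanges one-for-one only; escaping local optima that
  need two-for-one swaps is left to the optimizer (and visible as the
  occasional one-transplant gap to the exact optimum on |M| ~ 40+
  instances, mirroring the published behavior at that scale).
* Branch and bound is exponential in the worst case; it is comfortable
  at the benchmark scales here (|M| up to ~1000 with k = 3), but very
  dense pools would need a dedicated ILP solver.
* Multi-criteria objectives (waiting time, registration time) and
  never-ending chain carry-over across rounds are out of scope; weights
  `w_ij` are the single extension point.
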