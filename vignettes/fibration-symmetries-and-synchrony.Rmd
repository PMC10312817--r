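---
title: "Fibration symmetries, building blocks and cluster synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibration symmetries, building blocks and cluster synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibersync)
```

## The problem

Small neuronal circuits — the motivating case being the forward and backward
locomotion sub-networks of *C. elegans*, with 20–30 neurons coupled by
directed chemical synapses and undirected gap junctions — show *cluster
synchronization*: groups of neurons whose activity traces coincide. This
package implements the structural theory that predicts those groups from
connectivity alone, and the dynamical machinery to verify the prediction.

The structural notion is the **graph fibration**. Two nodes belong to the
same *fiber* when their *input trees* — the rooted trees of all walks
terminating at each node, with edge multiplicity given by integer weight —
are isomorphic. Equivalently, the fiber partition is the **minimal balanced
coloring**: the coarsest partition in which every node of a cell receives
the same total weight from each cell, per channel. Under any *admissible*
dynamics (each node driven only by its inputs, identically parameterized),
nodes of one fiber started together and stimulated identically stay exactly
synchronous for all time. The competing notion, the **orbit partition** of
the automorphism group, constrains outputs as well as inputs; every orbit
is contained in a fiber, and on directed channels the containment is often
strict. Since membrane potentials respond to inputs, not outputs, fibers
are the partition that biology should follow.

## Partitioning machinery

`minimal_balanced_coloring()` refines from the all-one-cell coloring by
splitting on the per-cell, per-channel total input weight until a fixed
point. Refinement from the top and refinement from discrete colors reach
the same fixed point (equitable partitions form a lattice with a unique
coarsest element); we refine from the top because it directly certifies
coarseness. Cell identities are made deterministic by ordering cells by
(size, lexicographically smallest member). Binary mode replaces weights by
edge counts.

`input_tree()` stores layers as per-node walk counts (an edge of weight w
contributes w parallel entries), so the layer-count sequence `a` is exact
while the tree itself never needs to be expanded — at depth n−1 a dense
30-node graph would have ~10^15 explicit entries. `trees_isomorphic()` is
iterated in-neighborhood colour refinement on the disjoint union of the two
host graphs: after d rounds, equal root colours are equivalent to layerwise
rooted-tree isomorphism at depth d. Depth n−1 suffices to separate all
non-isomorphic trees, and the suite checks the equivalence *tree
isomorphism at depth n−1 = same fiber* on planted lifts.

`automorphisms()` is exact backtracking with equitable pruning: candidates
are restricted to cells of the double (in + out profile) refinement and
partial images are checked against every channel adjacency. This is
deliberate — the target networks have at most a few dozen nodes, weights
must be respected, and an exact enumerator doubles as the test oracle
(small groups are verified against brute force over all permutations).
`orbit_coloring()` does not enumerate the whole group: for each unmerged
same-cell pair it searches for *one* automorphism mapping u to v and merges
the full permutation's node/image pairs in a union-find. Exact search on
networks beyond 64 nodes is refused rather than attempted.

## Building blocks and fiber numbers

Each fiber's **building block** is the induced subgraph on (1) the fiber,
(2) its immediate in-neighbors, (3) the shortest non-self loop through a
fiber node, and (4), if the result is disconnected, the shortest undirected
connecting paths (the block is then *composite*). Shortest loops and paths
are found by breadth-first search with lexicographic tie-breaks.

Blocks are classified by the fiber numbers |n, ℓ⟩:

* **|n⟩, branching ratio** — the growth rate of the input-tree layer counts
  a_{i+1}/a_i. It is computed twice: from the layer recursion itself, and as
  the Perron root of the adjacency restricted to the root's in-component;
  the two must agree within 1e-6. The layer iteration stops only when the
  ratio is stable to ~1e-11 over ten consecutive layers (slowly drifting
  ratios are flagged as non-converged rather than reported early, and the
  spectral value is used; an acyclic in-component returns 0 exactly). A
  non-integer |n⟩ marks a nested-loop ("Fibonacci") block: the golden-ratio
  base `[[1,1],[1,0]]` gives 1.6180…, and the two-node base `[[1,8],[1,0]]`
  gives (1+√33)/2 = 3.3723….
* **|ℓ⟩, trail count** — the number of edge-distinct walks terminating at
  the collapsed fiber in the multiplicity-free base, with the root's
  outgoing edges removed. That convention is fixed by the three-node
  reference toy (nodes C, M, P; edges M→C, P→C, M→P, P→M), whose six trails
  are enumerated explicitly. The count is exhaustive (reverse DFS over the
  edge set) and cross-checked against an independently written forward
  enumeration. Because the field also uses ℓ for the number of
  *regulators* — non-fiber nodes with only outgoing edges inside the
  block — both quantities are computed and reported; the rendered
  expression uses trails. Fiber nodes feeding back into their own fiber are
  reported separately as `feedback`, not counted as regulators, so a
  self-contained cycle block is |n, 0⟩ with zero regulators.

Multilayer expressions chain blocks through their regulators: layer 1 is
the main block, layer k+1 the blocks of layer k's regulator fibers (each
fiber appearing once), rendered `|n1,ℓ1⟩ ⊕ |n2,ℓ2⟩ + |n3,ℓ3⟩` with ⊕
between layers and + within one.

## Admissible dynamics

Three models couple membrane potentials V_i (SI units internally; the
interface speaks mV and pA):

* **gap**: `V̇ = −α_leak (V_i − V_rest) − α_gap Σ_j A^gap_ji (V_i − V_j) + α_ext I_i`
* **chem I**: sigmoid-gated currents, `− α_chem Σ_j A^chem_ji Φ(V_j) (V_i − V_s,j)`
* **chem II**: a synaptic activity variable per node,
  `ṡ_i = a_r Φ(V_i)(1 − s_i) − a_d s_i`, gating the same current with s_j.

`Φ(V) = 1/(1+exp(−γ(V − V_threshold)))` is centered per node at the
equilibrium of the coupled system, obtained by `threshold_voltages()` as
the solution of the linear stationarity system with Φ pinned at 1/2 (and
s at s_eq). Two placement choices in that system were genuinely open and
were settled by requiring the residual of the model right-hand side at the
solved equilibrium to vanish (the suite demands < 1e-12 V/s): the gap
off-diagonal enters per entry (not summed), and the external-current term
sits inside the 1/α_leak factor — both follow from dividing the
stationarity equation by α_leak, and the isolated-neuron closed form
(V_rest + I/(C α_leak), i.e. +0.1 V per pA) confirms the scaling.

Parameters follow the standard single-compartment calibration: α_leak =
10 s⁻¹, α_gap = α_chem = 100 s⁻¹, α_ext = 1/C with C = 1 pF, γ = 125 V⁻¹,
a_r = 1 s⁻¹, a_d = 5 s⁻¹, hence s_eq = a_r/(a_r + 2 a_d) = 1/11 ≈ 0.09.
V_rest defaults to −35 mV; a −37 mV value also circulates for the resting
state, and the parameter is settable, but the figure-calibrated −35 mV is
the default. All synapses default to excitatory (V_s = 0 mV); inhibitory
nodes (V_s = −70 mV) are supported through the node attribute.

Integration is fixed-step classical Runge-Kutta at dt = 0.1 ms
(`simulate_network()`), deterministic without noise; the suite verifies
4th-order convergence under dt halving and ~1e-8 relative accuracy against
the closed-form leak decay. Noise stimuli are seeded Gaussian random walks
advanced with √dt increments, min-max rescaled into the amplitude band
[−amp, +amp], shared within each stimulated fiber cell and held constant
within a step; a seed fully reproduces a run. Balanced-mode stimuli refuse
to split a fiber cell — targeting half a left-right pair, or giving two
same-cell nodes different parameters, is a validation error, because the
synchronization theorem assumes cell-constant input.

## Stability

`jacobian_matrix()` evaluates the three Jacobians at the equilibrium. The
gap Jacobian is −α_leak I − α_gap L with L the gap Laplacian — independent
of the drive, leading eigenvalue exactly −α_leak (uniform eigenvector),
hence unconditionally stable. The chemical Jacobians are obtained by
differentiating the model equations at Φ = 1/2, Φ′ = γ/4, s = s_eq; signs
are not taken on faith but pinned by a central finite-difference check
(< 1e-6 relative error, part of the suite). The drive enters only through
the equilibrium voltages in the off-diagonal blocks, which is why the
leading eigenvalue moves linearly with injected current.
`instability_threshold()` scans the drive at 0.1 pA resolution and bisects
the first sign change to 0.01 pA, matching a dense 0.001 pA scan on toys;
"positive" means real part > 1e-9 s⁻¹.

## Synchrony metrics

`los_matrix()` computes the Level of Synchronicity, the time-averaged
Gaussian kernel `exp(−(V_i−V_j)²/2σ²)` over the trailing window (default
the last simulated second) with σ = 0.1 mV, so a constant offset of one
kernel width scores e^{−1/2} ≈ 0.61. `plv_matrix()` computes phase-locking
values from analytic-signal (spectral Hilbert) phases of de-meaned
signals; pairs with an undefined phase (non-identical constants) are
scored 0 and flagged. `agreement_score()` binarizes LoS at 1 − 10⁻³
(the rounding precision used for "equal to 1" is not canonical; the
threshold is a parameter) and normalizes the difference from the
partition's ideal block matrix by 2(n²−n): zero is perfect fiber
separation, negative means fibers synchronized with each other — which the
theory permits — and positive would mean a fiber failed to synchronize.
`masked_difference()` restricts the comparison to within-fiber blocks for
the perturbation sweeps.

## The synthetic generator, and what it does not emulate

`planted_lift()` realizes a fibration lift: every base node becomes a
fiber, every base chemical edge x→b of weight w is scattered so that each
lifted b-node receives total weight w from fiber(x) with uniformly random
tails, and gap edges lift through deterministic circulants (cross-fiber
gap demands equal fiber sizes; an odd within-fiber demand on an odd fiber
falls back to flagged self-pairings). When the base is *identifiable* (its
own minimal balanced coloring is discrete), the lattice structure of
balanced partitions guarantees the lift's coarsest balanced coloring is
exactly the planted one — the recovery property the suite sweeps over 50
seeds. `locomotion_fixture()` lifts an identifiable 7-node base into a
20-neuron circuit shaped like the forward locomotion system: three
left-right interneuron pairs (AVB-, PVC-, RIB-like) driving four
motor-neuron classes, chemical feed-forward plus within-class gap
junctions. Fixture sizes (pairs of 2, classes of 3–4, ~30 edges) were
chosen once to match the scale of the real sub-networks.

The generator emulates the *symmetry structure* of the repaired locomotion
networks, not their particular wiring: it does not reproduce the exact
repaired connectomes, rectifying or inhibitory circuitry, heterogeneous
neuron parameters, or synaptic delays. Tests passing on fixtures therefore
certify the algorithms and the admissibility of the models, not any claim
about a specific worm's wiring; the published repaired networks can be
dropped in as edge-list TSVs and are consumed by the same functions (the
suite contains optional integration checks that activate when those files
are present).

The three simulation protocols are bundled by `simulation_protocol()`:
free running from randomized initial conditions (voltage sd read as
millivolts, 0–0.1 mV, the synaptic sd dimensionless 0–0.1); driving at
90% of the instability threshold plus a 5% sinusoid (2 Hz interneurons,
1 Hz motor neurons; gap networks get a second motor drive because a single
balanced drive leaves them globally synchronous); and the
weight-perturbation sweep (0.1 pA constant + 0.5 pA sinusoid + 0.01 pA
noise band — 0.61 pA peak, below every measured threshold — with zero-mean
Gaussian weight noise, sd 0 to 0.1, replicate-averaged). Perturbed weights
are clipped at a 1e-6 floor rather than allowed to change sign: a negative
conductance is unphysical (the floor can be disabled). Subtracting versus
adding zero-mean noise is the same distribution; addition is implemented.

## Problem sizes and runtime choices

The checked-in analyses and tests run on the 20-node fixture and smaller
toys: simulations of 0.25–3 s at dt = 0.1 ms, perturbation sweeps of sd ∈
{0, 0.02, …, 0.1} with 3 replicates, and oracle sweeps of tens to hundreds
of seeded cases. These sizes keep any one suite in minutes on a single
core while exercising every code path; all of them scale by argument if
larger studies are wanted.

## Known limitations

* Exact automorphism search is exponential in the worst case; it is gated
  at 64 nodes and intended for circuit-scale graphs, not whole connectomes.
* Trail enumeration is exhaustive and refuses blocks beyond a configurable
  edge budget (default 40 distinct edges).
* The stochastic integration advances a pre-generated, rescaled noise path
  at step resolution; it is a reproducible driven-noise scheme, not a
  strong-order SDE solver.
* Cross-fiber gap lifting requires equal fiber sizes; asymmetric gap
  quotients are represented with directed weights on the base only.
* PLV is computed from the raw analytic signal without band filtering;
  broadband signals with weak oscillatory content yield noisy phases.
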