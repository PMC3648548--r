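---
title: "Perturbation-based Markovian transmission: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-based Markovian transmission: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The model

`allopath` treats a folded multi-chain protein as a residue-level Markov
chain. Each residue is a node; the coupling between residues $i$ and $j$ is
the number $n_{ij}$ of heavy-atom pairs (one atom in each residue) within a
distance cutoff, 4.5&nbsp;&Aring; by default. Row normalization gives the
transmission probability

$$m_{ij} = \frac{n_{ij}}{\sum_k n_{ik}},$$

the probability that a signal sitting at residue $i$ is handed to residue
$j$ in one step. A perturbation — ligand binding, a cluster of mutations —
is injected as an initial probability vector $p(0)$, uniform over the
perturbed residues, and evolves under the master equation

$$\frac{dp}{dt} = p\,R, \qquad R = M - I .$$

The per-residue probability flux $f(t) = p(t)R$ is the model's observable:
positive flux is net signal inflow, negative flux net outflow, and the time
at which a residue's flux peaks is its signal arrival time. Because $M$ is
the row normalization of a symmetric count matrix the chain is reversible,
and the equilibrium distribution has the closed form
$\pi_i = \sum_j n_{ij} / \sum_{ij} n_{ij}$: where the signal ends up at
$t=\infty$ depends only on the network, never on where it started.

For discrete signaling *routes*, the transition matrix is turned into a
cost graph, $c_{ij} = 1/m_{ij}$ on existing contacts, and Yen's loopless
$k$-shortest-path algorithm enumerates the $k$ cheapest simple paths from a
perturbed residue to a target (the channel gate). Low summed cost is the
model's proxy for high transmission probability.

Assumptions worth keeping in mind: coupling strength is purely steric
(contact counts), so van der Waals packing is weighted over electrostatics
— salt-bridge-mediated routes are systematically under-ranked; the network
is built from one static conformation; and a single-step probability model
says nothing about the energetics of the conformational change itself.

## Parameters

* **`cutoff`** (&Aring;, default 4.5): atom-pair contact distance, compared
  inclusively (`d <= cutoff`). This value is the one at which signal
  propagation through contact networks of this type is fastest; the whole
  network is rebuilt for any other choice.
* **`diagonal_mode`** (`"zero"` default, `"self_atoms"`): the self-contact
  count $n_{ii}$ has no unambiguous structural definition. `"zero"` makes
  transmission purely inter-residue; `"self_atoms"` (residue's heavy-atom
  count) adds mass-proportional self-retention, which rescales the time
  axis but cannot change any shortest path — self-loops never shorten a
  simple path when all costs are positive.
* **`cost_mode`** (`"inverse"` default, `"neglog"`): minimizing
  $\sum 1/m_{ij}$ (the element-wise inverse) is the stated cost transform
  and the default, but it is not mathematically identical to maximizing
  $\prod m_{ij}$; `-log m_{ij}` is, and is provided as an explicit option
  rather than silently substituted. Both are reported with each path's
  probability product so the ranking difference is visible.
* **`times`** (default `time_grid()`: $t=0$ plus 200 log-spaced points in
  $[10^{-3}, 10^3]$ model-time units): model time is in arbitrary units
  (one unit is one expected Markov step), so the grid is a rendering
  choice; it is recorded in every trajectory object.
* **`k`** (default 10): paths per (source, scenario) query.
* **Regions** for path classification, as chain-agnostic residue numbers.
  For the GLIC system the defaults are `beta1_beta2_loop = 32:37` and
  `pre_TM1 = 192:200`, inferred from the residues canonically assigned to
  those elements; the classified fractions are sensitive to these bounds,
  which is why they are plain arguments and the classifier reports
  `ambiguous`/`other` labels explicitly instead of forcing a binary split.

## Conventions and numerical choices

**Orientation.** $m_{ij}$ is the probability of transmission *from* $i$
*to* $j$; probability row-vectors multiply $M$ on the left, and
conservation follows from row-stochasticity. Although $n$ is symmetric,
rows have different sums, so $M$ is asymmetric and the cost graph is
directed.

**Propagator.** $M = D^{-1} n$ is similar to the symmetric matrix
$D^{-1/2} n D^{-1/2}$ (with $D$ the diagonal degree matrix), so one
symmetric eigendecomposition gives the exact action of $\exp(tR)$ at every
grid time. This replaces iterative Krylov stepping with an exact spectral
evaluation; the package tests verify agreement with a dense matrix
exponential to $10^{-8}$ on networks of several hundred residues, and the
decomposition cost ($O(N^3)$, once) is negligible for channel-sized
networks ($N \approx 1{,}500$).

**Flux peak.** "Arrival time" maximizes the *signed* flux, matching the
inflow/outflow sign convention of the flux heat maps; initially perturbed
residues have negative flux throughout, so their signed maximum sits at
the end of the grid, while `signed = FALSE` switches to the $|f|$ peak.
Grid ties take the earliest time.

**Determinism.** Equal-cost paths are ordered by the lexicographic order of
their node-index sequences (inside the search, distance ties prefer the
smaller predecessor index); structure parsing resolves altloc duplicates to
the highest-occupancy conformer (ties alphabetically), uses only the first
model of multi-model files, always strips hydrogens and waters, and indexes
residues by (chain, number, insertion code) in file chain order. Identical
input bytes and configuration therefore give identical outputs, which the
pipeline tests assert at the byte level.

**Degenerate inputs.** A residue with no contacts under the chosen diagonal
mode is a hard connectivity error naming the residue (a silent zero row
would make $M$ sub-stochastic); a disconnected contact graph is an error
for the equilibrium (not unique) and a per-query "no path" error for path
search; a two-node path has no interior and classifies as `other`.

**Subunit adjacency.** The three ending-subunit scenarios (same chain,
counterclockwise neighbor, clockwise neighbor) are derived from the angular
positions of chain centers of mass around the global center — chain
*labels* carry no guarantee about spatial order around the pore.

## What the synthetic structures emulate

Real pentamer coordinates cannot ship with the package, so the generators
in `make_fixture()` / `make_pore_pentamer()` build minimal structures whose
contact topology is known *analytically* — the ground-truth matrix is
derived from the placement rules, never measured — giving every stage an
independent oracle. The pore pentamer emulates the features the method
actually exercises: exact C5 symmetry (chain $k$ is chain 1 rotated by
$72k^\circ$), an extracellular column per subunit, a pore-lining column
whose gate-level residues pack against the neighboring chains, and a
single extracellular inter-subunit crossing, so that a perturbation can
reach a neighboring subunit's gate either by crossing early (the analogue
of an extracellular-interface route) or by descending its own subunit and
crossing at the gate (the analogue of a TM-level route).

What it does **not** emulate: realistic side-chain packing (residues are
single-atom, so contact counts are 0/1 rather than tens of atom pairs),
the contact-degree heterogeneity of real folds, loops and secondary
structure, or crystallographic artifacts (altlocs, missing residues,
hetero groups — those parsing behaviors are tested on small hand-written
records instead). Passing the synthetic suite therefore demonstrates the
correctness of the machinery — counting, normalization, propagation,
path search, classification — not the biological conclusions on any real
channel; those require the user-supplied deposited coordinates (see
`find_structure()`), for which the full protocol (9 perturbed residues
across two extracellular sites, gate residue 233, three scenarios,
$k = 10$, i.e. 270 paths) is wired into the acceptance tests and the
`analysis/` scripts.

## Problem sizes

The shipped test suite works at sizes chosen to keep every oracle exact:
brute-force contact counting up to a few dozen residues, exhaustive
simple-path enumeration on 100 seeded digraphs of at most 8 nodes and on
the 70-residue pentamer, and dense-matrix-exponential comparisons at
$N = 300$. The full deposited-structure protocol ($N \approx 1{,}550$)
runs in minutes on one core when the coordinate files are supplied.

## Known limitations

* Contact counts are the only coupling measure; no distance weighting,
  energy weighting, or side-chain/backbone distinction.
* One static structure per analysis; conformational ensembles must be run
  structure by structure.
* Yen's algorithm is exact but enumerative: very large $k$ on dense
  networks grows quickly in spur-path Dijkstra calls.
* mmCIF input is not parsed; convert to PDB first.
* Hetero groups can be included as network nodes (`include_hetero`), but
  region classification is residue-number based and ignores them.
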