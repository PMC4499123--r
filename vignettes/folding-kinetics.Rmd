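---
title: "Stochastic RNA folding kinetics at base-pair resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic RNA folding kinetics at base-pair resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

An RNA secondary structure is a nested set of canonical base pairs
(G-C, A-U, G-U) with at least three unpaired nucleotides in every
hairpin loop; lonely (isolated) pairs are allowed.  `rnakinetics`
treats folding as a continuous-time Markov chain on this state space.
Two states are neighbours when they differ by one elementary move, and
the chain is simulated exactly with the Gillespie algorithm: in a state
with moves of rates $k_{0i}$ and total flux $\Phi = \sum_i k_{0i}$, the
waiting time is exponential, $\tau = -\ln(r_2)/\Phi$, and move $\mu$
fires when it is the first with $\sum_{i \le \mu} k_{0i} > r_1\Phi$.

The move set contains six kinds of elementary reactions:

* **helix nucleation** — pairing two unpaired nucleotides of one loop;
* **helix extension** — adding a pair stacked on an existing helix end;
* **helix retraction** — removing a helix-terminal pair (removal of a
  lone pair, the inverse of nucleation, is treated as part of this
  class);
* **interior pair opening** — removing a pair strictly inside a helix,
  splitting it around a new 1x1 interior loop;
* **helix morphing** and **defect diffusion** — shift moves that remove
  one pair and add another sharing an endpoint.  Defect diffusion moves
  the freed nucleotide by a single position; morphing re-pairs it with a
  nucleotide bordering a neighbouring helix.  Only one nucleotide moves
  per reaction.

All moves except nucleation take the symmetric Kawasaki rate
$k = k_0 e^{-\beta \Delta G/2}$, so the forward/backward ratio is
$e^{-\beta\Delta G}$ and the chain satisfies detailed balance with
respect to the Boltzmann distribution.  Nucleation of a pair whose new
loop closes $n$ ring elements takes the polymer loop-closure form
$k_f = k_{0,\mathrm{nuc}}\, n^{-\alpha}$ with $\alpha = 1.5$
(Jacobson–Stockmayer scaling) by default; the lone-pair removal then
takes the detailed-balance partner rate
$k_b = k_f\, e^{+\beta \Delta G_f}$.  The prefactors $k_0$ and
$k_{0,\mathrm{nuc}}$ (default 1) are pure time scales: equilibrium
properties are independent of them, and all times are reported in
$1/k_0$ units.  The published experimental calibration of these
prefactors is not reproduced here, so absolute times should be read as
order-of-magnitude only.

## Energy model

Free energies follow the Turner-99 nearest-neighbour rules at 37 °C,
bundled as plain-text tables under `inst/extdata` (stacks, loop-length
tables with log extrapolation beyond 30 nt, terminal mismatches,
dangles, 1x1/2x1/2x2 special interior loops, tetraloop bonuses,
terminal-AU penalty).  Two conventions needed pinning:

* **Dangles.**  Unpaired bases adjacent to helix ends in the exterior
  loop and in multiloops contribute dangle energies per base; a base
  shared between two helix ends contributes the more favourable of its
  two options.  This single-base convention reproduces the published
  equilibrium populations of the 20-nt benchmark exactly (the
  both-sides and no-dangle conventions shift the leading population by
  −6 and +7 percentage points respectively), and it keeps every loop's
  energy a function of that loop alone, which the O(1) incremental
  update relies on.
* **Multiloops.**  The closing penalty is linear in the branch count
  ($a + b\,h$ with $a = 3.4$, $b = 0.4$ kcal/mol); with the default
  `multiloop = "logarithmic"` the unpaired length adds
  $1.75\,RT\ln(u/6)$ beyond six unpaired nucleotides, the standard
  polymer-entropy form.  `"linear"` switches to the plain linear model,
  which is what the reference evaluator used in the cross-validation
  tests implements.  The two differ only for multiloops with more than
  six unpaired nucleotides and leave the 20-nt benchmark results
  unchanged to well below the reported precision.

Temperature is configurable but rescales only $\beta = 1/RT$; enthalpy
tables are not bundled, a documented limitation.

The structural conventions (minimum hairpin 3, lonely pairs allowed,
canonical pairs including G-U) were frozen against the exhaustive
enumeration count of the 20-nt benchmark (4127 states) before any other
quantity was evaluated.

## Loop elements and the incremental update

Every structure decomposes uniquely into *loop elements*: a loop of
unpaired nucleotides and branch pairs together with the continuous
helix closing it, labelled by the innermost pair $(i,j)$ of that helix;
the external loop is labelled $(N,1)$.  In the corner case where
positions 1 and $N$ pair, the structure carries both an internal
element $(1,N)$ and the external element $(N,1)$.

Each element owns a disjoint subset of the move list, and caches it
together with its partial flux $\phi_l$:

* moves that consume unpaired members of its loop (nucleation,
  extensions into the loop, shifts whose target nucleotide lies in the
  loop);
* removals of the pairs bordering its loop from its own side, with a
  lone helix's removal owned by the enclosed element;
* interior openings of its closing helix.

Ownership by the side whose unpaired nucleotides absorb or supply the
change keeps a cached rate valid unless its own loop (or the
immediately bordering helix turns) changes.  Assigning *both* ends of a
helix to the element it closes would instead leave outer-end retraction
rates stale whenever the outer loop changes, which is why this package
departs from that convention.  One genuine coupling remains: removing a
lone pair merges the two adjacent loops, so its rate depends on both.
After each step the engine therefore refreshes the rates of just those
lone-pair moves in partner loops (an O(1) amount of work per affected
helix) without re-enumerating any move list.  Full re-enumeration is
instrumented and never touches more than three pre-existing elements
per step, plus newly created ones.

The per-element fluxes live in a partial-sum tree: a binary tree whose
internal nodes store the sums of their children.  The total flux is the
root, a point update recomputes one leaf-to-root path, and selection
descends from the root — all $O(\log_2 N)$.  Destroyed loops release
their slot (the leaf is zeroed) and capacity doubles with a full
rebuild on overflow.  Because every internal node is recomputed exactly
from its children on each update, the root is always the exact pairwise
sum of the leaves; a periodic full rebuild is retained as a guard.

Free-energy differences of candidate moves are computed locally by
re-evaluating only the faces adjacent to the changed pairs on a scratch
pair table, which reproduces the full recomputation to $10^{-9}$
kcal/mol (asserted over $10^4$ random state–move pairs).

## Validation oracles

Three independent reference implementations back the test suite:

* an exhaustive enumerator (with a second, differently structured
  counting recursion) and the exact Boltzmann distribution over the
  enumerated ensemble;
* a brute-force neighbourhood generator that scans all candidate pair
  additions, removals and shifts globally with a crossing test;
* a naive Gillespie engine that rebuilds the complete neighbourhood,
  all rates and the flux from scratch every step.  Driven by the same
  random-number stream, it must reproduce the incremental engine's
  event sequence, waiting times and total flux exactly, which it does
  bitwise in the lockstep tests (the naive flux is summed in the same
  pairwise order, so agreement is exact rather than within rounding).

Energies are additionally cross-validated against a pre-installed
independent Turner-99 evaluator on tens of thousands of structures
(agreement to the printed 0.01 kcal/mol).

## Study conditions and problem sizes

The equilibrium benchmark follows the published protocol at reduced
scale: $10^4$ denatured-start trajectories of the 20-nt sequence
(UUGCUAAGCA ACCAUUGGUU), sampled at $t_\max = 4000$ time units.  The
horizon comes from a relaxation analysis: ensemble occupancies relax
with a slowest time constant of roughly 650 time units (the
lowest-energy hairpin is entered via rare nucleation events), so
$t_\max \approx 6\tau$ leaves the residual initialisation bias an order
of magnitude below the $4\sigma$ binomial band of $10^4$ trajectories.
Occupancy at $t_\max$ is read from the structure whose holding interval
covers $t_\max$ — sampling the post-jump state instead would bias
against long-lived states, a pitfall worth noting.

The lockstep comparison runs $10^4$ steps at $N \in \{20, 50, 100\}$;
locality and waiting-time checks use $10^5$ instrumented steps.  The
56-nt spliced-leader demonstration uses 60 first-passage trajectories
capped at 3000 time units: about half fold directly to the
lowest-energy stem-loop within tens of time units and the rest are
delayed by orders of magnitude in the competing stem-loop, the
bistable behaviour this RNA is known for.  Its sequence and reference
structures are literature-derived demonstration fixtures (see
`?example_rna`) and no quantitative claims attach to them.

## What the synthetic generators do and do not cover

`random_rna_sequence()` draws i.i.d. letters with a chosen G+C
fraction, and `random_structure()` samples uniformly from the complete
ensemble (short sequences) or by random walks of valid moves (longer
ones).  These exercise the full variety of loop topologies — lone
pairs, nested multiloops, the $(1,N)$ corner case — which is what the
structural and caching invariants need.  They do not emulate biological
base composition, co-transcriptional constraints, pseudoknots or
modified bases; passing tests therefore demonstrate algorithmic
correctness of the sampler and energy bookkeeping, not biological
realism of any particular trajectory.

## Numerical choices and degenerate inputs

* Energies are handled internally as doubles in units of 0.01 kcal/mol,
  so table sums stay exact; log-extrapolated loop terms are truncated
  to integer table units, matching the reference evaluator.
* Selection ties break by the strict rule "first slot with cumulative
  sum greater than the target"; a rounding-guard falls back to the last
  positive-rate move of the selected loop.
* Two RNG draws per step in fixed order (selection first, waiting time
  second) from a 64-bit Mersenne Twister; trajectories are
  bit-reproducible given a seed, and ensembles derive per-trajectory
  seeds from one master seed.
* Sequences with no pairable nucleotides (e.g. poly-A) terminate with
  reason `"no_moves"`; the open chain of any sequence is a valid state
  with a single external loop.
* Exhaustive enumeration refuses sequences beyond 30 nt.

## Known limitations

Pseudoknots, coaxial stacking, Turner-2004 parameters, temperature
dependence of the tables themselves, and co-transcriptional folding are
out of scope.  Absolute time calibration is approximate (unit
prefactors); only ratios of rates are thermodynamically constrained.
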