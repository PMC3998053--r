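---
title: "Molecular morphing: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular morphing: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Given two molecules that act on the same receptor, the compounds that lie
*between* them in chemical space are natural candidates for the same
mechanistic class. molmorph searches for such a connecting path. Starting
from the start molecule $M_S$, each iteration applies small random
structural edits ("morphing operators") to the current generation of
molecules, scores every valid product by its fingerprint distance to the
target $M_T$, and probabilistically admits the closest products into the
next generation. The search ends when some product's canonical SMILES
equals that of $M_T$; the chain of parent links from $M_T$ back to $M_S$ is
the morphing path, and the explored tree around it is a focused virtual
library.

Molecule identity is canonical SMILES equality throughout (deduplication,
tabu list, target detection). Identity by canonical form is deterministic
and immune to fingerprint collisions. The scope is single-fragment,
neutral organic molecules over C, N, O, S, P and the halogens; hydrogens
are implicit, stereochemistry and tautomer normalization are out of scope.

## Morphing operators

All operators act on the kekulized heavy-atom graph, with implicit
hydrogens filling each element's default valence. The operator inventory
is addressable by two-letter codes:

| code | edit | notes |
|------|------|-------|
| AA | add atom | new single-bonded atom from the element palette |
| RA | remove atom | degree-1 atoms only; connectivity can never break |
| AB | add bond | new single bond, or +1 bond order up to triple |
| RB | remove bond | −1 bond order, or delete an order-1 ring bond |
| MA | mutate atom | element swap where the new valence carries the bonds |
| BR | bond reroute | move one end of a bond to another atom |
| BC | bond contraction | delete a degree-2 atom, single-bond its neighbours |
| IA | interlay atom | insert a palette atom into a bond (off by default) |

The operator inventory is the conventional one for atom-and-bond-level
morphing; the precise site semantics above are this package's own, chosen
so that every enumerated site yields a valence-correct, connected product,
and so that the pairs AA/RA, AB/RB and BC/IA are mutual inverses on their
applicable cases (the package's test suite asserts these round trips).
Restricting RA to terminal atoms keeps connectivity proofs trivial —
interior deletions are exactly what BC provides. BR keeps the moved bond's
order, requires the receiving atom to have that much free valence, and
rejects sites that would disconnect the graph. IA is implemented but not
in the default operator set, since only the other seven are documented by
name; it can be enabled in the configuration.

The element palette for AA/MA/IA defaults to the elements present in the
target molecule plus carbon. This steers mutation chemistry toward the
target without a hand-tuned element pool and makes any target reachable in
principle.

Hypervalent-but-common groups (sulfones, phosphates, kekulized nitro
groups) parse and are preserved, but their atoms expose no free valence to
the operators: validation caps S at 6 and P at 5 while the editing
arithmetic uses the default valences (C 4, N 3, O 2, S 2, P 3, halogens 1).

## Distance model

Distance is `1 − similarity` between fingerprints: Morgan-type circular
fingerprints (radius-2 environments, folded to 2048 bits) with the
Tanimoto coefficient by default. A linear-path fingerprint (paths up to 7
atoms, 1024 bits) and a structural-key set (166 keys) are registered
alternatives, as are the Dice and Cosine coefficients; the registry is
extensible. With user-supplied decoy molecules the score becomes
`(d_target + min_k d_decoy_k) / 2` — only the nearest decoy counts — which
biases the search through remoter chemistry; because the decoy term is
halved, a decoy can never shift a distance by more than 0.5.

## Selection, idling and pruning

Each iteration draws `n_gen_per_parent` random edits per candidate
(default 80), pools the valid products, removes molecules already in the
tree or on the tabu list, applies the filters, and sorts the rest by
distance to the target with lexicographic canonical-form tie-breaks so the
ordering is fully deterministic. The best `accept_best` (K, default 50)
are accepted outright; the product at sorted rank $r > K$ is accepted with
probability $e^{-\lambda (r-K)/K}$ (default $\lambda = 1$), capped at
`accept_cap` (default 150) acceptances. A rank-based decay was chosen
because it is scale-free in the distance values and collapses to exact
top-K selection as $\lambda \to \infty$, which makes it testable in closed
form.

A candidate that produced no accepted child stays in the candidate set and
its idle counter increments; when an accepted child improves on a parent's
distance, the idle counters along that lineage reset in full — a dampened
reset would keep stale lineages alive longer for no clear benefit. A
non-root node whose idle count reaches
`idle_threshold` (default 5) is discarded with its entire subtree unless
it is the current best molecule or one of that molecule's ancestors.
Discarded canonical forms enter a tabu set and are never re-admitted,
which prevents discard/re-discover cycles. The run ends on target
discovery, on a generation that produces no morph at all (search
exhausted), or at `max_iterations` (default 1000), in which case the path
to the closest molecule found is reported as a partial solution.

## Filters

Products heavier than `mw_limit` (default 500 Da) are rejected first —
weight needs no fingerprint, and since both filters are pure predicates
the order cannot change the survivor set. The synthetic-accessibility
filter (on by default) rejects products scoring above `sa_threshold`
(default 6 on the 1–10 scale; 6 splits the scale at the conventional
hard-to-make boundary).

The SA score follows the classical fragment-contribution-plus-complexity
formulation: common substructure environments lower the score, while
molecular size, spiro atoms, bridgeheads and macrocycles raise it via
`n^1.005 − n` and `log10(count + 1)` penalty terms, a symmetry bonus of
`0.5·log(n_atoms / n_environments)` rewards regular structures, and the raw
value is mapped onto 1–10 with a logarithmic squash above 8. Widely used
fragment-frequency tables ship only in binary form and cannot be
redistributed here, so the fragment model is rebuilt at first use from a
packaged reference library
of 331 common organic and drug molecules
(`inst/extdata/synthetic_reference_library.smi`, an authored, clearly
synthetic stand-in): a fragment's contribution is the log10 document
frequency of its folded circular-fingerprint bit, centred on the 80th
percentile and clipped to [−4, 4], with unseen bits contributing −4. The
raw-score scaling constants (−4 and 1.5) were fixed once so that the
library itself spans roughly 2.8–5.7. Relative to count-level fragment
models this is a bit-level (presence/absence) variant; it preserves the
orderings that matter here (alkanes below fused polycycles, drug-like
morphs mostly below 6) but its absolute values should not be compared
across SA implementations.

## Layouts

Two 2D views of the explored space are provided. `pca_layout()` projects
the 0/1 fingerprint matrix onto its top two principal directions (axis
signs fixed by making each axis's largest loading positive, so the result
is deterministic). `kk_layout()` minimizes the classical stress
$E = \sum_{i<j} d_{ij}^{-2} (\lVert x_i - x_j\rVert - d_{ij})^2$ by
node-wise gradient relaxation with step halving from a seeded random
start, so the energy is non-increasing by construction; `d_ij` is the
fingerprint distance between molecules, not a graph-theoretic path length.
Duplicate molecules (off-diagonal zero distances) are coalesced before
layout and re-expanded to coincident points.

## The synthetic pair generator

Reference benchmark sets of start/target pairs are external data, so the
package generates its own study material. `make_synthetic_pair()`
applies `k` random valid edits to a seed molecule and returns the pair
with its replayable operator trace — ground truth for convergence tests.

Every accepted generator step must pass the same admission filters the
search applies (weight ≤ 500 Da, SA ≤ 6) and keep at least three heavy
atoms. This is a reachability requirement, not a tuning knob: benchmark
pairs stand in for real, synthesizable compounds, and a target that the
search's own filter refuses to accept — or a "molecule" reduced to a lone
water oxygen by three deletions — is unfindable or meaningless by
construction.
`make_band_pair()` emulates the stratified benchmark datasets (70–80%,
50–60% and 30–40% start/target similarity): it random-walks from the seed
until the Morgan/Tanimoto similarity to the start first falls inside the
requested band. Two constraints keep the walk on a structural continuum:
an edit may lower the similarity by at most `max_step` (default 0.25,
chosen from the observed per-edit similarity distribution on drug-sized
molecules, whose gentlest edits change similarity by about 0.1–0.25), and
edits that would overshoot below the band are rejected. Without the step
cap, a single ring-topology edit can jump straight into the 30–40% band,
which would make "distant" pairs trivially easy and is nothing like two
independently chosen real compounds. With it, the bands correspond to
roughly 1–2, 2–4 and 4–10 edits on drug-sized seeds.

What passing these tests shows — and does not show. Synthetic pairs are
reachable by construction and their similarity structure mirrors the
generator's own operator set, so convergence on them demonstrates that the
guidance, selection and pruning machinery works, and the band trend
demonstrates that iteration counts grow with fingerprint distance. Real
benchmark pairs are independent PubChem compounds; nothing here certifies
absolute iteration counts on such data, only the qualitative behaviour.

## Problem sizes and numerical choices

Search-heavy tests and the acceptance script use a scaled configuration —
30 morphs per parent, K = 15, acceptance cap 30, idle threshold 3 — with
all other parameters at their defaults; these sizes keep a full run in
the tens of seconds while leaving the per-iteration statistics
(acceptance ratios, pruning behaviour) in the same regime as the
defaults. The trend benchmark uses 10 pairs per band
(one run each, 1000-iteration cap) in the test suite and 5 per band in the
acceptance script. Five drug-sized seed structures (a tricyclic amine, an
aryloxypropanolamine, a benzylpiperidine ketone, a bis-amidine ether and a
phenothiazine-type molecule, MW ≈ 260–410) provide the band pairs; small
alcohols, amines and pyridine seed the k-edit convergence pairs.

Other numerical conventions: similarity of two all-zero fingerprints is
defined as 1 (identical objects); Tanimoto 0/0 likewise; ties in candidate
sorting break lexicographically; the best-node tie breaks toward the
older node; all randomness flows through R's RNG from a single
configuration seed, and OpenBabel (the external chemistry backend for
SMILES canonicalization and fingerprints) is deterministic, so fixed seed
plus fixed configuration gives bit-identical runs.

## Known limitations

* No stereochemistry, charges, isotopes or multi-fragment species.
* Operators act one heavy atom or bond at a time; scaffold-level moves
  (add/remove whole rings) are out of scope, so paths between molecules
  with very different ring systems can be long.
* The SA model is a synthetic re-calibration on a packaged library;
  scores are internally consistent but not comparable across software.
* Aromaticity is delegated to the backend's perception on re-parse; exotic
  aromatic systems outside its model may kekulize differently than drawn.
* The explorer is single-threaded; per-iteration chemistry is batched
  through one external converter process, which is where most of the
  runtime goes.
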