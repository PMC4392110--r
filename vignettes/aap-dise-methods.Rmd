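---
title: "Atom-Atom-Path similarity and Directed Sphere Exclusion clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-Atom-Path similarity and Directed Sphere Exclusion clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

A fragment-based screen of a few thousand low-molecular-weight compounds
typically returns more hits than structural biology and chemistry can
absorb. Triage needs two things at once: a structural grouping that a
medicinal chemist recognises as sensible, and an ordering that puts the
highest-quality chemical matter (usually measured by ligand efficiency)
in front of the review team first. `aapdise` implements a similarity
metric designed for fragment-sized molecules — the Atom-Atom-Path (AAP)
similarity — and couples it with Directed Sphere Exclusion (DISE)
clustering, which is deliberately order-dependent so that a
non-structural quality property controls which compounds become cluster
seeds.

## The AAP similarity model

### Atom path profiles

Every heavy atom is described by the multiset of linear paths that start
at it. A path is an alternating sequence of bond-type codes $b_k$
(1 single, 2 double, 3 triple, 4 aromatic) and atom-type codes $a_k$
(atomic number, plus 108 when the atom is aromatic), followed up to a
maximum of `max_bonds` bonds (default 7). Paths are *simple*: no atom,
including the origin, may appear twice, so a six-ring contributes paths
of length at most 5 around the ring. Every prefix of a longer path is
recorded as a path in its own right, and when the depth-first search
reaches the same encoded path through different atoms, each traversal
counts — the profile is a multiset, not a set.

Each path is folded into a single integer

$$p = (((b_1 \cdot n_{AT} + a_1) \cdot n_{BT} + b_2) \cdot n_{AT} + a_2)
\cdots$$

with $n_{AT} = 217$ (two blocks of 108 atom types plus one) and
$n_{BT} = 5$. The accumulator is truncated to `bits` bits (default 16)
at every step; overflow is ignored by design, so distinct long paths can
collide at narrow widths. Collisions can only *raise* an atom-pair
similarity, and only when a collision happens across the two molecules
of a pair; the package's stability tests compare 16-bit against 64-bit
profiles across randomly generated fragment pairs and require the
median absolute difference in molecular similarity to stay below 0.02.
R has no native 64-bit integer type, so 64-bit codes are carried as two
exact 32-bit halves and rendered as `"hi:lo"` strings; 8/16/32-bit codes
are exact doubles.

### Atom-to-atom similarity

For atoms $A_i$ and $B_j$ with total path counts $np_{A_i}$, $np_{B_j}$
and $nc_{A_i,B_j}$ shared paths (multiset intersection: the sum over
distinct codes of the smaller multiplicity),

$$\mathrm{Sim}_{A_i,B_j} = \delta_{A_i,B_j}\,
\frac{nc_{A_i,B_j} + \delta_{A_i,B_j}}
     {\max(np_{A_i}, np_{B_j}) \cdot 2 - nc_{A_i,B_j} + \delta_{A_i,B_j}}$$

where $\delta$ is 1 when the two atoms have the same atom-type code and
0 otherwise. The $\delta$ equality test uses the full code — element
plus aromaticity — consistent with the path encoding. Two bond-less
atoms of the same type score 1 (the degenerate case $0+1$ over $0+1$),
and identical environments score exactly 1.

### Atom mapping

The atoms of the smaller molecule are mapped injectively onto atoms of
the larger one to maximise the summed atom-pair similarity. Two
algorithms are provided:

* **Hungarian** (`method = "hungarian"`): the exact assignment-problem
  solution, implemented as the classical $O(n^3)$ potentials +
  augmenting-path algorithm. The rectangular matrix is padded to square
  with zeros. Exactness is tested against exhaustive enumeration of all
  injective assignments on small molecules.
* **Greedy** (`method = "greedy"`, the default): repeatedly map the two
  atoms with the highest remaining similarity and delete that row and
  column. Ties are broken by the order of the atoms in the input
  molecules — smallest row (molecule A) index first, then smallest
  column index. Because of tie-breaking, greedy similarity is not
  guaranteed symmetric in its arguments; the Hungarian value is, and it
  is also invariant under atom reordering. The greedy sum can never
  exceed the Hungarian sum, and since $x \mapsto x/(C-x)$ is increasing,
  the same holds for the molecular similarity.

The greedy heuristic is the default because its results deviate from
the optimum only rarely and slightly (the test suite measures the
empirical deviation distribution over hundreds of generated fragment
pairs and bounds both the deviation frequency and magnitude), while
being markedly cheaper on larger inputs.

### Molecular similarity

With mapped pairs $(i, j)$,

$$\mathrm{Sim}_{A,B} = \frac{\sum \mathrm{Sim}_{A_i,B_j}}
{\max(na_A, na_B)\cdot 2 - \sum \mathrm{Sim}_{A_i,B_j}}$$

which lies in $[0,1]$, equals 1 exactly for identical heavy-atom graphs,
and drops below 1 for any structural difference. AAP values run much
lower than fingerprint Tanimoto values; molecules at similarity 0.3
still share substantial structure, which motivates the default
clustering threshold.

## Molecule preparation

* **Hydrogens** are always removed before any similarity computation
  (deuterium and tritium count as hydrogen); atom input order is never
  permuted, only compacted, because the greedy tie-breaks and seed
  ordering depend on it.
* **Aromaticity** is perceived with one uniform model — ChemmineR's ring
  perception with its aromaticity test — and perceived-aromatic ring
  bonds are recoded to bond type 4. Bonds already coded 4 in the input
  are honoured as aromatic, which makes preparation idempotent and
  accepts files written with aromatic bond codes. Absolute similarity
  values for aromaticity-borderline rings (e.g. 2-pyridone) depend on
  this model choice; all comparisons within a run are internally
  consistent because a single model is applied to every record.
* **Multi-fragment records** (salts) are kept intact by default — paths
  never cross fragments, so the similarity is well defined on
  disconnected graphs — with an option to keep only the largest
  fragment.
* Atomic numbers above 108 would collide with the aromatic offset and
  are rejected, as are bond codes outside 1–4.

## DISE clustering

1. **Sort** records by the quality field (default `LE`, descending),
   stably: ties keep input order.
2. **Seed selection** by sphere exclusion: walking down the sorted list,
   a record becomes a new seed exactly when its similarity to *every*
   existing seed is strictly below the threshold (default 0.3).
   Boundary equality counts as inside the sphere — a record exactly at
   the threshold is excluded from seedhood and, under rule `first`,
   qualifies for membership. The two passes are thereby exact
   complements; the original publication leaves the boundary case
   unstated, so this convention is the package's own, documented and
   tested.
3. **Member assignment**: rule `first` assigns to the lowest-indexed
   seed at or above the threshold; rule `closest` (the default, and the
   rule used in the published application) assigns to the most similar
   seed, ties to the lower cluster index.

Seeds therefore have pairwise similarities below the threshold, seed
quality values are non-increasing with cluster index, and under rule
`first` every member is within its seed's sphere. Similarities are
computed on demand with a pair cache rather than as a full $N^2$
matrix. Output is ordered by cluster index, then by descending sort
value, and annotated with `clusterIdx`, `isSeed`, `seedId` and
`simToSeed` (4 decimals) tags; the pipeline is byte-deterministic.

**Ligand efficiency** is computed as $1.4 \cdot pK_d / n_{heavy}$ with
$pK_d = -\log_{10} K_d$ (molar).

**Triage pre-score**: each chosen property is binned high/medium/low for
2/1/0 points (higher values treated as better), and totals are re-binned
into priorities 1–3. The published scheme bins "based on histograms"
without stating edges; this implementation makes that concrete as
tertiles unless explicit edges are supplied — a deviation by necessity,
flagged here. With fewer than three distinct totals, every record gets
priority 1 with a warning rather than an arbitrary split.

## The synthetic fragment generator

`generate_fragment_set()` emulates the *shape* of a fragment-screening
hit set, since real kinase hit sets of this kind are not publicly
deposited:

* molecules of 5–25 heavy atoms built from a grammar of ten scaffolds
  (benzene, pyridine, pyrimidine, pyrrole, furan, thiophene, pyrazole,
  indazole, cyclohexane, piperidine) with 0–3 substituents (halogens,
  methyl/ethyl, hydroxyl, amino, methoxy, cyano, acetyl) at random ring
  positions;
* scaffolds are cycled round-robin so every run contains analog series
  sharing a scaffold, which is what makes clusters form at threshold
  0.3;
* a raw quality score — scaffold base level plus additive substituent
  effects plus Gaussian noise (sd 0.05) — is rescaled linearly across
  the batch to ligand efficiencies spanning 0.20–0.70, the range typical
  of fragment hits; $K_d$ is back-computed from LE and heavy-atom count
  (giving micromolar-to-millimolar values), so structurally similar
  molecules carry correlated affinities, the behaviour the
  cluster-plot's "similarity principle" colouring relies on.

The generator runs on its own seeded RNG stream (the global stream is
restored) and is byte-deterministic for fixed arguments. What it does
*not* emulate: real pharmacophores or binding-driven SAR, assay noise
structure, activity cliffs beyond what random noise produces, 3D
geometry, tautomers or charge states. Tests passing on generated sets
therefore demonstrate the algorithmic invariants (ranges, identity,
optimality bounds, clustering coverage and determinism), not
biological validity on any particular screen.

## Numerical choices and degenerate inputs

* Pair similarities are rationals computed in double precision;
  self-similarity is exactly 1.0 in floating point (the sum of $na$
  ones divided by $2na - na$). Outputs round to 4 decimals; internal
  values keep full precision.
* Modulo reduction happens at every accumulation step, equivalent to
  one final reduction for `+`/`×` but avoiding big-integer arithmetic.
* Empty path: an error; an isolated atom has an empty profile
  ($np = 0$), not an error.
* Zero heavy atoms after hydrogen stripping: an error naming the
  record.
* Greedy tie-breaks are deterministic (row-major scan), so all outputs
  are reproducible byte for byte.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in seconds
while still exercising every property: reference molecules of 1–12
heavy atoms for exact oracles, generated sets of 30–60 molecules for
clustering and distribution properties, 220 random pairs for the
greedy-vs-Hungarian comparison and 120 pairs for the 16-vs-64-bit
comparison.

## Known limitations

* Aromaticity perception differs from commercial toolkits on borderline
  rings; absolute similarity values are model-dependent even though
  rankings within a run are consistent.
* Greedy similarity is asymmetric on ties; use `method = "hungarian"`
  when exact symmetry matters (e.g. exporting a similarity matrix for
  downstream methods that assume it).
* V3000 SD files, stereochemistry, and 3D information are out of scope;
  coordinates are read through and written as zeros.
* The published per-cluster member similarities of the original
  application cannot be reproduced here because those structures were
  never deposited; the package's acceptance checks instead cover the
  printed worked example and the method's stated invariants.
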