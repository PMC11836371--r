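---
title: "Enumerating and growing fragment chemical space with growspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating and growing fragment chemical space with growspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fragment-based inhibitor design starts from a small scaffold (here, around
a dozen heavy atoms) and asks two quantitative questions. First, how large
is the chemical space the screen is sampling — all chemically stable
molecules up to a given heavy-atom count? Second, what part of that space
consists of *superstructures* of one particular scaffold, i.e. the
molecules reachable by fragment growing, and how does restricting the
growing vectors (for example, to directions compatible with a binding
site) shrink it? growspace implements the machinery for both: staged
exhaustive enumeration of small-molecule space, tag-based activation of
substituents and scaffolds, combinatorial superstructure generation,
exponential growth-curve extrapolation, and the screening-support
computations used to navigate the resulting libraries.

## Staged enumeration

`enumerate_space()` builds all chemically stable molecules up to `n_max`
heavy atoms in stages:

1. **Skeleton graphs.** All connected simple graphs with at most `n_max`
   nodes and maximum degree 4 (tetravalent carbon), one representative per
   isomorphism class, restricted to planar graphs. Generation is by vertex
   augmentation with BLISS canonical-form deduplication; every connected
   graph arises from a connected graph one vertex smaller because a
   non-cut vertex always exists. Planarity is decided by a
   Kuratowski-subdivision search, exact for graphs of this size, and is a
   toggleable filter (`planar = FALSE` disables it).
2. **Saturation.** Each node becomes a carbon and valences are completed
   with hydrogens, giving CnH(2n+2-2r) for cyclomatic number r.
3. **Strain filter.** Each hydrocarbon with a quaternary center is
   embedded once in 3D and, for every carbon with four heavy neighbors,
   the volume of the tetrahedron spanned by the neighbor positions is
   computed. The molecule is discarded if any volume falls below
   `strain_volume_threshold` (default 0.145 cubic angstroms). An ideal
   center with 1.54-angstrom bonds has a volume of about 1.87; fused
   small-ring cages collapse toward zero. Molecules without such centers
   pass vacuously.
4. **Unsaturation.** Every assignment of double/triple orders to C-C
   bonds for which both atoms can surrender the required hydrogens, taken
   combinatorially.
5. **Heteroatom mutation.** Every combinatorial replacement of carbons by
   N and/or O permitted by valence (`mutation_elements`).
6. **Forbidden motifs.** Molecules containing an acyclic N-N bond
   (hydrazines, azo), an acyclic O-O bond (peroxides), or a cumulated
   double-bond center (allenes, ketenes) are removed. The list is a
   configurable SMARTS vector; when it equals the default, an equivalent
   native graph test is used instead of per-molecule SMARTS matching
   (verified equal in the test suite).
7. **Decoration.** Single-site functional-group transformations:
   carboxylic acids to sulfonic acids, phenolic hydroxyls to halogens
   (F/Cl/Br/I). The shipped table (`decorations_default()`, mirrored in
   `inst/extdata/decoration_table.txt`) contains these transformations
   only; the set is deliberately small and editable, and introduces S and
   the halogens into the space.

Duplicates are removed globally by canonical SMILES with aromaticity
perception, so Kekule variants of one aromatic system count once.
Stereoisomers and tautomers are not enumerated.

```{r}
library(growspace)
space <- enumerate_space(enumeration_config(5))
space$count_table
```

### Symmetry handling

Unsaturation patterns and element assignments over a fixed skeleton are
duplicated exactly when related by an automorphism of that skeleton.
Assignments are therefore filtered to lexicographic orbit minima under the
skeleton's automorphism group (computed via BLISS on a bond-subdivided,
color-coded graph) before any strings are written; the final canonical
pass only has to merge aromatic Kekule forms. The test suite checks the
orbit route against brute-force enumeration plus explicit VF2
isomorphism deduplication.

### The deterministic embedder

No seedable external 3D generator is available to this package, and the
strain filter must be reproducible, so coordinates come from a small
deterministic distance-geometry embedder (`embed_coords()`): classical
MDS of the graph-distance matrix scaled by ideal bond lengths,
followed by BFGS refinement of harmonic 1-2 and 1-3 distance terms (the
1-3 targets encode tetrahedral angles) with a soft 2.6-angstrom lower
bound on topologically distant pairs. The symmetry-breaking jitter is
drawn from `embed_seed`, so a configuration reruns to identical output.
These geometries are not force-field-quality conformers; they are used
only to detect collapsed quaternary centers, for which the test suite
checks the ideal-center closed form (1.87 cubic angstroms) and the
collapse of spiro-fused three-ring systems. Strain decisions near the
threshold can differ from those an external 3D generator would make; this
geometry dialect is an accepted property of the implementation.

### What the enumeration does and does not claim

The stability ruleset here is the documented one: valence rules, the
strain filter, three forbidden-motif classes, and the two decoration
families. Published exhaustive databases built with richer rulesets
(more functional-group exclusions, ring-strain rules beyond quaternary
centers, tautomer canonicalization) are smaller at the same heavy-atom
count; counts from this package should be compared against its own rules,
which is what the tests do (brute-force oracles at small sizes,
log-linearity of cumulative counts over the fitted range at desk scale).

## Activation: growing vectors as tagged structures

A *connection site* is an atom or bond where a substituent can be
attached; each of the five mechanisms consumes hydrogens and is marked by
a dedicated tag element never produced by enumeration:

| mechanism | tag | hydrogen rule |
|---|---|---|
| single bond | Lu | at least 1 H |
| double bond | Hf | at least 2 H, and no existing multiple bond (else a cumulated system would form) |
| triple bond | Ta | at least 3 H on a terminal atom |
| ring fusion | W | a ring bond with 1 H on each atom; the single W tag bridges both atoms |
| spiro | Re | a ring atom with 2 H; Re is double-bonded |

Substituents (`activate_library()`) carry exactly one activation site and
are shelved by (heavy atoms, mechanism, chemotype). The chemotype
vocabulary is a fixed classification of the site environment (hydroxyl
oxygen, amine nitrogen, thiol sulfur, aromatic CH, aliphatic CH, ring
CH2, ring CH-CH bond); the compatibility relation forbids amine-on-amine
and hydroxyl-on-hydroxyl attachments, which would recreate the hydrazine
and peroxide motifs the enumeration excludes. Site symmetry is decided
operationally: two sites are equivalent iff tagging them gives the same
canonical structure.

Scaffolds (`activate_scaffold()`) may carry several tags, including
several on one atom while its hydrogen budget lasts; all non-empty
hydrogen-feasible assignments are enumerated and deduplicated by
isomorphism of the tagged structure. For benzene under single bonds this
gives the 12 binary necklaces of length 6. Because the counting
conventions (which mechanisms, multiple tags per atom, whether amide N-H
or aldehyde C-H count as vectors) are genuinely open,
`activation_census()` recomputes the total under each variation so that a
deviation from an external reference count can be attributed rather than
hidden.

## Growth

`distribute_atoms(n, k)` enumerates the compositions of `n` added heavy
atoms over `k` tagged sites, each site receiving at least one atom (the
zero case belongs to a different configuration); there are
`choose(n-1, k-1)` of them. `grow()` then attaches one compatible shelf
substituent of the prescribed size per site. A fused substituent shares
two atoms with the scaffold and a spiro substituent one, so shelves are
queried at `part + 2` and `part + 1` heavy atoms respectively, keeping
"added atoms" uniform across mechanisms: every product has scaffold plus
composition-sum heavy atoms and contains the scaffold as a substructure
(asserted exhaustively at toy scale). Compositions are generated ordered,
without symmetry reduction; duplicates arising from scaffold symmetry are
removed at the canonical dedupe. Masked (binding-site-constrained)
generation is a subset of unconstrained generation by construction.

## Space-size extrapolation

Because the number of stable molecules grows exponentially with size,
`fit_growth_model()` fits `log10(cumulative) = a + b * n_heavy` by least
squares over a trusted range ("logarithmic curves" in the sense of a
log-linear model; the fit range is user-chosen since small n are
dominated by valence edge effects). `extrapolate()` evaluates the line
and reports the nearest power of ten, matching how such sizes are usually
quoted; `coverage_percent()` is the exact ratio arithmetic. At desk scale
the package fits over 3 to 7 heavy atoms; the acceptance test requires
R-squared above 0.99 there.

## Screening support

- `scaffold_pattern()` turns a scaffold into a SMARTS superstructure
  query; in constrained mode every closed atom receives explicit
  hydrogen-count and degree terms so growth is only allowed at open
  positions, and constrained hits are a subset of unconstrained hits.
- `structural_filters()` applies the shipped alert lists: an N-acylated
  six-membered arylamine exclusion and a representative subset of
  well-known pan-assay interference motifs written for this package (not
  the full published catalog — absolute pass rates depend on the list,
  whose version is recorded in run manifests).
- `morgan_fingerprint()` is an iterative-neighborhood hashed circular
  fingerprint, radius 2, folded to 1024 bits. It is deterministic for a
  given canonical SMILES but not bit-compatible with other toolkits'
  circular fingerprints; Tanimoto values and cluster counts are
  comparable only within this package.
- `leader_cluster()` is the greedy score-ranked leader algorithm: best
  score founds a cluster, strictly-greater-than-threshold neighbors join,
  repeat. Score ties are broken lexicographically by SMILES for
  determinism. The result is a partition; raising the threshold never
  decreases the cluster count.
- `core_rmsd_filter()` selects, among the `top_k = 50` lowest-energy
  poses, the lowest-energy one whose common-core heavy-atom RMSD to a
  reference pose is below 2 angstroms. RMSD is computed in the shared
  receptor frame without refitting, minimized over all core-into-pose
  subgraph isomorphisms so symmetric cores cannot inflate the value; bond
  orders are ignored during matching so Kekule or protonation dialects in
  pose files do not break the mapping.
- `react_enumerate()` couples building blocks to a parent scaffold with
  the shipped reactions (amide coupling, Suzuki, Chan-Lam amination,
  Ullmann ether), applied as graph rewrites keyed by the SMIRKS strings
  in `inst/extdata/reaction_smirks.txt`; unknown SMIRKS raise a
  configuration error, and blocks with no compatible functional group are
  reported as skipped.

## Fixtures and the pipeline driver

`generate_fixtures()` writes small deterministic inputs so that every
module is testable without downloads: a 20-molecule library with eight
planted benzene-ring matches, a 5-pose SDF in which one pose sits at
exactly 3.0 angstroms translation (and the best-energy pose fails the
RMSD cut, exercising the selection rule), a building-block set covering
all shipped reactions plus an inert block, and a synthetic exponential
count table with known intercept and slope. These fixtures emulate the
*shape* of real screening data (scores, poses, match structure), not its
chemistry: passing tests show the algorithms implement their rules, not
that the rules reproduce any particular external database.
`run_pipeline()` chains enumerate - activate - shelve - activate-scaffold
- grow - fit with a manifest whose tallies reconcile, and
`inst/scripts/growspace.R` exposes the same steps as shell subcommands.

## Problem sizes and numerical choices

The package's own test and acceptance runs use: full enumeration to 7
heavy atoms (growth-curve fit over 3 to 7), brute-force oracle
comparisons at 5 to 6 nodes (graphs) and 2 to 3 heavy atoms (activation),
and toy shelves for growth. The scaffold worked example — all five
mechanisms on the 12-heavy-atom
N-(tetrahydrobenzisoxazol-3-yl)formamide core — enumerates a few thousand
configurations in seconds. Ties and orderings are fixed everywhere
(sorted canonical keys, lexicographic tie-breaks, seeded jitter), so
identical configurations rerun to byte-identical outputs.

One external reference point deserves a direct note: the published count
of unique growing-vector configurations for this fragment core is 7154,
whereas these conventions yield 3939 (closed form: a carbocycle factor of
985 from the four CH2 states coupled through three fusable ring bonds,
times 2 for the formyl C-H, times 2 for the amide N-H, minus the empty
assignment). None of the documented convention variations reproduced
7154 — `activation_census()` prints the variations and their totals — and
the upstream convention details are not public, so the discrepancy is
reported openly rather than tuned away. The note that the core is
sometimes described as having 13 heavy atoms, while the named structure
has 12, is part of the same ambiguity.

## Known limitations

- The stability ruleset is smaller than those of published exhaustive
  databases; absolute molecule counts are correspondingly larger.
- Charged species, stereochemistry, and tautomer normalization are out of
  scope; sulfur enters via decoration only, never via mutation.
- Triple bonds are accepted wherever valence permits, including rings too
  small to accommodate them physically; the strain filter acts on
  saturated skeletons only.
- The embedder's geometries are for strain detection, not conformational
  analysis.
- The PAINS list is a representative subset; the fingerprint is a
  package-local dialect.
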