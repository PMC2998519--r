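---
title: "The pathrepo data model and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pathrepo data model and its design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathrepo)
```

## The four-layer model

`pathrepo` organises network biology data in four interconnected layers.
An *entity* is any molecular species; its type comes from a controlled but
extensible vocabulary whose minimum is gene, RNA, polypeptide, protein
complex and metabolite. Genes are organism-specific; common metabolites
such as ATP or glucose are universal (no organism). A *localized entity*
binds an entity to a node of the subcellular compartment tree; this is a
separate layer because the same molecule in two compartments is two
distinct biochemical actors (the worked example in this package: ATP with
four localized entities in mitochondrion, nucleus, plastid and cytosol).
An *interaction* is a typed relation over role-tagged localized
participants. A *pathway* is an unordered, duplicate-free set of
interaction references with an organism and an optional position in a
pathway-ontology tree.

Participant roles are fixed to `input`, `output` and `modifier`, with
modifiers subtyped by effect (`catalysis`, `activation`, `inhibition`).
This is the minimal role set that supports endpoint detection, regulatory
filtering and a faithful SBML reactant/product/modifier mapping; richer
regulatory vocabularies (allosteric effectors, indirect regulation and the
like) are represented as additional interaction-type labels rather than
new roles, since nothing in the model needs to distinguish them
structurally. Reversibility is not modelled: a repository document states
each interaction in one direction.

Two structural invariants are enforced at validation time beyond simple
reference resolution: transport interactions must move a single entity
between distinct compartments, and the compartment and ontology
hierarchies must be forests.

## The repository and the lazy-retrieval contract

A repository is one JSON document (schema in
`inst/extdata/repository-schema.json`). This replaces a client/server
database with a desk-scale, diffable store while keeping the *access
semantics* of a remote back end: loading parses vocabularies and object
headers eagerly, but collection-valued detail — an interaction's
participant list, a pathway's interaction list — is materialized only on
first access and then memoized. Each first materialization increments a
counter visible through `access_stats()`. The contract is exact and
tested: enumerating every pathway header performs zero materializations;
accessing k distinct collections performs exactly k; repeated access
performs none. Validation runs on the raw parsed document and is therefore
invisible to the counters. Memoized state is only ever extended, never
invalidated, because the single mutating operation (`save_pathway()`) is
append-only.

Search is case-insensitive substring matching with `*` as a wildcard; the
choice is a package convention, as is the deterministic (name, id) result
ordering. Synonym matching is available but off by default, so the default
behaviour never over-reports. A location filter matches entities localized
at the given compartment *or any descendant*, which makes the compartment
tree useful as a query axis; the pathway-ontology filter behaves the same
way for pathways. An organism filter on entity search admits universal
entities (they belong to every organism); on pathway search it is strict,
since every pathway has exactly one organism.

`save_pathway()` publishes a user-defined network as a new pathway by
appending one record to the document on disk. Name collisions within an
organism are rejected, and publishing an empty network is an error unless
explicitly allowed (`allow_empty = TRUE`), so accidental no-op pathways
cannot arise silently. Pre-existing records are never rewritten; a
load–save-nothing cycle reproduces the file byte for byte.

## Network analytics

**Endpoints.** Sources are entities appearing in at least one input role
and no output role across the collection; sinks are the converse. The
tally is at the entity level (compartments collapsed), so a metabolite
produced in one organelle and consumed in another is interior, not an
endpoint. Entities participating only as modifiers are excluded from both
sets: start- and end-points concern mass flow, and catalysts or regulators
carry none. A closed loop therefore has no endpoints at all, which is the
expected answer for cycles such as the TCA cycle.

**p-neighbourhood.** "Distance p" counts interaction steps on the
bipartite entity–interaction graph: level 1 is every interaction the seed
entity touches, level k is every interaction sharing at least one entity
with level k−1, and the result is the union of levels 1..p. Counting
interaction steps (rather than bipartite hops) is stated explicitly
because the term is otherwise ambiguous; the tests pin the definition to
an independent breadth-first-search oracle over the bipartite graph
(`igraph::ego` at order 2p−1).

**Shared-gene matrix.** Cell (i, j) is the number of *gene* entities
common to pathways i and j; the diagonal holds each pathway's own gene
count. The raw count is kept as the stored quantity — it is a similarity,
with larger meaning closer — because it is the only well-defined primitive
here; any monotone transform belongs to rendering. Gene sharing is
computed on direct gene participants, compartment-collapsed; overlap via
gene→RNA→protein chains is deliberately not inferred. The dot exporter
maps counts to line thickness (`penwidth = 1 + count`, capped at 10) and
draws edges only for pairs at or above a `min_shared` threshold
(default 1); both the formula and the default are package conventions.

Networks are scoped to the repository they were built from; mixing
interactions from two repositories is rejected because id spaces are
per-document.

## Exporters

SBML output targets Level 2 Version 4, a widely consumed dialect of the
CellDesigner/Jarnac era: one compartment per cell location in use, one
species per localized entity, one reaction per interaction with
reactants/products/modifiers taken from participant roles. Information
depth is deliberately minimal — no kinetics, no annotations beyond names —
to maximise downstream compatibility. Ids are sanitized to valid SBML SIds
(non-alphanumerics to `_`, role prefixes `s_`/`c_`/`r_`); sanitization
collisions are reported as errors, never silently renamed.

XGMML uses a bipartite encoding with explicit interaction nodes. An
edge-only encoding cannot represent multi-substrate reactions or modifier
attachment without loss; with interaction nodes, every participant is one
directed edge (input→interaction, interaction→output, modifier edges
attributed with their effect) and the original adjacency is recoverable
exactly, which the tests check by parsing the output back. Entity nodes
carry type, organism and (optionally) compartment attributes.

All exporters emit UTF-8 with LF endings and iterate in sorted or input
order only, so output is byte-identical across runs and platforms — a
property asserted in the tests rather than merely intended.

## The synthetic generator

`generate_repository()` emulates the *structure* of a curated plant
pathway database: three organisms by default (Arabidopsis, soybean,
grapevine), the five-type entity vocabulary, the six-type interaction
vocabulary, and a two-level compartment tree (cell plus organelles,
default six nodes) reflecting organelle-level curation. Pathways default
to 4–8 interactions each. A fifth of interactions are regulatory
(`regulatory_fraction = 0.2`) and pathways reuse already-used genes with
probability `overlap_rate = 0.3` — values chosen once as plausible for a
mixed metabolic/regulatory curation, and the knob that matters for the
shared-gene analytics is exercised across its range in the tests
(including `overlap_rate = 0`, which provably yields an all-zero
off-diagonal).

Entities are created by drawing types from `entity_type_mix` until the
needed type appears, with surplus entities entering per-type free pools
for later use. The empirical type distribution is therefore an iid sample
from the mix regardless of what the interaction mechanics demand, and
converges to it (the tests assert agreement within three percentage points
beyond a thousand entities). Interaction mechanics are type-appropriate:
transcription consumes a gene and produces an RNA (reusing a gene reuses
its transcription interaction, so overlapping pathways share interactions,
not merely genes); translation turns an RNA into a polypeptide; enzymatic
steps convert one or two metabolites into a new one under a catalyst;
transport moves a metabolite between two sampled compartments; regulatory
interactions attach a regulator as a modifier to a target. The generator
uses a single seeded stream (Mersenne-Twister, rejection sampling) with a
fixed draw order; any change to the draw order is a breaking change, since
fixtures are identified by (parameters, seed) and must stay byte-stable.
The caller's RNG state is saved and restored.

What the generator does *not* emulate: realistic stoichiometry, hub
metabolites with power-law degree distributions, coherent regulatory
circuits, or cross-organism orthology. Passing tests on these fixtures
therefore demonstrate the correctness of set semantics, navigation,
accounting and serialization — not biological plausibility of any derived
topology statistic.

## Problem sizes and numerical choices

The test suite exercises the operations at the scales the package is
designed for: the full distance-matrix computation runs over a 403-pathway
synthetic repository and is compared cell-by-cell against a naive
double-loop intersection oracle; navigation symmetry is swept over fifty
20-pathway fixtures; endpoint detection over one hundred small fixtures;
neighbourhoods over ten fixtures at p ∈ {1, 2, 3} for every entity. All
matrix arithmetic is integer; there are no tolerances anywhere in the
package — every comparison in both implementation and tests is exact,
which is appropriate for set cardinalities and discrete structures.

Degenerate inputs are defined rather than accidental: an empty repository
is valid; an empty interaction collection has no entities and no
endpoints; a single-pathway distance matrix is 1×1 with the gene count on
the diagonal; exporting an empty network is a usage error; removing an
absent interaction from a network is a no-op.

## Known limitations

Kinetic parameters, sequence data and cross-database identifier mappings
are out of scope. The repository is single-writer; concurrent mutation is
not coordinated. Search spans names (and optionally synonyms) but not
free-text annotation. SBML import is not provided, only export. The
shared-gene matrix carries no significance model — deciding whether an
overlap of k genes is surprising requires a null model this package does
not claim.
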