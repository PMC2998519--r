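# pathrepo

Curated pathway databases describe metabolic and regulatory networks at
several levels at once: the molecules themselves, where in the cell each
molecule sits, the typed interactions that transform or regulate them, and
the pathways that curators assemble from those interactions. `pathrepo` is
an R toolkit that models exactly these four layers over a single,
file-backed JSON repository, for systems biologists and bioinformatics
developers who want programmatic, scriptable access to pathway-structured
data without a database server.

## The data model

* **Entity** — a molecular species (gene, RNA, polypeptide, protein
  complex, metabolite), organism-specific or universal.
* **LocalEntity** — an (entity, compartment) pair. ATP found in the
  mitochondrion, nucleus, plastid and cytosol is one entity with four
  localized entities.
* **Interaction** — a typed transformation or influence (enzymatic
  reaction, transport, transcription, translation, activation, inhibition)
  over role-tagged localized participants (input / output / modifier).
* **Pathway** — a named, unordered, duplicate-free collection of
  interactions with organism and ontology classification.
* **Network** — a user-defined interaction set, not confined to pathway
  boundaries; the unit of filtering, analysis and export.

Navigation is bidirectional: you can ask which entities make up a pathway
(`entities_of_pathway()`) as easily as which pathways an entity
participates in (`pathways_of_entity()`). Loading is lazy: listing object
headers is free, while participant lists and pathway interaction lists are
materialized on first access, memoized, and counted (`access_stats()`), so
the retrieval footprint of a workflow is observable and testable.

Two analytics are central. Sources and sinks of a collection are the
entities that are only consumed, respectively only produced, with roles
tallied at the entity level and pure modifiers (enzymes, regulators)
excluded. The shared-gene matrix over pathways \(P_1,\dots,P_n\) is

\[ D_{ij} = |\,\mathrm{genes}(P_i) \cap \mathrm{genes}(P_j)\,| \]

a similarity whose diagonal holds each pathway's own gene count; its
GraphViz rendering draws thicker edges for closer pathways. The
`p`-neighbourhood of an entity is the union of BFS levels 1..p over the
bipartite entity–interaction graph, counted in interaction steps.

Networks export to SBML Level 2 Version 4 (one species per localized
entity, one reaction per interaction), XGMML in a bipartite encoding
(entity and interaction nodes), GraphViz dot and RFC 4180 CSV — all
byte-deterministic.

## Worked example

```r
library(pathrepo)

path <- write_repository(builtin_fixture("hormone_pair"), "hp.json")
repo <- load_repository(path)
repo
#> <pathrepo repository> hp.json
#>   organisms: 1 | entities: 22 | local entities: 22 | interactions: 13 | pathways: 5

search_pathways(repo, query_spec(name_pattern = "auxin"))
#>       id               name organism pathway_class
#> 3 pw0003 auxin biosynthesis     org1    pc_hormone
#> 4 pw0004   auxin signalling     org1    pc_hormone
#> 5 pw0005    auxin transport     org1    pc_hormone

net <- network_from_pathways(repo, repo_pathways(repo)$id,
                             label = "hormone superpathway")
net
#> <pathrepo network> 'hormone superpathway': 13 interactions

shared_gene_matrix(repo, repo_pathways(repo)$id)$values
#>        pw0001 pw0002 pw0003 pw0004 pw0005
#> pw0001      3      2      0      0      0
#> pw0002      2      3      1      0      0
#> pw0003      0      1      3      2      1
#> pw0004      0      0      2      3      2
#> pw0005      0      0      1      2      3

endpoints(repo, filter_interactions(repo, net,
                                    keep_types = "enzymatic_reaction"))
#> <endpoints> sources: {m1} | sinks: {m6}

entities_in_min_pathways(repo, c("g1", "g3", "g6"), 2)
#> [1] "g3" "g6"
```

The five hormone pathways hold three genes each with staggered overlaps,
so the matrix diagonal is 3 and adjacent pathways share 2 genes; the
metabolic backbone runs m1 → … → m6, making m1 the only source and m6 the
only sink once transcription/translation interactions are filtered away.
`to_xgmml(repo, net)` turns the merged network into a single
Cytoscape-importable document, and `to_sbml(repo, net)` into SBML.

The same operations are available from a shell via `exec/pathrepo`, e.g.

```sh
exec/pathrepo search --repo hp.json --layer pathway --name auxin
exec/pathrepo distmat --repo hp.json --out-csv m.csv --out-dot m.dot
exec/pathrepo fixture --seed 42 --pathways 20 -o fix42.json --manifest
```

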