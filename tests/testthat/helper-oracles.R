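# Test helpers: fixture loading and independent brute-force oracles that
# operate directly on the serialized repository document (parsed with
# jsonlite), never through the package's indexed accessors.

fixture_repo <- function(name) {
  path <- tempfile(fileext = ".json")
  write_repository(builtin_fixture(name), path)
  load_repository(path)
}

random_repo <- function(seed, n_pathways = 5, ...) {
  path <- tempfile(fileext = ".json")
  doc <- generate_repository(fixture_params(seed = seed,
                                            n_pathways = n_pathways, ...))
  write_repository(doc, path)
  list(repo = load_repository(path),
       doc = jsonlite::read_json(path, simplifyVector = FALSE),
       path = path)
}

# --- document-scan oracles ---------------------------------------------

doc_index <- function(recs) {
  stats::setNames(recs, vapply(recs, function(r) r$id, character(1)))
}

doc_le_entity <- function(doc) {
  stats::setNames(
    vapply(doc$local_entities, function(r) r$entity, character(1)),
    vapply(doc$local_entities, function(r) r$id, character(1)))
}

# deduplicated entity union over interactions, compartments collapsed
oracle_entities_of <- function(doc, ixn_ids) {
  le2e <- doc_le_entity(doc)
  ixns <- doc_index(doc$interactions)
  ents <- unlist(lapply(ixn_ids, function(iid) {
    vapply(ixns[[iid]]$participants,
           function(p) le2e[[p$local_entity]], character(1))
  }))
  sort(unique(as.character(ents)))
}

oracle_genes_of <- function(doc, ixn_ids) {
  type_of <- stats::setNames(
    vapply(doc$entities, function(r) r$entity_type, character(1)),
    vapply(doc$entities, function(r) r$id, character(1)))
  gene_id <- vapply(doc$entity_types, function(t) t$id, character(1))[
    vapply(doc$entity_types, function(t) t$label, character(1)) == "gene"]
  ents <- oracle_entities_of(doc, ixn_ids)
  ents[type_of[ents] == gene_id]
}

oracle_pathway_ixns <- function(doc, pid) {
  p <- doc_index(doc$pathways)[[pid]]
  sort(unique(as.character(unlist(p$interactions))))
}

# entity-level in/out tally over an interaction collection
oracle_endpoints <- function(doc, ixn_ids) {
  le2e <- doc_le_entity(doc)
  ixns <- doc_index(doc$interactions)
  ins <- character(0); outs <- character(0)
  for (iid in ixn_ids) {
    for (p in ixns[[iid]]$participants) {
      e <- le2e[[p$local_entity]]
      if (p$role == "input") ins <- c(ins, e)
      if (p$role == "output") outs <- c(outs, e)
    }
  }
  list(sources = sort(setdiff(unique(ins), unique(outs))),
       sinks = sort(setdiff(unique(outs), unique(ins))))
}

# naive double loop over per-pathway gene sets
oracle_shared_matrix <- function(doc, pids) {
  sets <- lapply(pids, function(pid) {
    oracle_genes_of(doc, oracle_pathway_ixns(doc, pid))
  })
  n <- length(pids)
  m <- matrix(0L, n, n, dimnames = list(pids, pids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}

# BFS over the bipartite entity-interaction graph via igraph: interactions
# within 2p-1 bipartite hops of the seed entity
oracle_neighborhood <- function(doc, entity, p) {
  le2e <- doc_le_entity(doc)
  edges <- character(0)
  for (ixn in doc$interactions) {
    for (pp in ixn$participants) {
      edges <- c(edges, paste0("E:", le2e[[pp$local_entity]]),
                 paste0("I:", ixn$id))
    }
  }
  g <- igraph::simplify(igraph::make_graph(edges, directed = FALSE))
  seed <- paste0("E:", entity)
  if (!seed %in% igraph::V(g)$name) return(character(0))
  reach <- igraph::ego(g, order = 2L * p - 1L, nodes = seed)[[1]]$name
  sort(sub("^I:", "", reach[startsWith(reach, "I:")]))
}

# full inverted index pathway membership by document scan
oracle_pathways_of_entity <- function(doc, entity) {
  pids <- vapply(doc$pathways, function(p) p$id, character(1))
  hits <- vapply(doc$pathways, function(p) {
    entity %in% oracle_entities_of(
      doc, as.character(unlist(p$interactions)))
  }, logical(1))
  sort(pids[hits])
}
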