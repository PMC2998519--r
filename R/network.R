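# User-defined networks: duplicate-free interaction sets scoped to one
# repository, with set algebra, type filtering, endpoint detection,
# p-neighbourhood expansion and pathway analytics. A network is not confined
# to pathway boundaries; it is the unit of filtering, analysis and export.

#' Create a network
#'
#' @param repo The repository the interactions belong to. Networks are
#'   repository-scoped: mixing interactions from two repositories is an
#'   error.
#' @param interactions Character vector of interaction ids (deduplicated).
#' @param label Free-text label.
#' @return An object of class `pathrepo_network`.
#' @export
new_network <- function(repo, interactions = character(0),
                        label = "network") {
  assert_repo(repo)
  interactions <- as.character(interactions)
  bad <- setdiff(interactions, names(repo$interactions_raw))
  if (length(bad) > 0L) {
    stop_integrity(sprintf("unknown interaction ids: %s",
                           paste(bad, collapse = ", ")))
  }
  structure(list(label = label,
                 interactions = sort(unique(interactions)),
                 repo_token = repo$token),
            class = "pathrepo_network")
}

assert_network <- function(net, repo = NULL) {
  if (!inherits(net, "pathrepo_network")) {
    stop_usage("`net` must be a network created by new_network()")
  }
  if (!is.null(repo) && !identical(net$repo_token, repo$token)) {
    stop_usage("network was built against a different repository")
  }
  invisible(net)
}

#' @export
print.pathrepo_network <- function(x, ...) {
  cat(sprintf("<pathrepo network> '%s': %d interactions\n",
              x$label, length(x$interactions)))
  invisible(x)
}

#' Build a network from pathways
#'
#' The network's interaction set is the duplicate-free union of the
#' pathways' interaction sets.
#'
#' @param repo A repository.
#' @param pathways Character vector of pathway ids.
#' @param label Network label (default: the pathway ids joined by `+`).
#' @return A `pathrepo_network`.
#' @export
network_from_pathways <- function(repo, pathways,
                                  label = paste(pathways, collapse = "+")) {
  assert_repo(repo)
  ixns <- unlist(lapply(pathways, function(pid) {
    pathway_interactions(repo, pid)
  }))
  new_network(repo, unique(ixns), label)
}

#' Edit a network with set semantics
#'
#' Returns `(net` \eqn{\cup}{u} `add) \\ remove`. Adding a duplicate or
#' removing an absent interaction is a no-op; the input network is left
#' unmodified.
#'
#' @param repo The network's repository.
#' @param net A network.
#' @param add Interaction ids to add (must resolve in the repository).
#' @param remove Interaction ids to remove (need not be present).
#' @return A new `pathrepo_network`.
#' @export
network_edit <- function(repo, net, add = character(0),
                         remove = character(0)) {
  assert_repo(repo)
  assert_network(net, repo)
  add <- as.character(add)
  bad <- setdiff(add, names(repo$interactions_raw))
  if (length(bad) > 0L) {
    stop_integrity(sprintf("cannot add unknown interactions: %s",
                           paste(bad, collapse = ", ")))
  }
  out <- setdiff(union(net$interactions, add), as.character(remove))
  structure(list(label = net$label, interactions = sort(out),
                 repo_token = net$repo_token),
            class = "pathrepo_network")
}

#' Filter a network's interactions by type
#'
#' Exactly one criterion must be supplied: `keep_types` retains the listed
#' interaction-type labels, `drop_types` removes them (e.g. removing
#' `transcription` and `translation` clutter leaves the core metabolic
#' pathway), and `regulatory_only = TRUE` retains only types flagged
#' regulatory (activation/inhibition classes).
#'
#' @param repo The network's repository.
#' @param net A network.
#' @param keep_types Character vector of interaction-type labels to keep.
#' @param drop_types Character vector of interaction-type labels to drop.
#' @param regulatory_only Keep only regulatory interaction types.
#' @return A new `pathrepo_network`; the input is unmodified.
#' @export
filter_interactions <- function(repo, net, keep_types = NULL,
                                drop_types = NULL, regulatory_only = FALSE) {
  assert_repo(repo)
  assert_network(net, repo)
  n_criteria <- (!is.null(keep_types)) + (!is.null(drop_types)) +
    isTRUE(regulatory_only)
  if (n_criteria != 1L) {
    stop_usage(paste0("supply exactly one of keep_types, drop_types, ",
                      "regulatory_only"))
  }
  it <- repo$interaction_types
  label_of <- stats::setNames(it$label, it$id)
  if (isTRUE(regulatory_only)) {
    keep_labels <- it$label[it$is_regulatory]
  } else {
    labels <- if (!is.null(keep_types)) keep_types else drop_types
    unknown <- setdiff(labels, it$label)
    if (length(unknown) > 0L) {
      stop_vocab(sprintf("unknown interaction type labels: %s",
                         paste(unknown, collapse = ", ")))
    }
    keep_labels <- if (!is.null(keep_types)) keep_types
                   else setdiff(it$label, drop_types)
  }
  keep <- vapply(net$interactions, function(id) {
    label_of[[repo$interactions_raw[[id]]$interaction_type]] %in% keep_labels
  }, logical(1))
  structure(list(label = net$label,
                 interactions = net$interactions[keep],
                 repo_token = net$repo_token),
            class = "pathrepo_network")
}

#' Sources and sinks of a network or pathway
#'
#' A source is an entity appearing in at least one input role and no output
#' role over the whole collection; a sink appears in at least one output
#' role and no input role. Roles are tallied at the entity level
#' (compartments collapsed); entities that participate only as modifiers
#' (enzymes, regulators) carry no mass flow and appear in neither set.
#'
#' @param repo A repository.
#' @param x A `pathrepo_network` or a pathway id.
#' @return An object of class `pathrepo_endpoints`: a list with sorted
#'   character vectors `sources` and `sinks`.
#' @export
endpoints <- function(repo, x) {
  assert_repo(repo)
  ids <- if (inherits(x, "pathrepo_network")) {
    assert_network(x, repo)
    x$interactions
  } else if (is.character(x) && length(x) == 1L) {
    pathway_interactions(repo, x)
  } else {
    stop_usage("`x` must be a network or a single pathway id")
  }
  as_input <- character(0)
  as_output <- character(0)
  for (iid in ids) {
    ixn <- repo_interaction(repo, iid)
    for (p in ixn$participants) {
      ent <- repo$local_entities_by_id[[p$local_entity]]$entity
      if (identical(p$role, "input")) as_input <- c(as_input, ent)
      if (identical(p$role, "output")) as_output <- c(as_output, ent)
    }
  }
  as_input <- unique(as_input)
  as_output <- unique(as_output)
  structure(list(sources = sort(setdiff(as_input, as_output)),
                 sinks = sort(setdiff(as_output, as_input))),
            class = "pathrepo_endpoints")
}

#' @export
print.pathrepo_endpoints <- function(x, ...) {
  cat(sprintf("<endpoints> sources: {%s} | sinks: {%s}\n",
              paste(x$sources, collapse = ", "),
              paste(x$sinks, collapse = ", ")))
  invisible(x)
}

#' p-neighbourhood of an entity
#'
#' Breadth-first expansion over the bipartite entity-interaction graph,
#' counted in interaction steps: level 1 holds every interaction the seed
#' entity participates in; level k holds every interaction sharing at least
#' one entity with a level-(k-1) interaction. The result is the union of
#' levels 1..p.
#'
#' @param repo A repository.
#' @param entity Seed entity id.
#' @param p Number of interaction steps (>= 1).
#' @return A `pathrepo_network` labelled after the seed.
#' @export
neighborhood <- function(repo, entity, p) {
  assert_repo(repo)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != as.integer(p)) {
    stop_usage("`p` must be a positive integer")
  }
  seen_ixns <- character(0)
  seen_entities <- character(0)
  level_ixns <- interactions_of_entity(repo, entity)
  step <- 1L
  while (step <= p && length(level_ixns) > 0L) {
    seen_ixns <- union(seen_ixns, level_ixns)
    new_entities <- setdiff(
      entities_of(repo, level_ixns),
      c(seen_entities, entity))
    seen_entities <- union(seen_entities, c(entity, new_entities))
    step <- step + 1L
    if (step > p || length(new_entities) == 0L) break
    candidate <- unique(unlist(lapply(new_entities, function(e) {
      interactions_of_entity(repo, e)
    })))
    level_ixns <- setdiff(candidate, seen_ixns)
  }
  new_network(repo, seen_ixns,
              label = sprintf("%s-neighbourhood-p%d", entity, p))
}

#' Shared-gene distance matrix over pathways
#'
#' Square integer matrix whose (i, j) cell counts the gene entities common
#' to pathways i and j (compartment-collapsed); the diagonal holds each
#' pathway's own gene count. Larger counts mean closer pathways.
#'
#' @param repo A repository.
#' @param pathways Character vector of distinct pathway ids; row order
#'   follows input order.
#' @return An object of class `pathrepo_distmat`: list with `pathway_ids`,
#'   `pathway_names` and the integer matrix `values`.
#' @export
shared_gene_matrix <- function(repo, pathways) {
  assert_repo(repo)
  pathways <- as.character(pathways)
  if (anyDuplicated(pathways)) {
    stop_usage("pathway ids must be distinct")
  }
  gene_sets <- lapply(pathways, function(pid) {
    genes_of(repo, pathway_interactions(repo, pid))
  })
  all_genes <- sort(unique(unlist(gene_sets)))
  n <- length(pathways)
  if (length(all_genes) == 0L) {
    values <- matrix(0L, n, n)
  } else {
    inc <- matrix(0L, nrow = n, ncol = length(all_genes),
                  dimnames = list(NULL, all_genes))
    for (i in seq_len(n)) inc[i, gene_sets[[i]]] <- 1L
    values <- inc %*% t(inc)
    storage.mode(values) <- "integer"
  }
  dimnames(values) <- list(pathways, pathways)
  ph <- repo$pathway_headers
  names_of <- stats::setNames(ph$name, ph$id)
  structure(list(pathway_ids = pathways,
                 pathway_names = unname(names_of[pathways]),
                 values = values),
            class = "pathrepo_distmat")
}

#' @export
print.pathrepo_distmat <- function(x, ...) {
  cat(sprintf("<shared-gene matrix> %d pathways, %d shared-gene pairs\n",
              length(x$pathway_ids),
              sum(x$values[upper.tri(x$values)] > 0)))
  invisible(x)
}

#' Entities participating in at least k pathways
#'
#' @param repo A repository.
#' @param entities Character vector of entity ids; input order is preserved
#'   in the result.
#' @param k Minimum number of pathways (>= 1).
#' @return The sublist of `entities` found in at least `k` pathways.
#' @export
entities_in_min_pathways <- function(repo, entities, k) {
  assert_repo(repo)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != as.integer(k)) {
    stop_usage("`k` must be a positive integer")
  }
  counts <- vapply(entities, function(e) {
    length(pathways_of_entity(repo, e))
  }, integer(1))
  entities[counts >= k]
}
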