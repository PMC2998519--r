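# File-backed repository: a JSON document holding the vocabularies and the
# four data layers. Loading eagerly parses vocabularies and object headers;
# collection-valued detail (interaction participant lists, pathway
# interaction lists) is materialized on first access, memoized, and counted,
# so the retrieval footprint is observable: listing all pathway headers
# performs zero materializations, and k distinct collection accesses perform
# exactly k.

PR_FORMAT_VERSION <- "1.0"
PR_COLLECTIONS <- c("organisms", "entity_types", "interaction_types",
                    "cell_locations", "pathway_classes", "entities",
                    "local_entities", "interactions", "pathways")

# Each loaded repository gets a distinct token so networks can be checked
# against the repository they were built from.
pr_state <- new.env(parent = emptyenv())
pr_state$repo_counter <- 0L

#' Load a repository document
#'
#' Parses a repository JSON document, optionally validates it against the
#' shipped schema (structure, vocabularies, uniqueness, tree shape) and
#' checks referential integrity. Vocabularies and object headers (entity,
#' localized-entity, interaction and pathway core fields) are available
#' immediately; participant lists and pathway interaction lists are fetched
#' lazily on first access and memoized (see [access_stats()]).
#'
#' @param path Path to a repository JSON file.
#' @param validate Validate document structure on load (default `TRUE`).
#' @param check_refs Check referential integrity of every cross-reference on
#'   load (default `TRUE`). Integrity checking operates on the raw document
#'   and does not count as collection access.
#'
#' @return An object of class `pathrepo_repository`.
#' @export
#' @examples
#' path <- write_repository(builtin_fixture("atp_localization"),
#'                          tempfile(fileext = ".json"))
#' repo <- load_repository(path)
#' nrow(repo_local_entities(repo))  # ATP in 4 compartments
load_repository <- function(path, validate = TRUE, check_refs = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_usage(sprintf("repository file not found: '%s'", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (validate) validate_repository_document(doc, check_refs = check_refs)
  build_repository(doc, path)
}

build_repository <- function(doc, path) {
  repo <- new.env(parent = emptyenv())
  class(repo) <- "pathrepo_repository"
  pr_state$repo_counter <- pr_state$repo_counter + 1L
  repo$token <- sprintf("pathrepo-%d", pr_state$repo_counter)
  repo$path <- path
  repo$doc <- doc

  repo$organisms <- records_frame(doc$organisms, c("id", "name"))
  repo$entity_types <- records_frame(doc$entity_types, c("id", "label"))
  it <- records_frame(doc$interaction_types, c("id", "label"))
  it$is_regulatory <- vapply(doc$interaction_types,
                             function(r) isTRUE(r$is_regulatory), logical(1))
  repo$interaction_types <- it
  repo$cell_locations <- tree_frame(doc$cell_locations)
  repo$pathway_classes <- tree_frame(doc$pathway_classes)

  ent <- records_frame(doc$entities, c("id", "name", "entity_type"))
  ent$organism <- vapply(doc$entities, function(r) {
    if (is.null(r$organism)) NA_character_ else r$organism
  }, character(1))
  repo$entities <- ent
  repo$entities_by_id <- index_by_id(doc$entities)

  repo$local_entities <- records_frame(doc$local_entities,
                                       c("id", "entity", "location"))
  repo$local_entities_by_id <- index_by_id(doc$local_entities)

  ih <- records_frame(doc$interactions, c("id", "interaction_type"))
  ih$organism <- vapply(doc$interactions, function(r) {
    if (is.null(r$organism)) NA_character_ else r$organism
  }, character(1))
  repo$interaction_headers <- ih
  repo$interactions_raw <- index_by_id(doc$interactions)

  ph <- records_frame(doc$pathways, c("id", "name", "organism"))
  ph$pathway_class <- vapply(doc$pathways, function(r) {
    if (is.null(r$pathway_class)) NA_character_ else r$pathway_class
  }, character(1))
  repo$pathway_headers <- ph
  repo$pathways_raw <- index_by_id(doc$pathways)

  repo$participants_cache <- new.env(parent = emptyenv())
  repo$pathway_cache <- new.env(parent = emptyenv())
  repo$pathway_entities_cache <- new.env(parent = emptyenv())
  repo$stats <- new.env(parent = emptyenv())
  repo$stats$participant_materializations <- 0L
  repo$stats$interaction_list_materializations <- 0L
  repo
}

records_frame <- function(records, fields) {
  if (length(records) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(fields)), fields),
      stringsAsFactors = FALSE)
    return(out)
  }
  cols <- lapply(fields, function(f) {
    vapply(records, function(r) {
      v <- r[[f]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  })
  stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE), fields)
}

tree_frame <- function(records) {
  out <- records_frame(records, c("id", "name"))
  out$parent <- vapply(records, function(r) {
    if (is.null(r$parent)) NA_character_ else r$parent
  }, character(1))
  out
}

index_by_id <- function(records) {
  stats::setNames(records, vapply(records, function(r) r$id, character(1)))
}

assert_repo <- function(repo) {
  if (!inherits(repo, "pathrepo_repository")) {
    stop_usage("`repo` must be a repository created by load_repository()")
  }
}

#' @export
print.pathrepo_repository <- function(x, ...) {
  cat(sprintf(
    paste0("<pathrepo repository> %s\n",
           "  organisms: %d | entities: %d | local entities: %d | ",
           "interactions: %d | pathways: %d\n"),
    x$path, nrow(x$organisms), nrow(x$entities), nrow(x$local_entities),
    nrow(x$interaction_headers), nrow(x$pathway_headers)))
  invisible(x)
}

# --- header accessors (never materialize collections) -------------------

#' Repository layer and vocabulary tables
#'
#' Data-frame views of the loaded vocabularies and object headers. None of
#' these accessors materializes participant or interaction lists, so they
#' leave [access_stats()] untouched.
#'
#' @param repo A repository.
#' @return A data frame, one row per record.
#' @name repo-tables
NULL

#' @rdname repo-tables
#' @export
repo_organisms <- function(repo) { assert_repo(repo); repo$organisms }

#' @rdname repo-tables
#' @export
repo_entity_types <- function(repo) { assert_repo(repo); repo$entity_types }

#' @rdname repo-tables
#' @export
repo_interaction_types <- function(repo) {
  assert_repo(repo); repo$interaction_types
}

#' @rdname repo-tables
#' @export
repo_cell_locations <- function(repo) { assert_repo(repo); repo$cell_locations }

#' @rdname repo-tables
#' @export
repo_pathway_classes <- function(repo) {
  assert_repo(repo); repo$pathway_classes
}

#' @rdname repo-tables
#' @export
repo_entities <- function(repo) { assert_repo(repo); repo$entities }

#' @rdname repo-tables
#' @export
repo_local_entities <- function(repo) { assert_repo(repo); repo$local_entities }

#' @rdname repo-tables
#' @export
repo_interactions <- function(repo) {
  assert_repo(repo); repo$interaction_headers
}

#' @rdname repo-tables
#' @export
repo_pathways <- function(repo) { assert_repo(repo); repo$pathway_headers }

# --- object accessors ---------------------------------------------------

#' Fetch a single interaction with its participants
#'
#' The participant list is materialized on first access for each interaction
#' and memoized; the materialization is counted in [access_stats()].
#'
#' @param repo A repository.
#' @param id Interaction id.
#' @return A list with `id`, `interaction_type`, `organism` and
#'   `participants` (a list of participant records).
#' @export
repo_interaction <- function(repo, id) {
  assert_repo(repo)
  raw <- repo$interactions_raw[[id]]
  if (is.null(raw)) stop_not_found(sprintf("unknown interaction id '%s'", id))
  if (!exists(id, envir = repo$participants_cache, inherits = FALSE)) {
    parts <- lapply(raw$participants, function(p) {
      list(local_entity = p$local_entity,
           role = p$role,
           modifier_effect = p$modifier_effect,
           stoichiometry = if (is.null(p$stoichiometry)) 1 else
             as.numeric(p$stoichiometry))
    })
    assign(id, parts, envir = repo$participants_cache)
    repo$stats$participant_materializations <-
      repo$stats$participant_materializations + 1L
  }
  list(id = raw$id,
       interaction_type = raw$interaction_type,
       organism = raw$organism,
       participants = get(id, envir = repo$participants_cache))
}

#' Fetch an entity record
#'
#' @param repo A repository.
#' @param id Entity id.
#' @return A list with `id`, `name`, `entity_type`, `organism` (or `NULL`
#'   for universal entities) and `synonyms`.
#' @export
repo_entity <- function(repo, id) {
  assert_repo(repo)
  rec <- repo$entities_by_id[[id]]
  if (is.null(rec)) stop_not_found(sprintf("unknown entity id '%s'", id))
  list(id = rec$id, name = rec$name, entity_type = rec$entity_type,
       organism = rec$organism,
       synonyms = as.character(unlist(rec$synonyms)))
}

#' Localized entities of an entity
#'
#' @param repo A repository.
#' @param entity Entity id.
#' @return The rows of [repo_local_entities()] whose `entity` matches,
#'   ordered by local-entity id.
#' @export
local_entities_of_entity <- function(repo, entity) {
  assert_repo(repo)
  if (is.null(repo$entities_by_id[[entity]])) {
    stop_not_found(sprintf("unknown entity id '%s'", entity))
  }
  le <- repo$local_entities
  out <- le[le$entity == entity, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

#' Interaction ids of a pathway
#'
#' Materialized on first access per pathway and memoized; counted in
#' [access_stats()].
#'
#' @param repo A repository.
#' @param id Pathway id.
#' @return Character vector of interaction ids (a set, sorted).
#' @export
pathway_interactions <- function(repo, id) {
  assert_repo(repo)
  raw <- repo$pathways_raw[[id]]
  if (is.null(raw)) stop_not_found(sprintf("unknown pathway id '%s'", id))
  if (!exists(id, envir = repo$pathway_cache, inherits = FALSE)) {
    ids <- sort(unique(as.character(unlist(raw$interactions))))
    assign(id, ids, envir = repo$pathway_cache)
    repo$stats$interaction_list_materializations <-
      repo$stats$interaction_list_materializations + 1L
  }
  get(id, envir = repo$pathway_cache)
}

#' Access accounting for lazy collection retrieval
#'
#' Listing headers costs nothing; fetching an interaction's participant list
#' or a pathway's interaction list counts once per distinct object (results
#' are memoized, so repeated access does not increment the counters).
#' Counters are monotone and reset only when a repository is reloaded.
#'
#' @param repo A repository.
#' @return Named list with `participant_materializations` and
#'   `interaction_list_materializations`.
#' @export
access_stats <- function(repo) {
  assert_repo(repo)
  list(
    participant_materializations =
      repo$stats$participant_materializations,
    interaction_list_materializations =
      repo$stats$interaction_list_materializations
  )
}

# --- search -------------------------------------------------------------

#' Build a search query
#'
#' At least one criterion must be present. `name_pattern` is matched
#' case-insensitively as a substring; `*` acts as a wildcard for any run of
#' characters.
#'
#' @param name_pattern Substring/wildcard pattern against object names, or
#'   `NULL`.
#' @param type Entity-type id filter, or `NULL`.
#' @param organism Organism id filter, or `NULL`. For entity search,
#'   universal entities (no organism) match any organism filter.
#' @param location Compartment id filter (entities localized there or in any
#'   descendant compartment), or `NULL`.
#' @param include_synonyms Also match `name_pattern` against entity synonyms
#'   (default `FALSE`: names only).
#'
#' @return An object of class `pathrepo_query`.
#' @export
query_spec <- function(name_pattern = NULL, type = NULL, organism = NULL,
                       location = NULL, include_synonyms = FALSE) {
  if (is.null(name_pattern) && is.null(type) && is.null(organism) &&
      is.null(location)) {
    stop_usage("a query needs at least one criterion")
  }
  structure(list(name_pattern = name_pattern, type = type,
                 organism = organism, location = location,
                 include_synonyms = isTRUE(include_synonyms)),
            class = "pathrepo_query")
}

pattern_regex <- function(pattern) {
  pieces <- strsplit(pattern, "*", fixed = TRUE)[[1]]
  if (length(pieces) == 0L) pieces <- ""
  esc <- vapply(pieces, function(p) {
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p)
  }, character(1))
  paste(esc, collapse = ".*")
}

match_pattern <- function(values, pattern) {
  grepl(pattern_regex(pattern), values, ignore.case = TRUE, perl = TRUE)
}

#' Search entities
#'
#' Returns all and only entities matching every present criterion of the
#' query; results are sorted by (name, id) for determinism.
#'
#' @param repo A repository.
#' @param q A [query_spec()].
#' @return A data frame of entity headers (`id`, `name`, `entity_type`,
#'   `organism`).
#' @export
search_entities <- function(repo, q) {
  assert_repo(repo)
  if (!inherits(q, "pathrepo_query")) stop_usage("`q` must be a query_spec()")
  ent <- repo$entities
  keep <- rep(TRUE, nrow(ent))
  if (!is.null(q$type)) {
    if (!q$type %in% repo$entity_types$id) {
      stop_vocab(sprintf("unknown entity type id '%s'", q$type))
    }
    keep <- keep & ent$entity_type == q$type
  }
  if (!is.null(q$organism)) {
    if (!q$organism %in% repo$organisms$id) {
      stop_vocab(sprintf("unknown organism id '%s'", q$organism))
    }
    keep <- keep & (is.na(ent$organism) | ent$organism == q$organism)
  }
  if (!is.null(q$location)) {
    if (!q$location %in% repo$cell_locations$id) {
      stop_vocab(sprintf("unknown location id '%s'", q$location))
    }
    locs <- tree_descendants(repo$cell_locations, q$location)
    le <- repo$local_entities
    localized <- unique(le$entity[le$location %in% locs])
    keep <- keep & ent$id %in% localized
  }
  if (!is.null(q$name_pattern)) {
    m <- match_pattern(ent$name, q$name_pattern)
    if (q$include_synonyms) {
      syn <- vapply(seq_len(nrow(ent)), function(i) {
        s <- repo$entities_by_id[[ent$id[i]]]$synonyms
        any(match_pattern(as.character(unlist(s)), q$name_pattern))
      }, logical(1))
      m <- m | syn
    }
    keep <- keep & m
  }
  out <- ent[keep, , drop = FALSE]
  out[order(out$name, out$id), , drop = FALSE]
}

#' Search pathways
#'
#' Matches pathway name and organism criteria of the query; `class_filter`
#' restricts to pathways classified under the given ontology node or any of
#' its descendants.
#'
#' @param repo A repository.
#' @param q A [query_spec()] (type/location criteria are ignored for
#'   pathways), or `NULL` when only `class_filter` is used.
#' @param class_filter Pathway-class id, or `NULL`.
#' @return A data frame of pathway headers sorted by (name, id).
#' @export
search_pathways <- function(repo, q = NULL, class_filter = NULL) {
  assert_repo(repo)
  if (is.null(q) && is.null(class_filter)) {
    stop_usage("a pathway search needs a query or a class filter")
  }
  ph <- repo$pathway_headers
  keep <- rep(TRUE, nrow(ph))
  if (!is.null(q)) {
    if (!inherits(q, "pathrepo_query")) stop_usage("`q` must be a query_spec()")
    if (!is.null(q$organism)) {
      if (!q$organism %in% repo$organisms$id) {
        stop_vocab(sprintf("unknown organism id '%s'", q$organism))
      }
      keep <- keep & ph$organism == q$organism
    }
    if (!is.null(q$name_pattern)) {
      keep <- keep & match_pattern(ph$name, q$name_pattern)
    }
  }
  if (!is.null(class_filter)) {
    if (!class_filter %in% repo$pathway_classes$id) {
      stop_vocab(sprintf("unknown pathway class id '%s'", class_filter))
    }
    classes <- tree_descendants(repo$pathway_classes, class_filter)
    keep <- keep & !is.na(ph$pathway_class) & ph$pathway_class %in% classes
  }
  out <- ph[keep, , drop = FALSE]
  out[order(out$name, out$id), , drop = FALSE]
}

# id plus all descendants under parent links
tree_descendants <- function(tree, id) {
  out <- id
  frontier <- id
  while (length(frontier) > 0L) {
    kids <- tree$id[!is.na(tree$parent) & tree$parent %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# --- cross-layer navigation --------------------------------------------

#' Pathways an entity participates in
#'
#' Upward navigation: all pathways containing at least one interaction with
#' a participant that maps (through its localized entity) to the given
#' entity.
#'
#' @param repo A repository.
#' @param entity Entity id.
#' @return Character vector of pathway ids, sorted.
#' @export
pathways_of_entity <- function(repo, entity) {
  assert_repo(repo)
  if (is.null(repo$entities_by_id[[entity]])) {
    stop_not_found(sprintf("unknown entity id '%s'", entity))
  }
  hits <- character(0)
  for (pid in repo$pathway_headers$id) {
    if (entity %in% pathway_entity_set(repo, pid)) hits <- c(hits, pid)
  }
  sort(hits)
}

# memoized compartment-collapsed entity set of a pathway; underlying
# collection materializations are still counted on first computation
pathway_entity_set <- function(repo, pid) {
  if (!exists(pid, envir = repo$pathway_entities_cache, inherits = FALSE)) {
    ents <- entities_of(repo, pathway_interactions(repo, pid))
    assign(pid, ents, envir = repo$pathway_entities_cache)
  }
  get(pid, envir = repo$pathway_entities_cache)
}

#' Entities a pathway is made of
#'
#' Downward navigation: the compartment-collapsed entity set over all the
#' pathway's interactions.
#'
#' @param repo A repository.
#' @param pathway Pathway id.
#' @return Sorted character vector of entity ids.
#' @export
entities_of_pathway <- function(repo, pathway) {
  assert_repo(repo)
  if (is.null(repo$pathways_raw[[pathway]])) {
    stop_not_found(sprintf("unknown pathway id '%s'", pathway))
  }
  pathway_entity_set(repo, pathway)
}

#' Interactions an entity participates in
#'
#' All interactions, in any compartment, with at least one participant
#' mapping to the entity.
#'
#' @param repo A repository.
#' @param entity Entity id.
#' @return Character vector of interaction ids, sorted.
#' @export
interactions_of_entity <- function(repo, entity) {
  assert_repo(repo)
  if (is.null(repo$entities_by_id[[entity]])) {
    stop_not_found(sprintf("unknown entity id '%s'", entity))
  }
  idx <- entity_interaction_index(repo)
  ixns <- idx[[entity]]
  if (is.null(ixns)) character(0) else ixns
}

# inverted index entity -> interaction ids, built on first use; building it
# materializes every participant list (and is counted accordingly)
entity_interaction_index <- function(repo) {
  if (is.null(repo$entity_ixn_index)) {
    ent_of_le <- stats::setNames(repo$local_entities$entity,
                                 repo$local_entities$id)
    idx <- list()
    for (iid in repo$interaction_headers$id) {
      parts <- repo_interaction(repo, iid)$participants
      ents <- unique(vapply(parts, function(p) {
        ent_of_le[[p$local_entity]]
      }, character(1)))
      for (e in ents) {
        idx[[e]] <- c(idx[[e]], iid)
      }
    }
    repo$entity_ixn_index <- lapply(idx, sort)
  }
  repo$entity_ixn_index
}

# --- publication --------------------------------------------------------

#' Publish a network as a new pathway
#'
#' Appends a new pathway record to the repository document on disk and
#' updates the loaded repository in place. Pre-existing records are never
#' modified.
#'
#' @param repo A repository.
#' @param net A network built against `repo` (see [new_network()]).
#' @param name Pathway name; must not collide with an existing pathway of
#'   the same organism.
#' @param organism Organism id for the new pathway.
#' @param pathway_class Optional pathway-class id.
#' @param allow_empty Permit publishing an empty network (default `FALSE`:
#'   an empty network is an error).
#'
#' @return The new pathway header as a list (`id`, `name`, `organism`,
#'   `pathway_class`).
#' @export
save_pathway <- function(repo, net, name, organism, pathway_class = NULL,
                         allow_empty = FALSE) {
  assert_repo(repo)
  assert_network(net, repo)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_usage("pathway name must be a non-empty string")
  }
  if (!organism %in% repo$organisms$id) {
    stop_vocab(sprintf("unknown organism id '%s'", organism))
  }
  if (!is.null(pathway_class) &&
      !pathway_class %in% repo$pathway_classes$id) {
    stop_vocab(sprintf("unknown pathway class id '%s'", pathway_class))
  }
  if (length(net$interactions) == 0L && !allow_empty) {
    stop_usage("refusing to publish an empty network (allow_empty = FALSE)")
  }
  bad <- setdiff(net$interactions, names(repo$interactions_raw))
  if (length(bad) > 0L) {
    stop_integrity(sprintf("network interactions not in repository: %s",
                           paste(bad, collapse = ", ")))
  }
  ph <- repo$pathway_headers
  if (any(ph$name == name & ph$organism == organism)) {
    stop_conflict(sprintf(
      "a pathway named '%s' already exists for organism '%s'",
      name, organism))
  }

  existing <- names(repo$pathways_raw)
  n <- length(existing) + 1L
  repeat {
    new_id <- sprintf("pw%04d", n)
    if (!new_id %in% existing) break
    n <- n + 1L
  }
  record <- list(id = new_id, name = name, organism = organism,
                 pathway_class = pathway_class,
                 interactions = as.list(sort(net$interactions)))

  doc <- repo$doc
  doc$pathways <- c(doc$pathways, list(record))
  write_repository(doc, repo$path)

  # update in-memory state; memoized collections stay valid (append-only)
  repo$doc <- doc
  repo$pathways_raw[[new_id]] <- record
  repo$pathway_headers <- rbind(
    repo$pathway_headers,
    data.frame(id = new_id, name = name, organism = organism,
               pathway_class = if (is.null(pathway_class)) NA_character_
                               else pathway_class,
               stringsAsFactors = FALSE))
  list(id = new_id, name = name, organism = organism,
       pathway_class = pathway_class)
}
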