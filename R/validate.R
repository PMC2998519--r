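# Structural and referential validation of repository documents. Errors
# carry JSON-pointer-style paths (e.g. /entities/3/entity_type) so a failing
# record can be located in the file. A machine-readable JSON Schema for the
# same format ships in inst/extdata/repository-schema.json.

#' Validate a repository document
#'
#' Checks document structure (required keys, field types, id uniqueness,
#' controlled vocabularies, tree shape of compartment and ontology
#' hierarchies) and, optionally, full referential integrity of every
#' cross-reference, including the transport constraint (input and output of
#' a transport interaction are the same entity in different compartments).
#'
#' @param doc A parsed repository document (nested lists, as read by
#'   `jsonlite::read_json(..., simplifyVector = FALSE)`), or a path to a
#'   JSON file.
#' @param check_refs Check cross-references (default `TRUE`).
#' @return Invisibly `TRUE`; signals a validation or integrity error
#'   otherwise.
#' @export
validate_repository_document <- function(doc, check_refs = TRUE) {
  if (is.character(doc) && length(doc) == 1L) {
    if (!file.exists(doc)) stop_usage(sprintf("no such file: '%s'", doc))
    doc <- jsonlite::read_json(doc, simplifyVector = FALSE)
  }
  if (!is.list(doc)) stop_validation("document is not a JSON object", "/")
  if (!identical(as.character(doc$format_version), PR_FORMAT_VERSION)) {
    stop_validation(
      sprintf("format_version must be \"%s\"", PR_FORMAT_VERSION),
      "/format_version")
  }
  for (key in PR_COLLECTIONS) {
    if (is.null(doc[[key]]) || !is.list(doc[[key]])) {
      stop_validation(sprintf("missing or non-array collection '%s'", key),
                      paste0("/", key))
    }
  }

  ids <- list()
  for (key in PR_COLLECTIONS) {
    recs <- doc[[key]]
    seen <- character(0)
    for (i in seq_along(recs)) {
      at <- sprintf("/%s/%d", key, i - 1L)
      r <- recs[[i]]
      if (!is.list(r)) stop_validation("record is not an object", at)
      id <- r$id
      if (!is.character(id) && !is.null(id)) id <- as.character(id)
      if (is.null(id) || length(id) != 1L || !nzchar(id)) {
        stop_validation("record id missing or empty", paste0(at, "/id"))
      }
      if (id %in% seen) {
        stop_validation(sprintf("duplicate id '%s'", id), paste0(at, "/id"))
      }
      seen <- c(seen, id)
    }
    ids[[key]] <- seen
  }

  check_string_field(doc$organisms, "organisms", "name")
  check_string_field(doc$entity_types, "entity_types", "label")
  check_unique_field(doc$entity_types, "entity_types", "label")
  if (length(doc$entity_types) == 0L) {
    stop_validation("entity type vocabulary must not be empty",
                    "/entity_types")
  }
  check_string_field(doc$interaction_types, "interaction_types", "label")
  check_unique_field(doc$interaction_types, "interaction_types", "label")
  for (i in seq_along(doc$interaction_types)) {
    r <- doc$interaction_types[[i]]
    at <- sprintf("/interaction_types/%d", i - 1L)
    if (!is.logical(r$is_regulatory) || length(r$is_regulatory) != 1L) {
      stop_validation("is_regulatory must be a boolean",
                      paste0(at, "/is_regulatory"))
    }
    if (r$label %in% PR_REGULATORY_LABELS && !isTRUE(r$is_regulatory)) {
      stop_validation(
        sprintf("'%s' must be flagged regulatory", r$label), at)
    }
    if (r$label %in% c("enzymatic_reaction", "transport") &&
        isTRUE(r$is_regulatory)) {
      stop_validation(
        sprintf("'%s' must not be flagged regulatory", r$label), at)
    }
  }

  check_tree(doc$cell_locations, "cell_locations", ids$cell_locations)
  check_tree(doc$pathway_classes, "pathway_classes", ids$pathway_classes)
  # compartment names unique among siblings
  key_of <- vapply(doc$cell_locations, function(r) {
    paste0(if (is.null(r$parent)) "" else r$parent, "\r", r$name)
  }, character(1))
  if (anyDuplicated(key_of)) {
    stop_validation("compartment names must be unique per parent",
                    "/cell_locations")
  }

  if (!check_refs) return(invisible(TRUE))

  # entities
  for (i in seq_along(doc$entities)) {
    r <- doc$entities[[i]]
    at <- sprintf("/entities/%d", i - 1L)
    if (!r$entity_type %in% ids$entity_types) {
      stop_integrity(sprintf(
        "entity '%s' references unknown entity type '%s' (at %s)",
        r$id, r$entity_type, at))
    }
    if (!is.null(r$organism) && !r$organism %in% ids$organisms) {
      stop_integrity(sprintf(
        "entity '%s' references unknown organism '%s' (at %s)",
        r$id, r$organism, at))
    }
  }

  # local entities: refs + (entity, location) uniqueness
  pair_seen <- character(0)
  for (i in seq_along(doc$local_entities)) {
    r <- doc$local_entities[[i]]
    at <- sprintf("/local_entities/%d", i - 1L)
    if (!r$entity %in% ids$entities) {
      stop_integrity(sprintf(
        "local entity '%s' references unknown entity '%s' (at %s)",
        r$id, r$entity, at))
    }
    if (!r$location %in% ids$cell_locations) {
      stop_integrity(sprintf(
        "local entity '%s' references unknown location '%s' (at %s)",
        r$id, r$location, at))
    }
    key <- paste0(r$entity, "\r", r$location)
    if (key %in% pair_seen) {
      stop_validation(sprintf(
        "duplicate (entity, location) pair for entity '%s'", r$entity), at)
    }
    pair_seen <- c(pair_seen, key)
  }

  le_entity <- stats::setNames(
    vapply(doc$local_entities, function(r) r$entity, character(1)),
    ids$local_entities)
  le_location <- stats::setNames(
    vapply(doc$local_entities, function(r) r$location, character(1)),
    ids$local_entities)
  type_label <- stats::setNames(
    vapply(doc$interaction_types, function(r) r$label, character(1)),
    ids$interaction_types)

  # interactions
  for (i in seq_along(doc$interactions)) {
    r <- doc$interactions[[i]]
    at <- sprintf("/interactions/%d", i - 1L)
    if (!r$interaction_type %in% ids$interaction_types) {
      stop_integrity(sprintf(
        "interaction '%s' references unknown interaction type '%s' (at %s)",
        r$id, r$interaction_type, at))
    }
    if (!is.null(r$organism) && !r$organism %in% ids$organisms) {
      stop_integrity(sprintf(
        "interaction '%s' references unknown organism '%s' (at %s)",
        r$id, r$organism, at))
    }
    if (length(r$participants) == 0L) {
      stop_validation(sprintf(
        "interaction '%s' has no participants", r$id),
        paste0(at, "/participants"))
    }
    for (j in seq_along(r$participants)) {
      p <- r$participants[[j]]
      pat <- sprintf("%s/participants/%d", at, j - 1L)
      if (is.null(p$local_entity) ||
          !p$local_entity %in% ids$local_entities) {
        stop_integrity(sprintf(
          "interaction '%s' references unknown local entity '%s' (at %s)",
          r$id, if (is.null(p$local_entity)) "<missing>" else p$local_entity,
          pat))
      }
      if (is.null(p$role) || !p$role %in% PR_ROLES) {
        stop_validation(sprintf(
          "participant role must be one of %s",
          paste(PR_ROLES, collapse = ", ")), paste0(pat, "/role"))
      }
      if (identical(p$role, "modifier")) {
        if (is.null(p$modifier_effect) ||
            !p$modifier_effect %in% PR_MODIFIER_EFFECTS) {
          stop_validation(sprintf(
            "modifier participants need a modifier_effect in {%s}",
            paste(PR_MODIFIER_EFFECTS, collapse = ", ")),
            paste0(pat, "/modifier_effect"))
        }
      } else if (!is.null(p$modifier_effect)) {
        stop_validation("modifier_effect is only allowed on modifiers",
                        paste0(pat, "/modifier_effect"))
      }
      if (!is.null(p$stoichiometry)) {
        s <- suppressWarnings(as.numeric(p$stoichiometry))
        if (is.na(s) || s <= 0) {
          stop_validation("stoichiometry must be a positive number",
                          paste0(pat, "/stoichiometry"))
        }
      }
    }
    if (identical(type_label[[r$interaction_type]], "transport")) {
      io <- Filter(function(p) p$role %in% c("input", "output"),
                   r$participants)
      ents <- unique(vapply(io, function(p) le_entity[[p$local_entity]],
                            character(1)))
      locs <- vapply(io, function(p) le_location[[p$local_entity]],
                     character(1))
      if (length(ents) != 1L || anyDuplicated(locs)) {
        stop_validation(sprintf(
          paste0("transport interaction '%s' must move one entity ",
                 "between distinct compartments"), r$id), at)
      }
    }
  }

  # pathways
  for (i in seq_along(doc$pathways)) {
    r <- doc$pathways[[i]]
    at <- sprintf("/pathways/%d", i - 1L)
    for (f in c("name", "organism")) {
      if (is.null(r[[f]]) || !nzchar(as.character(r[[f]]))) {
        stop_validation(sprintf("pathway field '%s' missing", f),
                        paste0(at, "/", f))
      }
    }
    if (!r$organism %in% ids$organisms) {
      stop_integrity(sprintf(
        "pathway '%s' references unknown organism '%s' (at %s)",
        r$id, r$organism, at))
    }
    if (!is.null(r$pathway_class) &&
        !r$pathway_class %in% ids$pathway_classes) {
      stop_integrity(sprintf(
        "pathway '%s' references unknown pathway class '%s' (at %s)",
        r$id, r$pathway_class, at))
    }
    pw_ixns <- as.character(unlist(r$interactions))
    if (anyDuplicated(pw_ixns)) {
      stop_validation(sprintf(
        "pathway '%s' lists a duplicate interaction", r$id),
        paste0(at, "/interactions"))
    }
    bad <- setdiff(pw_ixns, ids$interactions)
    if (length(bad) > 0L) {
      stop_integrity(sprintf(
        "pathway '%s' references unknown interactions: %s (at %s)",
        r$id, paste(bad, collapse = ", "), at))
    }
  }

  invisible(TRUE)
}

check_string_field <- function(recs, key, field) {
  for (i in seq_along(recs)) {
    v <- recs[[i]][[field]]
    if (is.null(v) || !nzchar(as.character(v))) {
      stop_validation(sprintf("field '%s' missing or empty", field),
                      sprintf("/%s/%d/%s", key, i - 1L, field))
    }
  }
}

check_unique_field <- function(recs, key, field) {
  vals <- vapply(recs, function(r) as.character(r[[field]]), character(1))
  if (anyDuplicated(vals)) {
    stop_validation(sprintf("values of '%s' must be unique", field),
                    paste0("/", key))
  }
}

# parent links must resolve within the collection and form a forest
check_tree <- function(recs, key, all_ids) {
  parent <- stats::setNames(vapply(recs, function(r) {
    if (is.null(r$parent)) NA_character_ else r$parent
  }, character(1)), all_ids)
  bad <- parent[!is.na(parent) & !parent %in% all_ids]
  if (length(bad) > 0L) {
    stop_integrity(sprintf("%s parent '%s' does not resolve",
                           key, bad[[1L]]))
  }
  for (id in all_ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) {
        stop_validation(sprintf("cycle in %s parent links at '%s'", key, id),
                        paste0("/", key))
      }
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  invisible(TRUE)
}
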