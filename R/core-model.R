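# Core domain vocabulary and the pure helpers that work over interactions
# and their role-tagged participants. The four data layers are:
#   entity -> local entity (entity @ compartment) -> interaction -> pathway.

#' Participant roles recognised by the data model
#'
#' Every participant of an interaction carries exactly one role: `input`
#' (consumed), `output` (produced) or `modifier` (influences the interaction
#' without mass flow; a modifier additionally carries a `modifier_effect` of
#' `catalysis`, `activation` or `inhibition`).
#'
#' @format Character vectors.
#' @name vocabulary
NULL

PR_ROLES <- c("input", "output", "modifier")
PR_MODIFIER_EFFECTS <- c("catalysis", "activation", "inhibition")

# Minimal controlled vocabularies; repositories may extend them.
PR_ENTITY_TYPE_LABELS <- c("gene", "RNA", "polypeptide", "protein_complex",
                           "metabolite")
PR_INTERACTION_TYPE_LABELS <- c("enzymatic_reaction", "transport",
                                "transcription", "translation",
                                "activation", "inhibition")
PR_REGULATORY_LABELS <- c("activation", "inhibition")

#' Extract participants of an interaction by role
#'
#' @param interaction An interaction object as returned by
#'   [repo_interaction()]: a list with at least a `participants` element.
#' @param role One of `"input"`, `"output"`, `"modifier"`, or `NULL` to
#'   return all participants.
#'
#' @return A list of participant records (each a list with `local_entity`,
#'   `role`, `stoichiometry` and, for modifiers, `modifier_effect`), in the
#'   order they appear in the interaction.
#' @export
#' @examples
#' repo <- load_repository(write_repository(builtin_fixture("chain"),
#'                                          tempfile(fileext = ".json")))
#' ixn <- repo_interaction(repo, repo_interactions(repo)$id[1])
#' length(participants_by_role(ixn, "input"))
participants_by_role <- function(interaction, role = NULL) {
  if (!is.list(interaction) || is.null(interaction$participants)) {
    stop_usage("`interaction` must be an interaction object with participants")
  }
  parts <- interaction$participants
  if (is.null(role)) {
    return(parts)
  }
  if (!is.character(role) || length(role) != 1L || !role %in% PR_ROLES) {
    stop_vocab(sprintf("unknown participant role '%s'; expected one of %s",
                       paste(role, collapse = ","),
                       paste(PR_ROLES, collapse = ", ")))
  }
  parts[vapply(parts, function(p) identical(p$role, role), logical(1))]
}

#' Entities participating in a collection of interactions
#'
#' Maps every participant through its localized entity back to the underlying
#' entity, collapsing compartment multiplicity: an entity present in four
#' compartments is reported once.
#'
#' @param repo A repository, see [load_repository()].
#' @param interactions Character vector of interaction ids, or a list of
#'   interaction objects.
#'
#' @return Sorted character vector of entity ids (a set).
#' @export
entities_of <- function(repo, interactions) {
  assert_repo(repo)
  ids <- character(0)
  for (ixn in resolve_interactions(repo, interactions)) {
    for (p in ixn$participants) {
      le <- repo$local_entities_by_id[[p$local_entity]]
      if (is.null(le)) {
        stop_integrity(sprintf(
          "interaction '%s' references unknown local entity '%s'",
          ixn$id, p$local_entity))
      }
      ids <- c(ids, le$entity)
    }
  }
  sort(unique(ids))
}

#' Gene entities participating in a collection of interactions
#'
#' [entities_of()] restricted to entities whose type carries the label
#' `gene`; the unit used by [shared_gene_matrix()].
#'
#' @inheritParams entities_of
#' @return Sorted character vector of gene entity ids.
#' @export
genes_of <- function(repo, interactions) {
  assert_repo(repo)
  gene_type <- type_id_for_label(repo, "gene")
  if (is.null(gene_type)) {
    stop_vocab("repository vocabulary has no entity type labelled 'gene'")
  }
  ents <- entities_of(repo, interactions)
  keep <- vapply(ents, function(e) {
    identical(repo$entities_by_id[[e]]$entity_type, gene_type)
  }, logical(1))
  ents[keep]
}

# --- internal -----------------------------------------------------------

# Accept interaction ids (materializing them through the repository, so
# access accounting applies) or already-fetched interaction objects.
resolve_interactions <- function(repo, interactions) {
  if (is.character(interactions)) {
    lapply(interactions, function(id) repo_interaction(repo, id))
  } else if (is.list(interactions)) {
    interactions
  } else {
    stop_usage("`interactions` must be interaction ids or interaction objects")
  }
}

type_id_for_label <- function(repo, label) {
  et <- repo$entity_types
  hit <- et$id[et$label == label]
  if (length(hit) == 0L) NULL else hit[[1L]]
}
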