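# Deterministic exporters. Every function here is a pure function of the
# repository content, the network's interaction id set and the options:
# ordering is fixed (sorted ids / input order), so output bytes are stable
# across runs and platforms. Depth of information is deliberately minimal:
# no kinetics, no annotations beyond names.

SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
XGMML_NS <- "http://www.cs.rpi.edu/XGMML"

# non-alphanumerics -> "_", role prefix guarantees a valid SId start;
# collisions are reported, never silently renamed
sanitize_ids <- function(ids, prefix) {
  out <- paste0(prefix, gsub("[^A-Za-z0-9]", "_", ids))
  if (anyDuplicated(out)) {
    clash <- ids[out %in% out[duplicated(out)]]
    stop_export(sprintf("id sanitization collision: %s",
                        paste(clash, collapse = ", ")))
  }
  stats::setNames(out, ids)
}

network_local_entities <- function(repo, net) {
  les <- unlist(lapply(net$interactions, function(iid) {
    vapply(repo_interaction(repo, iid)$participants,
           function(p) p$local_entity, character(1))
  }))
  sort(unique(les))
}

#' Export a network to SBML Level 2 Version 4
#'
#' One species per localized entity (its compartment taken from the
#' corresponding cell location), one compartment per cell location in use,
#' and one reaction per interaction with reactants = input participants,
#' products = output participants and modifiers = modifier participants.
#'
#' @param repo A repository.
#' @param net A non-empty `pathrepo_network`.
#' @return SBML document text (single character string, UTF-8, LF line
#'   endings).
#' @export
to_sbml <- function(repo, net) {
  assert_repo(repo)
  assert_network(net, repo)
  if (length(net$interactions) == 0L) {
    stop_usage("cannot export an empty network")
  }
  le_ids <- network_local_entities(repo, net)
  loc_ids <- sort(unique(vapply(le_ids, function(id) {
    repo$local_entities_by_id[[id]]$location
  }, character(1))))
  s_id <- sanitize_ids(le_ids, "s_")
  c_id <- sanitize_ids(loc_ids, "c_")
  r_id <- sanitize_ids(net$interactions, "r_")

  loc_name <- stats::setNames(repo$cell_locations$name,
                              repo$cell_locations$id)
  it_label <- stats::setNames(repo$interaction_types$label,
                              repo$interaction_types$id)

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model", id = "network",
                               name = net$label)

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (loc in loc_ids) {
    xml2::xml_add_child(comps, "compartment", id = c_id[[loc]],
                        name = loc_name[[loc]])
  }

  species <- xml2::xml_add_child(model, "listOfSpecies")
  for (le in le_ids) {
    rec <- repo$local_entities_by_id[[le]]
    ent <- repo$entities_by_id[[rec$entity]]
    xml2::xml_add_child(species, "species", id = s_id[[le]],
                        name = ent$name,
                        compartment = c_id[[rec$location]])
  }

  reactions <- xml2::xml_add_child(model, "listOfReactions")
  for (iid in net$interactions) {
    ixn <- repo_interaction(repo, iid)
    rxn <- xml2::xml_add_child(reactions, "reaction", id = r_id[[iid]],
                               name = it_label[[ixn$interaction_type]],
                               reversible = "false")
    ins <- participants_by_role(ixn, "input")
    outs <- participants_by_role(ixn, "output")
    mods <- participants_by_role(ixn, "modifier")
    if (length(ins) > 0L) {
      lst <- xml2::xml_add_child(rxn, "listOfReactants")
      for (p in ins) {
        xml2::xml_add_child(lst, "speciesReference",
                            species = s_id[[p$local_entity]],
                            stoichiometry = format(p$stoichiometry))
      }
    }
    if (length(outs) > 0L) {
      lst <- xml2::xml_add_child(rxn, "listOfProducts")
      for (p in outs) {
        xml2::xml_add_child(lst, "speciesReference",
                            species = s_id[[p$local_entity]],
                            stoichiometry = format(p$stoichiometry))
      }
    }
    if (length(mods) > 0L) {
      lst <- xml2::xml_add_child(rxn, "listOfModifiers")
      for (p in mods) {
        xml2::xml_add_child(lst, "modifierSpeciesReference",
                            species = s_id[[p$local_entity]])
      }
    }
  }
  xml_text_out(doc)
}

#' Export a network to XGMML
#'
#' Bipartite encoding: one node per localized entity (attributes: entity
#' type, organism and, when `include_localization`, the compartment) and one
#' node per interaction (attribute: interaction type); one directed edge per
#' participant, oriented input -> interaction and interaction -> output,
#' with modifier edges carrying their `modifier_effect`. Output is
#' byte-identical across runs for the same input.
#'
#' @param repo A repository.
#' @param net A non-empty `pathrepo_network`.
#' @param include_localization Attach compartment attributes to entity nodes
#'   (default `TRUE`).
#' @return XGMML document text.
#' @export
to_xgmml <- function(repo, net, include_localization = TRUE) {
  assert_repo(repo)
  assert_network(net, repo)
  if (length(net$interactions) == 0L) {
    stop_usage("cannot export an empty network")
  }
  le_ids <- network_local_entities(repo, net)
  loc_name <- stats::setNames(repo$cell_locations$name,
                              repo$cell_locations$id)
  org_name <- stats::setNames(repo$organisms$name, repo$organisms$id)
  et_label <- stats::setNames(repo$entity_types$label,
                              repo$entity_types$id)
  it_label <- stats::setNames(repo$interaction_types$label,
                              repo$interaction_types$id)

  doc <- xml2::xml_new_root("graph", xmlns = XGMML_NS,
                            label = net$label, directed = "1")
  add_att <- function(parent, name, value) {
    xml2::xml_add_child(parent, "att", name = name, value = value,
                        type = "string")
  }
  for (le in le_ids) {
    rec <- repo$local_entities_by_id[[le]]
    ent <- repo$entities_by_id[[rec$entity]]
    node <- xml2::xml_add_child(doc, "node", id = paste0("le:", le),
                                label = ent$name)
    add_att(node, "kind", "local_entity")
    add_att(node, "entity", ent$id)
    add_att(node, "entity_type", et_label[[ent$entity_type]])
    if (!is.null(ent$organism)) {
      add_att(node, "organism", org_name[[ent$organism]])
    }
    if (isTRUE(include_localization)) {
      add_att(node, "location", loc_name[[rec$location]])
    }
  }
  for (iid in net$interactions) {
    ixn <- repo_interaction(repo, iid)
    node <- xml2::xml_add_child(doc, "node", id = paste0("ixn:", iid),
                                label = iid)
    add_att(node, "kind", "interaction")
    add_att(node, "interaction_type", it_label[[ixn$interaction_type]])
  }
  for (iid in net$interactions) {
    ixn <- repo_interaction(repo, iid)
    for (p in ixn$participants) {
      le_node <- paste0("le:", p$local_entity)
      ixn_node <- paste0("ixn:", iid)
      if (identical(p$role, "output")) {
        edge <- xml2::xml_add_child(doc, "edge", source = ixn_node,
                                    target = le_node)
      } else {
        edge <- xml2::xml_add_child(doc, "edge", source = le_node,
                                    target = ixn_node)
      }
      add_att(edge, "role", p$role)
      if (identical(p$role, "modifier")) {
        add_att(edge, "modifier_effect", p$modifier_effect)
      }
    }
  }
  xml_text_out(doc)
}

#' Render a shared-gene matrix as a GraphViz dot graph
#'
#' Undirected graph with one node per pathway (labelled by name) and one
#' edge per unordered pathway pair sharing at least `min_shared` genes; edge
#' `penwidth` is 1 + shared count, capped at 10, so thicker lines indicate
#' closer pathways.
#'
#' @param matrix A `pathrepo_distmat` from [shared_gene_matrix()].
#' @param min_shared Minimum shared-gene count for drawing an edge
#'   (default 1).
#' @return dot document text.
#' @export
to_dot_distance <- function(matrix, min_shared = 1) {
  if (!inherits(matrix, "pathrepo_distmat")) {
    stop_usage("`matrix` must come from shared_gene_matrix()")
  }
  if (!is.numeric(min_shared) || length(min_shared) != 1L ||
      min_shared < 0) {
    stop_usage("`min_shared` must be a non-negative integer")
  }
  ids <- matrix$pathway_ids
  lines <- c("graph shared_genes {", "  node [shape=box];")
  for (i in seq_along(ids)) {
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];",
                              ids[i], dot_escape(matrix$pathway_names[i])))
  }
  n <- length(ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        shared <- matrix$values[i, j]
        if (shared >= min_shared) {
          lines <- c(lines, sprintf(
            "  \"%s\" -- \"%s\" [penwidth=%d, label=\"%d\"];",
            ids[i], ids[j], min(1L + shared, 10L), shared))
        }
      }
    }
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

dot_escape <- function(x) gsub("\"", "\\\\\"", x)

#' Render a shared-gene matrix as CSV
#'
#' RFC 4180 CSV: header row holds the pathway ids, column 1 holds row
#' labels, cells are integers; LF line endings and a trailing newline.
#'
#' @param matrix A `pathrepo_distmat`.
#' @return CSV text.
#' @export
to_csv_matrix <- function(matrix) {
  if (!inherits(matrix, "pathrepo_distmat")) {
    stop_usage("`matrix` must come from shared_gene_matrix()")
  }
  ids <- vapply(matrix$pathway_ids, csv_quote, character(1))
  header <- paste(c("", ids), collapse = ",")
  rows <- vapply(seq_along(matrix$pathway_ids), function(i) {
    paste(c(ids[i], matrix$values[i, ]), collapse = ",")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

csv_quote <- function(x) {
  if (grepl("[\",\n]", x)) paste0("\"", gsub("\"", "\"\"", x), "\"") else x
}

# serialize an xml2 document to stable UTF-8 text with LF endings
xml_text_out <- function(doc) {
  txt <- as.character(doc, options = c("format", "no_declaration"))
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n", txt)
}
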