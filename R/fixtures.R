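# Repository document generators: small named fixtures covering canonical
# situations (multi-compartment localization, linear chains, cycles,
# transcription/translation clutter, overlapping hormone pathways) and a
# seeded random generator that emulates a plant pathway database at a
# configurable scale. Both produce plain documents (nested lists) that
# serialize through write_repository() and pass full validation.

# --- shared vocabulary builders ----------------------------------------

PR_ORGANISM_POOL <- c("Arabidopsis thaliana", "Glycine max",
                      "Vitis vinifera")
PR_ORGANELLE_POOL <- c("cytosol", "nucleus", "mitochondrion", "plastid",
                       "vacuole", "endoplasmic_reticulum", "golgi",
                       "peroxisome", "chloroplast")

std_entity_types <- function() {
  lapply(PR_ENTITY_TYPE_LABELS, function(l) {
    list(id = paste0("et_", l), label = l)
  })
}

std_interaction_types <- function() {
  lapply(PR_INTERACTION_TYPE_LABELS, function(l) {
    list(id = paste0("it_", l), label = l,
         is_regulatory = l %in% PR_REGULATORY_LABELS)
  })
}

std_organisms <- function(n) {
  names <- c(PR_ORGANISM_POOL,
             if (n > length(PR_ORGANISM_POOL))
               sprintf("organism_%d", seq(length(PR_ORGANISM_POOL) + 1L, n)))
  lapply(seq_len(n), function(i) {
    list(id = sprintf("org%d", i), name = names[i])
  })
}

std_locations <- function(organelles) {
  c(list(list(id = "loc_cell", name = "cell", parent = NULL)),
    lapply(organelles, function(o) {
      list(id = paste0("loc_", o), name = o, parent = "loc_cell")
    }))
}

participant <- function(local_entity, role, modifier_effect = NULL,
                        stoichiometry = 1) {
  p <- list(local_entity = local_entity, role = role)
  if (!is.null(modifier_effect)) p$modifier_effect <- modifier_effect
  p$stoichiometry <- stoichiometry
  p
}

empty_document <- function() {
  list(format_version = PR_FORMAT_VERSION,
       organisms = list(), entity_types = std_entity_types(),
       interaction_types = std_interaction_types(),
       cell_locations = list(), pathway_classes = list(),
       entities = list(), local_entities = list(),
       interactions = list(), pathways = list())
}

# --- builtin fixtures ---------------------------------------------------

#' Built-in repository fixtures
#'
#' Deterministic, hand-constructed repository documents:
#' * `atp_localization` — a single universal metabolite (ATP) localized in
#'   four compartments (mitochondrion, nucleus, plastid, cytosol) with four
#'   transport interactions shuttling it between them.
#' * `chain` — a linear A -> B -> C pathway of two enzymatic reactions.
#' * `cycle` — a closed A -> B -> C -> A loop of three reactions.
#' * `clutter` — one pathway mixing 5 enzymatic, 3 transcription and 2
#'   translation interactions, for clutter-removal filtering.
#' * `hormone_pair` — 5 hormone pathways (brassinosteroid and auxin
#'   metabolism/signalling) with overlapping gene sets.
#'
#' @param name Fixture name.
#' @return A repository document (nested list); serialize it with
#'   [write_repository()].
#' @export
builtin_fixture <- function(name) {
  switch(name,
    atp_localization = fixture_atp(),
    chain = fixture_chain(),
    cycle = fixture_cycle(),
    clutter = fixture_clutter(),
    hormone_pair = fixture_hormone_pair(),
    stop_usage(sprintf("unknown fixture '%s'", name))
  )
}

fixture_atp <- function() {
  doc <- empty_document()
  doc$organisms <- std_organisms(1)
  comps <- c("mitochondrion", "nucleus", "plastid", "cytosol")
  doc$cell_locations <- std_locations(comps)
  doc$entities <- list(list(
    id = "ent_atp", name = "ATP", entity_type = "et_metabolite",
    organism = NULL, synonyms = list("adenosine triphosphate")))
  doc$local_entities <- lapply(comps, function(cc) {
    list(id = paste0("le_atp_", cc), entity = "ent_atp",
         location = paste0("loc_", cc))
  })
  hops <- list(c("cytosol", "mitochondrion"), c("mitochondrion", "nucleus"),
               c("nucleus", "plastid"), c("plastid", "cytosol"))
  doc$interactions <- lapply(seq_along(hops), function(i) {
    h <- hops[[i]]
    list(id = sprintf("x%04d", i), interaction_type = "it_transport",
         organism = NULL,
         participants = list(
           participant(paste0("le_atp_", h[1]), "input"),
           participant(paste0("le_atp_", h[2]), "output")))
  })
  doc$pathways <- list(list(
    id = "pw0001", name = "ATP compartmental shuttling",
    organism = "org1", pathway_class = NULL,
    interactions = as.list(sprintf("x%04d", 1:4))))
  doc
}

# linear or cyclic metabolite path over named species
metabolite_path <- function(species, close_cycle = FALSE,
                            pathway_name = "pathway") {
  doc <- empty_document()
  doc$organisms <- std_organisms(1)
  doc$cell_locations <- std_locations("cytosol")
  doc$entities <- lapply(species, function(s) {
    list(id = paste0("ent_", s), name = s, entity_type = "et_metabolite",
         organism = NULL, synonyms = list())
  })
  doc$local_entities <- lapply(species, function(s) {
    list(id = paste0("le_", s), entity = paste0("ent_", s),
         location = "loc_cytosol")
  })
  steps <- Map(c, species[-length(species)], species[-1])
  if (close_cycle) {
    steps <- c(steps, list(c(species[length(species)], species[1])))
  }
  doc$interactions <- lapply(seq_along(steps), function(i) {
    st <- steps[[i]]
    list(id = sprintf("x%04d", i),
         interaction_type = "it_enzymatic_reaction", organism = NULL,
         participants = list(
           participant(paste0("le_", st[1]), "input"),
           participant(paste0("le_", st[2]), "output")))
  })
  doc$pathways <- list(list(
    id = "pw0001", name = pathway_name, organism = "org1",
    pathway_class = NULL,
    interactions = as.list(vapply(seq_along(steps),
                                  function(i) sprintf("x%04d", i),
                                  character(1)))))
  doc
}

fixture_chain <- function() {
  metabolite_path(c("A", "B", "C"), close_cycle = FALSE,
                  pathway_name = "linear chain")
}

fixture_cycle <- function() {
  metabolite_path(c("A", "B", "C"), close_cycle = TRUE,
                  pathway_name = "three-step cycle")
}

fixture_clutter <- function() {
  doc <- empty_document()
  doc$organisms <- std_organisms(1)
  doc$cell_locations <- std_locations(c("cytosol", "nucleus"))
  ents <- list()
  les <- list()
  add_species <- function(id, name, type, loc) {
    ents[[length(ents) + 1L]] <<- list(
      id = id, name = name, entity_type = type, organism = "org1",
      synonyms = list())
    les[[length(les) + 1L]] <<- list(
      id = paste0("le_", id), entity = id, location = paste0("loc_", loc))
  }
  for (i in 1:3) {
    add_species(sprintf("g%d", i), sprintf("gene %d", i), "et_gene",
                "nucleus")
    add_species(sprintf("rna%d", i), sprintf("mRNA %d", i), "et_RNA",
                "cytosol")
  }
  for (i in 1:2) {
    add_species(sprintf("p%d", i), sprintf("enzyme %d", i),
                "et_polypeptide", "cytosol")
  }
  for (i in 1:6) {
    add_species(sprintf("m%d", i), sprintf("metabolite %d", i),
                "et_metabolite", "cytosol")
  }
  doc$entities <- ents
  doc$local_entities <- les

  ixns <- list()
  # 5 enzymatic steps m1 -> ... -> m6, catalysed by the two enzymes
  for (i in 1:5) {
    ixns[[length(ixns) + 1L]] <- list(
      id = sprintf("enz%d", i),
      interaction_type = "it_enzymatic_reaction", organism = "org1",
      participants = list(
        participant(sprintf("le_m%d", i), "input"),
        participant(sprintf("le_m%d", i + 1L), "output"),
        participant(sprintf("le_p%d", (i %% 2L) + 1L), "modifier",
                    "catalysis")))
  }
  # 3 transcription events g_i -> rna_i
  for (i in 1:3) {
    ixns[[length(ixns) + 1L]] <- list(
      id = sprintf("tx%d", i), interaction_type = "it_transcription",
      organism = "org1",
      participants = list(
        participant(sprintf("le_g%d", i), "input"),
        participant(sprintf("le_rna%d", i), "output")))
  }
  # 2 translation events rna_i -> p_i
  for (i in 1:2) {
    ixns[[length(ixns) + 1L]] <- list(
      id = sprintf("tl%d", i), interaction_type = "it_translation",
      organism = "org1",
      participants = list(
        participant(sprintf("le_rna%d", i), "input"),
        participant(sprintf("le_p%d", i), "output")))
  }
  doc$interactions <- ixns
  doc$pathways <- list(list(
    id = "pw0001", name = "cluttered core pathway", organism = "org1",
    pathway_class = NULL,
    interactions = lapply(ixns, function(x) x$id)))
  doc
}

fixture_hormone_pair <- function() {
  doc <- empty_document()
  doc$organisms <- std_organisms(1)
  doc$cell_locations <- std_locations(c("cytosol", "nucleus"))
  doc$pathway_classes <- list(
    list(id = "pc_root", name = "plant metabolism", parent = NULL),
    list(id = "pc_hormone", name = "hormone metabolism and signalling",
         parent = "pc_root"))
  ents <- list()
  les <- list()
  add_species <- function(id, name, type, loc) {
    ents[[length(ents) + 1L]] <<- list(
      id = id, name = name, entity_type = type, organism = "org1",
      synonyms = list())
    les[[length(les) + 1L]] <<- list(
      id = paste0("le_", id), entity = id, location = paste0("loc_", loc))
  }
  for (i in 1:8) {
    add_species(sprintf("g%d", i), sprintf("hormone gene %d", i),
                "et_gene", "nucleus")
    add_species(sprintf("rna%d", i), sprintf("hormone mRNA %d", i),
                "et_RNA", "cytosol")
  }
  for (i in 1:6) {
    add_species(sprintf("m%d", i), sprintf("hormone intermediate %d", i),
                "et_metabolite", "cytosol")
  }
  doc$entities <- ents
  doc$local_entities <- les

  ixns <- list()
  for (i in 1:8) {  # one transcription interaction per gene, shared
    ixns[[length(ixns) + 1L]] <- list(
      id = sprintf("tx%d", i), interaction_type = "it_transcription",
      organism = "org1",
      participants = list(
        participant(sprintf("le_g%d", i), "input"),
        participant(sprintf("le_rna%d", i), "output")))
  }
  for (i in 1:5) {  # one enzymatic step per pathway
    ixns[[length(ixns) + 1L]] <- list(
      id = sprintf("enz%d", i),
      interaction_type = "it_enzymatic_reaction", organism = "org1",
      participants = list(
        participant(sprintf("le_m%d", i), "input"),
        participant(sprintf("le_m%d", i + 1L), "output")))
  }
  doc$interactions <- ixns

  gene_sets <- list(c(1, 2, 3), c(2, 3, 4), c(4, 5, 6), c(5, 6, 7),
                    c(6, 7, 8))
  names <- c("brassinosteroid biosynthesis", "brassinosteroid signalling",
             "auxin biosynthesis", "auxin signalling", "auxin transport")
  doc$pathways <- lapply(1:5, function(i) {
    list(id = sprintf("pw%04d", i), name = names[i], organism = "org1",
         pathway_class = "pc_hormone",
         interactions = c(lapply(gene_sets[[i]],
                                 function(g) sprintf("tx%d", g)),
                          list(sprintf("enz%d", i))))
  })
  doc
}

# --- serialization ------------------------------------------------------

#' Write a repository document to disk
#'
#' Serializes a document to pretty-printed UTF-8 JSON with LF line endings;
#' serialization is deterministic, so the same document always produces the
#' same bytes. Optionally writes a sidecar manifest
#' (`<path>.manifest.json`) with the document's declared layer counts.
#'
#' @param doc A repository document (from [builtin_fixture()],
#'   [generate_repository()] or built by hand).
#' @param path Output file path.
#' @param manifest Also write the sidecar manifest (default `FALSE`).
#' @return `path`, invisibly usable for chaining into [load_repository()].
#' @export
write_repository <- function(doc, path, manifest = FALSE) {
  counts <- attr(doc, "counts")
  attr(doc, "counts") <- NULL
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                           null = "null", digits = NA)
  writeLines(json, path, sep = "\n", useBytes = TRUE)
  if (isTRUE(manifest)) {
    if (is.null(counts)) counts <- document_counts(doc)
    jsonlite::write_json(counts, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

document_counts <- function(doc) {
  stats::setNames(lapply(PR_COLLECTIONS, function(k) length(doc[[k]])),
                  PR_COLLECTIONS)
}

# --- random generator ---------------------------------------------------

#' Parameters for the random repository generator
#'
#' Defaults emulate the described plant pathway database content: three
#' organisms (Arabidopsis, soybean, grapevine), the five-label entity
#' vocabulary and six-label interaction vocabulary, a two-level compartment
#' tree (cell plus organelles), and pathways of a handful of interactions
#' with a moderate regulatory fraction and gene reuse across pathways.
#'
#' @param seed Integer seed; same parameters and seed give byte-identical
#'   documents.
#' @param n_pathways Number of pathways (>= 1; default 20).
#' @param n_organisms Number of organisms (default 3).
#' @param interactions_per_pathway Inclusive integer range (default 4..8).
#' @param entity_type_mix Named proportions over the five entity types;
#'   must sum to 1.
#' @param regulatory_fraction Probability an interaction is drawn from the
#'   regulatory types (activation/inhibition; default 0.2).
#' @param overlap_rate Probability a pathway reuses a gene already used by
#'   another pathway (default 0.3); with a single pathway this is a no-op.
#' @param n_locations Compartment count including the root cell
#'   (default 6).
#' @return An object of class `pathrepo_fixture_params`.
#' @export
fixture_params <- function(seed, n_pathways = 20, n_organisms = 3,
                           interactions_per_pathway = c(4, 8),
                           entity_type_mix = c(
                             gene = 0.3, RNA = 0.2, polypeptide = 0.2,
                             protein_complex = 0.1, metabolite = 0.2),
                           regulatory_fraction = 0.2, overlap_rate = 0.3,
                           n_locations = 6) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop_usage("`seed` must be a single integer")
  }
  if (!is.numeric(n_pathways) || n_pathways < 1) {
    stop_usage("`n_pathways` must be >= 1")
  }
  if (!is.numeric(n_organisms) || n_organisms < 1) {
    stop_usage("`n_organisms` must be >= 1")
  }
  ipp <- as.integer(interactions_per_pathway)
  if (length(ipp) != 2L || ipp[1] < 1 || ipp[2] < ipp[1]) {
    stop_usage("`interactions_per_pathway` must be a range c(lo, hi)")
  }
  if (!setequal(names(entity_type_mix), PR_ENTITY_TYPE_LABELS) ||
      abs(sum(entity_type_mix) - 1) > 1e-8 || any(entity_type_mix < 0)) {
    stop_usage("`entity_type_mix` must be proportions over the five entity types summing to 1")
  }
  if (regulatory_fraction < 0 || regulatory_fraction > 1 ||
      overlap_rate < 0 || overlap_rate > 1) {
    stop_usage("fractions must lie in [0, 1]")
  }
  if (!is.numeric(n_locations) || n_locations < 2) {
    stop_usage("`n_locations` must be >= 2 (cell plus one organelle)")
  }
  structure(list(seed = as.integer(seed),
                 n_pathways = as.integer(n_pathways),
                 n_organisms = as.integer(n_organisms),
                 interactions_per_pathway = ipp,
                 entity_type_mix = entity_type_mix[PR_ENTITY_TYPE_LABELS],
                 regulatory_fraction = regulatory_fraction,
                 overlap_rate = overlap_rate,
                 n_locations = as.integer(n_locations)),
            class = "pathrepo_fixture_params")
}

#' Generate a random repository document
#'
#' Seeded, reproducible generator. Entities are created by drawing types
#' from `entity_type_mix`, so the empirical type distribution converges to
#' the requested mix; pathways are assembled interaction by interaction
#' with type-appropriate participants (transcription produces RNA from a
#' gene, translation produces a polypeptide from an RNA, enzymatic steps
#' convert metabolites under a catalyst, transport moves one metabolite
#' between compartments, regulatory interactions attach a regulator as a
#' modifier). Gene reuse across pathways is governed by `overlap_rate`.
#' The draw order is fixed; changing it is a breaking change.
#'
#' @param params A [fixture_params()] object.
#' @return A repository document with a `counts` attribute declaring layer
#'   counts (also written as a manifest by
#'   `write_repository(..., manifest = TRUE)`).
#' @export
generate_repository <- function(params) {
  if (!inherits(params, "pathrepo_fixture_params")) {
    stop_usage("`params` must come from fixture_params()")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(params$seed, kind = "Mersenne-Twister",
           sample.kind = "Rejection")

  n_org <- params$n_organisms
  organelles <- c(PR_ORGANELLE_POOL,
                  sprintf("compartment_%d", seq_len(max(
                    0L, params$n_locations - 1L - length(PR_ORGANELLE_POOL)))))
  organelles <- organelles[seq_len(params$n_locations - 1L)]
  organelle_locs <- paste0("loc_", organelles)

  st <- new.env(parent = emptyenv())
  st$entities <- list()
  st$free <- stats::setNames(vector("list", length(PR_ENTITY_TYPE_LABELS)),
                             PR_ENTITY_TYPE_LABELS)
  st$type_count <- stats::setNames(rep(0L, length(PR_ENTITY_TYPE_LABELS)),
                                   PR_ENTITY_TYPE_LABELS)
  st$local_entities <- list()
  st$le_index <- new.env(parent = emptyenv())  # "entity\rlocation" -> le id
  st$home <- new.env(parent = emptyenv())      # entity -> home location
  st$interactions <- list()
  st$gene_tx <- new.env(parent = emptyenv())   # gene -> transcription ixn id
  st$used_genes <- character(0)                # genes used by any pathway

  mix <- params$entity_type_mix
  create_entity <- function(type) {
    n <- length(st$entities) + 1L
    st$type_count[[type]] <- st$type_count[[type]] + 1L
    id <- sprintf("e%05d", n)
    org <- if (type == "metabolite") NULL else
      sprintf("org%d", sample.int(n_org, 1L))
    st$entities[[n]] <- list(
      id = id, name = sprintf("%s_%05d", type, st$type_count[[type]]),
      entity_type = paste0("et_", type), organism = org,
      synonyms = list())
    st$free[[type]] <- c(st$free[[type]], id)
    id
  }
  need_entity <- function(type) {
    while (length(st$free[[type]]) == 0L) {
      create_entity(sample(names(mix), 1L, prob = mix))
    }
    id <- st$free[[type]][1L]
    st$free[[type]] <- st$free[[type]][-1L]
    id
  }
  local_entity <- function(entity, location = NULL) {
    if (is.null(location)) {
      if (!exists(entity, envir = st$home, inherits = FALSE)) {
        assign(entity, sample(organelle_locs, 1L), envir = st$home)
      }
      location <- get(entity, envir = st$home)
    }
    key <- paste0(entity, "\r", location)
    if (!exists(key, envir = st$le_index, inherits = FALSE)) {
      n <- length(st$local_entities) + 1L
      id <- sprintf("le%05d", n)
      st$local_entities[[n]] <- list(id = id, entity = entity,
                                     location = location)
      assign(key, id, envir = st$le_index)
    }
    get(key, envir = st$le_index)
  }
  add_interaction <- function(type, organism, participants) {
    n <- length(st$interactions) + 1L
    id <- sprintf("x%05d", n)
    st$interactions[[n]] <- list(id = id,
                                 interaction_type = paste0("it_", type),
                                 organism = organism,
                                 participants = participants)
    id
  }

  classes <- list(
    list(id = "pc_root", name = "cellular processes", parent = NULL),
    list(id = "pc_metabolism", name = "metabolism", parent = "pc_root"),
    list(id = "pc_regulation", name = "regulation", parent = "pc_root"),
    list(id = "pc_transport", name = "transport processes",
         parent = "pc_root"))

  pathways <- vector("list", params$n_pathways)
  ipp <- params$interactions_per_pathway
  nonreg_types <- c("enzymatic_reaction", "transcription", "translation",
                    if (length(organelle_locs) >= 2L) "transport")

  for (pw_i in seq_len(params$n_pathways)) {
    organism <- sprintf("org%d", sample.int(n_org, 1L))
    pclass <- sample(c("pc_metabolism", "pc_regulation", "pc_transport"),
                     1L)
    n_ixn <- sample(seq(ipp[1], ipp[2]), 1L)
    pw_ixns <- character(0)
    pw_genes <- character(0)
    pw_mets <- character(0)      # metabolites produced in this pathway
    pw_rnas <- character(0)
    pw_prots <- character(0)

    for (k in seq_len(n_ixn)) {
      regulatory <- stats::runif(1) < params$regulatory_fraction
      type <- if (regulatory) sample(c("activation", "inhibition"), 1L)
              else sample(nonreg_types, 1L)
      iid <- NULL
      if (type == "transcription") {
        reusable <- setdiff(st$used_genes, pw_genes)
        if (length(reusable) > 0L &&
            stats::runif(1) < params$overlap_rate) {
          gene <- sample(reusable, 1L)
        } else {
          gene <- need_entity("gene")
        }
        pw_genes <- c(pw_genes, gene)
        st$used_genes <- union(st$used_genes, gene)
        if (exists(gene, envir = st$gene_tx, inherits = FALSE)) {
          iid <- get(gene, envir = st$gene_tx)  # shared interaction
        } else {
          rna <- need_entity("RNA")
          pw_rnas <- c(pw_rnas, rna)
          gene_loc <- if ("loc_nucleus" %in% organelle_locs) "loc_nucleus"
                      else NULL
          iid <- add_interaction("transcription", organism, list(
            participant(local_entity(gene, gene_loc), "input"),
            participant(local_entity(rna), "output")))
          assign(gene, iid, envir = st$gene_tx)
        }
      } else if (type == "translation") {
        rna <- if (length(pw_rnas) > 0L) pw_rnas[length(pw_rnas)]
               else need_entity("RNA")
        pw_rnas <- union(pw_rnas, rna)
        prot <- need_entity("polypeptide")
        pw_prots <- c(pw_prots, prot)
        iid <- add_interaction("translation", organism, list(
          participant(local_entity(rna), "input"),
          participant(local_entity(prot), "output")))
      } else if (type == "enzymatic_reaction") {
        n_in <- 1L + (stats::runif(1) < 0.5)
        ins <- character(0)
        for (z in seq_len(n_in)) {
          m <- if (length(pw_mets) > 0L && stats::runif(1) < 0.5) {
            sample(pw_mets, 1L)
          } else need_entity("metabolite")
          ins <- union(ins, m)
        }
        out <- need_entity("metabolite")
        pw_mets <- union(pw_mets, out)
        cat_type <- if (stats::runif(1) < 0.7) "polypeptide"
                    else "protein_complex"
        cat_ent <- if (cat_type == "polypeptide" &&
                       length(pw_prots) > 0L && stats::runif(1) < 0.5) {
          sample(pw_prots, 1L)
        } else need_entity(cat_type)
        parts <- c(
          lapply(ins, function(m) participant(local_entity(m), "input")),
          list(participant(local_entity(out), "output"),
               participant(local_entity(cat_ent), "modifier", "catalysis")))
        iid <- add_interaction("enzymatic_reaction", organism, parts)
      } else if (type == "transport") {
        m <- if (length(pw_mets) > 0L && stats::runif(1) < 0.5) {
          sample(pw_mets, 1L)
        } else need_entity("metabolite")
        locs <- sample(organelle_locs, 2L)
        iid <- add_interaction("transport", organism, list(
          participant(local_entity(m, locs[1]), "input"),
          participant(local_entity(m, locs[2]), "output")))
      } else {  # activation / inhibition
        reg_type <- sample(c("polypeptide", "protein_complex", "RNA"), 1L)
        reg <- need_entity(reg_type)
        target <- need_entity(sample(c("RNA", "metabolite"), 1L))
        iid <- add_interaction(type, organism, list(
          participant(local_entity(reg), "modifier", type),
          participant(local_entity(target), "output")))
      }
      pw_ixns <- union(pw_ixns, iid)
    }
    pathways[[pw_i]] <- list(
      id = sprintf("pw%04d", pw_i),
      name = sprintf("synthetic pathway %04d", pw_i),
      organism = organism, pathway_class = pclass,
      interactions = as.list(pw_ixns))
  }

  doc <- list(format_version = PR_FORMAT_VERSION,
              organisms = std_organisms(n_org),
              entity_types = std_entity_types(),
              interaction_types = std_interaction_types(),
              cell_locations = std_locations(organelles),
              pathway_classes = classes,
              entities = st$entities,
              local_entities = st$local_entities,
              interactions = st$interactions,
              pathways = pathways)
  attr(doc, "counts") <- document_counts(doc)
  doc
}
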