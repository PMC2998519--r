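# Loading, lazy access accounting, search, navigation and publication.

test_that("loading exposes layer counts matching the generator manifest", {
  repo <- fixture_repo("atp_localization")
  expect_equal(nrow(repo_entities(repo)), 1)
  expect_equal(nrow(repo_local_entities(repo)), 4)

  path <- tempfile(fileext = ".json")
  doc <- generate_repository(fixture_params(seed = 42, n_pathways = 5))
  write_repository(doc, path, manifest = TRUE)
  counts <- jsonlite::read_json(paste0(path, ".manifest.json"))
  repo <- load_repository(path)
  expect_equal(nrow(repo_entities(repo)), counts$entities)
  expect_equal(nrow(repo_local_entities(repo)), counts$local_entities)
  expect_equal(nrow(repo_interactions(repo)), counts$interactions)
  expect_equal(nrow(repo_pathways(repo)), counts$pathways)
})

test_that("header enumeration is free; collection access is counted once each", {
  rr <- random_repo(seed = 7, n_pathways = 6)
  repo <- rr$repo
  invisible(repo_pathways(repo)$name)
  invisible(repo_interactions(repo))
  invisible(repo_entities(repo))
  s <- access_stats(repo)
  expect_equal(s$participant_materializations, 0)
  expect_equal(s$interaction_list_materializations, 0)

  pids <- repo_pathways(repo)$id
  invisible(pathway_interactions(repo, pids[1]))
  expect_equal(access_stats(repo)$interaction_list_materializations, 1)
  # repeated access is memoized
  invisible(pathway_interactions(repo, pids[1]))
  expect_equal(access_stats(repo)$interaction_list_materializations, 1)
  for (pid in pids[2:4]) invisible(pathway_interactions(repo, pid))
  expect_equal(access_stats(repo)$interaction_list_materializations, 4)

  iids <- repo_interactions(repo)$id
  invisible(repo_interaction(repo, iids[1]))
  invisible(repo_interaction(repo, iids[1]))
  invisible(repo_interaction(repo, iids[2]))
  expect_equal(access_stats(repo)$participant_materializations, 2)
})

test_that("entity search matches criteria and a brute-force document scan", {
  repo <- fixture_repo("atp_localization")
  hit <- search_entities(repo, query_spec(name_pattern = "atp"))
  expect_equal(hit$id, "ent_atp")  # case-insensitive
  expect_equal(nrow(search_entities(
    repo, query_spec(name_pattern = "zzz-no-such"))), 0)
  # wildcard
  expect_equal(search_entities(repo, query_spec(name_pattern = "A*P"))$id,
               "ent_atp")
  # synonym matching is opt-in
  expect_equal(nrow(search_entities(
    repo, query_spec(name_pattern = "adenosine"))), 0)
  expect_equal(search_entities(
    repo, query_spec(name_pattern = "adenosine",
                     include_synonyms = TRUE))$id, "ent_atp")
  expect_error(search_entities(repo, query_spec(type = "et_bogus")),
               class = "pathrepo_vocab_error")
  expect_error(query_spec(), class = "pathrepo_usage_error")

  rr <- random_repo(seed = 42, n_pathways = 6)
  got <- search_entities(rr$repo, query_spec(type = "et_gene"))$id
  want <- vapply(rr$doc$entities, function(e) e$id, character(1))[
    vapply(rr$doc$entities, function(e) e$entity_type,
           character(1)) == "et_gene"]
  expect_setequal(got, want)
  # result ordering is deterministic: (name, id)
  names_got <- search_entities(rr$repo, query_spec(type = "et_gene"))$name
  expect_equal(names_got, sort(names_got))
})

test_that("location filter includes descendant compartments", {
  repo <- fixture_repo("atp_localization")
  # the root 'cell' has the four organelles as children
  got <- search_entities(repo, query_spec(location = "loc_cell"))
  expect_equal(got$id, "ent_atp")
  got <- search_entities(repo, query_spec(location = "loc_plastid"))
  expect_equal(got$id, "ent_atp")
})

test_that("pathway search honours name, organism and ontology class filters", {
  repo <- fixture_repo("hormone_pair")
  all_classified <- search_pathways(repo, class_filter = "pc_root")
  expect_equal(nrow(all_classified), 5)  # root covers all descendants
  aux <- search_pathways(repo, query_spec(name_pattern = "auxin"))
  expect_equal(nrow(aux), 3)
  expect_equal(nrow(search_pathways(
    repo, query_spec(name_pattern = "gibberellin"))), 0)
  expect_error(search_pathways(repo, class_filter = "pc_bogus"),
               class = "pathrepo_vocab_error")

  rr <- random_repo(seed = 42, n_pathways = 10)
  got <- search_pathways(rr$repo, query_spec(organism = "org1"))$id
  want <- vapply(rr$doc$pathways, function(p) p$id, character(1))[
    vapply(rr$doc$pathways, function(p) p$organism,
           character(1)) == "org1"]
  expect_setequal(got, want)
})

test_that("navigation is symmetric between pathways and entities", {
  rr <- random_repo(seed = 42, n_pathways = 8)
  repo <- rr$repo
  for (pid in repo_pathways(repo)$id) {
    ents <- entities_of_pathway(repo, pid)
    expect_equal(ents, oracle_entities_of(rr$doc,
                                          oracle_pathway_ixns(rr$doc, pid)))
    for (e in ents) {
      expect_true(pid %in% pathways_of_entity(repo, e))
    }
  }
  # converse + equality with the brute-force inverted index
  for (e in sample(repo_entities(repo)$id, 25)) {
    pids <- pathways_of_entity(repo, e)
    expect_equal(pids, oracle_pathways_of_entity(rr$doc, e))
    for (pid in pids) {
      expect_true(e %in% entities_of_pathway(repo, pid))
    }
  }
  expect_error(pathways_of_entity(repo, "nope"),
               class = "pathrepo_not_found_error")
})

test_that("interactions_of_entity spans compartments and matches inversion", {
  repo <- fixture_repo("atp_localization")
  expect_length(interactions_of_entity(repo, "ent_atp"), 4)

  rr <- random_repo(seed = 42, n_pathways = 6)
  le2e <- doc_le_entity(rr$doc)
  for (e in sample(repo_entities(rr$repo)$id, 20)) {
    want <- sort(vapply(rr$doc$interactions, function(x) x$id,
                        character(1))[
      vapply(rr$doc$interactions, function(x) {
        any(vapply(x$participants,
                   function(p) le2e[[p$local_entity]] == e, logical(1)))
      }, logical(1))])
    expect_equal(interactions_of_entity(rr$repo, e), want)
  }
  # isolated entity (free pool, participates nowhere)
  used <- unique(unname(le2e[vapply(
    unlist(lapply(rr$doc$interactions, function(x) x$participants),
           recursive = FALSE),
    function(p) p$local_entity, character(1))]))
  isolated <- setdiff(repo_entities(rr$repo)$id, used)
  if (length(isolated) > 0) {
    expect_equal(interactions_of_entity(rr$repo, isolated[1]), character(0))
  }
})

test_that("save_pathway appends, round-trips and rejects collisions", {
  rr <- random_repo(seed = 11, n_pathways = 4)
  repo <- rr$repo
  pids <- repo_pathways(repo)$id
  net <- network_from_pathways(repo, pids[1:2])
  before <- jsonlite::read_json(rr$path, simplifyVector = FALSE)

  pw <- save_pathway(repo, net, "merged view", "org1")
  expect_match(pw$id, "^pw")

  reloaded <- load_repository(rr$path)
  found <- search_pathways(reloaded, query_spec(name_pattern = "merged view"))
  expect_equal(found$id, pw$id)
  expect_equal(pathway_interactions(reloaded, pw$id), net$interactions)
  # union-of-entity-sets oracle for the merged pathway
  expect_equal(entities_of_pathway(reloaded, pw$id),
               sort(union(entities_of_pathway(reloaded, pids[1]),
                          entities_of_pathway(reloaded, pids[2]))))
  # pre-existing records byte-for-byte unchanged
  after <- jsonlite::read_json(rr$path, simplifyVector = FALSE)
  expect_identical(after$pathways[seq_along(before$pathways)],
                   before$pathways)
  expect_identical(after$interactions, before$interactions)
  expect_identical(after$entities, before$entities)

  # collisions and empty networks
  expect_error(save_pathway(reloaded, network_from_pathways(
    reloaded, pids[1]), "merged view", "org1"),
    class = "pathrepo_conflict_error")
  empty <- new_network(reloaded)
  expect_error(save_pathway(reloaded, empty, "nothing", "org1"),
               class = "pathrepo_usage_error")
  pw2 <- save_pathway(reloaded, empty, "nothing", "org1",
                      allow_empty = TRUE)
  expect_equal(pathway_interactions(load_repository(rr$path), pw2$id),
               character(0))
})

test_that("a load -> save-nothing cycle is idempotent on bytes", {
  rr <- random_repo(seed = 3, n_pathways = 3)
  bytes1 <- readBin(rr$path, "raw", file.size(rr$path))
  repo <- load_repository(rr$path)
  write_repository(repo$doc, rr$path)
  bytes2 <- readBin(rr$path, "raw", file.size(rr$path))
  expect_identical(bytes1, bytes2)
})
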