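# Network construction, set-algebra edits, filtering, endpoints,
# p-neighbourhoods, shared-gene matrices and membership queries.

test_that("network_from_pathways takes the duplicate-free union", {
  repo <- fixture_repo("hormone_pair")
  single <- network_from_pathways(repo, "pw0001")
  expect_equal(single$interactions, pathway_interactions(repo, "pw0001"))

  # pw0001 {tx1,tx2,tx3,enz1} and pw0002 {tx2,tx3,tx4,enz2} share 2
  both <- network_from_pathways(repo, c("pw0001", "pw0002"))
  expect_length(both$interactions, 4 + 4 - 2)

  # disjoint pathways: counts add
  disj <- network_from_pathways(repo, c("pw0001", "pw0003"))
  expect_length(disj$interactions, 8)
  expect_error(network_from_pathways(repo, "pw9999"),
               class = "pathrepo_not_found_error")
})

test_that("network_edit follows set semantics and replays a random script", {
  repo <- fixture_repo("hormone_pair")
  net <- network_from_pathways(repo, "pw0001")
  roundtrip <- network_edit(repo,
                            network_edit(repo, net, add = "enz3"),
                            remove = "enz3")
  expect_equal(roundtrip$interactions, net$interactions)
  expect_equal(network_edit(repo, net, add = "tx1")$interactions,
               net$interactions)  # duplicate add is a no-op
  expect_equal(network_edit(repo, net, remove = "enz5")$interactions,
               net$interactions)  # absent removal is a no-op
  expect_error(network_edit(repo, net, add = "x9999"),
               class = "pathrepo_integrity_error")

  rr <- random_repo(seed = 42, n_pathways = 5)
  all_ixns <- repo_interactions(rr$repo)$id
  net <- new_network(rr$repo)
  reference <- character(0)
  set.seed(123)
  for (step in 1:30) {
    add <- sample(all_ixns, sample(0:3, 1))
    remove <- sample(all_ixns, sample(0:3, 1))
    net <- network_edit(rr$repo, net, add = add, remove = remove)
    reference <- setdiff(union(reference, add), remove)
    expect_setequal(net$interactions, reference)
  }
})

test_that("filtering removes clutter, restricts to regulation, is idempotent", {
  repo <- fixture_repo("clutter")
  net <- network_from_pathways(repo, "pw0001")
  expect_length(net$interactions, 10)  # 5 enzymatic + 3 tx + 2 tl

  core <- filter_interactions(repo, net,
                              drop_types = c("transcription", "translation"))
  expect_length(core$interactions, 5)
  expect_length(net$interactions, 10)  # input untouched

  reg <- filter_interactions(repo, net, regulatory_only = TRUE)
  expect_length(reg$interactions, 0)  # no activation/inhibition present

  expect_error(filter_interactions(repo, net),
               class = "pathrepo_usage_error")
  expect_error(filter_interactions(repo, net, keep_types = "transcription",
                                   regulatory_only = TRUE),
               class = "pathrepo_usage_error")
  expect_error(filter_interactions(repo, net, keep_types = "binding"),
               class = "pathrepo_vocab_error")

  rr <- random_repo(seed = 42, n_pathways = 6)
  full <- network_from_pathways(rr$repo, repo_pathways(rr$repo)$id)
  types <- repo_interaction_types(rr$repo)
  keep <- c("enzymatic_reaction", "transport")
  once <- filter_interactions(rr$repo, full, keep_types = keep)
  twice <- filter_interactions(rr$repo, once, keep_types = keep)
  expect_equal(twice$interactions, once$interactions)
  # keep(T) agrees with drop(complement of T)
  dropped <- filter_interactions(rr$repo, full,
                                 drop_types = setdiff(types$label, keep))
  expect_equal(dropped$interactions, once$interactions)
  # regulatory_only keeps exactly the flagged types
  reg <- filter_interactions(rr$repo, full, regulatory_only = TRUE)
  reg_types <- types$id[types$is_regulatory]
  for (iid in reg$interactions) {
    expect_true(repo_interaction(rr$repo, iid)$interaction_type
                %in% reg_types)
  }
  byhand <- filter_interactions(rr$repo, full,
                                keep_types = types$label[types$is_regulatory])
  expect_equal(reg$interactions, byhand$interactions)
})

test_that("endpoints: chain gives ({A},{C}), cycle gives (empty, empty)", {
  chain <- fixture_repo("chain")
  ep <- endpoints(chain, "pw0001")
  expect_equal(ep$sources, "ent_A")
  expect_equal(ep$sinks, "ent_C")

  cyc <- fixture_repo("cycle")
  ep <- endpoints(cyc, "pw0001")
  expect_equal(ep$sources, character(0))
  expect_equal(ep$sinks, character(0))
})

test_that("modifier-only entities are excluded from sources and sinks", {
  repo <- fixture_repo("clutter")
  core <- filter_interactions(repo,
                              network_from_pathways(repo, "pw0001"),
                              keep_types = "enzymatic_reaction")
  ep <- endpoints(repo, core)
  expect_equal(ep$sources, "m1")
  expect_equal(ep$sinks, "m6")
  expect_false(any(c("p1", "p2") %in% c(ep$sources, ep$sinks)))
})

test_that("endpoints match the in/out tally oracle on random fixtures", {
  for (seed in 0:9) {
    rr <- random_repo(seed = seed, n_pathways = 4)
    net <- network_from_pathways(rr$repo, repo_pathways(rr$repo)$id)
    got <- endpoints(rr$repo, net)
    want <- oracle_endpoints(rr$doc, net$interactions)
    expect_equal(got$sources, want$sources)
    expect_equal(got$sinks, want$sinks)
    expect_length(intersect(got$sources, got$sinks), 0)
  }
})

test_that("endpoint union over entity-disjoint networks is componentwise", {
  chain <- builtin_fixture("chain")
  # second, disjoint chain D -> E -> F in the same document
  for (s in c("D", "E", "F")) {
    chain$entities <- c(chain$entities, list(list(
      id = paste0("ent_", s), name = s, entity_type = "et_metabolite",
      organism = NULL, synonyms = list())))
    chain$local_entities <- c(chain$local_entities, list(list(
      id = paste0("le_", s), entity = paste0("ent_", s),
      location = "loc_cytosol")))
  }
  steps <- list(c("D", "E"), c("E", "F"))
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    chain$interactions <- c(chain$interactions, list(list(
      id = sprintf("y%04d", i), interaction_type = "it_enzymatic_reaction",
      organism = NULL,
      participants = list(
        list(local_entity = paste0("le_", st[1]), role = "input",
             stoichiometry = 1),
        list(local_entity = paste0("le_", st[2]), role = "output",
             stoichiometry = 1)))))
  }
  repo <- load_repository(write_repository(chain,
                                           tempfile(fileext = ".json")))
  n1 <- new_network(repo, c("x0001", "x0002"))
  n2 <- new_network(repo, c("y0001", "y0002"))
  nu <- new_network(repo, c(n1$interactions, n2$interactions))
  e1 <- endpoints(repo, n1); e2 <- endpoints(repo, n2)
  eu <- endpoints(repo, nu)
  expect_equal(eu$sources, sort(union(e1$sources, e2$sources)))
  expect_equal(eu$sinks, sort(union(e1$sinks, e2$sinks)))
})

test_that("neighborhood expands by interaction steps on a chain", {
  # A -> B -> C via two reactions; seed A
  repo <- fixture_repo("chain")
  p1 <- neighborhood(repo, "ent_A", 1)
  expect_equal(p1$interactions, "x0001")
  p2 <- neighborhood(repo, "ent_A", 2)
  expect_equal(p2$interactions, c("x0001", "x0002"))
  expect_error(neighborhood(repo, "ent_A", 0),
               class = "pathrepo_usage_error")
  expect_error(neighborhood(repo, "ghost", 1),
               class = "pathrepo_not_found_error")
})

test_that("neighborhood equals the bipartite BFS oracle and is monotone", {
  rr <- random_repo(seed = 42, n_pathways = 5)
  ents <- sample(repo_entities(rr$repo)$id, 15)
  for (e in ents) {
    prev <- character(0)
    for (p in 1:3) {
      got <- neighborhood(rr$repo, e, p)$interactions
      expect_equal(got, oracle_neighborhood(rr$doc, e, p))
      expect_true(all(prev %in% got))  # monotone in p
      prev <- got
    }
  }
  # fixpoint: for large p the neighbourhood is the connected component
  n_ixn <- nrow(repo_interactions(rr$repo))
  e <- ents[1]
  comp <- neighborhood(rr$repo, e, n_ixn)$interactions
  expect_equal(neighborhood(rr$repo, e, n_ixn + 5)$interactions, comp)
})

test_that("shared-gene matrix matches the double-loop oracle", {
  repo <- fixture_repo("hormone_pair")
  pids <- repo_pathways(repo)$id
  m <- shared_gene_matrix(repo, pids)
  expect_equal(unname(diag(m$values)), rep(3L, 5))  # 3 genes each
  # gene sets {1,2,3},{2,3,4},... -> known overlaps
  expect_equal(m$values["pw0001", "pw0002"], 2L)
  expect_equal(m$values["pw0001", "pw0003"], 0L)
  expect_error(shared_gene_matrix(repo, c("pw0001", "pw0001")),
               class = "pathrepo_usage_error")

  one <- shared_gene_matrix(repo, "pw0001")
  expect_equal(unname(one$values), matrix(3L, 1, 1))

  rr <- random_repo(seed = 42, n_pathways = 20)
  pids <- repo_pathways(rr$repo)$id
  m <- shared_gene_matrix(rr$repo, pids)
  expect_equal(m$values, oracle_shared_matrix(rr$doc, pids))
})

test_that("shared-gene matrix is symmetric with dominant diagonal", {
  for (seed in 0:9) {
    rr <- random_repo(seed = seed, n_pathways = 6)
    m <- shared_gene_matrix(rr$repo, repo_pathways(rr$repo)$id)$values
    expect_identical(m, t(m))
    expect_true(all(m >= 0))
    d <- diag(m)
    expect_true(all(m <= outer(d, d, pmin)))
  }
})

test_that("zero overlap rate yields all-zero off-diagonal gene sharing", {
  rr <- random_repo(seed = 5, n_pathways = 10, overlap_rate = 0)
  m <- shared_gene_matrix(rr$repo, repo_pathways(rr$repo)$id)$values
  expect_true(all(m[upper.tri(m)] == 0))
})

test_that("entities_in_min_pathways counts pathway membership", {
  repo <- fixture_repo("hormone_pair")
  # g6 is in pathways 3, 4, 5; g1 only in pathway 1
  expect_equal(entities_in_min_pathways(repo, c("g1", "g6"), 2), "g6")
  expect_equal(entities_in_min_pathways(repo, c("g6", "g1"), 1),
               c("g6", "g1"))  # input order preserved
  expect_equal(entities_in_min_pathways(repo, c("g1", "g6"), 99),
               character(0))
  expect_error(entities_in_min_pathways(repo, "ghost", 1),
               class = "pathrepo_not_found_error")

  rr <- random_repo(seed = 42, n_pathways = 8)
  ents <- sample(repo_entities(rr$repo)$id, 30)
  got <- entities_in_min_pathways(rr$repo, ents, 2)
  want <- ents[vapply(ents, function(e) {
    length(oracle_pathways_of_entity(rr$doc, e)) >= 2
  }, logical(1))]
  expect_equal(got, want)
})

test_that("networks are scoped to their repository", {
  r1 <- fixture_repo("chain")
  r2 <- fixture_repo("chain")
  net <- network_from_pathways(r1, "pw0001")
  expect_error(filter_interactions(r2, net, regulatory_only = TRUE),
               class = "pathrepo_usage_error")
})
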