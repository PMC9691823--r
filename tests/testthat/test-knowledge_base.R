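test_that("packaged knowledge base loads with the expected panel structure", {
  kb <- panel_kb()
  g <- glance(kb)
  expect_equal(g$n_genes, 9L)
  expect_equal(g$n_systems, 11L)
  expect_equal(g$n_syndromes, 8L)
  expect_equal(length(unique(kb$features$system)), 11L)
  # exactly one X-linked gene
  expect_equal(sum(kb$genes$inheritance == "x_linked"), 1L)
  expect_equal(kb$genes$symbol[kb$genes$inheritance == "x_linked"], "OFD1")
  # cardiomyopathy is major for the Alstrom column only
  cardio <- dplyr::filter(kb$weights, feature_id == "cardiomyopathy")
  expect_equal(cardio$syndrome_id, "ALMS")
  expect_equal(cardio$weight, "major")
})

test_that("loading rejects degenerate and inconsistent configs", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_error(load_knowledge_base(empty), class = "revphen_validation_error")
  expect_error(load_knowledge_base(tempfile()), class = "revphen_io_error")

  # dangling syndrome reference
  kb_raw <- yaml::read_yaml(pkg_extdata("ciliopathy_kb.yaml"))
  kb_raw$genes[[1]]$syndromes <- list("NOT_A_SYNDROME")
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(kb_raw, bad)
  expect_error(load_knowledge_base(bad), "unknown syndrome")

  kb_raw <- yaml::read_yaml(pkg_extdata("ciliopathy_kb.yaml"))
  kb_raw$features[[1]]$system <- "Imaginary system"
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(kb_raw, bad2)
  expect_error(load_knowledge_base(bad2), "body-system")
})

test_that("knowledge base round-trips through serialisation", {
  kb <- panel_kb()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_knowledge_base(kb, path)
  expect_equal(load_knowledge_base(path), kb)
})

test_that("features_for_gene pools weights across syndromes, major wins", {
  kb <- panel_kb()
  cep <- features_for_gene(kb, "CEP290")
  # retinal dystrophy is minor in the syndromic-nephronophthisis and Joubert
  # columns but major via the LCA/EOSRD column: pooled weight is major
  expect_equal(cep$weight[cep$feature_id == "retinal_dystrophy"], "major")
  wdr <- features_for_gene(kb, "WDR34")
  expect_equal(wdr$weight[wdr$feature_id == "narrow_chest"], "major")
  # single-syndrome gene equals its column
  alms_col <- dplyr::filter(kb$weights, syndrome_id == "ALMS")
  alms <- features_for_gene(kb, "ALMS1")
  expect_setequal(alms$feature_id, alms_col$feature_id)
  expect_equal(
    alms$weight[match(alms_col$feature_id, alms$feature_id)],
    alms_col$weight
  )
  expect_error(features_for_gene(kb, "NOTAGENE"), "unknown gene")
})

test_that("footnoted gene restrictions apply per gene", {
  kb <- panel_kb()
  # Joubert renal involvement is footnote-restricted to NPHP1/CEP290;
  # OFD1 causes Joubert too but must not inherit that weight
  ofd1 <- features_for_gene(kb, "OFD1")
  # renal is major for OFD1 via its own syndrome column, not minor via JBTS
  expect_equal(ofd1$weight[ofd1$feature_id == "renal_abnormality"], "major")
  # retinal dystrophy (JBTS m, restricted) must be absent for OFD1 entirely
  expect_false("retinal_dystrophy" %in% ofd1$feature_id)
  # but present (minor) for NPHP1 via the same column
  nphp1 <- features_for_gene(kb, "NPHP1")
  expect_equal(nphp1$weight[nphp1$feature_id == "retinal_dystrophy"], "minor")
})

test_that("pooled weight is monotone when a syndrome is added to a gene", {
  kb <- panel_kb()
  weight_rank <- c(minor = 1, major = 2)
  for (g in kb$genes$symbol) {
    before <- features_for_gene(kb, g)
    kb2 <- kb
    i <- match(g, kb2$genes$symbol)
    extra <- setdiff(kb2$syndromes$syndrome_id, kb2$genes$syndromes[[i]])
    if (length(extra) == 0L) next
    kb2$genes$syndromes[[i]] <- c(kb2$genes$syndromes[[i]], extra[1])
    after <- features_for_gene(kb2, g)
    shared <- intersect(before$feature_id, after$feature_id)
    expect_true(all(
      weight_rank[after$weight[match(shared, after$feature_id)]] >=
        weight_rank[before$weight[match(shared, before$feature_id)]]
    ))
    expect_true(all(before$feature_id %in% after$feature_id))
  }
})

test_that("expand_hpo returns the descendant closure", {
  # toy DAG: root with 3 descendants (one nested)
  edges <- tibble::tibble(
    child = c("HP:0000002", "HP:0000003", "HP:0000004"),
    parent = c("HP:0000001", "HP:0000001", "HP:0000002")
  )
  obo <- read_obo(write_toy_obo(edges))
  expect_setequal(
    expand_hpo("HP:0000001", obo),
    c("HP:0000001", "HP:0000002", "HP:0000003", "HP:0000004")
  )
  # leaf term -> itself
  expect_equal(expand_hpo("HP:0000004", obo), "HP:0000004")
  # two linked terms with a shared descendant -> no duplicates
  out <- expand_hpo(c("HP:0000001", "HP:0000002"), obo)
  expect_equal(anyDuplicated(out), 0L)
  # absent term is an error
  expect_error(expand_hpo("HP:9999999", obo), "absent")
})

test_that("expand_hpo matches a brute-force transitive closure on random DAGs", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    n <- sample(20:100, 1)
    ids <- sprintf("HP:%07d", seq_len(n))
    # random DAG: each non-root picks parents among earlier terms
    edges <- dplyr::bind_rows(lapply(2:n, function(i) {
      k <- sample(1:2, 1)
      tibble::tibble(child = ids[i], parent = sample(ids[seq_len(i - 1)], min(k, i - 1)))
    }))
    obo <- read_obo(write_toy_obo(edges, extra_roots = ids[1]))
    for (q in sample(ids, 5)) {
      expect_setequal(expand_hpo(q, obo), brute_closure(edges, q))
    }
  }
})

test_that("feature closures contain their anchors and are closed downwards", {
  kb <- panel_kb()
  obo <- mini_ontology()
  closures <- feature_closures(kb, obo)
  edges <- obo$edges
  for (i in seq_len(nrow(kb$features))) {
    cl <- closures[[kb$features$feature_id[i]]]
    expect_true(all(unlist(kb$features$hpo_terms[[i]]) %in% cl))
    # closed under descendant relation
    expect_true(all(edges$child[edges$parent %in% cl] %in% cl))
  }
})
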