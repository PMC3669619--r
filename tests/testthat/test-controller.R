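# Source-tree selection and the end-to-end pipeline.

test_that("selection maximizes coverage with documented tie-breaks", {
  fx <- mammal_fixture()
  small <- read_newick(text = "((Homo_sapiens,Gallus_gallus),Danio_rerio);")
  cfg <- workflow_config(trees = list(mammals = fx$tree, verts = small),
                         resolution = "off")
  sel <- select_source_tree(cfg, c("Homo_sapiens", "Pan_troglodytes", "Mus_musculus"))
  expect_equal(sel$id, "mammals")
  expect_equal(sel$coverage, 3)

  # tie on coverage -> the smaller tree wins
  sel2 <- select_source_tree(cfg, "Homo_sapiens")
  expect_equal(sel2$id, "verts")

  # tie on coverage and size -> lexicographic id
  t1 <- read_newick(text = "(Homo_sapiens,Pan_troglodytes);")
  cfg3 <- workflow_config(trees = list(b = t1, a = t1), resolution = "off")
  expect_equal(select_source_tree(cfg3, "Homo_sapiens")$id, "a")

  expect_error(select_source_tree(cfg, c("Nope_nope")), "no suitable source tree")
})

test_that("selection equals the exhaustive argmax oracle", {
  set.seed(31)
  for (rep in 1:30) {
    trees <- lapply(1:4, function(i) random_tree(sample(5:25, 1),
                                                 seed = 1200 + rep * 10 + i))
    names(trees) <- paste0("t", 1:4)
    pool <- unique(unlist(lapply(trees, `[[`, "tip.label")))
    q <- sample(pool, min(8, length(pool)))
    sel <- select_source_tree(workflow_config(trees = trees, resolution = "off"), q)
    cov <- vapply(trees, function(t) sum(q %in% t$tip.label), integer(1))
    size <- vapply(trees, ape::Ntip, integer(1))
    o <- order(-cov, size, names(trees))[1]
    expect_equal(sel$id, names(trees)[o])
    expect_equal(sel$coverage, unname(cov[o]))
  }
})

test_that("a clean-name pipeline equals direct pruning", {
  fx <- mammal_fixture()
  cfg <- workflow_config(trees = list(mammals = fx$tree), resolution = "off")
  q <- c("Homo_sapiens", "Pan_troglodytes", "Mus_musculus")
  res <- run_pipeline(q, cfg)
  expect_identical(write_newick(res$tree),
                   write_newick(prune_tree(fx$tree, q)$tree))
  expect_identical(write_newick(res$tree),
                   "((Homo_sapiens,Pan_troglodytes),Mus_musculus);")
  expect_equal(res$provenance$source_tree$id, "mammals")
})

test_that("fuzzy resolution recovers a misspelled name end to end", {
  fx <- mammal_fixture()
  cfg <- workflow_config(trees = list(mammals = fx$tree),
                         taxonomies = fx$taxonomy, resolution = "fuzzy")
  res <- run_pipeline(c("Homo sapien", "Pan troglodytes", "Mus musculus"), cfg)
  expect_true("Homo_sapiens" %in% res$tree$tip.label)
  fixed <- Filter(function(r) r$submitted == "Homo sapien",
                  res$provenance$names$resolved)[[1]]
  expect_equal(fixed$matched, "Homo sapiens")
  expect_lt(fixed$score, 1)

  # strict policy drops what it cannot match exactly
  cfg2 <- workflow_config(trees = list(mammals = fx$tree),
                          taxonomies = fx$taxonomy, resolution = "strict")
  res2 <- run_pipeline(c("Homo sapien", "Pan troglodytes", "Mus musculus"), cfg2)
  expect_false("Homo_sapiens" %in% res2$tree$tip.label)
  expect_equal(unlist(res2$provenance$names$unresolved), "Homo sapien")
})

test_that("synonyms resolve to accepted names before pruning", {
  fx <- mammal_fixture()
  cfg <- workflow_config(trees = list(mammals = fx$tree),
                         taxonomies = fx$taxonomy, resolution = "fuzzy")
  res <- run_pipeline(c("Canis familiaris", "Felis catus", "Mus musculus"), cfg)
  expect_setequal(res$tree$tip.label,
                  c("Canis_lupus", "Felis_catus", "Mus_musculus"))
})

test_that("the name-conservation ledger balances on random runs", {
  schema <- system.file("schema", "provenance-record.json", package = "phylotastic")
  set.seed(77)
  for (rep in 1:60) {
    tr <- random_tree(sample(8:40, 1), seed = 1500 + rep, lengths = FALSE)
    tax <- random_taxonomy(ape::Ntip(tr), seed = 1500 + rep, tips = tr$tip.label)
    accepted <- paste(tax$Genus, tax$Species)
    q <- sample(accepted, sample(2:5, 1))
    q <- c(q,
           if (rep %% 2 == 0) corrupt_name(sample(setdiff(accepted, q), 1),
                                           1, seed = rep),
           if (rep %% 3 == 0) "Totally unknown")
    cfg <- workflow_config(trees = stats::setNames(list(tr), "t"),
                           taxonomies = tax,
                           resolution = ifelse(rep %% 2 == 0, "fuzzy", "strict"))
    res <- tryCatch(run_pipeline(q, cfg),
                    warning = function(w) suppressWarnings(run_pipeline(q, cfg)))
    lg <- res$provenance$ledger
    expect_identical(lg$submitted, length(q))
    expect_identical(lg$submitted, lg$kept + lg$unresolved)
    expect_identical(lg$kept, lg$in_tree + lg$not_in_source_tree)
    expect_identical(lg$in_tree, ape::Ntip(res$tree))
    inst <- jsonlite::fromJSON(emit_provenance(res), simplifyVector = FALSE)
    expect_true(isTRUE(validate_against_schema(inst, schema)))
  }
})

test_that("identical inputs give identical trees and provenance", {
  fx <- mammal_fixture()
  cfg <- workflow_config(trees = list(mammals = fx$tree),
                         taxonomies = fx$taxonomy, resolution = "fuzzy")
  q <- c("Homo sapien", "Pan troglodytes", "Mus musculus", "Bos taurus")
  r1 <- run_pipeline(q, cfg); r2 <- run_pipeline(q, cfg)
  expect_identical(write_newick(r1$tree), write_newick(r2$tree))
  p1 <- r1$provenance; p2 <- r2$provenance
  p1$timestamp <- p2$timestamp <- NULL
  expect_identical(p1, p2)
})

test_that("scaling stages plug into the pipeline", {
  fx <- mammal_fixture()
  tr <- fx$tree
  tr$node.label <- c("Root", rep("", tr$Nnode - 1))
  cfg <- workflow_config(trees = list(mammals = tr), resolution = "off",
                         scaling = "bladj",
                         calibrations = calibration_set(c(Root = 90)))
  # the pruned tree keeps the root label, so bladj can anchor there
  res <- run_pipeline(c("Homo_sapiens", "Mus_musculus", "Ornithorhynchus_anatinus"),
                      cfg)
  expect_equal(max(res$tree$node.age), 90)
  d <- node_depths(res$tree)[seq_len(3)]
  expect_equal(unname(d), rep(90, 3), tolerance = 1e-9)

  # datelife scaling pulls node ages from a chronogram store
  store <- build_chronogram_store(list(list(
    id = "primates", citation = "P 2010",
    trees = "((Homo_sapiens:7,Pan_troglodytes:7):83,Mus_musculus:90);")))
  cfg2 <- workflow_config(trees = list(mammals = fx$tree), resolution = "off",
                          scaling = "datelife", chronogram_store = store)
  res2 <- run_pipeline(c("Homo_sapiens", "Pan_troglodytes", "Mus_musculus"), cfg2)
  expect_equal(sort(unique(round(res2$tree$node.age, 6))), c(0, 7, 90))
})

test_that("stage errors carry the stage name", {
  fx <- mammal_fixture()
  cfg <- workflow_config(trees = list(mammals = fx$tree), resolution = "off")
  expect_error(run_pipeline(c("Nope_a", "Nope_b"), cfg), "\\[select\\]")
  expect_error(run_pipeline("Homo_sapiens", cfg, tree_id = "missing"),
               "\\[select\\]")
  expect_error(run_pipeline(character(0), cfg), "\\[resolve\\]")
})
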