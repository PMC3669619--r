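# Name resolution: three-technique matcher, fuzzy scoring, token API,
# meta-service aggregation.

test_that("taxonomy tables load with a synonym index", {
  fx <- mammal_fixture()
  tab <- fx$taxonomy
  syn <- attr(tab, "synonyms")
  expect_true(nrow(syn) >= 5)
  expect_true("Canis familiaris" %in% syn$name)

  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), f, row.names = FALSE)
  tab2 <- read_taxonomy_csv(f, "copy")
  expect_equal(nrow(tab2), nrow(tab))
  expect_true("Canis familiaris" %in% attr(tab2, "synonyms")$name)

  expect_error(as_taxonomy(data.frame(Genus = c("A", "A"),
                                      Species = c("b", "b")), "dup"),
               "duplicate")
})

test_that("the three matching techniques fire in order", {
  fx <- mammal_fixture()
  tab <- fx$taxonomy
  # (1) exact binomial in Genus + Species
  m1 <- match_msw3("Homo sapiens", tab)
  expect_equal(m1$technique, "exact")
  expect_identical(m1$score, 1.0)
  expect_equal(m1$matched, "Homo sapiens")
  expect_match(m1$uri, "^local:msw3-fixture/")
  # case/underscore-insensitive on input, canonical case out
  expect_equal(match_msw3("homo_sapiens", tab)$matched, "Homo sapiens")
  # (2) italic-tagged synonym elsewhere in the row
  m2 <- match_msw3("Canis familiaris", tab)
  expect_equal(m2$technique, "synonym")
  expect_equal(m2$matched, "Canis lupus")
  expect_lt(m2$score, 1)
  # (3) cross-field assembly: epithet in Species, other word only in the
  # Synonyms text of the same row
  m3 <- match_msw3("Simia troglodytes", tab)
  expect_equal(m3$technique, "synonym")   # full synonym string wins first
  m3b <- match_msw3("silvestris catus", tab)
  expect_equal(m3b$technique, "cross_field")
  expect_equal(m3b$matched, "Felis catus")
  # no hit -> empty
  expect_equal(nrow(match_msw3("Qqqq zzzz", tab)), 0)
})

test_that("fuzzy scores follow 1 - d/maxlen and the distance cutoff", {
  fx <- mammal_fixture()
  tab <- fx$taxonomy
  f <- fuzzy_match("Homo sapien", tab)
  expect_equal(f$matched[1], "Homo sapiens")
  expect_equal(f$score[1], 1 - 1 / 12)
  expect_identical(fuzzy_match("Homo sapiens", tab)$score[1], 1.0)
  expect_equal(nrow(fuzzy_match("Xxxxxxx yyyyyyy", tab)), 0)

  # against the DP edit-distance oracle on corrupted names
  set.seed(21)
  tab2 <- random_taxonomy(40, seed = 17)
  accepted <- paste(tab2$Genus, tab2$Species)
  for (rep in 1:150) {
    true <- sample(accepted, 1)
    nd <- sample(0:2, 1)
    bad <- corrupt_name(true, n_edits = nd, seed = 100 + rep)
    res <- fuzzy_match(bad, tab2)
    # score formula applies to the canonical (case/whitespace) forms
    bn <- oracle_norm(bad); tn <- oracle_norm(true)
    d_oracle <- oracle_levenshtein(bn, tn)
    if (d_oracle <= 2) {
      row <- res[res$matched == true, ]
      expect_equal(nrow(row), 1)
      expect_equal(row$score,
                   1 - d_oracle / max(nchar(bn), nchar(tn)),
                   tolerance = 1e-12)
    }
    expect_true(all(res$score >= 0 & res$score <= 1))
    expect_false(is.unsorted(rev(res$score)))
  }
})

test_that("one-edit corruptions are always recovered", {
  tab <- random_taxonomy(60, seed = 33)
  accepted <- paste(tab$Genus, tab$Species)
  for (rep in 1:120) {
    true <- accepted[1 + (rep %% length(accepted))]
    bad <- corrupt_name(true, n_edits = 1, seed = 500 + rep)
    res <- fuzzy_match(bad, tab)
    expect_true(true %in% res$matched)
  }
})

test_that("submit/retrieve implements the asynchronous token contract", {
  fx <- mammal_fixture()
  tab <- fx$taxonomy
  tok <- tnrs_submit("Homo sapiens\nPan troglodytes", tab)
  expect_equal(tnrs_status(tok), "pending")
  rep1 <- tnrs_retrieve(tok)
  expect_equal(tnrs_status(tok), "done")
  expect_equal(rep1$status, "done")
  expect_length(rep1$names, 2)
  expect_equal(rep1$names[[1]]$submittedName, "Homo sapiens")
  expect_identical(rep1$names[[1]]$matches$score, 1.0)

  # unmatched gibberish -> empty match list, still one group
  rep2 <- tnrs_retrieve(tnrs_submit("Qqqq zzzz", tab))
  expect_length(rep2$names, 1)
  expect_equal(nrow(rep2$names[[1]]$matches), 0)

  # distinct tokens for identical submissions
  toks <- replicate(50, tnrs_submit("Homo sapiens", tab))
  expect_equal(anyDuplicated(toks), 0)
  expect_error(tnrs_retrieve("tnrs-no-such"), "unknown token")
  expect_error(tnrs_submit("  \n ", tab), "no names")
})

test_that("the meta-service aggregates adaptors without merging", {
  fx <- mammal_fixture()
  tab1 <- fx$taxonomy
  # twin adaptor: same accepted name served by a second source
  tab2 <- as_taxonomy(data.frame(Genus = c("Homo", "Pongo"),
                                 Species = c("sapiens", "abelii")), "alt")
  rep <- tnrs_retrieve(tnrs_submit("Homo sapiens", list(tab1, tab2)))
  m <- rep$names[[1]]$matches
  expect_equal(nrow(m), 2)
  expect_setequal(m$source, c("msw3-fixture", "alt"))
  expect_equal(length(unique(m$uri)), 2)

  # order-invariance under adaptor permutation
  repB <- tnrs_retrieve(tnrs_submit("Homo sapiens", list(tab2, tab1)))
  expect_identical(rep$names[[1]]$matches, repB$names[[1]]$matches)

  # batching invariance: one job vs several
  one <- tnrs_retrieve(tnrs_submit("Homo sapiens\nMus musculus", tab1))
  sep1 <- tnrs_retrieve(tnrs_submit("Homo sapiens", tab1))
  sep2 <- tnrs_retrieve(tnrs_submit("Mus musculus", tab1))
  expect_identical(one$names[[1]]$matches, sep1$names[[1]]$matches)
  expect_identical(one$names[[2]]$matches, sep2$names[[1]]$matches)
})

test_that("reports serialize to the frozen JSON wire format", {
  schema <- system.file("schema", "tnrs-report.json", package = "phylotastic")
  fx <- mammal_fixture()
  rep <- tnrs_retrieve(tnrs_submit("Homo sapien\nCanis familiaris\nQqqq zzzz",
                                   fx$taxonomy, fuzzy = TRUE))
  js <- tnrs_report_json(rep)
  inst <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_true(isTRUE(validate_against_schema(inst, schema)))
  expect_equal(inst$status, "done")
  expect_length(inst$names, 3)
})

test_that("all scores stay inside [0, 1] across techniques", {
  tab <- random_taxonomy(50, seed = 41, synonym_fraction = 0.5)
  accepted <- paste(tab$Genus, tab$Species)
  syn <- attr(tab, "synonyms")$name
  queries <- c(accepted[1:10], syn[seq_len(min(5, length(syn)))],
               vapply(1:10, function(i) corrupt_name(accepted[i], 1, seed = i),
                      character(1)))
  for (q in queries) {
    res <- phylotastic:::match_name(q, tab, fuzzy = TRUE)
    if (nrow(res)) expect_true(all(res$score >= 0 & res$score <= 1))
    if (q %in% accepted) expect_identical(res$score, rep(1.0, nrow(res)))
  }
})
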