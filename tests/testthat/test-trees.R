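# Tree I/O, MRCA and patristic distances.

test_that("Newick parsing handles the basic grammar", {
  tr <- read_newick(text = "((Homo_sapiens,Pan_troglodytes),Mus_musculus);")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  expect_null(tr$edge.length)
  expect_setequal(tr$tip.label,
                  c("Homo_sapiens", "Pan_troglodytes", "Mus_musculus"))

  tr2 <- read_newick(text = "(A:1.0,B:2.0):0.0;")
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(sort(tr2$edge.length), c(1, 2))

  expect_equal(write_newick(read_newick(text = "A;")), "A;")

  # underscores are significant by default, convertible on request
  tr3 <- read_newick(text = "(Homo_sapiens,Mus_musculus);",
                     underscores_to_spaces = TRUE)
  expect_true("Homo sapiens" %in% tr3$tip.label)
})

test_that("absent branch lengths stay absent and distinct from zero", {
  tr <- read_newick(text = "((A:1,B):2,C:0);")
  len <- rep(NA_real_, 5)
  len[tr$edge[, 2]] <- tr$edge.length
  expect_true(is.na(len[match("B", tr$tip.label)]))
  expect_identical(len[match("C", tr$tip.label)], 0)
  # writer omits the suffix only for the absent one
  expect_equal(write_newick(tr), "((A:1,B):2,C:0);")
})

test_that("parse errors name the offending token or position", {
  expect_error(read_newick(text = "((A,B),C;"), "unclosed")
  expect_error(read_newick(text = "(A,B)),C;"), "position")
  expect_error(read_newick(text = "((A,B),A);"), "duplicate tip labels: A")
  expect_error(read_newick(text = "((A:-1,B),C);"), "negative")
  expect_error(read_newick(text = "((A:x,B),C);"), "branch length")
})

test_that("quoted labels and bracket comments are handled", {
  tr <- read_newick(text = "('Genus species'[note]:1,B:2)root;")
  expect_true("Genus species" %in% tr$tip.label)
  out <- write_newick(tr)
  expect_equal(out, "('Genus species':1,B:2)root;")
  expect_isomorphic(read_newick(text = out), tr)
})

test_that("write-parse round trip is the identity on random trees", {
  for (seed in 1:60) {
    tr <- random_tree(sample(2:40, 1), seed = seed,
                      lengths = seed %% 2 == 0,
                      polytomy_prob = ifelse(seed %% 3 == 0, 0.3, 0))
    s <- write_newick(tr)
    tr2 <- read_newick(text = s)
    expect_identical(write_newick(tr2), s)          # fixed point
    expect_setequal(tr2$tip.label, tr$tip.label)
    expect_isomorphic(tr2, tr)
    if (!is.null(tr$edge.length)) {
      expect_equal(patristic_matrix(tr2), patristic_matrix(tr), tolerance = 1e-9)
    }
  }
})

test_that("own parser agrees with the reference reader on plain trees", {
  for (seed in 1:25) {
    tr <- random_tree(sample(3:30, 1), seed = 1000 + seed)
    s <- write_newick(tr)
    ref <- ape::read.tree(text = s)
    expect_isomorphic(read_newick(text = s), ref)
  }
})

test_that("NEXUS TREES blocks parse, with and without TRANSLATE", {
  nex <- paste(
    "#NEXUS", "BEGIN TREES;",
    "  TRANSLATE", "    1 Homo_sapiens,", "    2 Pan_troglodytes,",
    "    3 Mus_musculus;",
    "  TREE t1 = ((1,2),3);",
    "  TREE t2 = ((1:1,3:1):1,2:2);",
    "END;", sep = "\n")
  trees <- read_nexus_trees(text = nex)
  expect_length(trees, 2)
  expect_isomorphic(trees$t1,
                    read_newick(text = "((Homo_sapiens,Pan_troglodytes),Mus_musculus);"))
  expect_error(read_nexus_trees(text = "#NEXUS\nBEGIN TAXA;\nEND;"),
               "no TREES block")

  # cross-format: writer's NEXUS output re-reads to the same trees
  tr <- random_tree(12, seed = 7)
  nex2 <- paste(write_nexus_trees(list(a = tr)), collapse = "\n")
  expect_isomorphic(read_nexus_trees(text = nex2)[[1]], tr)
})

test_that("mrca returns the deepest shared ancestor", {
  tr <- read_newick(text = "((A,B)ab,C)r;")
  expect_equal(mrca_node(tr, c("A", "B")), 5)   # the (A,B) node
  expect_equal(mrca_node(tr, c("A", "C")), 4)   # the root
  expect_equal(mrca_node(tr, "A"), which(tr$tip.label == "A"))
  expect_error(mrca_node(tr, c("A", "Z")), "Z")

  # against the brute-force root-path intersection oracle
  set.seed(11)
  for (rep in 1:60) {
    tr <- random_tree(sample(4:50, 1), seed = 2000 + rep)
    labels <- sample(tr$tip.label, sample(2:min(6, ape::Ntip(tr)), 1))
    expect_equal(mrca_node(tr, labels), oracle_mrca(tr, labels))
  }
})

test_that("patristic distances are path-length sums", {
  tr <- read_newick(text = "((A:2,B:2):3,C:5);")
  m <- patristic_matrix(tr)
  expect_equal(m["A", "B"], 4)
  expect_equal(m["A", "C"], 10)
  expect_equal(m["B", "C"], 10)
  expect_equal(diag(m), c(A = 0, B = 0, C = 0))
  expect_equal(m, t(m))

  expect_equal(patristic_matrix(read_newick(text = "A:3;"))[1, 1], 0)
  expect_error(patristic_matrix(read_newick(text = "((A:1,B):2,C:1);")),
               "missing branch length")

  # spot-check entries against the per-pair path-sum oracle
  for (rep in 1:15) {
    tr <- random_tree(sample(4:25, 1), seed = 3000 + rep)
    m <- patristic_matrix(tr)
    pair <- sample(tr$tip.label, 2)
    expect_equal(m[pair[1], pair[2]],
                 oracle_patristic_pair(tr, pair[1], pair[2]),
                 tolerance = 1e-9)
  }
})

test_that("patristic distances satisfy the four-point condition", {
  for (seed in c(21, 22, 23)) {
    tr <- random_tree(sample(8:12, 1), seed = seed)
    m <- patristic_matrix(tr)
    tips <- rownames(m)
    quartets <- utils::combn(tips, 4, simplify = FALSE)
    for (q in quartets) {
      s <- sort(c(m[q[1], q[2]] + m[q[3], q[4]],
                  m[q[1], q[3]] + m[q[2], q[4]],
                  m[q[1], q[4]] + m[q[2], q[3]]))
      expect_lte(s[3] - s[2], 1e-9)   # two largest sums are equal
    }
  }
})

test_that("ultrametric trees have equal tip depths", {
  for (seed in 31:40) {
    tr <- random_ultrametric_tree(sample(2:30, 1), seed = seed, age_root = 7)
    d <- node_depths(tr)[seq_len(ape::Ntip(tr))]
    expect_equal(max(d) - min(d), 0, tolerance = 1e-9)
    expect_equal(max(d), 7, tolerance = 1e-9)
    expect_true(isTRUE(is_ultrametric_tree(tr)))
    m <- patristic_matrix(tr)
    expect_equal(max(apply(m, 1, max)), min(apply(m, 1, max)), tolerance = 1e-9)
  }
  skewed <- read_newick(text = "((A:1,B:5):1,C:2);")
  ok <- is_ultrametric_tree(skewed)
  expect_false(isTRUE(ok))
  expect_equal(attr(ok, "deviating_tip"), "A")
})
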