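# Independent oracles used across the test suite.  These deliberately avoid
# the code paths they check: plain parent-array algorithms and dynamic
# programming, written for clarity, not speed.

# The matcher compares names case- and whitespace-insensitively; the score
# oracle has to apply the same canonical form.
oracle_norm <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(gsub("_", " ", x))))

# Levenshtein distance by textbook dynamic programming (oracle for the
# fuzzy-match scoring, which uses utils::adist internally).
oracle_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1L, length(b) + 1L)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (a[i] != b[j]))
  }
  d[length(a) + 1L, length(b) + 1L]
}

# MRCA as the deepest common element of naively collected root paths.
oracle_mrca <- function(tree, labels) {
  par <- integer(ape::Ntip(tree) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  root_path <- function(v) {
    p <- v
    while (par[v] != 0L) { v <- par[v]; p <- c(p, v) }
    p
  }
  paths <- lapply(match(labels, tree$tip.label), root_path)
  common <- Reduce(intersect, paths)
  common[1]   # paths are tipward->rootward, so the first shared node is deepest
}

# Patristic distance for one tip pair by summing edges along the two root
# paths below their MRCA.
oracle_patristic_pair <- function(tree, a, b) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n); len <- rep(NA_real_, n)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  len[tree$edge[, 2]] <- tree$edge.length
  m <- oracle_mrca(tree, c(a, b))
  up <- function(v) { s <- 0; while (v != m) { s <- s + len[v]; v <- par[v] }; s }
  up(match(a, tree$tip.label)) + up(match(b, tree$tip.label))
}

# Naive pruning by repeated leaf deletion followed by unifurcation collapse
# (edge lengths summed), on plain arrays; child order preserved from the
# source.  Returns a phylo via ape, not via the package's builder.
oracle_prune <- function(tree, keep_labels) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  par <- integer(n); len <- rep(NA_real_, n); rank <- numeric(n)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  if (!is.null(tree$edge.length)) len[tree$edge[, 2]] <- tree$edge.length
  cnt <- integer(n)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; cnt[p] <- cnt[p] + 1L; rank[tree$edge[k, 2]] <- cnt[p]
  }
  lab <- c(tree$tip.label,
           if (is.null(tree$node.label)) rep(NA, tree$Nnode) else tree$node.label)
  lab[!is.na(lab) & lab == ""] <- NA
  alive <- rep(TRUE, n)
  is_leaf <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode))
  nchild <- cnt
  # delete unwanted leaves one at a time; parents becoming childless follow
  queue <- setdiff(seq_len(ntip), match(keep_labels, tree$tip.label))
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (!alive[v]) next
    alive[v] <- FALSE
    p <- par[v]
    if (p != 0L) {
      nchild[p] <- nchild[p] - 1L
      if (nchild[p] == 0L) queue <- c(queue, p)
    }
  }
  # collapse unifurcations: splice the single child onto the grandparent,
  # summing the two edge lengths (collapsed node's label is discarded, the
  # child keeps its own).  A unifurcating root is spliced to its child.
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (v in which(alive & !is_leaf)) {
      if (nchild[v] != 1L) next
      child <- which(alive & par == v)
      alive[v] <- FALSE; changed <- TRUE
      par[child] <- par[v]
      rank[child] <- rank[v]
      len[child] <- if (par[v] == 0L) NA_real_
                    else if (is.na(len[v]) || is.na(len[child])) NA_real_
                    else len[v] + len[child]
    }
  }
  oroot <- which(alive & (par == 0L | !alive[pmax(par, 1L)]))[1]
  build_newick <- function(v) {
    kids <- which(alive & par == v)
    kids <- kids[order(rank[kids])]
    s <- if (length(kids)) {
      paste0("(", paste(vapply(kids, build_newick, character(1)), collapse = ","),
             ")", if (!is.na(lab[v]) && !is_leaf[v]) lab[v] else "")
    } else lab[v]
    if (!is.na(len[v]) && v != oroot) {
      s <- paste0(s, ":", format(len[v], digits = 15, scientific = FALSE))
    }
    s
  }
  phylotastic::read_newick(text = paste0(build_newick(oroot), ";"))
}

# order-insensitive canonical Newick: children sorted by their smallest tip
# label, lengths rounded; used to compare trees for isomorphism
canonical_newick <- function(tree, digits = 9) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  lab <- c(tree$tip.label, rep(NA, tree$Nnode))
  len <- rep(NA_real_, n)
  if (!is.null(tree$edge.length)) len[tree$edge[, 2]] <- tree$edge.length
  kids <- vector("list", n)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; kids[[p]] <- c(kids[[p]], tree$edge[k, 2])
  }
  rec <- function(v) {
    if (v <= ntip) {
      key <- lab[v]; s <- lab[v]
    } else {
      sub <- lapply(kids[[v]], rec)
      keys <- vapply(sub, `[[`, character(1), "key")
      o <- order(keys)
      s <- paste0("(", paste(vapply(sub[o], `[[`, character(1), "s"), collapse = ","), ")")
      key <- keys[o][1]
    }
    if (!is.na(len[v])) s <- paste0(s, ":", round(len[v], digits))
    list(key = key, s = s)
  }
  if (ntip == 1 && tree$Nnode == 1) return(paste0(tree$tip.label, ";"))
  paste0(rec(ntip + 1L)$s, ";")
}

expect_isomorphic <- function(a, b) {
  testthat::expect_identical(canonical_newick(a), canonical_newick(b))
}
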