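# Internal helpers shared across modules.

# Shortest-ish decimal serialization for branch lengths and ages: up to 15
# significant digits, never scientific notation (Newick consumers vary in
# what they accept), trailing zeros trimmed.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (grepl("\\.", s)) s <- sub("0+$", "", sub("\\.$", "", sub("(\\.\\d*?)0+$", "\\1", s)))
    s <- sub("\\.$", "", s)
    s
  }, character(1))
  out
}

# Case-insensitive, underscore/space-insensitive canonical form used wherever
# taxon names are compared across components (tips vs taxonomy vs queries).
norm_name <- function(x) {
  x <- gsub("_", " ", x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  tolower(x)
}

# Tip-label form of a taxon name (Newick-friendly).
underscore_name <- function(x) gsub("[[:space:]]+", "_", trimws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# parent[i] for every node of a phylo (0 for the root); edge lengths indexed
# by child node (NA when the tree carries no lengths).
tree_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

tree_child_lengths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  len <- rep(NA_real_, n)
  if (!is.null(tree$edge.length)) {
    el <- tree$edge.length
    el[is.nan(el)] <- NA_real_
    len[tree$edge[, 2]] <- el
  }
  len
}

# Rank of each node among its siblings, in the tree's stored (edge-matrix)
# child order; root gets rank 1.  This is what makes pruning deterministic.
tree_child_ranks <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  rank <- integer(n)
  rank[tree$root %||% (ape::Ntip(tree) + 1L)] <- 1L
  cnt <- integer(n)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    cnt[p] <- cnt[p] + 1L
    rank[tree$edge[k, 2]] <- cnt[p]
  }
  rank
}

# Label of every node (tips then internals), NA where unlabeled.
tree_node_labels <- function(tree) {
  ntip <- ape::Ntip(tree)
  lab <- c(tree$tip.label, if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode) else tree$node.label)
  lab[!is.na(lab) & lab == ""] <- NA_character_
  lab
}

root_node <- function(tree) ape::Ntip(tree) + 1L

# Assemble a phylo from parent pointers over an arbitrary node id space.
#
# ids:     integer identifiers (any values, unique)
# parent:  parent id per node, 0/NA for the single root
# label:   character labels (NA allowed on internals; tips must be labeled)
# length:  edge length to parent (NA = absent)
# is_tip:  logical
# ord:     numeric sort key ordering children within a parent
build_phylo <- function(ids, parent, label, length, is_tip, ord) {
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  idx <- match(parent, ids)             # parent position, NA for root
  roots <- which(is.na(idx) | parent %in% c(0L, NA))
  if (length(roots) != 1L) stop("internal error: build_phylo needs exactly one root")
  kids <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  kids <- lapply(kids, function(k) k[order(ord[k])])

  ntip <- sum(is_tip)
  if (ntip == 1L && n == 1L) {
    # degenerate single-tip tree: represent as root + one tip edge
    tr <- structure(list(
      edge = matrix(c(2L, 1L), nrow = 1),
      tip.label = label[1],
      Nnode = 1L
    ), class = "phylo", order = "cladewise")
    if (!is.na(length[1])) tr$edge.length <- length[1]
    return(tr)
  }

  # preorder DFS assigning ape numbering: tips 1..ntip in encounter order,
  # internals ntip+1.. in preorder
  num <- integer(n)
  tip_ct <- 0L; int_ct <- 0L
  edge_from <- integer(n - 1L); edge_to <- integer(n - 1L); edge_len <- rep(NA_real_, n - 1L)
  e <- 0L
  stack <- roots
  order_visit <- integer(n); ov <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ov <- ov + 1L; order_visit[ov] <- v
    if (is_tip[v]) { tip_ct <- tip_ct + 1L; num[v] <- tip_ct }
    else { int_ct <- int_ct + 1L; num[v] <- ntip + int_ct }
    ch <- kids[[as.character(v)]]
    if (!is.null(ch) && length(ch)) stack <- c(stack, rev(ch))
  }
  for (v in order_visit) {
    if (is.na(idx[v]) || v %in% roots) next
    e <- e + 1L
    edge_from[e] <- num[idx[v]]; edge_to[e] <- num[v]; edge_len[e] <- length[v]
  }
  # edges in preorder of the child
  o <- order(match(edge_to, num[order_visit]))
  tip_lab <- character(ntip); node_lab <- rep(NA_character_, n - ntip)
  for (v in seq_len(n)) {
    if (is_tip[v]) tip_lab[num[v]] <- label[v] else node_lab[num[v] - ntip] <- label[v]
  }
  tr <- structure(list(
    edge = cbind(edge_from[o], edge_to[o]),
    tip.label = tip_lab,
    Nnode = n - ntip
  ), class = "phylo", order = "cladewise")
  if (any(!is.na(edge_len))) tr$edge.length <- edge_len[o]
  if (any(!is.na(node_lab))) {
    node_lab[is.na(node_lab)] <- ""
    tr$node.label <- node_lab
  }
  tr
}
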