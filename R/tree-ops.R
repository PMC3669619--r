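#' Most recent common ancestor of a set of tips
#'
#' Returns the deepest node ancestral to all named tips.  For a single label
#' the MRCA is the tip itself.
#'
#' @param tree a `phylo` object.
#' @param labels character vector of tip labels (at least one).
#' @return the node number of the MRCA (tips are `1..Ntip`, internals
#'   `Ntip+1..`).
#' @examples
#' tr <- read_newick(text = "((A,B),C);")
#' mrca_node(tr, c("A", "B"))   # the (A,B) node
#' mrca_node(tr, c("A", "C"))   # the root
#' @export
mrca_node <- function(tree, labels) {
  labels <- unique(labels)
  if (!length(labels)) stop("at least one tip label required")
  miss <- setdiff(labels, tree$tip.label)
  if (length(miss)) {
    stop("tip labels not in tree: ", paste(miss, collapse = ", "))
  }
  if (length(labels) == 1L) return(match(labels, tree$tip.label))
  ape::getMRCA(tree, labels)
}

#' Patristic distance matrix
#'
#' Tip-to-tip path-length matrix (sums of branch lengths through the MRCA).
#' All branch lengths must be present; rows and columns are sorted
#' alphabetically by tip label for a deterministic layout.
#'
#' @param tree a `phylo` object with complete branch lengths.
#' @return a symmetric labeled numeric matrix with zero diagonal.
#' @examples
#' tr <- read_newick(text = "((A:2,B:2):3,C:5);")
#' patristic_matrix(tr)["A", "C"]   # 10
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  len <- tree_child_lengths(tree)
  present <- rep(FALSE, length(len)); present[tree$edge[, 2]] <- TRUE
  bad <- which(present & is.na(len))
  if (length(bad)) {
    lab <- tree_node_labels(tree)[bad[1]]
    stop("missing branch length on edge to ",
         if (is.na(lab)) paste("node", bad[1]) else lab)
  }
  if (ape::Ntip(tree) == 1L) {
    m <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(m)
  }
  m <- ape::cophenetic.phylo(tree)
  o <- order(rownames(m))
  m[o, o, drop = FALSE]
}

#' Depth of every node below the root
#'
#' Sum of branch lengths from the root to each node; missing lengths
#' propagate as `NA`.
#'
#' @param tree a `phylo` object.
#' @return numeric vector indexed by node number.
#' @export
node_depths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  len <- tree_child_lengths(tree)
  depth <- rep(NA_real_, n)
  depth[root_node(tree)] <- 0
  for (k in seq_len(nrow(tree$edge))) {   # edges are in preorder
    depth[tree$edge[k, 2]] <- depth[tree$edge[k, 1]] + len[tree$edge[k, 2]]
  }
  depth
}

#' Test whether a tree is ultrametric
#'
#' A tree is ultrametric (a chronogram) when all root-to-tip path lengths
#' are equal within `tol`.
#'
#' @param tree a `phylo` object with complete branch lengths.
#' @param tol absolute tolerance; default `1e-6` times the maximum depth.
#' @return `TRUE`/`FALSE` with attribute `"deviating_tip"` naming the worst
#'   tip when `FALSE`.
#' @export
is_ultrametric_tree <- function(tree, tol = NULL) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  if (anyNA(d)) stop("missing branch lengths; cannot assess ultrametricity")
  if (is.null(tol)) tol <- 1e-6 * max(d)
  dev <- abs(d - max(d))
  ok <- max(dev) <= tol + 1e-15
  if (!ok) attr(ok, "deviating_tip") <- tree$tip.label[which.max(dev)]
  ok
}
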