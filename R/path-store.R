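#' Build the taxon-to-root path index for a tree
#'
#' Denormalizes a (mega)tree into one record per tip holding the ordered
#' chain of ancestors with the length of each traversed edge.  Pruning then
#' never touches the full tree again: a query is answered from the union of
#' the selected tips' paths.  The index preserves each node's stored child
#' rank so pruned trees come out in the source tree's child order.
#'
#' @param tree a `phylo` object with uniquely labeled tips.
#' @param tree_name identifier stored with the index (defaults to
#'   `"unnamed"`).
#' @return an object of class `path_store` with components `tree_name`,
#'   `tips`, `tip_paths` (per tip: integer ancestor ids and numeric edge
#'   lengths, tipward to rootward), `node_labels`, `child_rank`, `root`,
#'   `tip_ids` and `tip_count`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' ps <- build_path_store(tr, "demo")
#' ps$tip_paths[["A"]]
#' @seealso [prune()], [write_path_store()]
#' @export
build_path_store <- function(tree, tree_name = "unnamed") {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  par <- tree_parents(tree)
  len <- tree_child_lengths(tree)
  paths <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    nodes <- integer(0); lens <- numeric(0)
    v <- i
    while (par[v] != 0L) {
      nodes <- c(nodes, par[v]); lens <- c(lens, len[v])
      v <- par[v]
    }
    paths[[i]] <- list(nodes = nodes, lens = lens)
  }
  names(paths) <- tree$tip.label
  structure(list(
    tree_name = tree_name,
    tips = tree$tip.label,
    tip_ids = stats::setNames(seq_len(ntip), tree$tip.label),
    tip_paths = paths,
    node_labels = tree_node_labels(tree),
    child_rank = tree_child_ranks(tree),
    root = root_node(tree),
    n_nodes = ntip + tree$Nnode,
    tip_count = ntip,
    version = "1"
  ), class = "path_store")
}

#' @export
print.path_store <- function(x, ...) {
  cat("Taxon-to-root path store \"", x$tree_name, "\": ", x$tip_count,
      " tips, ", x$n_nodes, " nodes (format v", x$version, ")\n", sep = "")
  invisible(x)
}

#' Serialize a path store to a text file
#'
#' Versioned tab-separated format, one line per tip:
#' `P<TAB>tip<TAB>node:len|node:len|...` (empty `len` means unknown), plus
#' `N` lines recording each node's child rank and optional label.  A store
#' written, re-read and written again is byte-identical.
#'
#' @param store a `path_store`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_path_store <- function(store, file) {
  stopifnot(inherits(store, "path_store"))
  hdr <- c("#phylotastic-pathstore\tv1",
           paste0("#tree_name\t", store$tree_name),
           paste0("#root\t", store$root),
           paste0("#n_nodes\t", store$n_nodes))
  nl <- vapply(seq_len(store$n_nodes), function(v) {
    lab <- store$node_labels[v]
    paste("N", v, store$child_rank[v], if (is.na(lab)) "" else lab, sep = "\t")
  }, character(1))
  pl <- vapply(seq_along(store$tips), function(i) {
    p <- store$tip_paths[[i]]
    lens <- fmt_num(p$lens); lens[is.na(lens)] <- ""
    paste("P", store$tips[i], store$tip_ids[i],
          paste(paste0(p$nodes, ":", lens), collapse = "|"), sep = "\t")
  }, character(1))
  writeLines(c(hdr, nl, pl), file)
  invisible(file)
}

#' Read a serialized path store
#'
#' @param file path written by [write_path_store()].
#' @return a `path_store`.
#' @export
read_path_store <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#phylotastic-pathstore")) {
    stop("not a path-store file: ", file)
  }
  hget <- function(key) {
    ln <- lines[startsWith(lines, paste0("#", key, "\t"))][1]
    sub(paste0("^#", key, "\t"), "", ln)
  }
  tree_name <- hget("tree_name")
  root <- as.integer(hget("root"))
  n_nodes <- as.integer(hget("n_nodes"))
  node_labels <- rep(NA_character_, n_nodes)
  child_rank <- integer(n_nodes)
  tips <- character(0); tip_ids <- integer(0); tip_paths <- list()
  for (ln in lines[!startsWith(lines, "#")]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "N") {
      v <- as.integer(f[2])
      child_rank[v] <- as.integer(f[3])
      if (length(f) >= 4 && nzchar(f[4])) node_labels[v] <- f[4]
    } else if (f[1] == "P") {
      tips <- c(tips, f[2]); tip_ids <- c(tip_ids, as.integer(f[3]))
      segs <- strsplit(f[4], "|", fixed = TRUE)[[1]]
      parts <- strsplit(segs, ":", fixed = TRUE)
      nodes <- as.integer(vapply(parts, `[`, character(1), 1))
      lens <- vapply(parts, function(p) {
        if (length(p) < 2 || !nzchar(p[2])) NA_real_ else as.numeric(p[2])
      }, numeric(1))
      tip_paths[[f[2]]] <- list(nodes = nodes, lens = lens)
    }
  }
  structure(list(
    tree_name = tree_name, tips = tips,
    tip_ids = stats::setNames(tip_ids, tips),
    tip_paths = tip_paths, node_labels = node_labels,
    child_rank = child_rank, root = root, n_nodes = n_nodes,
    tip_count = length(tips), version = "1"
  ), class = "path_store")
}

#' Rebuild the full source tree from a path store
#'
#' @param store a `path_store`.
#' @return a `phylo` isomorphic (and child-order identical) to the source.
#' @export
path_store_tree <- function(store) {
  prune(store, store$tips)$tree
}

#' Prune a megatree to a set of tips via its path store
#'
#' Collects the queried tips' taxon-to-root paths, takes the union of their
#' node sets, rebuilds the induced tree and suppresses unifurcations
#' (summing the collapsed edge lengths), so patristic distances among
#' retained tips equal those in the source tree.  Work scales with the
#' number of queried tips and their path depths, not with the size of the
#' source tree.
#'
#' Labels that match internal node labels are not expanded to their
#' subtrees; they are reported under `internal_matches` (higher-taxon
#' handling is the grafter's concern).  Internal labels of collapsed nodes
#' are discarded; retained nodes keep their own labels.
#'
#' @param store a `path_store` built by [build_path_store()].
#' @param labels character vector of tip labels to retain.
#' @return an object of class `phylotastic_prune`: a list with `tree` (the
#'   pruned `phylo`), `found`, `not_found` and `internal_matches`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' pr <- prune(build_path_store(tr), c("A", "C"))
#' write_newick(pr$tree)   # "(A:2,C:2);"
#' @export
prune <- function(store, labels) {
  stopifnot(inherits(store, "path_store"))
  labels <- unique(labels)
  found <- labels[labels %in% store$tips]
  rest <- setdiff(labels, found)
  internal_hits <- rest[norm_name(rest) %in%
                          norm_name(store$node_labels[-store$tip_ids][
                            !is.na(store$node_labels[-store$tip_ids])])]
  not_found <- setdiff(rest, internal_hits)
  if (!length(found)) stop("no taxa found in source tree \"", store$tree_name, "\"")
  if (length(found) == 1L) {
    warning("only one queried taxon found in \"", store$tree_name,
            "\"; returning a single-tip tree")
    tr <- build_phylo(ids = 1L, parent = 0L, label = found,
                      length = NA_real_, is_tip = TRUE, ord = 1)
    return(structure(list(tree = tr, found = found, not_found = not_found,
                          internal_matches = internal_hits),
                     class = "phylotastic_prune"))
  }

  tip_ids <- store$tip_ids[found]
  # union of edges, keyed by child node (each child has a unique parent)
  par_u <- integer(store$n_nodes)   # 0 = not in union / root
  len_u <- rep(NA_real_, store$n_nodes)
  in_union <- rep(FALSE, store$n_nodes)
  for (i in seq_along(found)) {
    p <- store$tip_paths[[found[i]]]
    chain <- c(tip_ids[i], p$nodes)
    k <- 1L
    while (k < length(chain)) {
      ch <- chain[k]
      if (in_union[ch]) break   # rest of this path already recorded
      in_union[ch] <- TRUE
      par_u[ch] <- chain[k + 1L]
      len_u[ch] <- p$lens[k]
      k <- k + 1L
    }
    in_union[chain[length(chain)]] <- TRUE
  }
  # children-in-union count per node
  cnt <- tabulate(par_u[par_u > 0L], nbins = store$n_nodes)
  retained <- which((seq_len(store$n_nodes) %in% tip_ids) | cnt >= 2L)
  is_tip_r <- retained %in% tip_ids

  # pruned parent of each retained node = nearest retained strict ancestor;
  # sum collapsed edge lengths; remember the direct child of that ancestor
  # on the chain (its source child rank orders siblings deterministically)
  keep <- rep(FALSE, store$n_nodes); keep[retained] <- TRUE
  par_p <- integer(length(retained))
  len_p <- rep(NA_real_, length(retained))
  ord_p <- numeric(length(retained))
  has_any_len <- any(!is.na(len_u[in_union & par_u > 0L]))
  for (j in seq_along(retained)) {
    v <- retained[j]
    if (par_u[v] == 0L) { par_p[j] <- 0L; ord_p[j] <- 1; next }
    tot <- len_u[v]; u <- par_u[v]; below <- v
    while (u != 0L && !keep[u]) {
      below <- u
      tot <- tot + len_u[u]
      u <- par_u[u]
    }
    if (u == 0L) { par_p[j] <- 0L; ord_p[j] <- 1 }
    else { par_p[j] <- u; len_p[j] <- tot; ord_p[j] <- store$child_rank[below] }
  }
  if (!has_any_len) len_p[] <- NA_real_
  lab_r <- store$node_labels[retained]
  tr <- build_phylo(ids = retained, parent = par_p, label = lab_r,
                    length = len_p, is_tip = is_tip_r, ord = ord_p)
  structure(list(tree = tr, found = found, not_found = not_found,
                 internal_matches = internal_hits),
            class = "phylotastic_prune")
}

#' @export
print.phylotastic_prune <- function(x, ...) {
  cat("Pruned tree with", ape::Ntip(x$tree), "tips;",
      length(x$not_found), "label(s) not found,",
      length(x$internal_matches), "matched internal labels only\n")
  invisible(x)
}

#' One-shot pruning of a tree
#'
#' Convenience wrapper composing [build_path_store()] and [prune()] for a
#' single query against an in-memory tree.
#'
#' @inheritParams build_path_store
#' @inheritParams prune
#' @return as [prune()].
#' @export
prune_tree <- function(tree, labels, tree_name = "unnamed") {
  prune(build_path_store(tree, tree_name), labels)
}
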