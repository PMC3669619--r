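#' Parse a slash-delimited taxonomic derivation
#'
#' Taxonomic derivations name a taxon together with its higher taxa, most
#' inclusive first, e.g. `"rosales/rosaceae/prunus/Prunus persica"`.  The
#' last element is the terminal taxon to place.
#'
#' @param text a nonempty slash-delimited string.
#' @return an object of class `taxon_path` with components `ranks`
#'   (whitespace-trimmed, case preserved) and `terminal`.
#' @export
parse_taxon_path <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("taxonomic path must be a nonempty string")
  }
  ranks <- trimws(strsplit(text, "/", fixed = TRUE)[[1]])
  if (any(!nzchar(ranks))) {
    stop("taxonomic path format error: empty segment in \"", text, "\"")
  }
  structure(list(ranks = ranks, terminal = ranks[length(ranks)]),
            class = "taxon_path")
}

#' Format a taxonomic path back to its slash-delimited form
#' @param path a `taxon_path`.
#' @return the slash-delimited string.
#' @export
format_taxon_path <- function(path) paste(path$ranks, collapse = "/")

#' @export
print.taxon_path <- function(x, ...) {
  cat("<taxon_path> ", format_taxon_path(x), "\n", sep = "")
  invisible(x)
}

#' Graft missing taxa onto a tree taxonomically
#'
#' Phylomatic-style placement: each path's terminal taxon, when absent from
#' the tree, is attached as a new child of the node labeled with the
#' least-inclusive higher rank present in the tree (genus before family
#' before order).  Matching is case-insensitive and exact (fuzzy matching
#' belongs to name resolution, upstream).  Placement is resolved against
#' the original tree for every path, so the result does not depend on the
#' order of the input paths; taxa attached to the same node are added in
#' alphabetical order after the existing children.
#'
#' New edges carry no branch length (unknown, not zero) — lengths are the
#' scaling step's job.  Attaching to a node that is currently a tip converts
#' it into an internal node that keeps its label, with the original taxon
#' retained as a same-named child tip.  A bare binomial path (length 1)
#' falls back to matching its genus word against tree labels.
#'
#' If several tree nodes share the matched rank label the placement is
#' ambiguous and an error is raised rather than guessing.
#'
#' @param tree a `phylo`; tips and internal nodes may carry taxon labels at
#'   any rank.
#' @param paths a list of `taxon_path` objects (or slash-delimited strings).
#' @return an object of class `phylotastic_graft`: list with `tree` (the
#'   grafted `phylo`) and `report`, a tibble with columns `taxon`, `status`
#'   (`"placed"`, `"already_present"` or `"unplaceable"`) and `attached_to`.
#' @examples
#' tr <- read_newick(text = "(A,(B,C)GenusX);")
#' g <- graft(tr, list("FamY/GenusX/GenusX spD"))
#' write_newick(g$tree)   # "(A,(B,C,GenusX_spD)GenusX);"
#' @export
graft <- function(tree, paths) {
  validate_tree(tree)
  paths <- lapply(paths, function(p) if (inherits(p, "taxon_path")) p else parse_taxon_path(p))
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  labs <- tree_node_labels(tree)
  nlabs <- norm_name(labs)
  ntips_norm <- norm_name(tree$tip.label)

  taxon <- character(0); status <- character(0); attach_node <- integer(0)
  for (p in paths) {
    term <- p$terminal
    if (norm_name(term) %in% ntips_norm) {
      taxon <- c(taxon, term); status <- c(status, "already_present")
      attach_node <- c(attach_node, NA_integer_); next
    }
    cands <- rev(p$ranks[-length(p$ranks)])
    if (!length(cands)) {
      words <- strsplit(trimws(gsub("_", " ", term)), " ")[[1]]
      if (length(words) >= 2) cands <- words[1]
    }
    node <- NA_integer_
    for (rk in cands) {
      hit <- which(!is.na(nlabs) & nlabs == norm_name(rk))
      if (length(hit) > 1) {
        stop("ambiguous graft point: ", length(hit), " tree nodes are labeled \"",
             rk, "\" for taxon \"", term, "\"")
      }
      if (length(hit) == 1) { node <- hit; break }
    }
    taxon <- c(taxon, term)
    if (is.na(node)) {
      status <- c(status, "unplaceable"); attach_node <- c(attach_node, NA_integer_)
    } else {
      status <- c(status, "placed"); attach_node <- c(attach_node, node)
    }
  }

  placed <- which(status == "placed")
  out_tree <- tree
  if (length(placed)) {
    par <- tree_parents(tree)
    len <- tree_child_lengths(tree)
    rank <- tree_child_ranks(tree)
    ids <- seq_len(n)
    is_tip <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode))
    label <- labs
    # new tips appended after existing children, alphabetically within a node
    ord <- as.numeric(rank)
    new_id <- n
    for (v in unique(attach_node[placed])) {
      terms <- sort(unique(taxon[placed][attach_node[placed] == v]))
      if (is_tip[v]) {
        # tip -> internal: re-add the original taxon as a same-named child
        is_tip[v] <- FALSE
        new_id <- new_id + 1L
        ids <- c(ids, new_id); par <- c(par, v); len <- c(len, NA_real_)
        label <- c(label, label[v]); is_tip <- c(is_tip, TRUE); ord <- c(ord, 0)
      }
      for (k in seq_along(terms)) {
        new_id <- new_id + 1L
        ids <- c(ids, new_id); par <- c(par, v); len <- c(len, NA_real_)
        label <- c(label, underscore_name(terms[k])); is_tip <- c(is_tip, TRUE)
        ord <- c(ord, max(rank) + k)
      }
    }
    out_tree <- build_phylo(ids, par, label, len, is_tip, ord)
  }

  report <- tibble::tibble(
    taxon = taxon,
    status = status,
    attached_to = ifelse(is.na(attach_node), NA_character_, labs[attach_node])
  )
  structure(list(tree = out_tree, report = report), class = "phylotastic_graft")
}

#' @export
print.phylotastic_graft <- function(x, ...) {
  tb <- table(factor(x$report$status,
                     levels = c("placed", "already_present", "unplaceable")))
  cat("Grafted tree with", ape::Ntip(x$tree), "tips:",
      tb[["placed"]], "placed,", tb[["already_present"]], "already present,",
      tb[["unplaceable"]], "unplaceable\n")
  invisible(x)
}
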