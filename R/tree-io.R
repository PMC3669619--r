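#' Read a Newick tree
#'
#' Parses a single rooted Newick statement into an [ape::phylo] object, with
#' stricter validation than a plain parser: unbalanced parentheses are
#' reported with their character position, duplicate tip labels and negative
#' branch lengths are hard errors (tip labels are the join key of the whole
#' system), and square-bracket comments are skipped.  Quoted labels are
#' supported and the quotes removed.  Underscores are significant characters
#' and are NOT turned into spaces unless asked: `"Homo_sapiens"` stays
#' `"Homo_sapiens"`.
#'
#' Branch lengths that are absent in the input stay absent (`NA`), which is
#' distinct from an explicit zero: absent means unknown.
#'
#' @param file path to a file containing one Newick statement.
#' @param text the Newick string itself (overrides `file`).
#' @param underscores_to_spaces replace underscores in labels by spaces
#'   (default `FALSE`).
#' @return an object of class `phylo`, rooted at the outermost Newick node.
#' @examples
#' tr <- read_newick(text = "((Homo_sapiens,Pan_troglodytes),Mus_musculus);")
#' ape::Ntip(tr)
#' @seealso [write_newick()], [read_nexus_trees()]
#' @export
read_newick <- function(file = NULL, text = NULL, underscores_to_spaces = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `file` or `text`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text)) stop("empty Newick input")
  prep <- newick_preprocess(text)
  text <- prep$text
  check_newick_balance(text)
  if (!grepl(";", text, fixed = TRUE)) stop("Newick parse error: missing terminating \";\"")

  tr <- parse_newick_prepared(text)
  tr <- restore_quoted_labels(tr, prep$quoted)
  tr <- normalize_phylo(tr)
  if (underscores_to_spaces) {
    tr$tip.label <- gsub("_", " ", tr$tip.label)
    if (!is.null(tr$node.label)) tr$node.label <- gsub("_", " ", tr$node.label)
  }
  validate_tree(tr)
  tr
}

# strip [] comments and protect quoted labels with placeholder tokens
newick_preprocess <- function(text) {
  quoted <- character(0)
  if (grepl("'", text, fixed = TRUE)) {
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    out <- character(length(chars)); oi <- 0L
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "'") {
        j <- i + 1L; buf <- character(0)
        repeat {
          if (j > length(chars)) stop("Newick parse error: unterminated quoted label starting at position ", i)
          if (chars[j] == "'") {
            if (j < length(chars) && chars[j + 1L] == "'") { buf <- c(buf, "'"); j <- j + 2L }
            else { j <- j + 1L; break }
          } else { buf <- c(buf, chars[j]); j <- j + 1L }
        }
        quoted <- c(quoted, paste(buf, collapse = ""))
        tok <- sprintf("QUOTEDLBL%04dX", length(quoted))
        for (ch in strsplit(tok, "")[[1]]) { oi <- oi + 1L; out[oi] <- ch }
        i <- j
      } else { oi <- oi + 1L; out[oi] <- chars[i]; i <- i + 1L }
    }
    text <- paste(out[seq_len(oi)], collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text)
  list(text = text, quoted = quoted)
}

check_newick_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  bad <- which(depth < 0)
  if (length(bad)) {
    stop("Newick parse error: unbalanced \")\" at position ", bad[1])
  }
  if (depth[length(depth)] != 0) {
    stop("Newick parse error: ", depth[length(depth)],
         " unclosed \"(\" (first at position ", which(chars == "(")[1], ")")
  }
  invisible(TRUE)
}

# Tokenizing Newick parser.  A dedicated parser (rather than a generic
# library reader) keeps the error contract precise and handles the full
# grammar this toolkit needs: per-edge absent lengths, unifurcating chains
# (used by age-calibration examples), single-leaf statements, and internal
# labels bound to the correct node.
parse_newick_prepared <- function(text) {
  body <- trimws(sub(";.*$", "", text))
  if (!grepl("(", body, fixed = TRUE)) {
    # degenerate single-tip statement, e.g. "A;" or "A:1.5;"
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    lab <- trimws(parts[1])
    if (!nzchar(lab)) stop("Newick parse error: empty label in \"", text, "\"")
    len <- if (length(parts) > 1) as.numeric(parts[2]) else NA_real_
    return(build_phylo(ids = 1L, parent = 0L, label = lab, length = len,
                       is_tip = TRUE, ord = 1))
  }
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  is_special <- chars %in% c("(", ")", ",", ":")
  start_new <- is_special | c(TRUE, is_special[-length(is_special)])
  toks <- vapply(split(chars, cumsum(start_new)), paste, character(1), collapse = "")
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]

  ntok <- length(toks)
  par <- integer(ntok); lab <- rep(NA_character_, ntok)
  len <- rep(NA_real_, ntok); is_tip <- logical(ntok); ord <- numeric(ntok)
  child_count <- integer(ntok)
  stack <- integer(ntok); sp <- 0L
  n <- 0L; last <- 0L; expect_len <- FALSE

  new_node <- function(tip) {
    n <<- n + 1L
    p <- if (sp > 0L) stack[sp] else 0L
    par[n] <<- p
    if (p > 0L) { child_count[p] <<- child_count[p] + 1L; ord[n] <<- child_count[p] }
    else ord[n] <<- 1
    is_tip[n] <<- tip
    n
  }
  for (k in seq_len(ntok)) {
    tk <- toks[k]
    if (tk == "(") {
      v <- new_node(FALSE); sp <- sp + 1L; stack[sp] <- v; last <- 0L
    } else if (tk == ")") {
      last <- stack[sp]; sp <- sp - 1L
    } else if (tk == ",") {
      last <- 0L
    } else if (tk == ":") {
      if (last == 0L) stop("Newick parse error: \":\" with no preceding node (token ", k, ")")
      expect_len <- TRUE
    } else if (expect_len) {
      v <- suppressWarnings(as.numeric(tk))
      if (is.na(v)) stop("Newick parse error: invalid branch length \"", tk, "\" (token ", k, ")")
      len[last] <- v; expect_len <- FALSE
    } else if (last != 0L && !is_tip[last] && is.na(lab[last])) {
      lab[last] <- tk                     # internal label bound at its ")"
    } else if (last != 0L) {
      stop("Newick parse error: unexpected token \"", tk, "\" after a complete node")
    } else {
      last <- new_node(TRUE); lab[last] <- tk
    }
  }
  if (any(is_tip[seq_len(n)] & is.na(lab[seq_len(n)]))) {
    stop("Newick parse error: unlabeled tip")
  }
  build_phylo(ids = seq_len(n), parent = par[seq_len(n)], label = lab[seq_len(n)],
              length = len[seq_len(n)], is_tip = is_tip[seq_len(n)],
              ord = ord[seq_len(n)])
}

restore_quoted_labels <- function(tr, quoted) {
  if (!length(quoted)) return(tr)
  fix <- function(lab) {
    for (k in seq_along(quoted)) {
      lab <- gsub(sprintf("QUOTEDLBL%04dX", k), quoted[k], lab, fixed = TRUE)
    }
    lab
  }
  tr$tip.label <- fix(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- fix(tr$node.label)
  tr
}

# NaN lengths (ape's marker for "no length on this edge") -> NA; drop the
# whole edge.length vector when no edge carries a length
normalize_phylo <- function(tr) {
  if (!is.null(tr$edge.length)) {
    tr$edge.length[is.nan(tr$edge.length)] <- NA_real_
    if (all(is.na(tr$edge.length))) tr$edge.length <- NULL
  }
  if (!is.null(tr$node.label) && all(is.na(tr$node.label) | tr$node.label == "")) {
    tr$node.label <- NULL
  }
  tr
}

#' Validate the structural invariants of a tree
#'
#' Checks that a `phylo` object is a rooted tree usable by the rest of the
#' toolkit: exactly one root, unique non-empty tip labels, and finite
#' non-negative branch lengths where lengths are present.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  kids <- tabulate(tree$edge[, 1], nbins = n)
  pars <- tabulate(tree$edge[, 2], nbins = n)
  if (any(pars > 1)) stop("invalid tree: node ", which(pars > 1)[1], " has multiple parents")
  roots <- which(pars == 0)
  if (length(roots) != 1) stop("invalid tree: ", length(roots), " roots found")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(is.na(tree$tip.label) | tree$tip.label == "")) {
    stop("unlabeled tip: node ", which(is.na(tree$tip.label) | tree$tip.label == "")[1])
  }
  if (!is.null(tree$edge.length)) {
    el <- tree$edge.length
    bad <- which(!is.na(el) & (el < 0 | is.infinite(el)))
    if (length(bad)) {
      child <- tree$edge[bad[1], 2]
      lab <- tree_node_labels(tree)[child]
      stop("negative or non-finite branch length ", el[bad[1]], " on edge to ",
           if (is.na(lab)) paste("node", child) else lab)
    }
  }
  invisible(tree)
}

#' Write a tree as a Newick string
#'
#' Deterministic serializer: children appear in the tree's stored order,
#' labels containing Newick metacharacters are single-quoted, numbers are
#' printed in plain decimal notation, and edges with unknown (absent) length
#' get no `:length` suffix at all.  `write_newick(read_newick(x)) == x` for
#' canonical input, and write-parse-write is a fixed point.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is written there.
#' @param include_lengths emit branch lengths (default `TRUE`; lengths absent
#'   from the tree are never invented).
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, include_lengths = TRUE) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  lab <- tree_node_labels(tree)
  len <- tree_child_lengths(tree)
  if (!include_lengths) len[] <- NA_real_

  quote_lab <- function(x) {
    if (is.na(x)) return("")
    if (grepl("[][ ():;,']", x)) paste0("'", gsub("'", "''", x), "'") else x
  }
  piece <- function(v) {
    s <- node_str[v]
    if (!is.na(len[v])) s <- paste0(s, ":", fmt_num(len[v]))
    s
  }

  if (ntip == 1 && tree$Nnode == 1 && is.null(tree$node.label)) {
    # degenerate single-tip tree serializes as a bare label
    s <- quote_lab(tree$tip.label[1])
    if (!is.na(len[1])) s <- paste0(s, ":", fmt_num(len[1]))
    s <- paste0(s, ";")
    if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
    return(s)
  }

  kids <- vector("list", n)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2])
  }
  node_str <- character(n)
  # postorder: internal nodes in reverse preorder have all children ready
  pre <- unique(tree$edge[, 1])           # internal nodes in preorder
  for (v in seq_len(ntip)) node_str[v] <- quote_lab(lab[v])
  for (v in rev(pre)) {
    node_str[v] <- paste0("(", paste(vapply(kids[[v]], piece, character(1)), collapse = ","),
                          ")", quote_lab(lab[v]))
  }
  root <- root_node(tree)
  s <- paste0(node_str[root], ";")
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

#' Read trees from a NEXUS TREES block
#'
#' Reads every `TREE` statement of a NEXUS document's TREES block, resolving
#' an optional TRANSLATE table to the real labels.  Each tree is validated as
#' in [read_newick()].
#'
#' @param file path to a NEXUS file.
#' @param text the NEXUS document as a string (overrides `file`).
#' @param underscores_to_spaces as in [read_newick()].
#' @return a named list of `phylo` objects, one per TREE statement.
#' @export
read_nexus_trees <- function(file = NULL, text = NULL, underscores_to_spaces = FALSE) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".nex")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
  }
  if (is.null(file)) stop("supply `file` or `text`")
  doc <- paste(readLines(file, warn = FALSE), collapse = "\n")
  if (!grepl("begin\\s+trees", doc, ignore.case = TRUE)) {
    stop("NEXUS format error: no TREES block found")
  }
  trees <- tryCatch(ape::read.nexus(file),
                    error = function(e) stop("NEXUS parse error: ", conditionMessage(e)))
  if (inherits(trees, "phylo")) {
    nm <- attr(trees, "name")
    nm <- if (is.character(nm) && length(nm) == 1 && nzchar(nm)) nm else "tree_1"
    trees <- stats::setNames(list(trees), nm)
  }
  out <- lapply(trees, function(tr) {
    tr <- normalize_phylo(tr)
    if (underscores_to_spaces) {
      tr$tip.label <- gsub("_", " ", tr$tip.label)
      if (!is.null(tr$node.label)) tr$node.label <- gsub("_", " ", tr$node.label)
    }
    validate_tree(tr)
    tr
  })
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    names(out) <- paste0("tree_", seq_along(out))
  }
  out
}

#' Write trees as a minimal NEXUS TREES block
#'
#' @param trees a `phylo` or list of `phylo` objects.
#' @param file optional output path.
#' @param include_lengths as in [write_newick()].
#' @return the NEXUS document as a character vector of lines.
#' @export
write_nexus_trees <- function(trees, file = NULL, include_lengths = TRUE) {
  if (inherits(trees, "phylo")) trees <- list(tree_1 = trees)
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    names(trees) <- paste0("tree_", seq_along(trees))
  }
  lines <- c("#NEXUS", "BEGIN TREES;")
  for (nm in names(trees)) {
    lines <- c(lines, paste0("  TREE ", nm, " = ",
                             write_newick(trees[[nm]], include_lengths = include_lengths)))
  }
  lines <- c(lines, "END;")
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}
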