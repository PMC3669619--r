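# The end-to-end workflow: dirty names -> name resolution -> source-tree
# selection by coverage -> (optional graft) -> prune -> age scaling ->
# annotated tree plus a provenance record.

#' Configure a phylotastic workflow
#'
#' @param trees named list registering the source trees; each entry is a
#'   `phylo`, a Newick file path, or `list(tree=|path=, citation=)`.
#' @param taxonomies a `taxonomy_table` or list of them backing name
#'   resolution (optional; without them resolution is a pass-through).
#' @param resolution name-resolution policy: `"strict"` (exact matches
#'   only; ambiguity drops the name with a warning), `"fuzzy"` (edit
#'   distance <= 2 fallback; the highest score wins, ties broken
#'   alphabetically and flagged), or `"off"`.
#' @param scaling `"none"`, `"bladj"` or `"datelife"`.
#' @param calibrations a `calibration_set` or calibration file path
#'   (required for `scaling = "bladj"`).
#' @param chronogram_store a `chronogram_store` or store directory
#'   (required for `scaling = "datelife"`).
#' @param graft_paths optional list of `taxon_path` objects or
#'   slash-delimited strings used to graft taxa missing from the selected
#'   source tree before pruning.
#' @return an object of class `workflow_config`.
#' @export
workflow_config <- function(trees, taxonomies = NULL,
                            resolution = c("strict", "fuzzy", "off"),
                            scaling = c("none", "bladj", "datelife"),
                            calibrations = NULL, chronogram_store = NULL,
                            graft_paths = NULL) {
  resolution <- match.arg(resolution)
  scaling <- match.arg(scaling)
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    stop("registered trees must be named")
  }
  if (anyDuplicated(names(trees))) stop("registered tree names must be unique")
  trees <- lapply(trees, function(t) {
    if (inherits(t, "phylo")) list(tree = t, citation = "unknown")
    else if (is.character(t)) list(path = t, citation = "unknown")
    else t
  })
  if (!is.null(taxonomies) && inherits(taxonomies, "taxonomy_table")) {
    taxonomies <- list(taxonomies)
  }
  if (scaling == "bladj") {
    if (is.null(calibrations)) stop("scaling \"bladj\" needs `calibrations`")
    if (is.character(calibrations)) calibrations <- read_calibrations(calibrations)
  }
  if (scaling == "datelife") {
    if (is.null(chronogram_store)) stop("scaling \"datelife\" needs `chronogram_store`")
    if (is.character(chronogram_store)) chronogram_store <- read_chronogram_store(chronogram_store)
  }
  structure(list(trees = trees, taxonomies = taxonomies,
                 resolution = resolution, scaling = scaling,
                 calibrations = calibrations,
                 chronogram_store = chronogram_store,
                 graft_paths = graft_paths),
            class = "workflow_config")
}

config_tree <- function(config, id) {
  entry <- config$trees[[id]]
  tr <- entry$tree %||% read_newick(entry$path)
  validate_tree(tr)
  tr
}

#' Select the registered source tree with the best coverage
#'
#' Returns the tree maximizing the number of resolved names found among its
#' tips; ties are broken by fewer total tips, then lexicographic id.
#'
#' @param config a `workflow_config` (or a named list of `phylo` objects).
#' @param names character vector of (resolved) taxon names.
#' @return list with `id`, `coverage` and `n_tips`.
#' @export
select_source_tree <- function(config, names) {
  if (!inherits(config, "workflow_config")) {
    config <- workflow_config(trees = config, resolution = "off")
  }
  ids <- sort(base::names(config$trees))
  qn <- norm_name(names)
  best <- NULL
  for (id in ids) {
    tr <- config_tree(config, id)
    cov <- sum(qn %in% norm_name(tr$tip.label))
    cand <- list(id = id, coverage = cov, n_tips = ape::Ntip(tr))
    if (is.null(best) ||
        cand$coverage > best$coverage ||
        (cand$coverage == best$coverage && cand$n_tips < best$n_tips)) {
      best <- cand        # ids are visited in lexicographic order
    }
  }
  if (best$coverage == 0) {
    stop("no suitable source tree: no registered tree covers any queried name")
  }
  best
}

resolve_names <- function(names, config) {
  decisions <- tibble::tibble(submitted = names, matched = NA_character_,
                              score = NA_real_, source = NA_character_,
                              status = "kept", ambiguous = FALSE)
  if (config$resolution == "off" || is.null(config$taxonomies)) {
    decisions$matched <- names
    decisions$score <- 1
    decisions$source <- "passthrough"
    return(decisions)
  }
  fuzzy <- config$resolution == "fuzzy"
  rep <- tnrs_retrieve(tnrs_submit(names, config$taxonomies, fuzzy = fuzzy))
  for (i in seq_along(rep$names)) {
    m <- rep$names[[i]]$matches
    if (!nrow(m)) { decisions$status[i] <- "unresolved"; next }
    top <- m[m$score == max(m$score), , drop = FALSE]
    distinct <- unique(top$matched)
    if (length(distinct) > 1) {
      if (config$resolution == "strict") {
        warning("ambiguous resolution for \"", names[i], "\"; dropped (strict policy)")
        decisions$status[i] <- "unresolved"
        decisions$ambiguous[i] <- TRUE
        next
      }
      decisions$ambiguous[i] <- TRUE
    }
    pick <- top[order(top$matched), ][1, ]
    if (config$resolution == "strict" && pick$score < 1) {
      decisions$status[i] <- "unresolved"
      next
    }
    decisions$matched[i] <- pick$matched
    decisions$score[i] <- pick$score
    decisions$source[i] <- pick$source
  }
  decisions
}

#' Run the full names-to-phylogeny pipeline
#'
#' Executes the workflow stages in order — name resolution, best-coverage
#' source-tree selection, optional taxonomic grafting, path-store pruning,
#' and age scaling — and returns the resulting tree together with a
#' provenance record that itemizes every stage, every name-resolution
#' decision, and the names lost at each stage.  The record also carries a
#' name-conservation ledger which is checked before returning:
#' `|submitted| = |kept| + |unresolved|` and
#' `|kept| = |in tree| + |not in source tree|`.
#'
#' @param names character vector (or newline-separated string) of taxon
#'   names, possibly misspelled or deprecated.
#' @param config a `workflow_config`.
#' @param tree_id optionally force a registered source tree instead of
#'   automatic coverage-based selection.
#' @return an object of class `phylotastic_result`: list with `tree`,
#'   `provenance` (see [emit_provenance()]) and `prune` (the raw
#'   [prune()] result).
#' @examples
#' fx <- mammal_fixture()
#' cfg <- workflow_config(trees = list(mammals = fx$tree), resolution = "off")
#' res <- run_pipeline(c("Homo_sapiens", "Pan_troglodytes", "Mus_musculus"), cfg)
#' write_newick(res$tree)
#' @export
run_pipeline <- function(names, config, tree_id = NULL) {
  stopifnot(inherits(config, "workflow_config"))
  names <- unlist(strsplit(names, "\n", fixed = TRUE))
  names <- trimws(names); names <- names[nzchar(names)]
  if (!length(names)) stop("pipeline error [resolve]: no names supplied")
  ops <- list()

  # 1. name resolution
  decisions <- withCallingHandlers(
    resolve_names(names, config),
    error = function(e) stop("pipeline error [resolve]: ", conditionMessage(e)))
  kept <- decisions[decisions$status == "kept", , drop = FALSE]
  unresolved <- decisions$submitted[decisions$status == "unresolved"]
  ops <- c(ops, list(list(op = "resolve", policy = config$resolution,
                          n_in = length(names), n_kept = nrow(kept),
                          n_unresolved = length(unresolved))))
  if (!nrow(kept)) stop("pipeline error [resolve]: no names could be resolved")

  # 2. source-tree selection (a user-forced tree is mandatory when given)
  sel <- if (is.null(tree_id)) {
    tryCatch(select_source_tree(config, kept$matched),
             error = function(e) stop("pipeline error [select]: ", conditionMessage(e)))
  } else {
    if (!tree_id %in% base::names(config$trees)) {
      stop("pipeline error [select]: unregistered tree \"", tree_id, "\"")
    }
    tr <- config_tree(config, tree_id)
    list(id = tree_id,
         coverage = sum(norm_name(kept$matched) %in% norm_name(tr$tip.label)),
         n_tips = ape::Ntip(tr))
  }
  source_tree <- config_tree(config, sel$id)
  citation <- config$trees[[sel$id]]$citation %||% "unknown"
  ops <- c(ops, list(list(op = "select", tree = sel$id, coverage = sel$coverage,
                          n_tips = sel$n_tips)))

  # 3. optional taxonomic grafting of taxa missing from the source tree
  graft_report <- NULL
  if (!is.null(config$graft_paths)) {
    g <- tryCatch(graft(source_tree, config$graft_paths),
                  error = function(e) stop("pipeline error [graft]: ", conditionMessage(e)))
    source_tree <- g$tree
    graft_report <- g$report
    ops <- c(ops, list(list(op = "graft", n_paths = length(config$graft_paths),
                            n_placed = sum(g$report$status == "placed"))))
  }

  # 4. pruning via the path store
  query_tips <- underscore_name(kept$matched)
  store <- build_path_store(source_tree, sel$id)
  tipmap <- store$tips[match(norm_name(query_tips), norm_name(store$tips))]
  in_tree <- !is.na(tipmap)
  pruned <- tryCatch(prune(store, tipmap[in_tree]),
                     error = function(e) stop("pipeline error [prune]: ", conditionMessage(e)))
  ops <- c(ops, list(list(op = "prune", n_query = nrow(kept),
                          n_found = length(pruned$found),
                          n_not_in_tree = sum(!in_tree))))

  # 5. age scaling
  tree <- pruned$tree
  if (config$scaling == "bladj") {
    tree <- tryCatch(bladj(tree, config$calibrations),
                     error = function(e) stop("pipeline error [scale]: ", conditionMessage(e)))
    ops <- c(ops, list(list(op = "scale", method = "bladj",
                            n_calibrations = length(config$calibrations$ages))))
  } else if (config$scaling == "datelife") {
    tree <- tryCatch(datelife_scale(tree, config$chronogram_store),
                     error = function(e) stop("pipeline error [scale]: ", conditionMessage(e)))
    ops <- c(ops, list(list(op = "scale", method = "datelife",
                            n_sources = length(config$chronogram_store$records))))
  }

  ledger <- list(
    submitted = length(names),
    kept = nrow(kept),
    unresolved = length(unresolved),
    in_tree = sum(in_tree),
    not_in_source_tree = sum(!in_tree)
  )
  if (ledger$submitted != ledger$kept + ledger$unresolved ||
      ledger$kept != ledger$in_tree + ledger$not_in_source_tree) {
    stop("internal error: name-conservation ledger does not balance")
  }

  provenance <- list(
    tool = "phylotastic",
    version = as.character(utils::packageVersion("phylotastic")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    source_tree = list(id = sel$id, citation = citation),
    operations = ops,
    names = list(
      submitted = as.list(decisions$submitted),
      resolved = lapply(which(decisions$status == "kept"), function(i) list(
        submitted = decisions$submitted[i], matched = decisions$matched[i],
        score = decisions$score[i], source = decisions$source[i],
        ambiguous = decisions$ambiguous[i])),
      unresolved = as.list(unresolved),
      not_in_source_tree = as.list(kept$matched[!in_tree])
    ),
    ledger = ledger
  )
  structure(list(tree = tree, provenance = provenance, prune = pruned,
                 graft_report = graft_report, decisions = decisions),
            class = "phylotastic_result")
}

# hybrid scaling: calibrate pruned-tree nodes from the chronogram store
# where their MRCAs match, then bladj-interpolate the rest
datelife_scale <- function(tree, store) {
  ntip <- ape::Ntip(tree)
  labs <- tree_node_labels(tree)
  kids_tips <- lapply((ntip + 1):(ntip + tree$Nnode), function(v) {
    tree$tip.label[intersect(seq_len(ntip), phylotastic_descendants(tree, v))]
  })
  ages <- c(); nl <- labs
  for (k in seq_along(kids_tips)) {
    v <- ntip + k
    est <- tryCatch(query_ages(store, kids_tips[[k]]), error = function(e) NULL)
    if (is.null(est)) next
    if (is.na(nl[v])) nl[v] <- sprintf("node%d", v)
    ages[nl[v]] <- stats::median(est$per_source$mrca_age)
  }
  root <- root_node(tree)
  if (!(nl[root] %in% names(ages))) {
    stop("datelife scaling: no chronogram dates the root of the pruned tree")
  }
  tree$node.label <- nl[(ntip + 1):(ntip + tree$Nnode)]
  # interpolation requires monotone fixed ages; drop violating descendants
  bladj(tree, calibration_set(drop_inconsistent(tree, ages)))
}

phylotastic_descendants <- function(tree, v) {
  out <- integer(0); stack <- tree$edge[tree$edge[, 1] == v, 2]
  while (length(stack)) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, w)
    stack <- c(stack, tree$edge[tree$edge[, 1] == w, 2])
  }
  out
}

drop_inconsistent <- function(tree, ages) {
  labs <- tree_node_labels(tree)
  node_of <- function(lab) which(!is.na(labs) & labs == lab)
  keep <- names(ages)
  repeat {
    bad <- NULL
    for (lab in keep) {
      v <- node_of(lab)
      for (w in phylotastic_descendants(tree, v)) {
        wl <- labs[w]
        if (!is.na(wl) && wl %in% keep && ages[wl] > ages[lab] + 1e-9) {
          bad <- wl; break
        }
      }
      if (!is.null(bad)) break
    }
    if (is.null(bad)) break
    keep <- setdiff(keep, bad)
  }
  ages[keep]
}

#' @export
print.phylotastic_result <- function(x, ...) {
  cat("Phylotastic tree with ", ape::Ntip(x$tree), " tips from source \"",
      x$provenance$source_tree$id, "\"\n", sep = "")
  lg <- x$provenance$ledger
  cat("  names: ", lg$submitted, " submitted = ", lg$kept, " kept + ",
      lg$unresolved, " unresolved; ", lg$in_tree, " in tree\n", sep = "")
  invisible(x)
}

#' Serialize a provenance record as JSON
#'
#' Schema-valid JSON (see
#' `system.file("schema", "provenance-record.json", package = "phylotastic")`)
#' identifying the source tree and its citation, every operation applied
#' with its parameters, the per-name resolution decisions, and the
#' name-conservation ledger.
#'
#' @param record the `provenance` component of a [run_pipeline()] result
#'   (or the result itself).
#' @param file optional path to write to.
#' @return the JSON string, invisibly when `file` is given.
#' @export
emit_provenance <- function(record, file = NULL) {
  if (inherits(record, "phylotastic_result")) record <- record$provenance
  json <- as.character(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA))
  if (!is.null(file)) { writeLines(json, file); return(invisible(json)) }
  json
}
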