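#' Build a chronogram record
#'
#' A record bundles one published source of divergence-time estimates: one or
#' more ultrametric trees (several trees typically being post-burnin samples
#' from a Bayesian analysis), a citation, and per-tree patristic matrices
#' precomputed once so that age queries reduce to matching row names and
#' subsetting an array.
#'
#' @param id short unique identifier.
#' @param citation free-text citation for crediting the source.
#' @param trees a `phylo`, a list of `phylo`, or Newick strings.
#' @return an object of class `chronogram_record`.
#' @export
chronogram_record <- function(id, citation, trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(t) {
    if (is.character(t)) t <- read_newick(text = t)
    validate_tree(t)
    t
  })
  for (t in trees) {
    ok <- is_ultrametric_tree(t)   # errors on missing lengths
    if (!isTRUE(ok)) {
      stop("tree in record \"", id, "\" is not ultrametric: tip \"",
           attr(ok, "deviating_tip"), "\" deviates beyond tolerance")
    }
  }
  mats <- lapply(trees, patristic_matrix)
  structure(list(
    id = id, citation = citation, trees = trees, matrices = mats,
    taxa = sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  ), class = "chronogram_record")
}

#' Build a chronogram store
#'
#' @param records a list of `chronogram_record` objects, or of
#'   `list(id=, citation=, trees=)` specifications.
#' @return an object of class `chronogram_store` (records indexed by id).
#' @examples
#' st <- build_chronogram_store(list(
#'   list(id = "demo", citation = "Demo 2020", trees = "((A:2,B:2):3,C:5);")
#' ))
#' query_ages(st, c("A", "B"))$overall_range
#' @export
build_chronogram_store <- function(records = list()) {
  recs <- lapply(records, function(r) {
    if (inherits(r, "chronogram_record")) r
    else chronogram_record(r$id, r$citation, r$trees)
  })
  ids <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate record ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = stats::setNames(recs, ids)), class = "chronogram_store")
}

#' @export
print.chronogram_store <- function(x, ...) {
  cat("Chronogram store:", length(x$records), "record(s),",
      length(unique(unlist(lapply(x$records, `[[`, "taxa")))), "distinct taxa\n")
  invisible(x)
}

#' Serialize a chronogram store to a directory
#'
#' Writes a `manifest.json` plus one Newick file per sample tree; matrices
#' are recomputed at load time.  Writing, reading and writing again is
#' byte-identical.
#'
#' @param store a `chronogram_store`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chronogram_store <- function(store, dir) {
  stopifnot(inherits(store, "chronogram_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(store$records, function(r) {
    files <- sprintf("%s_%d.nwk", r$id, seq_along(r$trees))
    for (k in seq_along(r$trees)) {
      write_newick(r$trees[[k]], file = file.path(dir, files[k]))
    }
    list(id = r$id, citation = r$citation, trees = files)
  })
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a chronogram store from a directory
#' @param dir directory written by [write_chronogram_store()].
#' @return a `chronogram_store`.
#' @export
read_chronogram_store <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  build_chronogram_store(lapply(mf, function(r) {
    list(id = r$id, citation = r$citation,
         trees = lapply(r$trees, function(f) read_newick(file.path(dir, f))))
  }))
}

#' Query MRCA ages for a set of taxa
#'
#' For every record whose trees contain at least two of the queried taxa,
#' the MRCA age is read off the precomputed patristic matrix as
#' `max(d[i,j]) / 2` over matched pairs — exact on an ultrametric tree, with
#' no tree traversal at query time.  Records holding several sample trees
#' contribute all sample ages; a record's point estimate is the median
#' sample age (the median is this implementation's summary choice and is
#' labeled as such in output).
#'
#' @param store a `chronogram_store`.
#' @param taxa character vector of two or more taxon names (use name
#'   resolution first: names must match the chronogram labels exactly, up to
#'   case and underscore/space).
#' @return an object of class `age_estimate`: list with `query_taxa`,
#'   `per_source` (tibble: `id`, `citation`, `mrca_age` (median),
#'   `n_matched`, `age_min`, `age_median`, `age_max`, `sample_ages`
#'   list-column), `no_estimate` (ids with fewer than two matches) and
#'   `overall_range` over all sources and samples.
#' @export
query_ages <- function(store, taxa) {
  stopifnot(inherits(store, "chronogram_store"))
  taxa <- unique(taxa)
  if (length(taxa) < 2) stop("age queries need at least two taxa")
  if (!length(store$records)) stop("no dated source: the chronogram store is empty")
  qnorm <- norm_name(taxa)

  rows <- list(); no_est <- character(0)
  for (r in store$records) {
    ages <- numeric(0); nmatch <- 0L; matched_best <- character(0)
    for (m in r$matrices) {
      hit <- rownames(m)[norm_name(rownames(m)) %in% qnorm]
      if (length(hit) >= 2) {
        sub <- m[hit, hit, drop = FALSE]
        ages <- c(ages, max(sub) / 2)
        if (length(hit) > nmatch) { nmatch <- length(hit); matched_best <- hit }
      }
    }
    if (length(ages)) {
      rows[[r$id]] <- tibble::tibble(
        id = r$id, citation = r$citation,
        mrca_age = stats::median(ages), n_matched = nmatch,
        age_min = min(ages), age_median = stats::median(ages), age_max = max(ages),
        sample_ages = list(ages), matched_taxa = list(matched_best)
      )
    } else {
      no_est <- c(no_est, r$id)
    }
  }
  if (!length(rows)) {
    stop("no dated source: no chronogram matches two or more of the queried taxa")
  }
  per_source <- do.call(rbind, rows[order(names(rows))])
  all_ages <- unlist(per_source$sample_ages)
  structure(list(
    query_taxa = taxa,
    per_source = per_source,
    no_estimate = sort(no_est),
    overall_range = c(min(all_ages), max(all_ages))
  ), class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat("MRCA age estimate for {", paste(x$query_taxa, collapse = ", "), "}\n", sep = "")
  cat("  sources with an estimate:", nrow(x$per_source),
      "; overall range [", fmt_num(x$overall_range[1]), ", ",
      fmt_num(x$overall_range[2]), "]\n", sep = "")
  invisible(x)
}

#' Render an age estimate as JSON or Newick
#'
#' JSON follows the shipped response schema
#' (`system.file("schema", "datelife-response.json", package = "phylotastic")`).
#' Newick output is a star tree of the matched taxa from the single
#' best-covering source (most matched taxa; ties broken by lexicographically
#' smaller id), scaled so the root age equals that source's MRCA age.
#'
#' @param estimate an `age_estimate`.
#' @param format `"json"` or `"newick"`.
#' @return a character string.
#' @export
render_estimate <- function(estimate, format = c("json", "newick")) {
  stopifnot(inherits(estimate, "age_estimate"))
  format <- match.arg(format)
  ps <- estimate$per_source
  if (format == "json") {
    obj <- list(
      query = as.list(estimate$query_taxa),
      per_source = lapply(seq_len(nrow(ps)), function(i) list(
        id = ps$id[i], citation = ps$citation[i],
        mrca_age = ps$mrca_age[i], n_matched = ps$n_matched[i],
        sample_ages = as.list(ps$sample_ages[[i]])
      )),
      overall_range = as.list(estimate$overall_range)
    )
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)))
  }
  if (!nrow(ps)) stop("no matching source to render as Newick")
  best <- ps[order(-ps$n_matched, ps$id), ][1, ]
  taxa <- sort(best$matched_taxa[[1]])
  age <- best$mrca_age
  paste0("(", paste(paste0(underscore_name(taxa), ":", fmt_num(age)), collapse = ","), ");")
}
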