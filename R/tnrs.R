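# Local taxonomic name resolution: CSV-backed adaptors, the MSW3-style
# three-technique matcher, fuzzy matching, and the asynchronous
# submit/retrieve token API aggregating over adaptors.

#' Load a taxonomy table from CSV
#'
#' Expects a header row with at least `Genus` and `Species` columns
#' (case-insensitive); any further columns (family, order, author, synonym
#' text, ...) are kept and searched by the matcher.  Synonym names embedded
#' in free-text columns between `<i>` and `</i>` tags are extracted into a
#' synonym index at load time.
#'
#' @param file CSV path (UTF-8, header row).
#' @param source_id identifier of this taxonomy source (defaults to the
#'   file name without extension).
#' @return a `taxonomy_table`: a tibble with attributes `source_id` and
#'   `synonyms` (tibble of `row`, `name`).
#' @export
read_taxonomy_csv <- function(file, source_id = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  as_taxonomy(df, source_id %||% sub("\\.[^.]*$", "", basename(file)))
}

#' Turn a data frame into a taxonomy table
#'
#' @param df data frame with `Genus` and `Species` columns
#'   (case-insensitive names).
#' @param source_id identifier of the taxonomy source.
#' @return a `taxonomy_table`; see [read_taxonomy_csv()].
#' @export
as_taxonomy <- function(df, source_id) {
  names(df)[tolower(names(df)) == "genus"] <- "Genus"
  names(df)[tolower(names(df)) == "species"] <- "Species"
  if (!all(c("Genus", "Species") %in% names(df))) {
    stop("taxonomy table needs Genus and Species columns")
  }
  binom <- paste(df$Genus, df$Species)
  if (anyDuplicated(binom)) {
    stop("duplicate (Genus, Species) pairs: ",
         paste(utils::head(unique(binom[duplicated(binom)]), 3), collapse = "; "))
  }
  tb <- tibble::as_tibble(df)
  syn_rows <- integer(0); syn_names <- character(0)
  other <- setdiff(names(tb)[vapply(tb, is.character, logical(1))], c("Genus", "Species"))
  for (col in other) {
    hits <- regmatches(tb[[col]], gregexpr("<i>(.*?)</i>", tb[[col]]))
    for (i in seq_along(hits)) {
      if (length(hits[[i]])) {
        nm <- trimws(gsub("</?i>", "", hits[[i]]))
        nm <- nm[nzchar(nm)]
        syn_rows <- c(syn_rows, rep(i, length(nm)))
        syn_names <- c(syn_names, nm)
      }
    }
  }
  attr(tb, "source_id") <- source_id
  attr(tb, "synonyms") <- tibble::tibble(row = syn_rows, name = syn_names)
  class(tb) <- c("taxonomy_table", class(tb))
  tb
}

taxonomy_source <- function(table) attr(table, "source_id") %||% "taxonomy"

accepted_binomials <- function(table) paste(table$Genus, table$Species)

match_row <- function(table, rows, submitted, score, technique) {
  tibble::tibble(
    submitted = submitted,
    matched = accepted_binomials(table)[rows],
    score = score,
    source = taxonomy_source(table),
    uri = sprintf("local:%s/%d", taxonomy_source(table), rows),
    technique = technique
  )
}

#' Match a name against a taxonomy table (three-technique matcher)
#'
#' Applies, in order, (1) exact binomial match against the Genus and Species
#' columns, (2) match against names extracted from the other columns
#' (italic-tagged synonyms), and (3) cross-field assembly: the words of the
#' query found in different parts of a single row (e.g. the epithet in the
#' Species field but the genus only in the synonym text).  The first
#' technique that hits determines the match set; base scores are 1.0, 0.9
#' and 0.8 — an exact accepted name always scores exactly 1.
#'
#' @param name one submitted name.
#' @param table a `taxonomy_table`.
#' @return a tibble of matches (`submitted`, `matched`, `score`, `source`,
#'   `uri`, `technique`); zero rows when nothing hits.
#' @export
match_msw3 <- function(name, table) {
  q <- norm_name(name)
  # technique 1: exact binomial in Genus + Species
  rows <- which(norm_name(accepted_binomials(table)) == q)
  if (length(rows)) return(match_row(table, rows, name, 1.0, "exact"))
  # technique 2: name indexed from other columns (italic-tagged synonyms)
  syn <- attr(table, "synonyms")
  if (!is.null(syn) && nrow(syn)) {
    rows <- sort(unique(syn$row[norm_name(syn$name) == q]))
    if (length(rows)) return(match_row(table, rows, name, 0.9, "synonym"))
  }
  # technique 3: words of the name mentioned in different parts of one row
  words <- strsplit(q, " ", fixed = TRUE)[[1]]
  if (length(words) >= 2) {
    chr_cols <- names(table)[vapply(table, is.character, logical(1))]
    found <- lapply(words, function(w) {
      pat <- paste0("\\b", w, "\\b")
      hit <- rep(FALSE, nrow(table))
      for (col in chr_cols) hit <- hit | grepl(pat, table[[col]], ignore.case = TRUE)
      hit
    })
    rows <- which(Reduce(`&`, found))
    if (length(rows)) return(match_row(table, rows, name, 0.8, "cross_field"))
  }
  match_row(table, integer(0), character(0), numeric(0), character(0))
}

#' Fuzzy-match a misspelled name against accepted binomials
#'
#' Candidate accepted names within Levenshtein edit distance 2 of the query;
#' the score is `1 - d / max(nchar(query), nchar(candidate))`, sorted
#' score-descending with alphabetical tie-break.  An exact name scores 1.
#'
#' @inheritParams match_msw3
#' @param max_dist maximum edit distance (default 2).
#' @return a tibble of matches as in [match_msw3()].
#' @examples
#' tab <- as_taxonomy(data.frame(Genus = "Homo", Species = "sapiens"), "demo")
#' fuzzy_match("Homo sapien", tab)$score   # 1 - 1/12
#' @export
fuzzy_match <- function(name, table, max_dist = 2) {
  cands <- accepted_binomials(table)
  d <- as.integer(utils::adist(norm_name(name), norm_name(cands)))
  keep <- which(d <= max_dist)
  if (!length(keep)) {
    return(match_row(table, integer(0), character(0), numeric(0), character(0)))
  }
  score <- 1 - d[keep] / pmax(nchar(norm_name(name)), nchar(norm_name(cands[keep])))
  out <- match_row(table, keep, name, score, "fuzzy")
  out[order(-out$score, out$matched), ]
}

match_name <- function(name, table, fuzzy = FALSE) {
  res <- match_msw3(name, table)
  if (!nrow(res) && fuzzy) res <- fuzzy_match(name, table)
  res
}

#' Aggregate per-adaptor match tables into a meta report
#'
#' The meta-service union: all matches from all adaptors are returned side
#' by side, never merged or deduplicated across sources — choosing among
#' sources is the client's decision.  Rows are sorted (score descending,
#' then matched name, then source) so the result is invariant under adaptor
#' ordering.
#'
#' @param results list of match tibbles for one submitted name.
#' @return a single sorted match tibble.
#' @export
aggregate_matches <- function(results) {
  out <- do.call(rbind, results)
  if (is.null(out) || !nrow(out)) {
    return(tibble::tibble(submitted = character(0), matched = character(0),
                          score = numeric(0), source = character(0),
                          uri = character(0), technique = character(0)))
  }
  out[order(-out$score, out$matched, out$source), ]
}

# in-process job registry backing the asynchronous submit/retrieve API
.tnrs_registry <- new.env(parent = emptyenv())
assign("counter", 0L, envir = .tnrs_registry)

#' Submit names for resolution (asynchronous API)
#'
#' Records a resolution job and returns a token immediately; the
#' (potentially expensive, e.g. fuzzy) matching itself runs lazily when the
#' report is first retrieved.  Submitting the same input twice yields two
#' distinct tokens.
#'
#' @param names a single newline-separated string, or a character vector of
#'   names; blanks are dropped, surrounding whitespace trimmed.
#' @param tables a `taxonomy_table` or list of them (the adaptors to query).
#' @param fuzzy enable fuzzy matching as a fallback for unmatched names.
#' @return the job token (character).
#' @seealso [tnrs_retrieve()], [tnrs_status()]
#' @export
tnrs_submit <- function(names, tables, fuzzy = FALSE) {
  names <- unlist(strsplit(names, "\n", fixed = TRUE))
  names <- trimws(names)
  names <- names[nzchar(names)]
  if (!length(names)) stop("no names submitted")
  if (inherits(tables, "taxonomy_table")) tables <- list(tables)
  n <- get("counter", envir = .tnrs_registry) + 1L
  assign("counter", n, envir = .tnrs_registry)
  token <- sprintf("tnrs-%08d", n)
  assign(token, list(names = names, tables = tables, fuzzy = fuzzy,
                     status = "pending", result = NULL),
         envir = .tnrs_registry)
  token
}

#' Status of a resolution job
#' @param token a token from [tnrs_submit()].
#' @return `"pending"` or `"done"`.
#' @export
tnrs_status <- function(token) {
  if (!exists(token, envir = .tnrs_registry)) stop("unknown token: ", token)
  get(token, envir = .tnrs_registry)$status
}

#' Retrieve the report for a resolution job
#'
#' Processes the job if still pending, then returns one result group per
#' submitted name with every match from every queried adaptor.
#'
#' @param token a token from [tnrs_submit()].
#' @return an object of class `tnrs_report`: list with `status` (`"done"`)
#'   and `names`, a list of `list(submittedName=, matches=<tibble>)`.
#' @export
tnrs_retrieve <- function(token) {
  if (!exists(token, envir = .tnrs_registry)) stop("unknown token: ", token)
  job <- get(token, envir = .tnrs_registry)
  if (job$status == "pending") {
    groups <- lapply(job$names, function(nm) {
      list(submittedName = nm,
           matches = aggregate_matches(lapply(job$tables, function(tb) {
             match_name(nm, tb, fuzzy = job$fuzzy)
           })))
    })
    job$result <- structure(list(status = "done", names = groups),
                            class = "tnrs_report")
    job$status <- "done"
    assign(token, job, envir = .tnrs_registry)
  }
  job$result
}

#' @export
print.tnrs_report <- function(x, ...) {
  nm <- sum(vapply(x$names, function(g) nrow(g$matches) > 0, logical(1)))
  cat("TNRS report:", length(x$names), "name(s) submitted,", nm, "with matches\n")
  invisible(x)
}

#' Serialize a TNRS report as JSON
#'
#' Frozen wire format (see
#' `system.file("schema", "tnrs-report.json", package = "phylotastic")`):
#' `{"status":"done","names":[{"submittedName":..., "matches":[{
#' "matchedName":...,"score":...,"sourceId":...,"uri":...}]}]}`.
#'
#' @param report a `tnrs_report`.
#' @return a JSON string.
#' @export
tnrs_report_json <- function(report) {
  stopifnot(inherits(report, "tnrs_report"))
  obj <- list(
    status = report$status,
    names = lapply(report$names, function(g) list(
      submittedName = g$submittedName,
      matches = lapply(seq_len(nrow(g$matches)), function(i) list(
        matchedName = g$matches$matched[i],
        score = g$matches$score[i],
        sourceId = g$matches$source[i],
        uri = g$matches$uri[i]
      ))
    ))
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Resolve names synchronously
#'
#' Convenience wrapper: submit, retrieve, and flatten the report into one
#' tibble of matches.
#'
#' @inheritParams tnrs_submit
#' @return a tibble with one row per (submitted name, match).
#' @export
tnrs_resolve <- function(names, tables, fuzzy = FALSE) {
  rep <- tnrs_retrieve(tnrs_submit(names, tables, fuzzy = fuzzy))
  do.call(rbind, lapply(rep$names, `[[`, "matches"))
}
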