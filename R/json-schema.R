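# Minimal structural JSON-schema validator covering the subset used by the
# shipped schemas: type, required, properties, items, enum, minItems.
# Instances are R lists as produced by jsonlite::fromJSON(simplifyVector =
# FALSE).

#' Validate a parsed JSON instance against a shipped schema
#'
#' Structural validation for the JSON documents this package emits (TNRS
#' reports, age-estimate responses, provenance records).  Schemas live under
#' `system.file("schema", package = "phylotastic")`.
#'
#' @param instance an R list, as returned by
#'   `jsonlite::fromJSON(..., simplifyVector = FALSE)`.
#' @param schema a schema as an R list, or a path to a schema JSON file.
#' @return `TRUE` when valid, otherwise a character vector of violations
#'   (so `isTRUE()` is the pass test).
#' @export
validate_against_schema <- function(instance, schema) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- jsonlite::read_json(schema)
  }
  errs <- schema_check(instance, schema, "$")
  if (length(errs)) errs else TRUE
}

schema_check <- function(x, sch, path) {
  errs <- character(0)
  ty <- sch$type
  if (!is.null(ty)) {
    ok <- switch(ty,
      object  = is.list(x) && (length(x) == 0 || !is.null(names(x))),
      array   = is.list(x) && is.null(names(x)),
      string  = is.character(x) && length(x) == 1,
      number  = is.numeric(x) && length(x) == 1,
      integer = is.numeric(x) && length(x) == 1 && x == as.integer(x),
      boolean = is.logical(x) && length(x) == 1,
      null    = is.null(x),
      TRUE)
    if (!isTRUE(ok)) {
      return(paste0(path, ": expected ", ty))
    }
  }
  if (!is.null(sch$enum)) {
    if (!x %in% unlist(sch$enum)) {
      errs <- c(errs, paste0(path, ": value not in enum"))
    }
  }
  if (identical(ty, "object")) {
    for (req in unlist(sch$required)) {
      if (!req %in% names(x)) errs <- c(errs, paste0(path, ": missing required \"", req, "\""))
    }
    for (key in names(sch$properties)) {
      if (key %in% names(x)) {
        errs <- c(errs, schema_check(x[[key]], sch$properties[[key]],
                                     paste0(path, ".", key)))
      }
    }
  }
  if (identical(ty, "array")) {
    if (!is.null(sch$minItems) && length(x) < sch$minItems) {
      errs <- c(errs, paste0(path, ": fewer than ", sch$minItems, " items"))
    }
    if (!is.null(sch$items)) {
      for (i in seq_along(x)) {
        errs <- c(errs, schema_check(x[[i]], sch$items, paste0(path, "[", i, "]")))
      }
    }
  }
  errs
}
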