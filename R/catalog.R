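# GenArk-style assembly catalog: a local TSV of assembly hubs, searchable
# the way the GenArk Genomes browser panel searches them.

CATALOG_COLUMNS <- c("accession", "assembly_name", "scientific_name",
                     "common_name", "taxon_id", "hub_url")

#' Load an assembly catalog TSV
#'
#' The header line must name the six columns `accession`, `assembly_name`,
#' `scientific_name`, `common_name`, `taxon_id`, `hub_url` in any order.
#' Blank and `#` lines are skipped; a row whose taxon_id is not an integer
#' is skipped with a warning.
#'
#' @param text The file contents.
#' @return Data frame with the six columns in canonical order, rows in file
#'   order; `taxon_id` is integer.
#' @export
load_catalog <- function(text) {
  text <- decode_text(text)
  lines <- strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (!length(lines)) qh_format_error("catalog has no header line")

  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(CATALOG_COLUMNS, header)
  if (length(missing)) {
    qh_format_error(sprintf("catalog is missing required column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  col_at <- match(CATALOG_COLUMNS, header)

  rows <- list()
  for (line in lines[-1]) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    f <- c(f, rep("", max(0, max(col_at) - length(f))))
    vals <- f[col_at]
    names(vals) <- CATALOG_COLUMNS
    tid <- suppressWarnings(as.integer(vals[["taxon_id"]]))
    if (is.na(tid) || !grepl("^[0-9]+$", vals[["taxon_id"]])) {
      qh_warn(sprintf("catalog row '%s' has non-integer taxon_id '%s'; skipped",
                      vals[["accession"]], vals[["taxon_id"]]))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      accession = vals[["accession"]], assembly_name = vals[["assembly_name"]],
      scientific_name = vals[["scientific_name"]],
      common_name = vals[["common_name"]], taxon_id = tid,
      hub_url = vals[["hub_url"]]
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), assembly_name = character(),
               scientific_name = character(), common_name = character(),
               taxon_id = integer(), hub_url = character())
  if (anyDuplicated(out$accession)) {
    qh_format_error("catalog accessions must be unique")
  }
  rownames(out) <- NULL
  out
}

#' Search an assembly catalog
#'
#' Splits the query into whitespace tokens; every token must match
#' (AND semantics).  A token matches a record by case-insensitive substring
#' against common name, scientific name, assembly name or accession, or by
#' exact decimal match against the taxon id.  The empty query matches
#' everything; result order is catalog order.
#'
#' @param records Catalog data frame from [load_catalog()].
#' @param query Search string.
#' @return The matching rows, in catalog order.
#' @export
search_catalog <- function(records, query = "") {
  tokens <- strsplit(trimws(query), "[ \t]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(records)
  keep <- rep(TRUE, nrow(records))
  for (tok in tokens) {
    # fixed substring semantics (no regex), case-insensitive
    sub_hit <- Reduce(`|`, lapply(
      records[c("common_name", "scientific_name", "assembly_name",
                "accession")],
      function(col) {
        grepl(tolower(tok), tolower(col), fixed = TRUE)
      }))
    keep <- keep & (sub_hit | as.character(records$taxon_id) == tok)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quickload URL for a catalog assembly
#'
#' Convenience wrapper: the assembly's hub URL run through
#' [make_converted_url()] in the `to_quickload` direction, ready to paste
#' into IGB.
#'
#' @param record One catalog row (data frame or list with `hub_url`).
#' @param service_base Base URL of the translator service.
#' @param synonyms Unused; accepted for interface symmetry with the
#'   translation entry points.
#' @return The converted Quickload URL.
#' @export
open_assembly <- function(record, service_base, synonyms = NULL) {
  make_converted_url("to_quickload", record$hub_url[[1]], service_base)
}
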