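#' Parse and serialize the UCSC RA-style stanza dialect
#'
#' hub.txt, genomes.txt and trackDb.txt all share the same simple text
#' dialect: blank-line-separated "stanzas" of `key value` lines.  The parser
#' here is deliberately dumb about semantics -- it preserves entry order and
#' every non-comment entry verbatim (including duplicate keys); meaning is
#' assigned later by [build_trackhub()].
#'
#' Dialect rules applied on parse:
#' * LF and CRLF are both accepted; comment lines (first non-blank character
#'   `#`) are skipped and do not terminate a stanza.
#' * Leading indentation is cosmetic and stripped; track hierarchy comes from
#'   `parent`/`superTrack` keys, never from indentation.
#' * A trailing backslash joins the following line (with a single space)
#'   before the key/value split.
#' * The first whitespace run splits key from value; the value keeps internal
#'   whitespace but trailing whitespace is trimmed.  A line with no
#'   whitespace is a key with an empty value.
#'
#' @param text A single string (the whole file).
#' @return A list of `qh_stanza` objects, each with character vectors
#'   `$keys` and `$values` (parallel, in source order) and `$source_line`,
#'   the 1-based line number of the stanza's first entry.
#' @examples
#' sts <- parse_stanzas("track t1\nshortLabel T1\n\ntrack t2\ntype bigWig\n")
#' length(sts)
#' sts[[1]]$keys
#' @seealso [serialize_stanzas()]
#' @export
parse_stanzas <- function(text) {
  text <- decode_text(text)
  text <- gsub("\r\n", "\n", text, fixed = TRUE)
  text <- gsub("\r", "\n", text, fixed = TRUE)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]

  stanzas <- list()
  keys <- character()
  vals <- character()
  first_line <- NA_integer_

  flush <- function() {
    if (length(keys)) {
      stanzas[[length(stanzas) + 1L]] <<- new_stanza(keys, vals, first_line)
    }
    keys <<- character(); vals <<- character(); first_line <<- NA_integer_
  }

  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    lineno <- i
    # backslash continuation: join before any other interpretation
    while (grepl("\\\\$", line) && i < n) {
      i <- i + 1L
      line <- paste(sub("[ \t]*\\\\$", "", line),
                    sub("^[ \t]+", "", lines[[i]]))
    }
    stripped <- sub("^[ \t]+", "", line)
    if (!nzchar(sub("[ \t]+$", "", stripped))) {
      flush()                       # blank line: stanza boundary
    } else if (startsWith(stripped, "#")) {
      # comment: skipped, does not break the stanza
    } else {
      m <- regexpr("[ \t]", stripped)
      if (m == -1L) {
        key <- stripped
        val <- ""
      } else {
        key <- substr(stripped, 1L, m - 1L)
        val <- sub("[ \t]+$", "", substring(stripped, m + 1L))
        val <- sub("^[ \t]+", "", val)
      }
      if (!nzchar(key)) {
        qh_parse_error("line has no key token", lineno)
      }
      if (!length(keys)) first_line <- lineno
      keys <- c(keys, key)
      vals <- c(vals, val)
    }
    i <- i + 1L
  }
  flush()
  stanzas
}

new_stanza <- function(keys, values, source_line = NA_integer_) {
  structure(
    list(keys = as.character(keys), values = as.character(values),
         source_line = as.integer(source_line)),
    class = "qh_stanza"
  )
}

#' @export
print.qh_stanza <- function(x, ...) {
  cat(sprintf("<stanza: %d entries, line %s>\n", length(x$keys),
              ifelse(is.na(x$source_line), "?", x$source_line)))
  for (i in seq_along(x$keys)) cat(" ", x$keys[i], x$values[i], "\n")
  invisible(x)
}

# Last-wins lookup of a key in a stanza; NA when absent.  Duplicate
# non-identity keys are tolerated at parse time (permissive ingestion); the
# model layer warns and takes the last occurrence.
stanza_get <- function(st, key) {
  hit <- which(st$keys == key)
  if (!length(hit)) return(NA_character_)
  st$values[[hit[length(hit)]]]
}

stanza_has <- function(st, key) any(st$keys == key)

#' Serialize stanzas back to RA-style text
#'
#' Emits one `key value` line per entry (a bare `key` when the value is
#' empty), one blank line between stanzas, LF endings, trailing newline.
#' `parse_stanzas(serialize_stanzas(x))` recovers `x` up to `source_line`,
#' and serialize-parse-serialize is byte-stable.
#'
#' @param stanzas A list of `qh_stanza` objects (as from [parse_stanzas()]).
#' @return A single string; `""` for an empty list.
#' @export
serialize_stanzas <- function(stanzas) {
  if (!length(stanzas)) return("")
  blocks <- vapply(stanzas, function(st) {
    paste(ifelse(nzchar(st$values), paste(st$keys, st$values), st$keys),
          collapse = "\n")
  }, character(1))
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}
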