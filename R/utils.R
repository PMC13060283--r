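# Internal helpers: classed conditions, URL arithmetic, seed scoping.

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

#' @noRd
qh_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "quickhub_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

qh_parse_error <- function(msg, line = NA_integer_) {
  qh_stop(
    if (is.na(line)) msg else sprintf("%s (line %d)", msg, line),
    "quickhub_parse_error", line = line
  )
}

qh_structural_error <- function(msg) qh_stop(msg, "quickhub_structural_error")
qh_value_error <- function(msg) qh_stop(msg, "quickhub_value_error")
qh_format_error <- function(msg) qh_stop(msg, "quickhub_format_error")

#' @noRd
qh_warn <- function(msg) {
  warning(structure(
    class = c("quickhub_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Run code collecting quickhub warnings into a character vector instead of
# letting them escape; returns list(value, warnings).
collect_warnings <- function(expr) {
  warns <- character()
  value <- withCallingHandlers(
    expr,
    quickhub_warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  list(value = value, warnings = warns)
}

# ---- URL / path arithmetic -------------------------------------------------
# Data file locations are opaque strings: either absolute URLs, absolute
# filesystem paths, or paths relative to the directory of the referencing
# metadata file.  We never touch the referenced bytes here.

url_is_absolute <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x) | startsWith(x, "/")
}

# Directory of a URL or path naming a file ("https://x/a/hub.txt" -> "https://x/a")
url_dirname <- function(x) {
  if (!grepl("/", x)) return(".")
  sub("/[^/]*$", "", x)
}

# Collapse "." and ".." segments without touching the scheme/host part.
url_normalize <- function(x) {
  m <- regmatches(x, regexpr("^[A-Za-z][A-Za-z0-9+.-]*://[^/]*", x))
  prefix <- if (length(m)) m else ""
  rest <- substring(x, nchar(prefix) + 1L)
  lead <- if (startsWith(rest, "/")) "/" else ""
  segs <- strsplit(rest, "/", fixed = TRUE)[[1]]
  out <- character()
  for (s in segs) {
    if (s == "" || s == ".") next
    if (s == ".." && length(out) && out[length(out)] != "..") {
      out <- out[-length(out)]
    } else {
      out <- c(out, s)
    }
  }
  paste0(prefix, lead, paste(out, collapse = "/"))
}

# Resolve `rel` against the directory `base_dir`; absolute inputs pass through.
url_resolve <- function(base_dir, rel) {
  if (is.null(rel) || !nzchar(rel)) return("")
  if (url_is_absolute(rel) || !nzchar(base_dir)) return(rel)
  url_normalize(paste0(sub("/+$", "", base_dir), "/", rel))
}

# ---- seeds -----------------------------------------------------------------
# Evaluate `code` under set.seed(seed) and restore the caller's RNG state, so
# fixture generation is a pure function of its spec.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Decode raw bytes to UTF-8 text, replacing undecodable bytes with a warning
# rather than failing: remote metadata files are occasionally mis-encoded.
decode_text <- function(bytes) {
  if (is.character(bytes)) return(bytes)
  txt <- rawToChar(bytes)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    qh_warn("input is not valid UTF-8; undecodable bytes replaced")
    txt <- iconv(txt, from = "UTF-8", to = "UTF-8", sub = "?")
  }
  txt
}

# Truncate a display label to `n` characters (UCSC recommends short labels
# of at most 17 characters).
truncate_label <- function(x, n) {
  ifelse(nchar(x) > n, substr(x, 1L, n), x)
}
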