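# Injectable transports.  Every byte any module reads from "outside" flows
# through a transport: a function(url, range = NULL) returning a raw vector,
# or NULL when the resource does not exist.  `range = c(offset, length)`
# (0-based offset) asks for a byte slice; a transport may return more than
# asked (callers slice), but must honor the offset.

as_bytes <- function(x) if (is.raw(x)) x else charToRaw(x)

slice_range <- function(bytes, range) {
  if (is.null(range)) return(bytes)
  start <- range[[1]] + 1
  end <- min(length(bytes), range[[1]] + range[[2]])
  if (start > length(bytes)) return(raw(0))
  bytes[start:end]
}

#' In-memory transport for tests and fixtures
#'
#' @param files Named list mapping absolute URL -> content (character or
#'   raw).
#' @return A transport function `(url, range = NULL) -> raw or NULL`.
#' @examples
#' tr <- memory_transport(list("https://x.org/hub.txt" = "hub h\n"))
#' rawToChar(tr("https://x.org/hub.txt"))
#' @export
memory_transport <- function(files) {
  files <- lapply(files, as_bytes)
  function(url, range = NULL) {
    if (!url %in% names(files)) return(NULL)
    slice_range(files[[url]], range)
  }
}

#' Local filesystem transport
#'
#' Serves plain paths (and `file://` URLs) from disk; anything with another
#' URL scheme is reported missing.
#'
#' @return A transport function.
#' @export
file_transport <- function() {
  function(url, range = NULL) {
    path <- sub("^file://", "", url)
    if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", path)) return(NULL)
    if (!file.exists(path) || dir.exists(path)) return(NULL)
    n <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    if (is.null(range)) {
      readBin(con, "raw", n = n)
    } else {
      seek(con, where = range[[1]])
      readBin(con, "raw", n = range[[2]])
    }
  }
}

#' HTTP(S) transport
#'
#' Fetches over the network using the curl package, honoring byte ranges
#' with a `Range` header.  Only needed when converting live hubs; tests and
#' fixtures use [memory_transport()] / [file_transport()].
#'
#' @return A transport function.
#' @export
http_transport <- function() {
  if (!requireNamespace("curl", quietly = TRUE)) {
    qh_stop("the 'curl' package is required for http_transport()",
            "quickhub_value_error")
  }
  function(url, range = NULL) {
    h <- curl::new_handle()
    if (!is.null(range)) {
      curl::handle_setheaders(h, Range = sprintf(
        "bytes=%.0f-%.0f", range[[1]], range[[1]] + range[[2]] - 1))
    }
    resp <- tryCatch(curl::curl_fetch_memory(url, handle = h),
                     error = function(e) NULL)
    if (is.null(resp) || resp$status_code >= 400) return(NULL)
    resp$content
  }
}

#' Wrap a transport, recording every URL it is asked for
#'
#' Used to assert laziness: e.g. that serving contents.txt never touches a
#' bigDataUrl.
#'
#' @param transport The transport to wrap.
#' @return The wrapped transport, with attribute `log`, an environment
#'   whose `$urls` accumulates requested URLs in order.
#' @export
recording_transport <- function(transport) {
  log <- new.env(parent = emptyenv())
  log$urls <- character()
  f <- function(url, range = NULL) {
    log$urls <- c(log$urls, url)
    transport(url, range)
  }
  attr(f, "log") <- log
  f
}

#' @rdname recording_transport
#' @param recorder A transport made by [recording_transport()].
#' @return `recorded_urls()`: character vector of URLs requested so far.
#' @export
recorded_urls <- function(recorder) {
  attr(recorder, "log")$urls
}

# fetch text through a transport, failing with an upstream error when absent
fetch_text <- function(transport, url) {
  bytes <- transport(url)
  if (is.null(bytes)) {
    qh_stop(sprintf("upstream resource not reachable: %s", url),
            "quickhub_upstream_error", url = url)
  }
  decode_text(bytes)
}
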