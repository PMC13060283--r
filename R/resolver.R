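# The facade: virtual request paths under a conversion base URL map to
# lazily translated documents.  Serving a path fetches only the source
# files that path needs -- contents.txt never touches a trackDb, and no
# path ever touches a data file.

#' Encode and decode converted URLs
#'
#' A conversion URL deterministically and reversibly embeds the direction
#' and the percent-encoded source URL under the service base:
#' `<service_base>convert/<direction>/<encoded source>`.
#'
#' @param direction `"to_quickload"` (source is a hub.txt URL) or
#'   `"to_trackhub"` (source is a Quickload root URL).
#' @param source_url Absolute http(s) URL of the source.
#' @param service_base Base URL of the translator service.
#' @return `make_converted_url()`: the converted URL string.
#' @examples
#' u <- make_converted_url("to_quickload", "https://x.org/hub.txt",
#'                         "https://svc.example/")
#' parse_converted_url(u)
#' @export
make_converted_url <- function(direction = c("to_quickload", "to_trackhub"),
                               source_url, service_base) {
  direction <- match.arg(direction)
  if (!grepl("^https?://", source_url)) {
    qh_value_error(sprintf(
      "source_url must be an absolute http(s) URL, got '%s'", source_url))
  }
  base <- sub("/*$", "/", service_base)
  paste0(base, "convert/", direction, "/", percent_encode(source_url))
}

# RFC 3986 component encoding; base R's URLencode leaves '%' alone, which
# breaks reversibility, so this is spelled out.
percent_encode <- function(x) {
  bytes <- charToRaw(enc2utf8(x))
  ok <- as.raw(c(0x2D, 0x2E, 0x5F, 0x7E,            # - . _ ~
                 0x30:0x39, 0x41:0x5A, 0x61:0x7A))  # 0-9 A-Z a-z
  paste(ifelse(bytes %in% ok, rawToChar(bytes, multiple = TRUE),
               sprintf("%%%02X", as.integer(bytes))),
        collapse = "")
}

#' @rdname make_converted_url
#' @param url A URL produced by `make_converted_url()`.
#' @return `parse_converted_url()`: list with `direction` and `source_url`.
#' @export
parse_converted_url <- function(url) {
  m <- regmatches(url, regexec("convert/(to_quickload|to_trackhub)/(.+)$", url))[[1]]
  if (length(m) != 3L) {
    qh_value_error(sprintf("'%s' is not a converted URL", url))
  }
  list(direction = m[[2]], source_url = utils::URLdecode(m[[3]]))
}

#' Construct a conversion request
#'
#' @param direction `"to_quickload"` or `"to_trackhub"`.
#' @param source_url Absolute URL (or local directory) of the source
#'   hub.txt / Quickload root.
#' @param rel_path Virtual path below the conversion base, e.g.
#'   `"contents.txt"`, `"H_sapiens_Dec_2013/annots.xml"`, `"hub.txt"`,
#'   `"hg38/trackDb.txt"`.
#' @return A `qh_conversion_request`.
#' @export
conversion_request <- function(direction = c("to_quickload", "to_trackhub"),
                               source_url, rel_path) {
  direction <- match.arg(direction)
  if (grepl("(^|/)\\.\\.(/|$)", rel_path)) {
    qh_value_error("rel_path must not contain '..' segments")
  }
  structure(list(direction = direction, source_url = source_url,
                 rel_path = rel_path),
            class = "qh_conversion_request")
}

qh_response <- function(status, media_type, body) {
  structure(list(status = as.integer(status), media_type = media_type,
                 body = body),
            class = "qh_response")
}

#' @export
print.qh_response <- function(x, ...) {
  cat(sprintf("<response %d %s, %d byte(s)>\n", x$status, x$media_type,
              nchar(x$body, type = "bytes")))
  invisible(x)
}

# fetch + parse the hub-side sources needed for one request; trackdb_for
# limits trackDb fetches to one genome (NULL fetches none, "*" all)
load_hub_lazy <- function(source_url, transport, trackdb_for = NULL) {
  hub_text <- fetch_text(transport, source_url)
  hub_dir <- url_dirname(source_url)
  sts <- parse_stanzas(hub_text)
  hub_at <- which(vapply(sts, stanza_has, logical(1), key = "hub"))
  if (!length(hub_at)) {
    qh_structural_error("hub.txt has no stanza with a 'hub' key")
  }
  manifest <- manifest_from_stanza(sts[[hub_at[[1]]]])

  if (manifest$use_one_file) {
    return(build_trackhub(hub_text, base_url = hub_dir))
  }
  gfile <- if (nzchar(manifest$genomes_file)) manifest$genomes_file
           else "genomes.txt"
  genomes_text <- fetch_text(transport, url_resolve(hub_dir, gfile))
  genomes <- lapply(parse_stanzas(genomes_text), genome_from_stanza,
                    one_file = FALSE)
  genomes_dir <- url_dirname(url_resolve(hub_dir, gfile))

  trackdb_texts <- list()
  if (!is.null(trackdb_for)) {
    for (g in genomes) {
      if (!identical(trackdb_for, "*") && !g$genome_id %in% trackdb_for) next
      trackdb_texts[[g$genome_id]] <-
        fetch_text(transport, url_resolve(genomes_dir, g$trackdb_path))
    }
  }
  tracks_by_genome <- lapply(trackdb_texts, parse_trackdb_text)
  track_hub(manifest, genomes, tracks_by_genome, base_url = hub_dir)
}

# quickload-side lazy loader; annots_for limits annots.xml fetches
load_quickload_lazy <- function(source_url, transport, annots_for = NULL) {
  root <- sub("/+$", "", source_url)
  contents_text <- fetch_text(transport, paste0(root, "/contents.txt"))
  contents <- parse_contents(contents_text)
  genomes <- list()
  if (!is.null(annots_for)) {
    for (ce in contents) {
      d <- ce$genome_dir
      if (!identical(annots_for, "*") && !d %in% annots_for) next
      xml <- fetch_text(transport, paste0(root, "/", d, "/annots.xml"))
      genomes[[d]] <- quickload_genome(d, annots = parse_annots(xml))
    }
  }
  quickload_repo(contents, genomes, base_url = root)
}

#' Serve one virtual path of a conversion
#'
#' The heart of the facade: given a conversion request, fetch only the
#' source files that the requested path needs, build the models, translate,
#' and serialize.  Responses are deterministic -- repeated identical
#' requests yield byte-identical documents -- and no data file
#' (bigDataUrl) is ever fetched.
#'
#' Virtual paths served: direction `to_quickload` -- `contents.txt`,
#' `<genome_dir>/annots.xml`, `<genome_dir>/genome.txt` (synthesized from
#' the hub's `twoBitPath` via ranged 2bit reads); direction `to_trackhub`
#' -- `hub.txt`, `genomes.txt`, `<genome_id>/trackDb.txt`.
#'
#' @param request A [conversion_request()].
#' @param transport A transport function (see [memory_transport()]).
#' @param synonyms A [synonym_table()].
#' @return A `qh_response` with `$status` (200, 404, or 502),
#'   `$media_type`, and `$body` (text).  Upstream failures surface as 502
#'   with diagnostics in the body, never as silently empty documents.
#' @export
resolve <- function(request, transport, synonyms = default_synonyms()) {
  tryCatch(
    resolve_impl(request, transport, synonyms),
    quickhub_upstream_error = function(e) {
      qh_response(502, "text/plain",
                  paste0("upstream error: ", conditionMessage(e), "\n"))
    },
    quickhub_error = function(e) {
      qh_response(502, "text/plain",
                  paste0("source error: ", conditionMessage(e), "\n"))
    }
  )
}

not_found <- function(path) {
  qh_response(404, "text/plain", sprintf("not found: %s\n", path))
}

resolve_impl <- function(request, transport, synonyms) {
  rel <- request$rel_path
  src <- request$source_url

  if (request$direction == "to_quickload") {
    if (identical(rel, "contents.txt")) {
      hub <- load_hub_lazy(src, transport, trackdb_for = NULL)
      tr <- suppress_qh_warnings(hub_to_quickload(hub, synonyms))
      return(qh_response(200, "text/plain",
                         serialize_contents(tr$repo$contents)))
    }
    m <- regmatches(rel, regexec("^([^/]+)/(annots\\.xml|genome\\.txt)$", rel))[[1]]
    if (length(m) != 3L) return(not_found(rel))
    gdir <- m[[2]]
    hub <- load_hub_lazy(src, transport, trackdb_for = NULL)
    gids <- vapply(hub$genomes, function(g) g$genome_id, character(1))
    mapped <- vapply(gids, function(id) syn_to_quickload(synonyms, id),
                     character(1))
    hit <- which(mapped == gdir)
    if (!length(hit)) return(not_found(rel))
    g <- hub$genomes[[hit[[1]]]]

    if (identical(m[[3]], "annots.xml")) {
      hub <- load_hub_lazy(src, transport, trackdb_for = g$genome_id)
      tr <- suppress_qh_warnings(hub_to_quickload(hub, synonyms))
      return(qh_response(200, "application/xml",
                         serialize_annots(tr$repo$genomes[[gdir]]$annots)))
    }
    # genome.txt: synthesized from the assembly 2bit, index reads only
    if (!nzchar(g$two_bit_path)) return(not_found(rel))
    gfile <- if (nzchar(hub$manifest$genomes_file)) hub$manifest$genomes_file
             else "genomes.txt"
    genomes_dir <- if (hub$manifest$use_one_file) hub$base_url
                   else url_dirname(url_resolve(hub$base_url, gfile))
    url2bit <- url_resolve(genomes_dir, g$two_bit_path)
    idx <- twobit_index_via_transport(url2bit, transport)
    return(qh_response(200, "text/plain",
                       serialize_genome_table(genome_table_from_twobit(idx))))
  }

  # to_trackhub
  if (rel %in% c("hub.txt", "genomes.txt")) {
    repo <- load_quickload_lazy(src, transport, annots_for = NULL)
    tr <- suppress_qh_warnings(quickload_to_hub(repo, synonyms))
    files <- serialize_trackhub(tr$hub, one_file = FALSE)
    return(qh_response(200, "text/plain", files[[rel]]))
  }
  m <- regmatches(rel, regexec("^([^/]+)/trackDb\\.txt$", rel))[[1]]
  if (length(m) != 2L) return(not_found(rel))
  gid <- m[[2]]
  repo <- load_quickload_lazy(src, transport, annots_for = NULL)
  dirs <- vapply(repo$contents, function(ce) ce$genome_dir, character(1))
  mapped <- vapply(dirs, function(d) syn_to_ucsc(synonyms, d), character(1))
  hit <- which(mapped == gid)
  if (!length(hit)) return(not_found(rel))
  repo <- load_quickload_lazy(src, transport, annots_for = dirs[[hit[[1]]]])
  tr <- suppress_qh_warnings(quickload_to_hub(repo, synonyms))
  files <- serialize_trackhub(tr$hub, one_file = FALSE)
  body <- files[[paste0(gid, "/trackDb.txt")]]
  if (is.null(body)) return(not_found(rel))
  qh_response(200, "text/plain", body)
}

suppress_qh_warnings <- function(expr) {
  withCallingHandlers(expr, quickhub_warning = function(w) {
    invokeRestart("muffleWarning")
  })
}

#' Serve the facade over HTTP
#'
#' A thin development server on top of [resolve()] using the httpuv
#' package.  Paths have the form
#' `/convert/<direction>/<percent-encoded source URL>/<rel_path>`.
#' Intended for local use; production deployments should sit behind a
#' caching proxy (responses are deterministic, so external caching is
#' safe).
#'
#' @param port TCP port to listen on.
#' @param transport Transport used to fetch sources ([http_transport()] by
#'   default).
#' @param synonyms A [synonym_table()].
#' @param host Interface to bind.
#' @return The httpuv server handle (invisibly).
#' @export
serve_facade <- function(port = 8080L, transport = http_transport(),
                         synonyms = default_synonyms(),
                         host = "127.0.0.1") {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    qh_stop("the 'httpuv' package is required for serve_facade()",
            "quickhub_value_error")
  }
  app <- list(call = function(req) {
    path <- sub("^/", "", req$PATH_INFO)
    m <- regmatches(path,
                    regexec("^convert/(to_quickload|to_trackhub)/([^/]+)/(.+)$",
                            path))[[1]]
    if (length(m) != 4L) {
      return(list(status = 404L,
                  headers = list("Content-Type" = "text/plain"),
                  body = "not found\n"))
    }
    resp <- resolve(
      conversion_request(m[[2]], utils::URLdecode(m[[3]]), m[[4]]),
      transport, synonyms)
    list(status = resp$status,
         headers = list("Content-Type" = resp$media_type),
         body = resp$body)
  })
  httpuv::runServer(host, port, app)
}
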