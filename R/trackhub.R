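# Typed model of a UCSC track hub: hub manifest, genome entries, and track
# definitions with hierarchy, built from RA-style stanzas.

# Keys the translation engine interprets.  Everything else is carried in
# `extras` verbatim so serialization is lossless.
TRACK_KEYS <- c("track", "type", "bigDataUrl", "bigDataIndex", "shortLabel",
                "longLabel", "visibility", "color", "altColor", "parent",
                "superTrack", "container", "compositeTrack", "priority",
                "html", "group")
GENOME_KEYS <- c("genome", "trackDb", "twoBitPath", "organism",
                 "scientificName", "defaultPos")
HUB_KEYS <- c("hub", "shortLabel", "longLabel", "genomesFile", "email",
              "descriptionUrl", "useOneFile")

VISIBILITY_VALUES <- c("hide", "dense", "squish", "pack", "full")
TRACK_TYPE_KINDS <- c("bigWig", "bigBed", "bam", "cram", "vcfTabix",
                      "bigGenePred")

#' Construct a hub manifest
#'
#' @param hub_name Symbolic hub name (the `hub` line of hub.txt).
#' @param short_label,long_label Display labels.
#' @param genomes_file Path of the genome list file relative to hub.txt;
#'   ignored (and forced empty) when `use_one_file` is `TRUE`.
#' @param email,description_url Optional contact / documentation settings.
#' @param use_one_file `TRUE` for the single-file hub dialect in which
#'   genome and track stanzas are embedded in hub.txt.
#' @return A `qh_hub_manifest` list.
#' @export
hub_manifest <- function(hub_name, short_label = "", long_label = "",
                         genomes_file = "genomes.txt", email = "",
                         description_url = "", use_one_file = FALSE) {
  if (!nzchar(hub_name)) qh_value_error("hub_name must be non-empty")
  if (use_one_file) genomes_file <- ""
  if (!use_one_file && !nzchar(genomes_file)) genomes_file <- "genomes.txt"
  structure(
    list(hub_name = hub_name, short_label = short_label,
         long_label = long_label, genomes_file = genomes_file,
         email = email, description_url = description_url,
         use_one_file = isTRUE(use_one_file)),
    class = "qh_hub_manifest"
  )
}

#' Construct a genome entry of a hub
#'
#' @param genome_id UCSC database name (`"hg38"`) or assembly accession
#'   (`"GCF_000001405.40"`).
#' @param trackdb_path Path of the genome's trackDb.txt relative to the
#'   genome list file.
#' @param two_bit_path Optional path of the assembly 2bit file (assembly
#'   hubs); empty for database hubs.
#' @param organism,scientific_name,default_pos Optional display settings.
#' @param extras Named character vector of unrecognized settings, preserved
#'   verbatim.
#' @return A `qh_genome_entry` list.
#' @export
genome_entry <- function(genome_id, trackdb_path, two_bit_path = "",
                         organism = "", scientific_name = "",
                         default_pos = "", extras = character()) {
  if (!nzchar(genome_id)) qh_value_error("genome_id must be non-empty")
  if (!nzchar(trackdb_path)) qh_value_error("trackdb_path must be non-empty")
  structure(
    list(genome_id = genome_id, trackdb_path = trackdb_path,
         two_bit_path = two_bit_path, organism = organism,
         scientific_name = scientific_name, default_pos = default_pos,
         extras = as_extras(extras)),
    class = "qh_genome_entry"
  )
}

as_extras <- function(x) {
  x <- unlist(x)
  if (!length(x)) return(stats::setNames(character(), character()))
  storage.mode(x) <- "character"
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    qh_value_error("extras must be a named character vector")
  }
  x
}

# Classify a raw trackDb `type` string ("bigBed 12 +" -> kind "bigBed").
track_type_kind <- function(raw) {
  tok <- strsplit(trimws(raw), "[ \t]+")[[1]]
  if (length(tok) && tok[[1]] %in% TRACK_TYPE_KINDS) tok[[1]] else "other"
}

#' Construct a track definition
#'
#' @param track_name Unique word-like track identifier.
#' @param type_raw The raw trackDb `type` string (e.g. `"bigBed 12 +"`);
#'   the kind is derived from its first token.
#' @param big_data_url Location of the data file; required for leaf tracks,
#'   typically empty for containers.
#' @param big_data_index Optional explicit index (.bai/.tbi) location.
#' @param short_label,long_label Display labels.
#' @param visibility One of hide, dense, squish, pack, full.
#' @param color_rgb,alt_color_rgb Integer vector `c(r, g, b)` in 0--255, or
#'   `NULL` when unset.
#' @param parent_name Name of the container this track belongs to (from
#'   `parent` or `superTrack` membership keys); empty for root tracks.
#' @param parent_default_on Whether the track is on by default within its
#'   parent.
#' @param container_kind `"none"` for data tracks, else `"superTrack"`,
#'   `"composite"` or `"multiWig"`.
#' @param priority Optional decimal sort weight (ascending).
#' @param html_path Optional documentation page location.
#' @param group Optional UCSC group assignment.
#' @param extras Named character vector of unrecognized settings.
#' @return A `qh_track_def` list with a derived `$track_type$kind`.
#' @export
track_def <- function(track_name, type_raw = "", big_data_url = "",
                      big_data_index = "", short_label = "", long_label = "",
                      visibility = "hide", color_rgb = NULL,
                      alt_color_rgb = NULL, parent_name = "",
                      parent_default_on = TRUE,
                      container_kind = c("none", "composite", "multiWig",
                                         "superTrack"),
                      priority = NULL, html_path = "", group = "",
                      extras = character()) {
  if (!nzchar(track_name)) qh_value_error("track_name must be non-empty")
  container_kind <- match.arg(container_kind)
  if (!visibility %in% VISIBILITY_VALUES) {
    qh_warn(sprintf("track '%s': unknown visibility '%s'; using 'pack'",
                    track_name, visibility))
    visibility <- "pack"
  }
  if (!is.null(color_rgb)) color_rgb <- check_rgb(color_rgb)
  if (!is.null(alt_color_rgb)) alt_color_rgb <- check_rgb(alt_color_rgb)
  structure(
    list(track_name = track_name,
         track_type = list(kind = track_type_kind(type_raw), raw = type_raw),
         big_data_url = big_data_url, big_data_index = big_data_index,
         short_label = short_label, long_label = long_label,
         visibility = visibility, color_rgb = color_rgb,
         alt_color_rgb = alt_color_rgb, parent_name = parent_name,
         parent_default_on = isTRUE(parent_default_on),
         container_kind = container_kind,
         priority = if (is.null(priority)) NULL else as.numeric(priority),
         html_path = html_path, group = group, extras = as_extras(extras)),
    class = "qh_track_def"
  )
}

check_rgb <- function(x) {
  x <- as.integer(x)
  if (length(x) != 3L || anyNA(x) || any(x < 0L) || any(x > 255L)) {
    qh_value_error("color must be three integers in 0..255")
  }
  x
}

#' Construct a whole track hub model
#'
#' @param manifest A [hub_manifest()].
#' @param genomes List of [genome_entry()] values.
#' @param tracks_by_genome Named list (genome_id -> list of [track_def()]).
#'   Genomes without tracks may be omitted.
#' @param base_url Absolute URL or local directory containing hub.txt.
#' @return A `qh_track_hub` list.
#' @export
track_hub <- function(manifest, genomes, tracks_by_genome = list(),
                      base_url = "") {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  unknown <- setdiff(names(tracks_by_genome), ids)
  if (length(unknown)) {
    qh_structural_error(sprintf(
      "tracks_by_genome names genomes absent from the genome list: %s",
      paste(unknown, collapse = ", ")))
  }
  structure(
    list(manifest = manifest, genomes = genomes,
         tracks_by_genome = tracks_by_genome, base_url = base_url),
    class = "qh_track_hub"
  )
}

#' @export
print.qh_track_hub <- function(x, ...) {
  n_tracks <- sum(vapply(x$tracks_by_genome, length, integer(1)))
  cat(sprintf("<track hub '%s': %d genome(s), %d track(s)%s>\n",
              x$manifest$hub_name, length(x$genomes), n_tracks,
              if (x$manifest$use_one_file) ", useOneFile" else ""))
  invisible(x)
}

# ---- building from text ----------------------------------------------------

# Collapse duplicate keys (last occurrence wins, with a warning), keeping the
# position of the surviving occurrence.
dedup_stanza <- function(st, what) {
  dup <- unique(st$keys[duplicated(st$keys)])
  if (length(dup)) {
    qh_warn(sprintf("%s: duplicate key(s) %s; last occurrence wins",
                    what, paste(dup, collapse = ", ")))
    keep <- !duplicated(st$keys, fromLast = TRUE)
    st <- new_stanza(st$keys[keep], st$values[keep], st$source_line)
  }
  st
}

stanza_extras <- function(st, recognized) {
  sel <- !(st$keys %in% recognized)
  stats::setNames(st$values[sel], st$keys[sel])
}

manifest_from_stanza <- function(st) {
  st <- dedup_stanza(st, "hub stanza")
  use_one <- identical(tolower(stanza_get(st, "useOneFile")), "on")
  hub_manifest(
    hub_name = stanza_get(st, "hub"),
    short_label = stanza_get(st, "shortLabel") %|NA|% "",
    long_label = stanza_get(st, "longLabel") %|NA|% "",
    genomes_file = if (use_one) "" else stanza_get(st, "genomesFile") %|NA|% "",
    email = stanza_get(st, "email") %|NA|% "",
    description_url = stanza_get(st, "descriptionUrl") %|NA|% "",
    use_one_file = use_one
  )
}

`%|NA|%` <- function(x, y) if (length(x) != 1L || is.na(x)) y else x

genome_from_stanza <- function(st, one_file) {
  st <- dedup_stanza(st, sprintf("genome stanza at line %s", st$source_line))
  gid <- stanza_get(st, "genome")
  if (is.na(gid) || !nzchar(gid)) {
    qh_structural_error(sprintf(
      "genome stanza at line %s is missing the 'genome' key", st$source_line))
  }
  tdb <- stanza_get(st, "trackDb")
  if (is.na(tdb) || !nzchar(tdb)) {
    if (!one_file) {
      qh_structural_error(sprintf(
        "genome stanza '%s' is missing the 'trackDb' key", gid))
    }
    # single-file hubs have no trackDb line; adopt the canonical layout so
    # the same model can be re-serialized in split form.
    tdb <- paste0(gid, "/trackDb.txt")
  }
  genome_entry(
    genome_id = gid, trackdb_path = tdb,
    two_bit_path = stanza_get(st, "twoBitPath") %|NA|% "",
    organism = stanza_get(st, "organism") %|NA|% "",
    scientific_name = stanza_get(st, "scientificName") %|NA|% "",
    default_pos = stanza_get(st, "defaultPos") %|NA|% "",
    extras = stanza_extras(st, GENOME_KEYS)
  )
}

parse_rgb_setting <- function(val, track, key) {
  parts <- suppressWarnings(as.integer(strsplit(val, ",", fixed = TRUE)[[1]]))
  if (length(parts) != 3L || anyNA(parts) ||
      any(parts < 0L) || any(parts > 255L)) {
    qh_warn(sprintf("track '%s': invalid %s '%s' ignored", track, key, val))
    return(NULL)
  }
  parts
}

track_from_stanza <- function(st) {
  name <- stanza_get(st, "track")
  if (is.na(name) || !nzchar(name)) {
    qh_warn(sprintf("stanza at line %s has no 'track' key; skipped",
                    st$source_line))
    return(NULL)
  }
  st <- dedup_stanza(st, sprintf("track '%s'", name))

  extras <- stanza_extras(st, TRACK_KEYS)
  container_kind <- "none"
  parent_name <- ""
  parent_on <- TRUE

  sup <- stanza_get(st, "superTrack")
  if (!is.na(sup)) {
    tok <- strsplit(trimws(sup), "[ \t]+")[[1]]
    if (identical(tok, "on")) {
      container_kind <- "superTrack"
    } else if (length(tok)) {
      parent_name <- tok[[1]]
      parent_on <- identical(tok[2] %|NA|% "", "show")
    }
  }
  if (identical(tolower(stanza_get(st, "compositeTrack")), "on")) {
    container_kind <- "composite"
  }
  cont <- stanza_get(st, "container")
  if (!is.na(cont)) {
    if (identical(cont, "multiWig")) {
      container_kind <- "multiWig"
    } else {
      qh_warn(sprintf("track '%s': unknown container '%s' kept as extra",
                      name, cont))
      extras <- c(extras, stats::setNames(cont, "container"))
    }
  }
  par <- stanza_get(st, "parent")
  if (!is.na(par)) {
    tok <- strsplit(trimws(par), "[ \t]+")[[1]]
    parent_name <- tok[[1]]
    flag <- tok[2] %|NA|% ""
    parent_on <- !identical(flag, "off") && !identical(flag, "hide")
  }

  color <- stanza_get(st, "color")
  alt <- stanza_get(st, "altColor")
  pri <- stanza_get(st, "priority")
  priority <- NULL
  if (!is.na(pri)) {
    priority <- suppressWarnings(as.numeric(pri))
    if (is.na(priority)) {
      qh_warn(sprintf("track '%s': non-numeric priority '%s' ignored",
                      name, pri))
      priority <- NULL
    }
  }

  track_def(
    track_name = name,
    type_raw = stanza_get(st, "type") %|NA|% "",
    big_data_url = stanza_get(st, "bigDataUrl") %|NA|% "",
    big_data_index = stanza_get(st, "bigDataIndex") %|NA|% "",
    short_label = stanza_get(st, "shortLabel") %|NA|% "",
    long_label = stanza_get(st, "longLabel") %|NA|% "",
    visibility = stanza_get(st, "visibility") %|NA|% "hide",
    color_rgb = if (!is.na(color)) parse_rgb_setting(color, name, "color"),
    alt_color_rgb = if (!is.na(alt)) parse_rgb_setting(alt, name, "altColor"),
    parent_name = parent_name, parent_default_on = parent_on,
    container_kind = container_kind, priority = priority,
    html_path = stanza_get(st, "html") %|NA|% "",
    group = stanza_get(st, "group") %|NA|% "",
    extras = extras
  )
}

parse_trackdb_text <- function(text) {
  tracks <- list()
  for (st in parse_stanzas(text)) {
    td <- track_from_stanza(st)
    if (!is.null(td)) tracks[[length(tracks) + 1L]] <- td
  }
  names_seen <- vapply(tracks, function(t) t$track_name, character(1))
  dup <- unique(names_seen[duplicated(names_seen)])
  if (length(dup)) {
    qh_warn(sprintf("duplicate track name(s) in trackDb: %s",
                    paste(dup, collapse = ", ")))
  }
  tracks
}

#' Build a track hub model from its configuration texts
#'
#' Interprets the recognized keys of the hub/genome/track stanzas into typed
#' fields; every unrecognized key is preserved in `extras`.  Both the split
#' (hub.txt + genomes.txt + trackDb.txt) and the `useOneFile` single-file
#' layouts are accepted and produce the same model.
#'
#' @param hub_text Contents of hub.txt.
#' @param genomes_text Contents of genomes.txt; empty for `useOneFile` hubs.
#' @param trackdb_texts Named list (genome_id -> trackDb.txt contents);
#'   ignored for `useOneFile` hubs.
#' @param base_url Absolute URL or local directory containing hub.txt.
#' @return A `qh_track_hub`.
#' @export
build_trackhub <- function(hub_text, genomes_text = "",
                           trackdb_texts = list(), base_url = "") {
  sts <- parse_stanzas(hub_text)
  hub_at <- which(vapply(sts, stanza_has, logical(1), key = "hub"))
  if (!length(hub_at)) {
    qh_structural_error("hub.txt has no stanza with a 'hub' key")
  }
  manifest <- manifest_from_stanza(sts[[hub_at[[1]]]])

  genomes <- list()
  tracks_by_genome <- list()

  if (manifest$use_one_file) {
    current <- NULL
    for (i in seq_along(sts)) {
      if (i == hub_at[[1]]) next
      st <- sts[[i]]
      if (stanza_has(st, "genome")) {
        g <- genome_from_stanza(st, one_file = TRUE)
        genomes[[length(genomes) + 1L]] <- g
        current <- g$genome_id
        tracks_by_genome[[current]] <- list()
      } else if (stanza_has(st, "track")) {
        if (is.null(current)) {
          qh_structural_error(sprintf(
            "track stanza at line %s appears before any genome stanza",
            st$source_line))
        }
        td <- track_from_stanza(st)
        if (!is.null(td)) {
          tracks_by_genome[[current]] <-
            c(tracks_by_genome[[current]], list(td))
        }
      } else {
        qh_warn(sprintf("unrecognized stanza at line %s ignored",
                        st$source_line))
      }
    }
  } else {
    for (st in parse_stanzas(genomes_text)) {
      genomes[[length(genomes) + 1L]] <-
        genome_from_stanza(st, one_file = FALSE)
    }
    for (gid in names(trackdb_texts)) {
      tracks_by_genome[[gid]] <- parse_trackdb_text(trackdb_texts[[gid]])
    }
  }

  track_hub(manifest, genomes, tracks_by_genome, base_url)
}

# ---- hierarchy -------------------------------------------------------------

#' Reconstruct the container hierarchy of one trackDb
#'
#' Parent/child edges come from `parent_name` (populated by both `parent`
#' and `superTrack <name>` membership keys); indentation in the source file
#' is never consulted.  Roots are tracks without a parent; a track naming a
#' parent that does not exist becomes a root with a warning.  Source order
#' is preserved among siblings.
#'
#' @param tracks List of [track_def()] from one trackDb.
#' @return A forest: list of nodes, each `list(track_name, index, children)`
#'   where `children` is again a forest and `index` points into `tracks`.
#' @export
track_hierarchy <- function(tracks) {
  n <- length(tracks)
  if (!n) return(list())
  nm <- vapply(tracks, function(t) t$track_name, character(1))
  parent <- vapply(tracks, function(t) t$parent_name, character(1))
  pidx <- match(parent, nm)

  dangling <- nzchar(parent) & is.na(pidx)
  if (any(dangling)) {
    qh_warn(sprintf("dangling parent(s): %s; treated as roots",
                    paste(sprintf("%s -> %s", nm[dangling], parent[dangling]),
                          collapse = ", ")))
  }

  # cycle detection by following parent links
  for (i in seq_len(n)) {
    seen <- integer()
    j <- i
    while (!is.na(j)) {
      if (j %in% seen) {
        cyc <- nm[seen[which(seen == j):length(seen)]]
        qh_structural_error(sprintf("parent cycle among tracks: {%s}",
                                    paste(cyc, collapse = ", ")))
      }
      seen <- c(seen, j)
      j <- pidx[[j]]
    }
  }

  build <- function(parent_index) {
    kids <- if (is.na(parent_index)) {
      which(is.na(pidx))
    } else {
      which(!is.na(pidx) & pidx == parent_index)
    }
    lapply(kids, function(k) {
      list(track_name = nm[[k]], index = k, children = build(k))
    })
  }
  build(NA_integer_)
}

# ---- serialization ---------------------------------------------------------

fmt_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE, digits = 15)
}

push_kv <- function(keys, vals, key, val) {
  list(keys = c(keys, key), vals = c(vals, val))
}

manifest_to_stanza <- function(m, one_file) {
  keys <- "hub"; vals <- m$hub_name
  add <- function(k, v) {
    if (nzchar(v)) { keys <<- c(keys, k); vals <<- c(vals, v) }
  }
  add("shortLabel", m$short_label)
  add("longLabel", m$long_label)
  if (one_file) {
    keys <- c(keys, "useOneFile"); vals <- c(vals, "on")
  } else {
    add("genomesFile", if (nzchar(m$genomes_file)) m$genomes_file
                       else "genomes.txt")
  }
  add("email", m$email)
  add("descriptionUrl", m$description_url)
  new_stanza(keys, vals)
}

genome_to_stanza <- function(g, one_file) {
  keys <- "genome"; vals <- g$genome_id
  add <- function(k, v) {
    if (nzchar(v)) { keys <<- c(keys, k); vals <<- c(vals, v) }
  }
  if (!one_file) add("trackDb", g$trackdb_path)
  add("twoBitPath", g$two_bit_path)
  add("organism", g$organism)
  add("scientificName", g$scientific_name)
  add("defaultPos", g$default_pos)
  keys <- c(keys, names(g$extras)); vals <- c(vals, unname(g$extras))
  new_stanza(keys, vals)
}

track_to_stanza <- function(t) {
  keys <- "track"; vals <- t$track_name
  add <- function(k, v) {
    if (nzchar(v)) { keys <<- c(keys, k); vals <<- c(vals, v) }
  }
  add("type", t$track_type$raw)
  add("bigDataUrl", t$big_data_url)
  add("bigDataIndex", t$big_data_index)
  add("shortLabel", t$short_label)
  add("longLabel", t$long_label)
  add("visibility", t$visibility)
  if (!is.null(t$color_rgb)) add("color", paste(t$color_rgb, collapse = ","))
  if (!is.null(t$alt_color_rgb)) {
    add("altColor", paste(t$alt_color_rgb, collapse = ","))
  }
  if (nzchar(t$parent_name)) {
    add("parent", paste(t$parent_name,
                        if (t$parent_default_on) "on" else "off"))
  }
  switch(t$container_kind,
    superTrack = add("superTrack", "on"),
    composite = add("compositeTrack", "on"),
    multiWig = add("container", "multiWig"),
    none = NULL
  )
  if (!is.null(t$priority)) add("priority", fmt_num(t$priority))
  add("html", t$html_path)
  add("group", t$group)
  keys <- c(keys, names(t$extras)); vals <- c(vals, unname(t$extras))
  new_stanza(keys, vals)
}

#' Serialize a track hub model back to its configuration texts
#'
#' Typed fields re-emit under their canonical keys (in the canonical UCSC
#' order), extras re-emit verbatim after them.  `build_trackhub()` on the
#' output reproduces the model (modulo `base_url`), in either layout.
#'
#' @param hub A `qh_track_hub`.
#' @param one_file Emit the `useOneFile` single-file dialect?
#' @return Named list mapping relative path -> file text.  Always contains
#'   `"hub.txt"`; split layout adds the genomes file and one trackDb.txt per
#'   genome.
#' @export
serialize_trackhub <- function(hub, one_file = hub$manifest$use_one_file) {
  m <- hub$manifest
  out <- list()
  if (one_file) {
    sts <- list(manifest_to_stanza(m, TRUE))
    for (g in hub$genomes) {
      sts <- c(sts, list(genome_to_stanza(g, TRUE)))
      for (t in hub$tracks_by_genome[[g$genome_id]] %||% list()) {
        sts <- c(sts, list(track_to_stanza(t)))
      }
    }
    out[["hub.txt"]] <- serialize_stanzas(sts)
  } else {
    gfile <- if (nzchar(m$genomes_file)) m$genomes_file else "genomes.txt"
    out[["hub.txt"]] <- serialize_stanzas(list(manifest_to_stanza(m, FALSE)))
    out[[gfile]] <- serialize_stanzas(
      lapply(hub$genomes, genome_to_stanza, one_file = FALSE))
    gdir <- url_dirname(gfile)
    for (g in hub$genomes) {
      path <- if (identical(gdir, ".")) g$trackdb_path
              else paste0(gdir, "/", g$trackdb_path)
      out[[path]] <- serialize_stanzas(
        lapply(hub$tracks_by_genome[[g$genome_id]] %||% list(),
               track_to_stanza))
    }
  }
  out
}
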