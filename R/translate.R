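# The core bidirectional mapping engine between track hub and Quickload
# models, with an explicit lossiness report.
#
# Lossless round-tripping is achieved by stashing settings that have no home
# in the target dialect under reserved attribute/key prefixes: trackDb
# settings travel as "x_hub_<key>" annots.xml attributes, and annots.xml
# settings travel as "x_ql_<attr>" trackDb keys.  The canonical core
# (resolved data URL, type kind, color, visibility, long label, hierarchy
# path) must survive a round trip even without the stash.

#' Color conversions between trackDb RGB triples and annots.xml hex
#'
#' @param r,g,b Integer components in 0--255.
#' @return `rgb_to_hex()`: an uppercase 6-hex-digit string.
#' @examples
#' rgb_to_hex(0, 0, 255)    # "0000FF"
#' hex_to_rgb("0000FF")     # c(0, 0, 255)
#' @export
rgb_to_hex <- function(r, g, b) {
  v <- check_rgb(c(r, g, b))
  sprintf("%02X%02X%02X", v[1], v[2], v[3])
}

#' @rdname rgb_to_hex
#' @param hex6 A 6-hex-digit string (either case).
#' @return `hex_to_rgb()`: integer vector `c(r, g, b)`.
#' @export
hex_to_rgb <- function(hex6) {
  if (length(hex6) != 1L || is.na(hex6) || !grepl("^[0-9A-Fa-f]{6}$", hex6)) {
    qh_value_error(sprintf("'%s' is not a 6-hex-digit color", hex6))
  }
  strtoi(c(substr(hex6, 1, 2), substr(hex6, 3, 4), substr(hex6, 5, 6)),
         base = 16L)
}

#' Which track types survive translation
#'
#' Both browsers can read the indexed binary formats bigWig, bigBed, BAM,
#' CRAM and tabix-indexed VCF; bigGenePred is treated as a bigBed-flavored
#' annotation track.  Everything else (bedGraph, plain BED/GFF, ...) is
#' unsupported and becomes a dropped-track entry in the conversion report.
#'
#' @param track_type Either a `$track_type` list (`kind`, `raw`) from a
#'   [track_def()] or a raw type string.
#' @return List `list(supported = logical, reason = character)`; `reason`
#'   carries the raw type string when unsupported.
#' @export
map_track_type_to_quickload <- function(track_type) {
  if (is.character(track_type)) {
    track_type <- list(kind = track_type_kind(track_type), raw = track_type)
  }
  if (track_type$kind %in% TRACK_TYPE_KINDS) {
    list(supported = TRUE, reason = "")
  } else {
    list(supported = FALSE,
         reason = sprintf("unsupported track type '%s'",
                          if (nzchar(track_type$raw)) track_type$raw
                          else "<none>"))
  }
}

#' Infer a hub track type from a Quickload data file name
#'
#' Track hubs require indexed binary formats, so only extensions with such a
#' format map: `.bw`/`.bigWig` -> bigWig, `.bb`/`.bigBed` -> bigBed,
#' `.bam` -> bam, `.cram` -> cram, `.vcf.gz` -> vcfTabix (all
#' case-insensitive).  Plain `.bed`, `.gff3`, un-bgzipped `.vcf` etc. are
#' unsupported.
#'
#' @param file_name Data file path or URL.
#' @return List `list(type = character or NA, reason = character)`.
#' @export
map_file_to_hub_type <- function(file_name) {
  low <- tolower(file_name)
  ext_map <- c("\\.bw$" = "bigWig", "\\.bigwig$" = "bigWig",
               "\\.bb$" = "bigBed", "\\.bigbed$" = "bigBed",
               "\\.bam$" = "bam", "\\.cram$" = "cram",
               "\\.vcf\\.gz$" = "vcfTabix")
  for (pat in names(ext_map)) {
    if (grepl(pat, low)) return(list(type = ext_map[[pat]], reason = ""))
  }
  ext <- sub("^.*\\.", "", basename(low))
  list(type = NA_character_,
       reason = sprintf(
         "no indexed hub format for '%s' (extension '%s')",
         basename(file_name), ext))
}

# ---- synonyms --------------------------------------------------------------

#' Genome naming synonyms between UCSC ids and Quickload directory names
#'
#' A one-to-one table like `hg38` <-> `H_sapiens_Dec_2013`.  Names without a
#' synonym pass through unchanged in both directions, which is the only safe
#' default for the tens of thousands of accession-named GenArk assemblies.
#'
#' @param ucsc,quickload Parallel character vectors of paired names.
#' @return A `qh_synonym_table`.
#' @export
synonym_table <- function(ucsc = character(), quickload = character()) {
  ucsc <- as.character(ucsc); quickload <- as.character(quickload)
  if (length(ucsc) != length(quickload)) {
    qh_value_error("ucsc and quickload must have the same length")
  }
  if (anyDuplicated(ucsc) || anyDuplicated(quickload)) {
    qh_value_error("synonym table must be one-to-one")
  }
  structure(list(ucsc = ucsc, quickload = quickload),
            class = "qh_synonym_table")
}

#' @rdname synonym_table
#' @return `default_synonyms()`: the shipped table covering common UCSC
#'   database names and their IGB Quickload directory counterparts.
#' @export
default_synonyms <- function() {
  synonym_table(
    ucsc = c("hg38", "hg19", "mm39", "mm10", "mm9", "rn6", "dm6", "ce11",
             "danRer11", "sacCer3", "galGal6", "bosTau9", "TAIR10"),
    quickload = c("H_sapiens_Dec_2013", "H_sapiens_Feb_2009",
                  "M_musculus_Jun_2020", "M_musculus_Dec_2011",
                  "M_musculus_Jul_2007", "R_norvegicus_Jul_2014",
                  "D_melanogaster_Aug_2014", "C_elegans_Feb_2013",
                  "D_rerio_May_2017", "S_cerevisiae_Apr_2011",
                  "G_gallus_Mar_2018", "B_taurus_Apr_2018",
                  "A_thaliana_Jun_2009")
  )
}

#' @rdname synonym_table
#' @param syn A `qh_synonym_table`.
#' @param ucsc_id,genome_dir The name to map; names absent from the table
#'   pass through unchanged.
#' @return `syn_to_quickload()` / `syn_to_ucsc()`: the mapped name.
#' @export
syn_to_quickload <- function(syn, ucsc_id) {
  i <- match(ucsc_id, syn$ucsc)
  if (is.na(i)) ucsc_id else syn$quickload[[i]]
}

#' @rdname synonym_table
#' @export
syn_to_ucsc <- function(syn, genome_dir) {
  i <- match(genome_dir, syn$quickload)
  if (is.na(i)) genome_dir else syn$ucsc[[i]]
}

# ---- conversion report -----------------------------------------------------

new_report <- function() {
  env <- new.env(parent = emptyenv())
  env$tracks_in <- 0L
  env$tracks_out <- 0L
  env$dropped <- list()      # list of list(track, reason)
  env$warnings <- character()
  env$genome_name_map <- character()
  env
}

report_drop <- function(rep, track, reason) {
  rep$dropped[[length(rep$dropped) + 1L]] <- list(track = track,
                                                  reason = reason)
}

seal_report <- function(rep) {
  structure(
    list(tracks_in = rep$tracks_in, tracks_out = rep$tracks_out,
         dropped = rep$dropped, warnings = rep$warnings,
         genome_name_map = rep$genome_name_map),
    class = "qh_conversion_report"
  )
}

#' @export
print.qh_conversion_report <- function(x, ...) {
  cat(sprintf("<conversion: %d track(s) in, %d out, %d dropped, %d warning(s)>\n",
              x$tracks_in, x$tracks_out, length(x$dropped),
              length(x$warnings)))
  for (d in x$dropped) cat(sprintf("  dropped %s: %s\n", d$track, d$reason))
  invisible(x)
}

#' Format a conversion report as log lines
#' @param x A `qh_conversion_report`.
#' @return Character vector of log lines.
#' @export
format_report <- function(x) {
  lines <- sprintf("tracks in: %d; out: %d; dropped: %d",
                   x$tracks_in, x$tracks_out, length(x$dropped))
  for (d in x$dropped) {
    lines <- c(lines, sprintf("dropped %s: %s", d$track, d$reason))
  }
  for (w in x$warnings) lines <- c(lines, paste("warning:", w))
  lines
}

# ---- sibling ordering ------------------------------------------------------

# Order the nodes of one forest level by priority (ascending, unset last),
# then source order; applied recursively.
order_siblings <- function(forest, tracks) {
  if (!length(forest)) return(forest)
  pri <- vapply(forest, function(nd) {
    p <- tracks[[nd$index]]$priority
    if (is.null(p)) Inf else p
  }, numeric(1))
  src <- vapply(forest, function(nd) nd$index, integer(1))
  forest <- forest[order(pri, src)]
  lapply(forest, function(nd) {
    nd$children <- order_siblings(nd$children, tracks)
    nd
  })
}

track_label <- function(t) {
  if (nzchar(t$long_label)) t$long_label
  else if (nzchar(t$short_label)) t$short_label
  else t$track_name
}

# ---- hub -> quickload ------------------------------------------------------

#' Translate a track hub into a Quickload repository
#'
#' Each genome becomes a contents.txt entry (using the synonym table, else
#' the genome id verbatim, with the hub's long label as description).  Each
#' leaf track of a supported type becomes an annots.xml entry: the data URL
#' is resolved to be absolute, the title is the `/`-joined path of container
#' and track labels (so superTracks/composites render as IGB folders), the
#' trackDb color becomes the foreground hex color, and the html page the
#' info url.  Settings with no annots.xml counterpart (visibility, raw type,
#' priority, every extras key, ...) are stashed as `x_hub_`-prefixed
#' attributes so [quickload_to_hub()] can restore them.  Container tracks
#' emit no entry of their own; unsupported track types are dropped and
#' accounted for in the report.  Siblings are ordered by priority
#' (ascending, unset last), then source order.
#'
#' @param hub A `qh_track_hub`.
#' @param synonyms A [synonym_table()].
#' @return List `list(repo, report)` with a `qh_quickload_repo` and a
#'   `qh_conversion_report` satisfying
#'   `tracks_out + length(dropped) == tracks_in`.
#' @export
hub_to_quickload <- function(hub, synonyms = default_synonyms()) {
  rep <- new_report()
  contents <- list()
  genomes <- list()

  gfile <- hub$manifest$genomes_file
  genomes_dir <- if (hub$manifest$use_one_file || !nzchar(gfile)) {
    hub$base_url
  } else {
    url_resolve_dir(hub$base_url, url_dirname(gfile))
  }

  res <- collect_warnings({
    for (g in hub$genomes) {
      gdir <- syn_to_quickload(synonyms, g$genome_id)
      rep$genome_name_map[[g$genome_id]] <- gdir
      contents[[length(contents) + 1L]] <-
        contents_entry(gdir, hub$manifest$long_label)

      tracks <- hub$tracks_by_genome[[g$genome_id]] %||% list()
      trackdb_dir <- url_resolve_dir(genomes_dir, url_dirname(g$trackdb_path))
      forest <- order_siblings(track_hierarchy(tracks), tracks)

      annots <- list()
      walk <- function(nodes, path) {
        for (nd in nodes) {
          t <- tracks[[nd$index]]
          is_container <- t$container_kind != "none" || length(nd$children)
          if (is_container) {
            walk(nd$children, c(path, track_label(t)))
            next
          }
          rep$tracks_in <- rep$tracks_in + 1L
          ok <- map_track_type_to_quickload(t$track_type)
          if (!ok$supported) {
            report_drop(rep, t$track_name, ok$reason)
            next
          }
          if (!nzchar(t$big_data_url)) {
            report_drop(rep, t$track_name, "leaf track has no bigDataUrl")
            next
          }
          annots[[length(annots) + 1L]] <<- track_to_annot(t, path, trackdb_dir)
          rep$tracks_out <- rep$tracks_out + 1L
        }
      }
      walk(forest, character())

      genomes[[gdir]] <- quickload_genome(
        genome_dir = gdir, annots = annots,
        two_bit_name = if (nzchar(g$two_bit_path)) basename(g$two_bit_path)
                       else ""
      )
    }
    NULL
  })
  rep$warnings <- c(rep$warnings, res$warnings)

  list(repo = quickload_repo(contents, genomes, base_url = hub$base_url),
       report = seal_report(rep))
}

# directory-of-directory resolution helper: `rel_dir` may be "." for flat
# layouts.
url_resolve_dir <- function(base_dir, rel_dir) {
  if (identical(rel_dir, ".") || !nzchar(rel_dir)) base_dir
  else url_resolve(base_dir, rel_dir)
}

# Translate one leaf track into an annots.xml entry.
track_to_annot <- function(t, path, trackdb_dir) {
  stash <- c(
    x_hub_track = t$track_name,
    if (nzchar(t$track_type$raw)) c(x_hub_type = t$track_type$raw),
    x_hub_visibility = t$visibility,
    if (nzchar(t$short_label)) c(x_hub_shortLabel = t$short_label),
    if (nzchar(t$big_data_index)) c(x_hub_bigDataIndex = t$big_data_index),
    if (!is.null(t$alt_color_rgb))
      c(x_hub_altColor = paste(t$alt_color_rgb, collapse = ",")),
    if (!is.null(t$priority)) c(x_hub_priority = fmt_num(t$priority)),
    if (nzchar(t$group)) c(x_hub_group = t$group)
  )
  # annots-native settings previously stashed on the hub side come home
  restored <- list()
  for (k in names(t$extras)) {
    if (startsWith(k, "x_ql_")) {
      restored[[substring(k, 6L)]] <- t$extras[[k]]
    } else {
      stash <- c(stash, stats::setNames(t$extras[[k]], paste0("x_hub_", k)))
    }
  }
  annot_entry(
    file_name = url_resolve(trackdb_dir, t$big_data_url),
    title = paste(c(path, track_label(t)), collapse = "/"),
    description = t$long_label,
    foreground_hex = if (!is.null(t$color_rgb))
      rgb_to_hex(t$color_rgb[1], t$color_rgb[2], t$color_rgb[3]),
    background_hex = restored[["background"]],
    load_hint = restored[["load_hint"]],
    label_field = restored[["label_field"]],
    info_url = if (nzchar(t$html_path)) url_resolve(trackdb_dir, t$html_path)
               else restored[["url"]],
    extras = stash
  )
}

# ---- quickload -> hub ------------------------------------------------------

#' Translate a Quickload repository into a track hub
#'
#' Each contents.txt entry becomes a genome (reverse synonym, else the
#' directory name verbatim).  Each annots.xml entry whose file extension has
#' an indexed hub format becomes a leaf track: the track name is a sanitized
#' unique token derived from the title leaf (or the stashed original name),
#' short label is the title leaf truncated to 17 characters, long label is
#' the description (else the title), the foreground color becomes the
#' trackDb color, and visibility defaults to `pack` unless a stashed
#' `x_hub_visibility` restores the original.  Multi-segment titles
#' synthesize one container track per distinct folder path (superTrack at
#' the top level, composite below), with children attached via `parent`.
#' `x_hub_`-prefixed stash attributes are restored to their original trackDb
#' keys; annots-native settings with no trackDb counterpart are stashed as
#' `x_ql_` extras for the return trip.  Unsupported extensions are dropped
#' with the extension in the reason.
#'
#' @param repo A `qh_quickload_repo`.
#' @param synonyms A [synonym_table()].
#' @return List `list(hub, report)`.
#' @export
quickload_to_hub <- function(repo, synonyms = default_synonyms()) {
  rep <- new_report()
  desc <- if (length(repo$contents)) repo$contents[[1]]$description else ""
  manifest <- hub_manifest(
    hub_name = "quickload_hub",
    short_label = truncate_label(if (nzchar(desc)) desc else "Quickload", 17L),
    long_label = if (nzchar(desc)) desc else "Converted Quickload repository"
  )

  genomes <- list()
  tracks_by_genome <- list()

  res <- collect_warnings({
    for (ce in repo$contents) {
      gid <- syn_to_ucsc(synonyms, ce$genome_dir)
      rep$genome_name_map[[ce$genome_dir]] <- gid
      qg <- repo$genomes[[ce$genome_dir]]
      genomes[[length(genomes) + 1L]] <- genome_entry(
        genome_id = gid,
        trackdb_path = paste0(gid, "/trackDb.txt"),
        two_bit_path = if (!is.null(qg) && nzchar(qg$two_bit_name))
          paste0(ce$genome_dir, "/", qg$two_bit_name) else ""
      )
      if (is.null(qg)) next
      genome_dir_url <- url_resolve(repo$base_url, ce$genome_dir)
      tracks_by_genome[[gid]] <-
        annots_to_tracks(qg$annots, genome_dir_url, rep)
    }
    NULL
  })
  rep$warnings <- c(rep$warnings, res$warnings)

  hub <- track_hub(manifest, genomes, tracks_by_genome,
                   base_url = repo$base_url)
  list(hub = hub, report = seal_report(rep))
}

sanitize_track_name <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  if (!nzchar(x)) x <- "t"
  if (grepl("^[0-9]", x)) x <- paste0("t_", x)
  x
}

annots_to_tracks <- function(annots, genome_dir_url, rep) {
  tracks <- list()
  used <- character()
  containers <- character()  # folder path -> container track name

  unique_name <- function(base) {
    nm <- base
    i <- 1L
    while (nm %in% used) {
      i <- i + 1L
      nm <- sprintf("%s_%d", base, i)
    }
    used <<- c(used, nm)
    nm
  }

  ensure_container <- function(segs) {
    # create container tracks for every prefix of `segs`; returns the name
    # of the deepest one ("" when segs is empty)
    parent <- ""
    for (d in seq_along(segs)) {
      key <- paste(segs[1:d], collapse = "/")
      if (!key %in% names(containers)) {
        nm <- unique_name(sanitize_track_name(key))
        containers[[key]] <<- nm
        tracks[[length(tracks) + 1L]] <<- track_def(
          track_name = nm,
          short_label = truncate_label(segs[[d]], 17L),
          long_label = segs[[d]],
          parent_name = parent,
          container_kind = if (d == 1L) "superTrack" else "composite"
        )
      }
      parent <- containers[[key]]
    }
    parent
  }

  for (a in annots) {
    rep$tracks_in <- rep$tracks_in + 1L

    stash <- list()
    extras <- character()
    for (k in names(a$extras)) {
      if (startsWith(k, "x_hub_")) {
        stash[[substring(k, 7L)]] <- a$extras[[k]]
      } else {
        extras <- c(extras, stats::setNames(a$extras[[k]],
                                            paste0("x_ql_", k)))
      }
    }
    # annots-native typed settings with no trackDb home ride along too
    if (!is.null(a$background_hex)) {
      extras <- c(extras, c(x_ql_background = a$background_hex))
    }
    if (!is.null(a$load_hint)) {
      extras <- c(extras, c(x_ql_load_hint = a$load_hint))
    }
    if (!is.null(a$label_field)) {
      extras <- c(extras, c(x_ql_label_field = a$label_field))
    }

    type_raw <- stash[["type"]]
    if (is.null(type_raw)) {
      m <- map_file_to_hub_type(a$file_name)
      if (is.na(m$type)) {
        report_drop(rep, if (nzchar(a$title)) a$title else a$file_name,
                    m$reason)
        next
      }
      type_raw <- m$type
    }

    segs <- strsplit(a$title, "/", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    leaf <- if (length(segs)) segs[[length(segs)]] else basename(a$file_name)
    folder <- if (length(segs) > 1L) segs[-length(segs)] else character()
    parent <- ensure_container(folder)

    base_name <- stash[["track"]] %||% sanitize_track_name(leaf)
    nm <- unique_name(sanitize_track_name(base_name))

    vis <- stash[["visibility"]] %||% "pack"
    pri <- if (!is.null(stash[["priority"]]))
      suppressWarnings(as.numeric(stash[["priority"]])) else NULL
    if (length(pri) && is.na(pri)) pri <- NULL
    alt <- if (!is.null(stash[["altColor"]]))
      suppressWarnings(as.integer(
        strsplit(stash[["altColor"]], ",", fixed = TRUE)[[1]])) else NULL
    if (length(alt) && anyNA(alt)) alt <- NULL

    consumed <- c("track", "type", "visibility", "shortLabel",
                  "bigDataIndex", "altColor", "priority", "group")
    for (k in setdiff(names(stash), consumed)) {
      extras <- c(extras, stats::setNames(stash[[k]], k))
    }

    tracks[[length(tracks) + 1L]] <- track_def(
      track_name = nm,
      type_raw = type_raw,
      big_data_url = url_resolve(genome_dir_url, a$file_name),
      big_data_index = stash[["bigDataIndex"]] %||% "",
      short_label = stash[["shortLabel"]] %||% truncate_label(leaf, 17L),
      long_label = if (nzchar(a$description)) a$description else leaf,
      visibility = vis,
      color_rgb = if (!is.null(a$foreground_hex)) hex_to_rgb(a$foreground_hex),
      alt_color_rgb = alt,
      parent_name = parent,
      parent_default_on = TRUE,
      priority = pri,
      html_path = a$info_url %||% "",
      group = stash[["group"]] %||% "",
      extras = extras
    )
    rep$tracks_out <- rep$tracks_out + 1L
  }
  tracks
}

# ---- canonical core --------------------------------------------------------

#' The canonical per-track core preserved by a round trip
#'
#' Reduces a hub to the per-track facts that must survive
#' hub -> Quickload -> hub translation for supported track types even
#' without the `x_hub_` stash: resolved data URL, type kind, color,
#' visibility, long label, and `/`-joined hierarchy path of labels.  Used
#' by round-trip tests; container tracks and unsupported types are excluded.
#'
#' @param hub A `qh_track_hub`.
#' @return Data frame keyed by `url`, sorted by `url`, with columns `url`,
#'   `kind`, `color`, `visibility`, `long_label`, `path`.
#' @export
canonical_track_core <- function(hub) {
  gfile <- hub$manifest$genomes_file
  genomes_dir <- if (hub$manifest$use_one_file || !nzchar(gfile)) {
    hub$base_url
  } else {
    url_resolve_dir(hub$base_url, url_dirname(gfile))
  }
  rows <- list()
  for (g in hub$genomes) {
    tracks <- hub$tracks_by_genome[[g$genome_id]] %||% list()
    trackdb_dir <- url_resolve_dir(genomes_dir, url_dirname(g$trackdb_path))
    forest <- track_hierarchy(tracks)
    walk <- function(nodes, path) {
      for (nd in nodes) {
        t <- tracks[[nd$index]]
        if (t$container_kind != "none" || length(nd$children)) {
          walk(nd$children, c(path, track_label(t)))
          next
        }
        if (!map_track_type_to_quickload(t$track_type)$supported) next
        rows[[length(rows) + 1L]] <<- data.frame(
          genome = g$genome_id,
          url = url_resolve(trackdb_dir, t$big_data_url),
          kind = t$track_type$kind,
          color = if (is.null(t$color_rgb)) ""
                  else paste(t$color_rgb, collapse = ","),
          visibility = t$visibility,
          long_label = t$long_label,
          path = paste(c(path, track_label(t)), collapse = "/")
        )
      }
    }
    walk(forest, character())
  }
  if (!length(rows)) {
    return(data.frame(genome = character(), url = character(),
                      kind = character(), color = character(),
                      visibility = character(), long_label = character(),
                      path = character()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$url), , drop = FALSE]
  rownames(out) <- NULL
  out
}
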