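# Whole-repository conversion: load a complete source (local directory or
# URL), translate, write the full translated tree to disk.  This is the
# offline counterpart of the on-demand facade in resolve().

#' Load a complete track hub through a transport
#'
#' @param source Path or URL of hub.txt (a directory is taken to contain
#'   `hub.txt`).
#' @param transport A transport function; defaults to [file_transport()]
#'   for local paths.
#' @return A `qh_track_hub` with every genome's trackDb loaded.
#' @export
read_trackhub <- function(source, transport = file_transport()) {
  if (dir.exists(source)) source <- file.path(source, "hub.txt")
  load_hub_lazy(source, transport, trackdb_for = "*")
}

#' Load a complete Quickload repository through a transport
#'
#' Reads contents.txt, then each genome's annots.xml (a genome directory
#' without one is modeled as empty, with a warning) and genome.txt when
#' present.
#'
#' @param source Path or URL of the repository root directory.
#' @param transport A transport function.
#' @return A `qh_quickload_repo`.
#' @export
read_quickload <- function(source, transport = file_transport()) {
  root <- sub("/+$", "", source)
  contents <- parse_contents(fetch_text(transport, paste0(root, "/contents.txt")))
  genomes <- list()
  for (ce in contents) {
    d <- ce$genome_dir
    xml <- transport(paste0(root, "/", d, "/annots.xml"))
    if (is.null(xml)) {
      qh_warn(sprintf("genome '%s' has no annots.xml; modeled as empty", d))
      annots <- list()
    } else {
      annots <- parse_annots(decode_text(xml))
    }
    gt <- transport(paste0(root, "/", d, "/genome.txt"))
    genomes[[d]] <- quickload_genome(
      d, annots = annots,
      chromosomes = if (!is.null(gt)) parse_genome_table(decode_text(gt))
    )
  }
  quickload_repo(contents, genomes, base_url = root)
}

write_file_tree <- function(files, out_dir) {
  for (path in names(files)) {
    dest <- file.path(out_dir, path)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    content <- files[[path]]
    if (is.raw(content)) {
      writeBin(content, dest)
    } else {
      con <- file(dest, "wb")   # keep LF endings everywhere
      writeChar(content, con, eos = NULL)
      close(con)
    }
  }
  invisible(names(files))
}

#' Convert a whole repository and write it to disk
#'
#' Loads the complete source, translates it, and writes the full target
#' tree under `out_dir` (for `to_quickload`: contents.txt plus per-genome
#' annots.xml and, when the hub declares a `twoBitPath`, a synthesized
#' genome.txt; for `to_trackhub`: hub.txt, genomes.txt, per-genome
#' trackDb.txt).
#'
#' @param source Local directory/file or URL of the source hub.txt /
#'   Quickload root.
#' @param direction `"to_quickload"` or `"to_trackhub"`.
#' @param out_dir Output directory (created if needed).
#' @param synonyms A [synonym_table()].
#' @param transport Transport used to fetch the source.
#' @param one_file For `to_trackhub`, emit the `useOneFile` dialect?
#' @return Invisibly, a list with `status` (0 ok, 1 structural problems),
#'   `report` (the `qh_conversion_report`) and `files` (relative paths
#'   written).
#' @export
cli_convert <- function(source,
                        direction = c("to_quickload", "to_trackhub"),
                        out_dir, synonyms = default_synonyms(),
                        transport = file_transport(), one_file = FALSE) {
  direction <- match.arg(direction)
  status <- 0L

  if (direction == "to_quickload") {
    hub <- read_trackhub(source, transport)
    tr <- suppress_qh_warnings(hub_to_quickload(hub, synonyms))
    repo <- tr$repo
    # synthesize genome.txt for assembly hubs from the 2bit index
    gfile <- if (nzchar(hub$manifest$genomes_file)) hub$manifest$genomes_file
             else "genomes.txt"
    genomes_dir <- if (hub$manifest$use_one_file) hub$base_url
                   else url_dirname(url_resolve(hub$base_url, gfile))
    for (g in hub$genomes) {
      if (!nzchar(g$two_bit_path)) next
      gdir <- syn_to_quickload(synonyms, g$genome_id)
      idx <- tryCatch(
        twobit_index_via_transport(url_resolve(genomes_dir, g$two_bit_path),
                                   transport),
        quickhub_error = function(e) {
          qh_warn(sprintf("cannot read 2bit for %s: %s", g$genome_id,
                          conditionMessage(e)))
          NULL
        })
      if (!is.null(idx)) {
        repo$genomes[[gdir]]$chromosomes <- genome_table_from_twobit(idx)
      }
    }
    files <- serialize_quickload(repo)
  } else {
    repo <- read_quickload(source, transport)
    tr <- suppress_qh_warnings(quickload_to_hub(repo, synonyms))
    files <- serialize_trackhub(tr$hub, one_file = one_file)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_file_tree(files, out_dir)
  invisible(list(status = status, report = tr$report, files = names(files)))
}
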