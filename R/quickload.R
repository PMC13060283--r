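# Typed model of an IGB Quickload repository: contents.txt (genome
# directory list), per-genome annots.xml (track definitions) and genome.txt
# (chromosome names and lengths).

# Canonical annots.xml attributes, in emission order; everything else is
# preserved in extras.
ANNOT_ATTRS <- c(name = "file_name", title = "title",
                 description = "description", foreground = "foreground_hex",
                 background = "background_hex", load_hint = "load_hint",
                 label_field = "label_field", url = "info_url")

#' Construct a contents.txt entry
#'
#' @param genome_dir Genome directory name (e.g. `"H_sapiens_Dec_2013"`);
#'   must not contain a tab or `/`.
#' @param description Free-text description shown in IGB's genome chooser.
#' @return A `qh_contents_entry` list.
#' @export
contents_entry <- function(genome_dir, description = "") {
  if (!nzchar(genome_dir)) qh_value_error("genome_dir must be non-empty")
  if (grepl("[\t/]", genome_dir)) {
    qh_value_error(sprintf("genome_dir '%s' contains a tab or '/'",
                           genome_dir))
  }
  structure(list(genome_dir = genome_dir, description = description),
            class = "qh_contents_entry")
}

#' Construct an annots.xml entry
#'
#' @param file_name Data file path (relative to the genome directory) or
#'   absolute URL.
#' @param title Display title; `/`-separated segments encode the folder
#'   hierarchy shown in IGB's Available Data tab.
#' @param description Free-text description.
#' @param foreground_hex,background_hex 6-hex-digit colors (normalized to
#'   uppercase) or `NULL` when unset.
#' @param load_hint,label_field,info_url Optional IGB display settings
#'   (`NULL` when unset).
#' @param extras Named character vector of additional attributes preserved
#'   verbatim.
#' @return A `qh_annot_entry` list.
#' @export
annot_entry <- function(file_name, title = "", description = "",
                        foreground_hex = NULL, background_hex = NULL,
                        load_hint = NULL, label_field = NULL,
                        info_url = NULL, extras = character()) {
  if (!nzchar(file_name)) qh_value_error("file_name must be non-empty")
  norm_hex <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!grepl("^[0-9A-Fa-f]{6}$", x)) {
      qh_value_error(sprintf("%s '%s' is not a 6-hex-digit color", what, x))
    }
    toupper(x)
  }
  structure(
    list(file_name = file_name, title = title, description = description,
         foreground_hex = norm_hex(foreground_hex, "foreground"),
         background_hex = norm_hex(background_hex, "background"),
         load_hint = load_hint, label_field = label_field,
         info_url = info_url, extras = as_extras(extras)),
    class = "qh_annot_entry"
  )
}

#' Construct a Quickload genome
#'
#' @param genome_dir Directory name, matching a [contents_entry()].
#' @param annots List of [annot_entry()] values in display order.
#' @param chromosomes Data frame with columns `seq_name`, `length`
#'   (genome.txt rows), or `NULL`/empty when unknown.
#' @param two_bit_name File name of the assembly 2bit within the genome
#'   directory, or `""`.
#' @return A `qh_quickload_genome` list.
#' @export
quickload_genome <- function(genome_dir, annots = list(),
                             chromosomes = NULL, two_bit_name = "") {
  chromosomes <- as_genome_table(chromosomes)
  structure(
    list(genome_dir = genome_dir, annots = annots,
         chromosomes = chromosomes, two_bit_name = two_bit_name),
    class = "qh_quickload_genome"
  )
}

as_genome_table <- function(x) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x))) {
    return(data.frame(seq_name = character(), length = numeric()))
  }
  x <- as.data.frame(x)
  stopifnot(all(c("seq_name", "length") %in% names(x)))
  x <- x[, c("seq_name", "length")]
  if (anyDuplicated(x$seq_name)) {
    qh_value_error("duplicate seq_name in genome table")
  }
  if (any(x$length < 1)) {
    qh_value_error("genome table lengths must be >= 1")
  }
  rownames(x) <- NULL
  x
}

#' Construct a whole Quickload repository model
#'
#' @param contents List of [contents_entry()] values in display order.
#' @param genomes Named list (genome_dir -> [quickload_genome()]); every
#'   name must appear in `contents`.
#' @param base_url Absolute URL or local directory of the repository root.
#' @return A `qh_quickload_repo` list.
#' @export
quickload_repo <- function(contents, genomes = list(), base_url = "") {
  dirs <- vapply(contents, function(x) x$genome_dir, character(1))
  unknown <- setdiff(names(genomes), dirs)
  if (length(unknown)) {
    qh_structural_error(sprintf(
      "genomes absent from contents.txt: %s", paste(unknown, collapse = ", ")))
  }
  structure(list(contents = contents, genomes = genomes, base_url = base_url),
            class = "qh_quickload_repo")
}

#' @export
print.qh_quickload_repo <- function(x, ...) {
  n_annots <- sum(vapply(x$genomes, function(g) length(g$annots), integer(1)))
  cat(sprintf("<quickload repo: %d genome(s), %d annot(s)>\n",
              length(x$contents), n_annots))
  invisible(x)
}

# ---- contents.txt ----------------------------------------------------------

#' Parse contents.txt
#'
#' Each non-blank, non-`#` line splits on the first tab into a genome
#' directory name and a free-text description (a line without a tab has an
#' empty description).
#'
#' @param text File contents.
#' @return List of [contents_entry()] values in file order.
#' @export
parse_contents <- function(text) {
  text <- decode_text(text)
  lines <- strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    tab <- regexpr("\t", line, fixed = TRUE)
    if (tab == -1L) {
      dir <- trimws(line); desc <- ""
    } else {
      dir <- substr(line, 1L, tab - 1L)
      desc <- sub("[ \t]+$", "", substring(line, tab + 1L))
    }
    if (!nzchar(dir)) qh_parse_error("contents.txt line has no genome directory", i)
    out[[length(out) + 1L]] <- contents_entry(dir, desc)
  }
  out
}

#' @rdname parse_contents
#' @param entries List of [contents_entry()] values.
#' @return `serialize_contents()`: a single string, one tab-separated line
#'   per entry with trailing newline.
#' @export
serialize_contents <- function(entries) {
  if (!length(entries)) return("")
  paste0(paste(vapply(entries, function(e) {
    paste0(e$genome_dir, "\t", e$description)
  }, character(1)), collapse = "\n"), "\n")
}

# ---- annots.xml ------------------------------------------------------------

#' Parse annots.xml
#'
#' Reads every direct child element named `file` of the document root (any
#' root element name is accepted).  Canonical attributes (`name`, `title`,
#' `description`, `foreground`, `background`, `load_hint`, `label_field`,
#' `url`) populate typed fields; all other attributes are preserved in
#' `extras`.  Hex colors are normalized to uppercase; 3-digit shorthand is
#' rejected with a warning (the entry is kept with the color unset).  A
#' `file` element without a `name` attribute is skipped with a warning.
#'
#' @param xml_text The XML document as a string.
#' @return List of [annot_entry()] values in document order.
#' @export
parse_annots <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(decode_text(xml_text)),
                  error = function(e) {
                    qh_parse_error(paste("malformed annots.xml:",
                                         conditionMessage(e)))
                  })
  out <- list()
  for (node in xml2::xml_find_all(doc, "/*/file")) {
    at <- xml2::xml_attrs(node)
    if (!"name" %in% names(at) || !nzchar(at[["name"]])) {
      qh_warn("annots.xml 'file' element without a name attribute skipped")
      next
    }
    take_hex <- function(key) {
      if (!key %in% names(at)) return(NULL)
      v <- at[[key]]
      if (!grepl("^[0-9A-Fa-f]{6}$", v)) {
        qh_warn(sprintf("file '%s': %s color '%s' is not 6 hex digits; unset",
                        at[["name"]], key, v))
        return(NULL)
      }
      toupper(v)
    }
    take <- function(key) if (key %in% names(at)) at[[key]] else NULL
    extras <- at[!(names(at) %in% names(ANNOT_ATTRS))]
    out[[length(out) + 1L]] <- annot_entry(
      file_name = at[["name"]],
      title = take("title") %||% "",
      description = take("description") %||% "",
      foreground_hex = take_hex("foreground"),
      background_hex = take_hex("background"),
      load_hint = take("load_hint"),
      label_field = take("label_field"),
      info_url = take("url"),
      extras = extras
    )
  }
  out
}

#' Serialize annots.xml
#'
#' Emits a `<files>` root with one `<file>` element per entry; canonical
#' attributes first (in canonical order), extras after, attribute values
#' XML-escaped.  The output re-parses to the same entries.
#'
#' @param entries List of [annot_entry()] values.
#' @return The XML document as a string (with XML declaration and trailing
#'   newline).
#' @export
serialize_annots <- function(entries) {
  doc <- xml2::xml_new_root("files")
  for (e in entries) {
    attrs <- c(
      name = e$file_name,
      if (nzchar(e$title)) c(title = e$title),
      if (nzchar(e$description)) c(description = e$description),
      if (!is.null(e$foreground_hex)) c(foreground = e$foreground_hex),
      if (!is.null(e$background_hex)) c(background = e$background_hex),
      if (!is.null(e$load_hint)) c(load_hint = e$load_hint),
      if (!is.null(e$label_field)) c(label_field = e$label_field),
      if (!is.null(e$info_url)) c(url = e$info_url),
      e$extras
    )
    node <- xml2::xml_add_child(doc, "file")
    xml2::xml_set_attrs(node, attrs)
  }
  as.character(doc)
}

# ---- genome.txt ------------------------------------------------------------

#' Parse and serialize genome.txt chromosome tables
#'
#' genome.txt lists one `seq_name<TAB>length` row per chromosome, in the
#' order the browser should present them (never re-sorted).
#'
#' @param text File contents.
#' @return `parse_genome_table()`: data frame with columns `seq_name`,
#'   `length` (numeric, to allow chromosomes beyond 2^31 bases).
#' @export
parse_genome_table <- function(text) {
  text <- decode_text(text)
  lines <- strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  nm <- character(); len <- numeric()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[[1]])) {
      qh_parse_error("genome.txt line is not 'seq_name<TAB>length'", i)
    }
    l <- suppressWarnings(as.numeric(parts[[2]]))
    if (is.na(l) || l < 1) {
      qh_parse_error(sprintf("invalid sequence length '%s'", parts[[2]]), i)
    }
    nm <- c(nm, parts[[1]]); len <- c(len, l)
  }
  as_genome_table(data.frame(seq_name = nm, length = len))
}

#' @rdname parse_genome_table
#' @param rows Data frame with columns `seq_name`, `length`; unique names,
#'   lengths >= 1.
#' @return `serialize_genome_table()`: tab-separated text, one row per
#'   sequence in input order.
#' @export
serialize_genome_table <- function(rows) {
  rows <- as_genome_table(rows)
  if (!nrow(rows)) return("")
  paste0(paste(paste0(rows$seq_name, "\t", fmt_num(rows$length)),
               collapse = "\n"), "\n")
}

# ---- whole repository ------------------------------------------------------

#' Build a Quickload repository model from its file texts
#'
#' @param contents_text contents.txt contents.
#' @param annots_texts Named list (genome_dir -> annots.xml text).
#' @param genome_texts Named list (genome_dir -> genome.txt text); optional.
#' @param two_bit_names Named character vector (genome_dir -> 2bit file
#'   name); optional.
#' @param base_url Absolute URL or local directory of the repository root.
#' @return A `qh_quickload_repo`.
#' @export
build_quickload <- function(contents_text, annots_texts = list(),
                            genome_texts = list(),
                            two_bit_names = character(), base_url = "") {
  contents <- parse_contents(contents_text)
  genomes <- list()
  for (ce in contents) {
    d <- ce$genome_dir
    if (is.null(annots_texts[[d]]) && is.null(genome_texts[[d]])) next
    genomes[[d]] <- quickload_genome(
      genome_dir = d,
      annots = if (!is.null(annots_texts[[d]]))
                 parse_annots(annots_texts[[d]]) else list(),
      chromosomes = if (!is.null(genome_texts[[d]]))
                      parse_genome_table(genome_texts[[d]]) else NULL,
      two_bit_name = if (d %in% names(two_bit_names)) two_bit_names[[d]] else ""
    )
  }
  quickload_repo(contents, genomes, base_url)
}

#' Serialize a Quickload repository model to its file texts
#'
#' @param repo A `qh_quickload_repo`.
#' @return Named list mapping relative path -> file text: `contents.txt`
#'   plus `<genome_dir>/annots.xml` per modeled genome and
#'   `<genome_dir>/genome.txt` where chromosomes are known.
#' @export
serialize_quickload <- function(repo) {
  out <- list()
  out[["contents.txt"]] <- serialize_contents(repo$contents)
  for (d in names(repo$genomes)) {
    g <- repo$genomes[[d]]
    out[[paste0(d, "/annots.xml")]] <- serialize_annots(g$annots)
    if (nrow(g$chromosomes)) {
      out[[paste0(d, "/genome.txt")]] <- serialize_genome_table(g$chromosomes)
    }
  }
  out
}
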