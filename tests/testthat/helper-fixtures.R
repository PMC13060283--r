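# Shared helpers: rebuild models from generated fixture files, and an
# independent naive stanza parser used as an oracle.

# Rebuild a hub model from the files emitted by generate_hub() (split form).
rebuild_hub <- function(fx) {
  gids <- vapply(fx$hub$genomes, function(g) g$genome_id, character(1))
  tdb <- stats::setNames(
    lapply(fx$hub$genomes, function(g) fx$files[[g$trackdb_path]]), gids)
  build_trackhub(fx$files[["hub.txt"]], fx$files[["genomes.txt"]],
                 trackdb_texts = tdb, base_url = fx$hub$base_url)
}

rebuild_quickload <- function(fq) {
  dirs <- names(fq$repo$genomes)
  build_quickload(
    fq$files[["contents.txt"]],
    annots_texts = stats::setNames(
      lapply(dirs, function(d) fq$files[[paste0(d, "/annots.xml")]]), dirs),
    genome_texts = stats::setNames(
      lapply(dirs, function(d) fq$files[[paste0(d, "/genome.txt")]]), dirs),
    two_bit_names = vapply(fq$repo$genomes, function(g) g$two_bit_name,
                           character(1)),
    base_url = fq$repo$base_url
  )
}

# Memory transport serving a fixture's files below an absolute base URL.
fixture_transport <- function(files, base) {
  memory_transport(stats::setNames(files, paste0(base, "/", names(files))))
}

# Independent oracle for the stanza dialect: strip comments and
# indentation, then split blocks on blank lines and each line on the first
# whitespace run.  Shares no code with parse_stanzas().
naive_stanza_oracle <- function(text) {
  lines <- strsplit(gsub("\r\n?", "\n", text), "\n")[[1]]
  lines <- lines[!grepl("^[ \t]*#", lines)]
  lines <- sub("^[ \t]+", "", lines)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  out <- list()
  for (b in blocks) {
    b <- b[nzchar(trimws(b))]
    if (!length(b)) next
    keys <- sub("[ \t].*$", "", b)
    vals <- ifelse(grepl("[ \t]", b),
                   sub("[ \t]+$", "", sub("^[^ \t]+[ \t]+", "", b)), "")
    out[[length(out) + 1L]] <- list(keys = keys, values = vals)
  }
  out
}

stanza_pairs <- function(stanzas) {
  lapply(stanzas, function(s) list(keys = s$keys, values = s$values))
}

# sum of leaf (non-container) tracks in a hub model
count_leaf_tracks <- function(hub) {
  total <- 0L
  for (gid in names(hub$tracks_by_genome)) {
    tracks <- hub$tracks_by_genome[[gid]]
    parents <- unlist(lapply(tracks, function(t) t$parent_name))
    for (t in tracks) {
      is_container <- t$container_kind != "none" ||
        t$track_name %in% parents
      if (!is_container) total <- total + 1L
    }
  }
  total
}

expect_same_model <- function(got, want) {
  expect_equal(got, want)
}

# Brute-force catalog search oracle, independent of search_catalog()'s
# vectorized implementation: loop over rows and tokens.
scan_oracle <- function(records, query) {
  tokens <- strsplit(trimws(query), "[ \t]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(records)
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    ok <- TRUE
    for (tok in tokens) {
      fields <- c(records$common_name[i], records$scientific_name[i],
                  records$assembly_name[i], records$accession[i])
      hit <- any(grepl(tolower(tok), tolower(fields), fixed = TRUE)) ||
        identical(as.character(records$taxon_id[i]), tok)
      if (!hit) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
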