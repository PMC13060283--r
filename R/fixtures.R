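# Deterministic synthetic-data generator.  Every other module is tested
# against hubs, Quickload repositories, 2bit files and catalogs produced
# here: generation is a pure function of the fixture spec (seeded), and the
# ground-truth model is returned alongside the serialized files so parsers
# can be checked field by field.  Placeholder data files are zero-byte on
# purpose -- the translator's contract is to never open them.

#' Specification for one synthetic fixture
#'
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param n_genomes Number of genomes.
#' @param tracks_per_genome Length-2 integer range (inclusive) of leaf
#'   tracks per genome.
#' @param type_mix Named non-negative weights over
#'   `bigWig, bigBed, bam, cram, vcfTabix, unsupported` for sampling leaf
#'   track types.
#' @param hierarchy_depth 0 (flat), 1 (superTrack folders) or 2
#'   (superTrack > composite).
#' @param with_two_bit Emit a real miniature 2bit per genome (and declare
#'   it via `twoBitPath` / genome.txt)?
#' @param with_colors Probability that a track gets an explicit color.
#' @return A `qh_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genomes = 1L,
                         tracks_per_genome = c(2L, 4L),
                         type_mix = c(bigWig = 3, bigBed = 2, bam = 2,
                                      cram = 1, vcfTabix = 1,
                                      unsupported = 0),
                         hierarchy_depth = 1L, with_two_bit = FALSE,
                         with_colors = 0.7) {
  if (any(type_mix < 0) || all(type_mix == 0)) {
    qh_value_error("type_mix weights must be non-negative and not all zero")
  }
  if (!hierarchy_depth %in% 0:2) {
    qh_value_error("hierarchy_depth must be 0, 1 or 2")
  }
  structure(
    list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
         tracks_per_genome = as.integer(tracks_per_genome),
         type_mix = type_mix, hierarchy_depth = as.integer(hierarchy_depth),
         with_two_bit = isTRUE(with_two_bit),
         with_colors = as.numeric(with_colors)),
    class = "qh_fixture_spec"
  )
}

TYPE_EXT <- c(bigWig = ".bw", bigBed = ".bb", bam = ".bam", cram = ".cram",
              vcfTabix = ".vcf.gz", unsupported = ".bedGraph")

sample_weighted <- function(choices, weights, n) {
  keep <- weights > 0
  sample(choices[keep], n, replace = TRUE, prob = weights[keep])
}

rand_dna <- function(len, with_n_run = FALSE) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (with_n_run && len >= 6L) {
    at <- sample.int(len - 3L, 1L)
    bases[at:(at + 2L)] <- "N"
  }
  paste(bases, collapse = "")
}

fixture_genome_ids <- function(n) {
  pool <- c("hg38", "mm39", "dm6", "ce11", "danRer11", "sacCer3", "galGal6",
            "bosTau9", "rn6", "TAIR10")
  ids <- sample(pool, min(n, length(pool)))
  while (length(ids) < n) {
    ids <- c(ids, sprintf("GCF_%09d.1", sample.int(999999999L, 1L)))
  }
  ids
}

# leaf tracks plus containers for one genome; returns list(tracks)
gen_tracks <- function(spec, gi) {
  n_leaf <- sample(seq(spec$tracks_per_genome[[1]],
                       spec$tracks_per_genome[[2]]), 1L)
  kinds <- sample_weighted(names(spec$type_mix), spec$type_mix, n_leaf)

  tracks <- list()
  super_name <- ""
  comp_name <- ""
  if (spec$hierarchy_depth >= 1L) {
    super_name <- sprintf("grp_g%d", gi)
    tracks[[length(tracks) + 1L]] <- track_def(
      track_name = super_name,
      short_label = sprintf("Group %d", gi),
      long_label = sprintf("Sample group %d", gi),
      container_kind = "superTrack"
    )
  }
  if (spec$hierarchy_depth >= 2L) {
    comp_name <- sprintf("rep_g%d", gi)
    tracks[[length(tracks) + 1L]] <- track_def(
      track_name = comp_name,
      short_label = sprintf("Replicates %d", gi),
      long_label = sprintf("Replicate set %d", gi),
      parent_name = super_name, container_kind = "composite"
    )
  }

  for (i in seq_len(n_leaf)) {
    kind <- kinds[[i]]
    nm <- sprintf("trk_g%d_%d", gi, i)
    parent <- if (spec$hierarchy_depth == 0L) {
      ""
    } else if (spec$hierarchy_depth == 1L) {
      if (i %% 2L == 1L) super_name else ""
    } else {
      c("", super_name, comp_name)[[(i %% 3L) + 1L]]
    }
    color <- if (stats::runif(1) < spec$with_colors) {
      sample(0:255, 3L, replace = TRUE)
    }
    pri <- if (stats::runif(1) < 0.4) sample(1:50, 1L)
    extras <- if (stats::runif(1) < 0.3) {
      c(maxHeightPixels = "100:32:8")
    } else {
      character()
    }
    tracks[[length(tracks) + 1L]] <- track_def(
      track_name = nm,
      type_raw = if (kind == "unsupported") "bedGraph" else kind,
      big_data_url = paste0("data/", nm, TYPE_EXT[[kind]]),
      short_label = truncate_label(sprintf("T %d.%d", gi, i), 17L),
      long_label = sprintf("Coverage sample %d replicate %d", gi, i),
      visibility = sample(VISIBILITY_VALUES, 1L),
      color_rgb = color,
      parent_name = parent,
      priority = pri,
      extras = extras
    )
  }
  tracks
}

#' Generate a synthetic track hub
#'
#' Emits hub.txt (+ genomes.txt + per-genome trackDb.txt in split layout),
#' zero-byte placeholder data files at every referenced relative location,
#' and (with `with_two_bit`) a real miniature 2bit per genome, together
#' with the ground-truth model the files encode.
#'
#' @param spec A [fixture_spec()].
#' @param one_file Emit the `useOneFile` single-file dialect?
#' @param base_url Hub location baked into the model (fixtures default to
#'   an absolute https URL so resolved data URLs are absolute).
#' @return List `list(files, hub)`: `files` maps relative path -> content
#'   (text or raw), `hub` is the `qh_track_hub` that
#'   [build_trackhub()] on those files must reproduce.
#' @export
generate_hub <- function(spec, one_file = FALSE,
                         base_url = "https://example.org/fixturehub") {
  with_seed(spec$seed, {
    gids <- fixture_genome_ids(spec$n_genomes)
    genomes <- list()
    tracks_by_genome <- list()
    files <- list()

    for (gi in seq_along(gids)) {
      gid <- gids[[gi]]
      two_bit_path <- ""
      if (spec$with_two_bit) {
        n_seq <- sample(1:3, 1L)
        seqs <- stats::setNames(
          vapply(seq_len(n_seq),
                 function(s) rand_dna(sample(20:60, 1L), s == 1L),
                 character(1)),
          paste0("chr", seq_len(n_seq)))
        two_bit_path <- paste0(gid, ".2bit")
        files[[two_bit_path]] <- write_twobit(seqs)
      }
      genomes[[gi]] <- genome_entry(
        genome_id = gid,
        trackdb_path = paste0(gid, "/trackDb.txt"),
        two_bit_path = two_bit_path,
        organism = sprintf("Organism %d", gi)
      )
      tracks <- gen_tracks(spec, gi)
      tracks_by_genome[[gid]] <- tracks
      for (t in tracks) {
        if (nzchar(t$big_data_url)) {
          files[[paste0(gid, "/", t$big_data_url)]] <- raw(0)
        }
      }
    }

    manifest <- hub_manifest(
      hub_name = sprintf("fixture_hub_%d", spec$seed),
      short_label = "Fixture hub",
      long_label = sprintf("Synthetic fixture hub seed %d", spec$seed),
      use_one_file = one_file
    )
    hub <- track_hub(manifest, genomes, tracks_by_genome, base_url)
    files <- c(serialize_trackhub(hub, one_file = one_file), files)
    list(files = files, hub = hub)
  })
}

fixture_quickload_dirs <- function(n) {
  pool <- c("H_sapiens_Dec_2013", "M_musculus_Jun_2020",
            "D_melanogaster_Aug_2014", "C_elegans_Feb_2013",
            "D_rerio_May_2017", "S_cerevisiae_Apr_2011",
            "G_gallus_Mar_2018", "B_taurus_Apr_2018")
  dirs <- sample(pool, min(n, length(pool)))
  while (length(dirs) < n) {
    dirs <- c(dirs, sprintf("GCA_%09d.1", sample.int(999999999L, 1L)))
  }
  dirs
}

QL_EXT <- c(bigWig = ".bw", bigBed = ".bb", bam = ".bam", cram = ".cram",
            vcfTabix = ".vcf.gz", unsupported = ".gff3")

#' Generate a synthetic Quickload repository
#'
#' Mirror image of [generate_hub()]: emits contents.txt, per-genome
#' annots.xml (titles carry `/` folder paths when `hierarchy_depth > 0`),
#' genome.txt plus a real 2bit when `with_two_bit`, zero-byte placeholder
#' data files, and the ground-truth model.
#'
#' @param spec A [fixture_spec()].
#' @param base_url Repository root baked into the model.
#' @return List `list(files, repo)`.
#' @export
generate_quickload <- function(spec,
                               base_url = "https://example.org/fixtureql") {
  with_seed(spec$seed, {
    dirs <- fixture_quickload_dirs(spec$n_genomes)
    contents <- list()
    genomes <- list()
    files <- list()

    for (gi in seq_along(dirs)) {
      d <- dirs[[gi]]
      contents[[gi]] <- contents_entry(
        d, sprintf("Synthetic fixture repository seed %d", spec$seed))

      n_annot <- sample(seq(spec$tracks_per_genome[[1]],
                            spec$tracks_per_genome[[2]]), 1L)
      kinds <- sample_weighted(names(spec$type_mix), spec$type_mix, n_annot)
      annots <- list()
      for (i in seq_len(n_annot)) {
        leaf <- sprintf("Sample %d track %d", gi, i)
        folder <- if (spec$hierarchy_depth == 0L) {
          character()
        } else if (spec$hierarchy_depth == 1L) {
          if (i %% 2L == 1L) sprintf("Folder %d", gi) else character()
        } else {
          switch((i %% 3L) + 1L, character(),
                 sprintf("Folder %d", gi),
                 c(sprintf("Folder %d", gi), "Deep"))
        }
        fname <- sprintf("data/s%d_t%d%s", gi, i, QL_EXT[[kinds[[i]]]])
        annots[[i]] <- annot_entry(
          file_name = fname,
          title = paste(c(folder, leaf), collapse = "/"),
          description = sprintf("Synthetic annot %d.%d", gi, i),
          foreground_hex = if (stats::runif(1) < spec$with_colors) {
            sprintf("%02X%02X%02X", sample(0:255, 1), sample(0:255, 1),
                    sample(0:255, 1))
          },
          load_hint = if (stats::runif(1) < 0.2) "no load" else NULL
        )
        files[[paste0(d, "/", fname)]] <- raw(0)
      }

      chroms <- NULL
      two_bit_name <- ""
      if (spec$with_two_bit) {
        n_seq <- sample(1:3, 1L)
        seqs <- stats::setNames(
          vapply(seq_len(n_seq),
                 function(s) rand_dna(sample(20:60, 1L), s == 1L),
                 character(1)),
          paste0("chr", seq_len(n_seq)))
        two_bit_name <- paste0(d, ".2bit")
        files[[paste0(d, "/", two_bit_name)]] <- write_twobit(seqs)
        chroms <- data.frame(seq_name = names(seqs),
                             length = nchar(seqs))
      }
      genomes[[d]] <- quickload_genome(d, annots = annots,
                                       chromosomes = chroms,
                                       two_bit_name = two_bit_name)
    }

    repo <- quickload_repo(contents, genomes, base_url)
    files <- c(serialize_quickload(repo), files)
    list(files = files, repo = repo)
  })
}

#' Generate a synthetic assembly catalog
#'
#' @param seed Integer seed.
#' @param n Number of records.
#' @return List `list(text, records)`: the TSV text and the ground-truth
#'   data frame [load_catalog()] must reproduce.
#' @export
generate_catalog <- function(seed = 1L, n = 10L) {
  with_seed(seed, {
    genera <- c("Homo", "Mus", "Danio", "Gallus", "Apis", "Zea", "Bos",
                "Canis", "Felis", "Arabidopsis")
    species <- c("sapiens", "musculus", "rerio", "gallus", "mellifera",
                 "mays", "taurus", "familiaris", "catus", "thaliana")
    commons <- c("human", "mouse", "zebrafish", "chicken", "honey bee",
                 "maize", "cattle", "dog", "cat", "thale cress")
    rows <- lapply(seq_len(n), function(i) {
      k <- sample.int(length(genera), 1L)
      acc <- sprintf("GC%s_%09d.%d", sample(c("A", "F"), 1L),
                     sample.int(999999999L, 1L), sample(1:3, 1L))
      data.frame(
        accession = acc,
        assembly_name = sprintf("ASM%dv%d", sample.int(99999L, 1L),
                                sample(1:4, 1L)),
        scientific_name = paste(genera[[k]], species[[k]]),
        common_name = commons[[k]],
        taxon_id = sample.int(999999L, 1L),
        hub_url = sprintf("https://hgdownload.example.org/hubs/%s/hub.txt",
                          acc)
      )
    })
    records <- if (n > 0L) do.call(rbind, rows) else
      load_catalog(paste(CATALOG_COLUMNS, collapse = "\t"))
    if (n > 0L && anyDuplicated(records$accession)) {
      records <- records[!duplicated(records$accession), , drop = FALSE]
    }
    rownames(records) <- NULL
    header <- paste(CATALOG_COLUMNS, collapse = "\t")
    body <- if (nrow(records)) {
      paste(records$accession, records$assembly_name,
            records$scientific_name, records$common_name,
            records$taxon_id, records$hub_url, sep = "\t")
    } else {
      character()
    }
    text <- paste0(paste(c(header, body), collapse = "\n"), "\n")
    list(text = text, records = records)
  })
}
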