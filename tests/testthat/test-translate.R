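test_that("rgb/hex conversions and error paths", {
  expect_equal(rgb_to_hex(0, 0, 255), "0000FF")
  expect_equal(rgb_to_hex(255, 255, 255), "FFFFFF")
  expect_error(rgb_to_hex(256, 0, 0), class = "quickhub_value_error")
  expect_error(rgb_to_hex(-1, 0, 0), class = "quickhub_value_error")
  expect_equal(hex_to_rgb("0000FF"), c(0L, 0L, 255L))
  expect_equal(hex_to_rgb("a1b2c3"), c(161L, 178L, 195L))
  expect_error(hex_to_rgb("GG0000"), class = "quickhub_value_error")
  expect_error(hex_to_rgb("FFF"), class = "quickhub_value_error")
  expect_error(hex_to_rgb("0000FF0"), class = "quickhub_value_error")
})

test_that("color mapping is a bijection over a channel sweep", {
  set.seed(42)
  for (r in 0:255) {
    g <- sample(0:255, 1)
    b <- sample(0:255, 1)
    expect_identical(hex_to_rgb(rgb_to_hex(r, g, b)),
                     as.integer(c(r, g, b)))
  }
  # and the reverse composition on sampled hex strings
  for (i in 1:100) {
    hex <- sprintf("%06X", sample(0:16777215, 1))
    v <- hex_to_rgb(hex)
    expect_identical(rgb_to_hex(v[1], v[2], v[3]), hex)
  }
})

test_that("track-type support sets match the shared indexed formats", {
  for (kind in c("bigWig", "bigBed", "bam", "cram", "vcfTabix",
                 "bigGenePred")) {
    expect_true(map_track_type_to_quickload(kind)$supported, info = kind)
  }
  bad <- map_track_type_to_quickload("bedGraph")
  expect_false(bad$supported)
  expect_match(bad$reason, "bedGraph")

  expect_equal(map_file_to_hub_type("x.bw")$type, "bigWig")
  expect_equal(map_file_to_hub_type("x.BigWig")$type, "bigWig")
  expect_equal(map_file_to_hub_type("x.VCF.GZ")$type, "vcfTabix")
  expect_equal(map_file_to_hub_type("x.bb")$type, "bigBed")
  expect_true(is.na(map_file_to_hub_type("x.gff3")$type))
  expect_true(is.na(map_file_to_hub_type("x.vcf")$type))
  expect_match(map_file_to_hub_type("genes.gff3")$reason, "gff3")
})

test_that("hub to quickload maps fields per the translation rules", {
  tracks <- list(
    track_def("cov", type_raw = "bigWig", big_data_url = "data/cov.bw",
              long_label = "Heart coverage", color_rgb = c(0, 0, 255),
              visibility = "full"),
    track_def("aln", type_raw = "bam", big_data_url = "data/aln.bam",
              long_label = "Heart alignments"),
    track_def("bg", type_raw = "bedGraph", big_data_url = "data/bg.bedGraph",
              long_label = "Unsupported graph")
  )
  hub <- track_hub(
    hub_manifest("h", long_label = "My hub"),
    list(genome_entry("hg38", "hg38/trackDb.txt")),
    list(hg38 = tracks),
    base_url = "https://x.org/hub"
  )
  out <- hub_to_quickload(hub)
  expect_equal(out$report$tracks_in, 3L)
  expect_equal(out$report$tracks_out, 2L)
  expect_length(out$report$dropped, 1L)
  expect_equal(out$report$dropped[[1]]$track, "bg")
  expect_match(out$report$dropped[[1]]$reason, "bedGraph")

  expect_equal(out$repo$contents[[1]]$genome_dir, "H_sapiens_Dec_2013")
  expect_equal(out$repo$contents[[1]]$description, "My hub")
  annots <- out$repo$genomes$H_sapiens_Dec_2013$annots
  expect_length(annots, 2L)
  a <- annots[[1]]
  expect_equal(a$file_name, "https://x.org/hub/hg38/data/cov.bw")
  expect_equal(a$title, "Heart coverage")
  expect_equal(a$foreground_hex, "0000FF")
  expect_equal(a$description, "Heart coverage")
  expect_equal(unname(a$extras[["x_hub_visibility"]]), "full")
})

test_that("empty trackDb still lists the genome with zero annots", {
  hub <- track_hub(hub_manifest("h", long_label = "L"),
                   list(genome_entry("GCF_000001405.40",
                                     "GCF_000001405.40/trackDb.txt")),
                   list(), base_url = "https://x.org/h")
  out <- hub_to_quickload(hub)
  expect_equal(out$repo$contents[[1]]$genome_dir, "GCF_000001405.40")
  expect_length(out$repo$genomes$GCF_000001405.40$annots, 0L)
  expect_equal(out$report$tracks_in, 0L)
})

test_that("container hierarchy becomes '/'-joined folder titles", {
  tracks <- list(
    track_def("rnaseq", container_kind = "superTrack",
              long_label = "RNA-Seq"),
    track_def("heart", type_raw = "bigWig", big_data_url = "h.bw",
              long_label = "Heart coverage", parent_name = "rnaseq")
  )
  hub <- track_hub(hub_manifest("h"),
                   list(genome_entry("hg38", "hg38/trackDb.txt")),
                   list(hg38 = tracks), base_url = "https://x.org/h")
  out <- hub_to_quickload(hub)
  expect_equal(out$repo$genomes$H_sapiens_Dec_2013$annots[[1]]$title,
               "RNA-Seq/Heart coverage")
})

test_that("sibling order: priority ascending, unset last, then source", {
  mk <- function(nm, pri) track_def(nm, type_raw = "bigWig",
                                    big_data_url = paste0(nm, ".bw"),
                                    long_label = nm, priority = pri)
  hub <- track_hub(hub_manifest("h"),
                   list(genome_entry("hg38", "hg38/trackDb.txt")),
                   list(hg38 = list(mk("a", NULL), mk("b", 2), mk("c", 1),
                                    mk("d", NULL))),
                   base_url = "https://x.org/h")
  annots <- hub_to_quickload(hub)$repo$genomes$H_sapiens_Dec_2013$annots
  expect_equal(vapply(annots, `[[`, "", "title"), c("c", "b", "a", "d"))
})

test_that("quickload to hub maps fields per the translation rules", {
  repo <- quickload_repo(
    list(contents_entry("H_sapiens_Dec_2013", "Human")),
    list(H_sapiens_Dec_2013 = quickload_genome(
      "H_sapiens_Dec_2013",
      annots = list(
        annot_entry("a.bw", title = "Cov", foreground_hex = "FF0000"),
        annot_entry("sub/genes.gff3", title = "Genes")
      ))),
    base_url = "https://q.org/ql"
  )
  out <- quickload_to_hub(repo)
  expect_equal(out$report$tracks_in, 2L)
  expect_equal(out$report$tracks_out, 1L)
  expect_match(out$report$dropped[[1]]$reason, "gff3")

  expect_equal(out$hub$genomes[[1]]$genome_id, "hg38")
  t <- out$hub$tracks_by_genome$hg38[[1]]
  expect_equal(t$track_type$kind, "bigWig")
  expect_equal(t$color_rgb, c(255L, 0L, 0L))
  expect_equal(t$visibility, "pack")
  expect_equal(t$big_data_url, "https://q.org/ql/H_sapiens_Dec_2013/a.bw")
  expect_equal(t$short_label, "Cov")
})

test_that("multi-segment titles synthesize containers with parent links", {
  repo <- quickload_repo(
    list(contents_entry("H_sapiens_Dec_2013")),
    list(H_sapiens_Dec_2013 = quickload_genome(
      "H_sapiens_Dec_2013",
      annots = list(annot_entry("h.bw", title = "RNA-Seq/Heart")))),
    base_url = "https://q.org/ql"
  )
  tracks <- quickload_to_hub(repo)$hub$tracks_by_genome$hg38
  expect_length(tracks, 2L)
  expect_equal(tracks[[1]]$container_kind, "superTrack")
  expect_equal(tracks[[1]]$long_label, "RNA-Seq")
  expect_equal(tracks[[2]]$parent_name, tracks[[1]]$track_name)
  expect_equal(tracks[[2]]$long_label, "Heart")
})

test_that("track names are sanitized, prefixed and uniquified", {
  repo <- quickload_repo(
    list(contents_entry("g")),
    list(g = quickload_genome("g", annots = list(
      annot_entry("a.bw", title = "9 o'clock sample"),
      annot_entry("b.bw", title = "9 o'clock sample")
    ))),
    base_url = "https://q.org/ql"
  )
  tracks <- quickload_to_hub(repo)$hub$tracks_by_genome$g
  nms <- vapply(tracks, `[[`, "", "track_name")
  expect_equal(nms[[1]], "t_9_o_clock_sample")
  expect_false(nms[[1]] == nms[[2]])
  expect_match(nms[[2]], "^t_9_o_clock_sample_")
})

test_that("conservation holds in both directions across fixtures", {
  for (seed in 1:12) {
    mix <- c(bigWig = 2, bigBed = 1, bam = 1, cram = 1, vcfTabix = 1,
             unsupported = seed %% 3)
    fx <- generate_hub(fixture_spec(seed = seed, n_genomes = 1 + seed %% 2,
                                    hierarchy_depth = seed %% 3,
                                    type_mix = mix))
    fwd <- hub_to_quickload(fx$hub)
    expect_equal(fwd$report$tracks_out + length(fwd$report$dropped),
                 fwd$report$tracks_in, info = paste("fwd seed", seed))
    expect_equal(fwd$report$tracks_in, count_leaf_tracks(fx$hub))

    fq <- generate_quickload(fixture_spec(seed = seed,
                                          hierarchy_depth = seed %% 3,
                                          type_mix = mix))
    rev <- quickload_to_hub(fq$repo)
    expect_equal(rev$report$tracks_out + length(rev$report$dropped),
                 rev$report$tracks_in, info = paste("rev seed", seed))
    expect_equal(rev$report$tracks_in,
                 sum(vapply(fq$repo$genomes,
                            function(g) length(g$annots), integer(1))))
  }
})

test_that("canonical core survives hub -> quickload -> hub", {
  for (seed in 1:15) {
    fx <- generate_hub(fixture_spec(seed = seed, n_genomes = 1 + seed %% 2,
                                    hierarchy_depth = seed %% 3))
    fwd <- hub_to_quickload(fx$hub)
    back <- quickload_to_hub(fwd$repo)
    want <- canonical_track_core(fx$hub)
    got <- canonical_track_core(back$hub)
    # genome ids map through the synonym table and back
    expect_equal(got[setdiff(names(got), "genome")],
                 want[setdiff(names(want), "genome")],
                 info = paste("seed", seed))
    expect_equal(unname(fwd$report$genome_name_map[want$genome]),
                 vapply(got$genome, function(id)
                   syn_to_quickload(default_synonyms(), id), character(1),
                   USE.NAMES = FALSE))
  }
})

test_that("translation is deterministic: identical serialized bytes", {
  fx <- generate_hub(fixture_spec(seed = 21, hierarchy_depth = 2))
  a <- serialize_quickload(hub_to_quickload(fx$hub)$repo)
  b <- serialize_quickload(hub_to_quickload(fx$hub)$repo)
  expect_identical(a, b)
})

test_that("synonym tables are one-to-one and default to identity", {
  expect_error(synonym_table(c("a", "a"), c("x", "y")),
               class = "quickhub_value_error")
  syn <- default_synonyms()
  expect_equal(syn_to_quickload(syn, "GCF_000001405.40"), "GCF_000001405.40")
  expect_equal(syn_to_ucsc(syn, "H_sapiens_Dec_2013"), "hg38")
  expect_equal(syn_to_quickload(syn, "hg38"), "H_sapiens_Dec_2013")
})
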