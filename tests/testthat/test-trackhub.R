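test_that("a fixture hub builds field-by-field to its ground truth", {
  fx <- generate_hub(fixture_spec(seed = 11, n_genomes = 2,
                                  hierarchy_depth = 1, with_two_bit = TRUE))
  expect_no_warning(hub <- rebuild_hub(fx))
  expect_equal(hub, fx$hub)
})

test_that("useOneFile and split layouts build the same genomes and tracks", {
  spec <- fixture_spec(seed = 4, n_genomes = 2, hierarchy_depth = 2)
  split <- generate_hub(spec, one_file = FALSE)
  one <- generate_hub(spec, one_file = TRUE)
  hub_split <- rebuild_hub(split)
  hub_one <- build_trackhub(one$files[["hub.txt"]],
                            base_url = one$hub$base_url)
  expect_true(hub_one$manifest$use_one_file)
  expect_equal(hub_one$genomes, hub_split$genomes)
  expect_equal(hub_one$tracks_by_genome, hub_split$tracks_by_genome)
})

test_that("direct key mappings: parent flag, containers, color, type kind", {
  tdb <- paste0(
    "track compTrack\ncompositeTrack on\nshortLabel comp\n\n",
    "track child\ntype bigBed 12 +\nbigDataUrl d/c.bb\n",
    "parent compTrack on\ncolor 0,0,255\n\n",
    "track st\nsuperTrack on\n\n",
    "track member\ntype bigWig\nbigDataUrl d/m.bw\nsuperTrack st show\n\n",
    "track ow\ntype bigWig\nbigDataUrl d/o.bw\ncontainer multiWig\n"
  )
  hub <- build_trackhub("hub h\ngenomesFile genomes.txt\n",
                        "genome hg38\ntrackDb trackDb.txt\n",
                        list(hg38 = tdb))
  tr <- hub$tracks_by_genome$hg38
  nm <- vapply(tr, function(t) t$track_name, character(1))
  child <- tr[[which(nm == "child")]]
  expect_equal(child$parent_name, "compTrack")
  expect_true(child$parent_default_on)
  expect_equal(child$track_type$kind, "bigBed")
  expect_equal(child$track_type$raw, "bigBed 12 +")
  expect_equal(child$color_rgb, c(0L, 0L, 255L))
  expect_equal(tr[[which(nm == "compTrack")]]$container_kind, "composite")
  expect_equal(tr[[which(nm == "st")]]$container_kind, "superTrack")
  member <- tr[[which(nm == "member")]]
  expect_equal(member$parent_name, "st")
  expect_true(member$parent_default_on)
  expect_equal(tr[[which(nm == "ow")]]$container_kind, "multiWig")
})

test_that("structural errors: missing hub stanza, missing genome keys", {
  expect_error(build_trackhub("shortLabel x\n"),
               class = "quickhub_structural_error")
  expect_error(
    build_trackhub("hub h\ngenomesFile genomes.txt\n", "genome hg38\n"),
    class = "quickhub_structural_error")
  expect_error(
    build_trackhub("hub h\ngenomesFile genomes.txt\n",
                   "trackDb x/trackDb.txt\n"),
    class = "quickhub_structural_error")
})

test_that("permissive ingestion warns: visibility, duplicates, bad color", {
  tdb <- "track t\ntype bigWig\nbigDataUrl d/t.bw\nvisibility sparkle\n"
  expect_warning(
    hub <- build_trackhub("hub h\ngenomesFile g.txt\n",
                          "genome hg38\ntrackDb trackDb.txt\n",
                          list(hg38 = tdb)),
    class = "quickhub_warning")
  expect_equal(hub$tracks_by_genome$hg38[[1]]$visibility, "pack")

  tdb2 <- "track t\ntype bigWig\nbigDataUrl a.bw\nbigDataUrl b.bw\n"
  expect_warning(
    hub2 <- build_trackhub("hub h\ngenomesFile g.txt\n",
                           "genome hg38\ntrackDb trackDb.txt\n",
                           list(hg38 = tdb2)),
    "last occurrence wins")
  expect_equal(hub2$tracks_by_genome$hg38[[1]]$big_data_url, "b.bw")

  tdb3 <- "track t\ntype bigWig\nbigDataUrl a.bw\ncolor 300,0,0\n"
  expect_warning(
    hub3 <- build_trackhub("hub h\ngenomesFile g.txt\n",
                           "genome hg38\ntrackDb trackDb.txt\n",
                           list(hg38 = tdb3)),
    "invalid color")
  expect_null(hub3$tracks_by_genome$hg38[[1]]$color_rgb)
})

test_that("every input key lands in a typed field or in extras", {
  TRACK_KEYS_FOR_TEST <- c("track", "type", "bigDataUrl", "bigDataIndex",
                           "shortLabel", "longLabel", "visibility", "color",
                           "altColor", "parent", "superTrack", "container",
                           "compositeTrack", "priority", "html", "group")
  for (seed in c(2, 9, 17)) {
    fx <- generate_hub(fixture_spec(seed = seed, hierarchy_depth = seed %% 3))
    hub <- rebuild_hub(fx)
    for (g in hub$genomes) {
      sts <- parse_stanzas(fx$files[[g$trackdb_path]])
      tracks <- hub$tracks_by_genome[[g$genome_id]]
      expect_length(tracks, length(sts))
      for (i in seq_along(sts)) {
        covered <- unique(c(TRACK_KEYS_FOR_TEST, names(tracks[[i]]$extras)))
        expect_true(all(sts[[i]]$keys %in% covered),
                    info = paste("seed", seed, "stanza", i))
      }
    }
  }
})

test_that("track hierarchy: forest shape, dangling parents, cycles", {
  mk <- function(name, parent = "", kind = "none") {
    track_def(name, type_raw = "bigWig", big_data_url = paste0(name, ".bw"),
              parent_name = parent,
              container_kind = kind)
  }
  s <- track_def("S", container_kind = "superTrack")
  forest <- track_hierarchy(list(s, mk("A", "S"), mk("B", "S")))
  expect_length(forest, 1L)
  expect_equal(forest[[1]]$track_name, "S")
  expect_equal(vapply(forest[[1]]$children, `[[`, "", "track_name"),
               c("A", "B"))

  flat <- track_hierarchy(list(mk("x"), mk("y"), mk("z")))
  expect_equal(vapply(flat, `[[`, "", "track_name"), c("x", "y", "z"))
  expect_true(all(lengths(lapply(flat, `[[`, "children")) == 0L))

  expect_warning(
    dang <- track_hierarchy(list(mk("a", parent = "ghost"))),
    "dangling")
  expect_equal(dang[[1]]$track_name, "a")

  expect_error(
    track_hierarchy(list(mk("A", "B"), mk("B", "A"))),
    class = "quickhub_structural_error")
})

test_that("build/serialize round trip is the identity on fixture hubs", {
  for (seed in 1:15) {
    one_file <- seed %% 2L == 0L
    fx <- generate_hub(fixture_spec(seed = seed, n_genomes = 1 + seed %% 2,
                                    hierarchy_depth = seed %% 3,
                                    with_two_bit = seed %% 4 == 0),
                       one_file = one_file)
    hub <- if (one_file) {
      build_trackhub(fx$files[["hub.txt"]], base_url = fx$hub$base_url)
    } else {
      rebuild_hub(fx)
    }
    expect_equal(hub, fx$hub, info = paste("seed", seed))
    # no silent drops: serialized output rebuilds identically
    files2 <- serialize_trackhub(hub, one_file = one_file)
    expect_identical(files2, fx$files[names(files2)])
  }
})

test_that("single-genome one-file hub emits exactly one path", {
  fx <- generate_hub(fixture_spec(seed = 8), one_file = TRUE)
  files <- serialize_trackhub(fx$hub, one_file = TRUE)
  expect_equal(names(files), "hub.txt")
})

test_that("color re-emits in trackDb r,g,b form", {
  t <- track_def("t", type_raw = "bigWig", big_data_url = "t.bw",
                 color_rgb = c(0, 0, 255))
  files <- serialize_trackhub(track_hub(
    hub_manifest("h"), list(genome_entry("hg38", "hg38/trackDb.txt")),
    list(hg38 = list(t))))
  expect_match(files[["hg38/trackDb.txt"]], "color 0,0,255", fixed = TRUE)
})
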