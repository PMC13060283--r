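test_that("converted URL encode/parse are mutual inverses", {
  u <- make_converted_url("to_quickload", "https://x.org/hub.txt",
                          "https://svc.example/")
  p <- parse_converted_url(u)
  expect_equal(p$direction, "to_quickload")
  expect_equal(p$source_url, "https://x.org/hub.txt")

  set.seed(5)
  for (i in 1:50) {
    src <- sprintf("http%s://host%d.example.org/a b/%s/hub.txt?x=%d&y=%s",
                   sample(c("", "s"), 1), i,
                   paste(sample(c(letters, "~", "-", "_"), 8, TRUE),
                         collapse = ""),
                   sample(1:99, 1),
                   paste(sample(c(LETTERS, "%", "#"), 4, TRUE), collapse = ""))
    dir <- sample(c("to_quickload", "to_trackhub"), 1)
    got <- parse_converted_url(make_converted_url(dir, src, "https://svc/"))
    expect_equal(got$source_url, src)
    expect_equal(got$direction, dir)
  }
})

test_that("converted URL encoding is deterministic and validates scheme", {
  a <- make_converted_url("to_quickload", "https://x.org/hub.txt", "https://s/")
  b <- make_converted_url("to_quickload", "https://x.org/hub.txt", "https://s/")
  expect_identical(a, b)
  expect_error(make_converted_url("to_quickload", "ftp://x.org/hub.txt",
                                  "https://s/"),
               class = "quickhub_value_error")
  expect_error(make_converted_url("to_quickload", "relative/hub.txt",
                                  "https://s/"),
               class = "quickhub_value_error")
  expect_error(conversion_request("to_quickload", "https://x.org/hub.txt",
                                  "a/../b"),
               class = "quickhub_value_error")
})

make_hub_site <- function(seed = 31, with_two_bit = TRUE) {
  fx <- generate_hub(fixture_spec(seed = seed, n_genomes = 2,
                                  hierarchy_depth = 1,
                                  with_two_bit = with_two_bit))
  base <- fx$hub$base_url
  list(fx = fx, base = base,
       transport = fixture_transport(fx$files, base),
       hub_url = paste0(base, "/hub.txt"))
}

test_that("facade serves contents.txt lazily and deterministically", {
  site <- make_hub_site()
  rec <- recording_transport(site$transport)
  req <- conversion_request("to_quickload", site$hub_url, "contents.txt")

  r1 <- resolve(req, rec)
  expect_equal(r1$status, 200L)
  expect_equal(r1$media_type, "text/plain")
  got <- parse_contents(r1$body)
  expect_length(got, 2L)

  # laziness: only hub.txt and genomes.txt were fetched -- no trackDb, and
  # never any data file
  fetched <- recorded_urls(rec)
  expect_setequal(unique(fetched),
                  c(site$hub_url, paste0(site$base, "/genomes.txt")))
  expect_false(any(grepl("/data/", fetched)))

  r2 <- resolve(req, rec)
  expect_identical(r1$body, r2$body)
})

test_that("facade serves annots.xml and synthesized genome.txt", {
  site <- make_hub_site()
  gid <- site$fx$hub$genomes[[1]]$genome_id
  gdir <- syn_to_quickload(default_synonyms(), gid)

  ra <- resolve(conversion_request("to_quickload", site$hub_url,
                                   paste0(gdir, "/annots.xml")),
                site$transport)
  expect_equal(ra$status, 200L)
  expect_equal(ra$media_type, "application/xml")
  annots <- parse_annots(ra$body)
  full <- hub_to_quickload(rebuild_hub(site$fx))$repo
  expect_equal(annots, full$genomes[[gdir]]$annots)

  rg <- resolve(conversion_request("to_quickload", site$hub_url,
                                   paste0(gdir, "/genome.txt")),
                site$transport)
  expect_equal(rg$status, 200L)
  tbl <- parse_genome_table(rg$body)
  idx <- read_twobit_index(site$fx$files[[paste0(gid, ".2bit")]])
  expect_equal(tbl, genome_table_from_twobit(idx))
})

test_that("facade error contract: 404 unknown paths, 502 upstream failures", {
  site <- make_hub_site()
  r404 <- resolve(conversion_request("to_quickload", site$hub_url,
                                     "nosuch/annots.xml"),
                  site$transport)
  expect_equal(r404$status, 404L)
  r404b <- resolve(conversion_request("to_quickload", site$hub_url,
                                      "weird.path"),
                   site$transport)
  expect_equal(r404b$status, 404L)

  r502 <- resolve(conversion_request("to_quickload",
                                     "https://gone.example/hub.txt",
                                     "contents.txt"),
                  site$transport)
  expect_equal(r502$status, 502L)
  expect_match(r502$body, "gone.example", fixed = TRUE)

  broken <- memory_transport(list("https://b.org/hub.txt" = "shortLabel only\n"))
  rbad <- resolve(conversion_request("to_quickload", "https://b.org/hub.txt",
                                     "contents.txt"), broken)
  expect_equal(rbad$status, 502L)
})

# parse a trackDb body through the public build path
parse_trackdb_text_for_test <- function(text) {
  hub <- build_trackhub("hub h\ngenomesFile g.txt\n",
                        "genome gid\ntrackDb trackDb.txt\n",
                        list(gid = text))
  hub$tracks_by_genome$gid
}

test_that("facade serves the reverse direction from a quickload source", {
  fq <- generate_quickload(fixture_spec(seed = 12, n_genomes = 2,
                                        hierarchy_depth = 1))
  base <- fq$repo$base_url
  tr <- fixture_transport(fq$files, base)

  rh <- resolve(conversion_request("to_trackhub", base, "hub.txt"), tr)
  expect_equal(rh$status, 200L)
  expect_match(rh$body, "^hub ")

  rg <- resolve(conversion_request("to_trackhub", base, "genomes.txt"), tr)
  expect_equal(rg$status, 200L)
  gids <- vapply(parse_stanzas(rg$body), stanza_get, "", key = "genome")
  expect_equal(gids, vapply(fq$repo$contents, function(ce)
    syn_to_ucsc(default_synonyms(), ce$genome_dir), character(1)))

  rtdb <- resolve(conversion_request("to_trackhub", base,
                                     paste0(gids[[1]], "/trackDb.txt")), tr)
  expect_equal(rtdb$status, 200L)
  want <- quickload_to_hub(fq$repo)$hub$tracks_by_genome[[gids[[1]]]]
  expect_equal(parse_trackdb_text_for_test(rtdb$body), want)
})
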