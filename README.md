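# quickhub

Bidirectional translation between the two metadata dialects used by
web-hosted genome-browser data collections:

* **UCSC track hubs** — `hub.txt`, `genomes.txt`, per-genome `trackDb.txt`
  in the RA-style stanza dialect, and
* **IGB Quickload repositories** — `contents.txt`, per-genome `annots.xml`
  and `genome.txt`.

Both browsers read the same indexed binary data formats (BAM, CRAM,
tabix-indexed VCF, bigBed, bigWig, 2bit) directly over HTTP, so a collection
published for one browser only needs its *metadata* translated to be usable
in the other. quickhub is for people who publish or consume such
collections: data producers who want one deployment viewable in both
browsers, and tool builders who want the tens of thousands of GenArk
assembly hubs (`GCA_`/`GCF_` accessions) openable in IGB.

## What it does

* **Typed models** of both formats with lossless parse/serialize:
  `parse_stanzas()`/`serialize_stanzas()`, `build_trackhub()`/
  `serialize_trackhub()` (split and `useOneFile` layouts),
  `parse_annots()`/`serialize_annots()`, `parse_contents()`,
  `parse_genome_table()`, plus `build_quickload()`/`serialize_quickload()`.
  Unrecognized settings ride along verbatim in `extras`.
* **The translation engine** `hub_to_quickload()` / `quickload_to_hub()`.
  Every conversion returns a `ConversionReport` with the conservation
  identity `tracks_out + dropped = tracks_in`; settings with no home in the
  target dialect are stashed under reserved `x_hub_`/`x_ql_` names so a
  round trip restores them. Track colors map bijectively between trackDb
  `r,g,b` and annots.xml 6-digit hex; container hierarchy maps to
  `/`-joined folder titles and back.
* **A minimal 2bit reader** (`read_twobit_index()`) that reads only the
  header, sequence index and per-record lengths — a few kilobytes even for a
  multi-gigabyte assembly over a ranged transport — to synthesize
  `genome.txt` for assembly hubs, and `write_twobit()` to build real
  miniature 2bit files for offline testing.
* **A lazy façade** `resolve()`: virtual paths under a conversion URL
  (`contents.txt`, `hg38/trackDb.txt`, …) are translated on demand, fetching
  only the source files each path needs, through an injectable transport
  (`memory_transport()`, `file_transport()`, `http_transport()`).
  `make_converted_url()`/`parse_converted_url()` encode a source URL into a
  service URL and back.
* **Assembly catalog search** (`load_catalog()`, `search_catalog()`,
  `open_assembly()`) over a GenArk-style TSV: substring matching on common
  name, scientific name, assembly name and accession, exact matching on
  taxon id, multi-token AND.
* **A deterministic fixture generator** (`fixture_spec()`,
  `generate_hub()`, `generate_quickload()`, `generate_catalog()`) returning
  files *and* their ground-truth models, so everything above is testable
  offline.
* **A CLI** at `inst/cli/quickhub.R`:
  `quickhub.R convert --to quickload SOURCE --out DIR`,
  `quickhub.R search QUERY --catalog FILE`, `quickhub.R serve --port N`.

## Worked example

```r
library(quickhub)

tracks <- list(
  track_def("rnaseq", container_kind = "superTrack", long_label = "RNA-Seq"),
  track_def("heart", type_raw = "bigWig", big_data_url = "data/heart.bw",
            long_label = "Heart coverage", parent_name = "rnaseq",
            color_rgb = c(0, 0, 255), visibility = "full"),
  track_def("genes", type_raw = "bedGraph", big_data_url = "data/genes.bg",
            long_label = "Unsupported graph")
)
hub <- track_hub(hub_manifest("demo", long_label = "Demo hub"),
                 list(genome_entry("hg38", "hg38/trackDb.txt")),
                 list(hg38 = tracks),
                 base_url = "https://data.example.org/demo")

out <- hub_to_quickload(hub)
out$report
#> <conversion: 2 track(s) in, 1 out, 1 dropped, 0 warning(s)>
#>   dropped genes: unsupported track type 'bedGraph'
```

Two *leaf* tracks went in (the superTrack is structural, not data); the
bedGraph track has no indexed format IGB can read from a hub, so it is
dropped and accounted for. The surviving track becomes an annots.xml entry
whose title encodes the folder hierarchy, whose color is now hex, and whose
hub-only settings are stashed in `x_hub_` attributes:

```r
cat(serialize_annots(out$repo$genomes$H_sapiens_Dec_2013$annots))
#> <?xml version="1.0" encoding="UTF-8"?>
#> <files>
#>   <file name="https://data.example.org/demo/hg38/data/heart.bw"
#>         title="RNA-Seq/Heart coverage" description="Heart coverage"
#>         foreground="0000FF" x_hub_track="heart" x_hub_type="bigWig"
#>         x_hub_visibility="full"/>
#> </files>
```

Note the genome directory: `hg38` mapped to IGB's `H_sapiens_Dec_2013`
through the shipped synonym table (unknown names pass through unchanged).
Translating back reconstructs the superTrack, the original track name,
visibility and color:

```r
back <- quickload_to_hub(out$repo)
cat(serialize_trackhub(back$hub)[["hg38/trackDb.txt"]])
#> track RNA_Seq
#> shortLabel RNA-Seq
#> longLabel RNA-Seq
#> visibility hide
#> superTrack on
#>
#> track heart
#> type bigWig
#> bigDataUrl https://data.example.org/demo/hg38/data/heart.bw
#> shortLabel Heart coverage
#> longLabel Heart coverage
#> visibility full
#> color 0,0,255
#> parent RNA_Seq on
```

The same conversion runs from the shell against a hub on disk or on the web:

```sh
Rscript inst/cli/quickhub.R convert --to quickload /path/to/hub --out /path/to/quickload
# tracks in: 4; out: 4; dropped: 0
```

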