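---
title: "Translating genome-browser track metadata between track hubs and Quickload"
author: "quickhub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating genome-browser track metadata between track hubs and Quickload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quickhub)
```

## The problem

The UCSC Genome Browser and the Integrated Genome Browser (IGB) both let
researchers publish collections of genomic data tracks as plain files on a web
server, described by small metadata files. The two ecosystems use different,
mutually unreadable dialects:

* A **track hub** is described by `hub.txt`, `genomes.txt` and per-genome
  `trackDb.txt` files in the RA-style stanza dialect (blank-line-separated
  blocks of `key value` lines). Track definitions carry a data URL
  (`bigDataUrl`), a `type`, labels, a `color` as an `r,g,b` triple, a
  `visibility` mode, and hierarchy keys (`parent`, `superTrack`,
  `compositeTrack`, `container`).
* A **Quickload** repository is described by `contents.txt` (tab-separated
  genome directory list), a per-genome `annots.xml` whose `<file>` elements
  declare data files, `/`-separated folder titles and hex colors, and a
  `genome.txt` table of chromosome names and lengths.

The data files themselves (BAM, CRAM, tabix-indexed VCF, bigBed, bigWig, 2bit)
are indexed binary formats both browsers can already read over HTTP. Only the
*metadata* needs translating, so a collection published for one browser can be
opened in the other without copying a byte of data. quickhub implements that
translation as a typed, lossless-where-possible mapping, plus a lazy façade
that serves translated metadata on demand.

## The translation model

Both formats are parsed into typed models (`qh_track_hub`,
`qh_quickload_repo`) whose constructors enforce the invariants of each
dialect. Translation then maps the models:

| trackDb setting            | annots.xml attribute        |
|----------------------------|-----------------------------|
| `bigDataUrl` (resolved)    | `name` (absolute URL)       |
| container/label hierarchy  | `title` with `/` separators |
| `longLabel`                | `description` (and title leaf) |
| `color r,g,b`              | `foreground` 6-digit hex    |
| `html` page (resolved)     | `url`                       |
| everything else            | `x_hub_<key>` stash         |

Key design points:

* **Support set.** Only types with an indexed binary format survive:
  bigWig, bigBed, BAM, CRAM, tabix-indexed VCF, and bigGenePred (treated as a
  bigBed-flavored annotation track). Anything else (bedGraph, plain BED/GFF,
  un-bgzipped VCF) is *dropped*, and every drop is accounted for in a
  `ConversionReport`: `tracks_out + dropped = tracks_in` always, where
  `tracks_in` counts leaf data tracks. Container tracks are structural — they
  become folder path segments, not entries — so they are neither emitted nor
  dropped.
* **The stash.** Settings with no counterpart in the target dialect are not
  discarded: trackDb settings travel as reserved `x_hub_`-prefixed
  annots.xml attributes, and annots.xml settings (e.g. `load_hint`,
  `background`) travel back as `x_ql_` trackDb extras. A round trip through
  the other format therefore restores the original settings. Independently of
  the stash, a *canonical core* — resolved data URL, type kind, color,
  visibility, long label, and hierarchy path — is guaranteed to survive
  hub → Quickload → hub, and `canonical_track_core()` is the function the
  round-trip tests compare.
* **Hierarchy.** UCSC has three container mechanisms (superTrack, composite,
  multiWig); all three collapse to one parent/child forest
  (`track_hierarchy()`), driven purely by `parent`/`superTrack` keys —
  indentation in published trackDb files is treated as cosmetic because it is
  inconsistent in the wild. In the reverse direction, multi-segment titles
  synthesize one container per distinct folder path: superTrack at the top
  level, composite below, since UCSC does not nest superTracks.
* **Ordering.** Siblings are ordered by `priority` ascending, tracks without
  a priority after those with one, ties broken by source order. This makes
  translation deterministic: identical inputs give byte-identical outputs,
  which in turn makes the façade safe to cache externally.
* **Genome naming.** A shipped one-to-one synonym table maps common UCSC
  database names to IGB Quickload directory names (`hg38` ↔
  `H_sapiens_Dec_2013`, …). Names not in the table pass through unchanged —
  the only safe default for the tens of thousands of accession-named GenArk
  assemblies (`GCF_…`/`GCA_…`).

```{r example}
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
                 list(hg38 = tracks), base_url = "https://data.example.org/demo")
out <- hub_to_quickload(hub)
out$report
cat(serialize_annots(out$repo$genomes$H_sapiens_Dec_2013$annots))
```

## Dialect choices

The published descriptions of both formats leave many corners unspecified;
these are the conventions this package fixes, chosen to be permissive on
input and canonical on output:

* **Stanza parsing.** LF and CRLF accepted (LF emitted); comments (`#` first
  non-blank character) are skipped without terminating a stanza; a trailing
  backslash joins the next line with a single space; the first whitespace run
  splits key from value; values keep internal whitespace, trailing whitespace
  trimmed. Duplicate keys within a stanza are preserved by the parser and
  collapsed last-wins (with a warning) only when the model is built. Files
  that are not valid UTF-8 are decoded with replacement characters and a
  warning rather than rejected.
* **Recognized trackDb keys** are exactly the sixteen the translator maps
  (`track`, `type`, `bigDataUrl`, `bigDataIndex`, `shortLabel`, `longLabel`,
  `visibility`, `color`, `altColor`, `parent`, `superTrack`, `container`,
  `compositeTrack`, `priority`, `html`, `group`); everything else is carried
  verbatim in `extras`. A coverage test asserts every input key lands in a
  typed field or in extras.
* **Visibility** outside the five UCSC tokens maps to `pack` with a warning;
  a track without a visibility line models as `hide` (the UCSC default).
  Tracks converted from Quickload default to `pack` unless a stashed
  original restores it. Visibility is never mapped to IGB's `load_hint`
  (no auto-loading on the user's behalf).
* **Colors** are normalized to uppercase 6-digit hex in annots.xml; 3-digit
  shorthand is rejected with a warning (entry kept, color unset). The
  RGB ↔ hex mapping is bijective and tested exhaustively per channel.
* **Labels.** `shortLabel` derived from a title leaf is truncated to 17
  characters, the UCSC guideline. The reverse `longLabel` is the annots
  `description`, else the title's leaf segment (titles are folder paths in
  this dialect; using the full path would leak folders into labels).
* **Track names** synthesized from titles are sanitized to `[A-Za-z0-9_]`,
  prefixed `t_` when starting with a digit, and uniquified with numeric
  suffixes.
* **URL resolution** follows UCSC semantics: `bigDataUrl` resolves against
  the directory of its trackDb.txt, `trackDb`/`twoBitPath` against the
  directory of genomes.txt (hub.txt for `useOneFile` hubs). Whenever the
  repository base is absolute, every emitted data URL is absolute.

## The 2bit reader and genome.txt synthesis

Assembly hubs declare their genome sequence as a `twoBitPath`; Quickload
needs an explicit `genome.txt` of chromosome names and lengths. quickhub
reads exactly the part of the 2bit binary format that answers that question:
the 16-byte header (signature `0x1A412743` in either byte order, version 0
only), the sequence index, and the 4-byte `dnaSize` at the head of each
record. Packed bases and block lists are never decoded, and over a ranged
transport the reader fetches only header + index + 4 bytes per sequence, so
a multi-gigabyte assembly 2bit costs a few kilobytes to index.

`write_twobit()` emits complete, valid 2bit files (packed bases, N-run
blocks) so the reader is testable offline; the test suite cross-checks both
directions against rtracklayer's independent 2bit implementation.

## The façade

`resolve()` maps virtual paths under a conversion URL to translated
documents: for a hub source, `contents.txt`, `<genome>/annots.xml` and
`<genome>/genome.txt`; for a Quickload source, `hub.txt`, `genomes.txt` and
`<genome>/trackDb.txt`. Each request fetches only the source files that path
needs — serving `contents.txt` reads hub.txt and genomes.txt, never a
trackDb and never a data file — through an injectable transport
(`memory_transport()` for tests, `file_transport()` for local trees,
`http_transport()` for live hubs). There is no caching layer: responses are
deterministic, so external caching is safe and the service stays stateless.
Upstream failures surface as 502-style responses with the failing URL, never
as silently empty repositories, because an empty answer is indistinguishable
from a valid empty hub. `make_converted_url()`/`parse_converted_url()` are
mutual inverses (the package carries its own RFC 3986 percent-encoder
because base R's `URLencode` does not escape `%`).

## What the fixtures emulate — and what they do not

`generate_hub()`/`generate_quickload()` produce repositories with known
ground-truth models: 1–2 genomes, 2–4 leaf tracks each, type mixes over the
supported set plus deliberately unsupported types, hierarchy depths 0–2,
optional colors, priorities, extras, and real miniature 2bit files
(20–60 bp chromosomes, N runs included). Data files are zero-byte
placeholders, which keeps fixtures tiny and honest: a recording transport
asserts the translator never opens them. The catalog generator emulates a
GenArk-style assembly list at 15–30 records.

Passing tests on these fixtures demonstrates the format contracts, the
translation algebra (conservation, canonical-core round trip, determinism)
and the façade's laziness. They do not demonstrate: tolerance to the full
variety of hand-written trackDb files in the wild (settings beyond the
recognized keys are preserved but not interpreted), the semantics of
track-type-specific settings (`viewLimits`, `maxHeightPixels`, … ride along
as extras), network behavior of live servers, or rendering fidelity inside
either browser. Translating browser view state, converting data file
*contents* between formats, and multiWig overlay semantics (beyond treating
it as a folder) are explicit non-goals.

## Problem sizes and numerical choices

The property suites run at: 200 generated hubs for the stanza fixpoint, 40
for the model round trip (alternating split and `useOneFile` layouts), ~100
for the canonical-core round trip across hierarchy depths {0, 1, 2}, a full
256-value channel sweep for the color bijection, 25 randomized sequence sets
for 2bit, and 8 catalogs × 8 queries against a brute-force search oracle.
These sizes give each property thousands of concrete instances while keeping
the whole suite under a minute; all randomness is seeded, so failures
reproduce exactly. Sequence lengths in 2bit fixtures stay under 100 bp —
the reader's arithmetic is over byte offsets stored as doubles, so lengths
up to 2^32 are representable, but desk-scale fixtures need not be large to
exercise every branch (N runs, zero-sequence files, both byte orders,
truncation at every boundary).

## Known limitations

* Only version-0 (32-bit offset) 2bit files are read; the long variant is
  rejected explicitly.
* `hubCheck`-grade semantic validation of trackDb settings is out of scope;
  unknown settings round-trip but are not checked.
* The synonym table ships with a small set of common genome name pairs;
  site-specific pairs can be supplied as a user table (`synonym_table()` or
  the CLI `--synonyms` file).
* `serve_facade()` is a thin development server (httpuv); production
  deployments should front `resolve()` with a real web stack and cache.
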