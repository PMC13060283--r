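Package: quickhub
Title: Translate Between UCSC Track Hub and IGB Quickload Repositories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bidirectional translation between the two metadata formats used
    by web-hosted genome browser data collections: UCSC Genome Browser track
    hubs (hub.txt, genomes.txt, trackDb.txt in the RA-style stanza dialect)
    and Integrated Genome Browser (IGB) Quickload repositories (contents.txt,
    annots.xml, genome.txt).  Includes typed models of both formats with
    lossless parsing and serialization, a translation engine with an explicit
    lossiness report, a minimal 2bit binary index reader and fixture writer
    used to synthesize chromosome tables for assembly hubs, a lazy facade
    resolver that serves translated documents on demand through an injectable
    transport, a GenArk-style assembly catalog search, and a deterministic
    synthetic fixture generator so everything is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    utils,
    tools,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    curl,
    httpuv,
    Biostrings,
    rtracklayer
Config/testthat/edition: 3
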