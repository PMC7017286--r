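Package: histomark
Title: Simulation, Quality Control and Consensus Peak Analysis for Histone Mark ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-tissue histone modification ChIP-seq analysis at
    desk scale: a deterministic simulator of aligned single-end ChIP and input
    libraries over synthetic genomes with planted regulatory elements and
    transcription factor motifs; alignment filtering and the six standard
    library-complexity and enrichment quality metrics (NRF, PBC1, PBC2, NSC,
    RSC, JSD) with threshold verdicts; simplified narrow and broad (island)
    peak callers with replicate consensus combining; cross-tissue peak
    comparison (Jaccard similarity, unique peaks, active enhancers);
    input-subtracted enrichment tracks and metagene topology profiles; and
    position weight matrix motif enrichment over tissue-specific enhancers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    tools,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
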