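Package: togcn
Title: Time-Ordered Gene Co-Expression Network Analysis for Developmental
    Time Courses
Version: 0.1.0
Authors@R:
    person("TOGCN", "Maintainers", email = "togcn@example.org",
           role = c("aut", "cre"))
Description: Builds time-ordered gene co-expression networks (TO-GCNs) from
    bulk time-course expression matrices: empirical Pearson-correlation
    cutoff selection from the right tail of the TF-TF pair distribution,
    co-expression graph construction, breadth-first-search level (time
    order) assignment from a seed transcription factor, per-level
    co-expressed gene sets with Fisher's exact enrichment under
    Benjamini-Hochberg FDR control, and comparison of two developmental
    programs through level differences, a 1.5x standard-deviation
    changed/unchanged classification, and window-based type-specific
    transcription factor calling. Ships a synthetic two-program time-course
    generator with planted activation waves so every pipeline stage is
    testable without external data, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
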