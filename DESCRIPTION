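Package: eventex
Title: Pattern-Based Biomedical Event Extraction with Pattern Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns three-layer linguistic patterns (token, word stem,
    part-of-speech) from gold-annotated biomedical event corpora in the
    BioNLP standoff format (.txt/.a1/.a2), matches them against new
    sentences by multi-layer semi-global sequence alignment, and improves
    extraction precision with simple pattern filters: trigger-word
    hit-rate filtering, pattern-length filtering, per-pattern performance
    filtering, and a resampling-based pattern selection protocol. Includes
    a synthetic standoff-corpus generator with known ground truth for
    fully reproducible evaluation, event-level scoring with approximate
    trigger-span matching, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
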