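Package: tsat
Title: Screening and Prioritization of Nano- and Microplastic Toxicity Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A toxicity study assessment tool for nano- and microplastic
    (NMP) human-health effect studies. Provides a configurable QA/QC
    criteria registry with shipped defaults for in vivo (26 criteria) and
    in vitro (23 criteria) test systems, validation and consensus merging
    of multi-rater 0/1/2 evaluation sheets, total assessment score (TAS)
    aggregation, three screening schemes (a red-criteria Tier-1 gate, the
    Fernandez-Cruz reliability classification and the de Ruijter
    all-nonzero adequacy rule), corpus-level per-criterion score
    distributions and summaries, a deterministic synthetic-corpus fixture
    generator, and a command-line interface for batch workflows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
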