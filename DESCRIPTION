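Package: termflex
Title: Detection of Non-Templated 3'-Terminal Extensions in Small RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for discovering RNA fragments whose 3' termini carry
    non-templated, highly diversified extensions in bacterial small RNA-seq
    data. Implements exact 5'-end read mapping with fractional multi-locus
    attribution, a sliding-window differential secretion screen, rule-based
    classification of sequence deviations (non-template additions, chimeras,
    indels, mismatches), a Shannon-diversity scan for loci emitting fragments
    with random 3' flanks, motif-richness summaries, fold-change statistics
    for oligonucleotide-treated bacterial communities, and a deterministic
    simulator of small-RNA libraries with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    S4Vectors,
    stats,
    stringi,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
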