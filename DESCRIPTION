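Package: gatorgc
Title: Targeted Genome Mining with Proximity-Weighted Gene-Cluster Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene-cluster windows (GATOR windows) across bacterial
    genomes from user-defined required and optional protein queries, scores
    all-vs-all window similarity with a proximity-weighted GATOR Focal Score
    (GFS), deduplicates identical windows, quantifies gene conservation and
    taxonomic diversity (Shannon entropy), and emits annotated GenBank files,
    summary tables and vectorized (SVG) comparison figures. Homology evidence
    can be ingested from DIAMOND/BLAST tabular and HMMER domain-table files,
    or computed at desk scale with a built-in Smith-Waterman search.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
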