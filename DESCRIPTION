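Package: epipangene
Title: Gene Methylation Epialleles and Expression Across a Pan-Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying gene methylation epialleles (unmethylated,
    gene-body methylated, and TE-like methylated) from per-cytosine methylome
    records restricted to coding sequence, for organizing genes from many
    genome assemblies into pangene matrices, and for quantifying the
    association between epiallele state and steady-state expression.
    Includes readers for CGmap methylome text, GFF3 gene annotations, TE
    annotations and pangene tables; strand-aware metagene methylation
    profiles; per-gene structural feature summaries; pangene stability and
    tandem-duplication classification; paired sign and signed-rank and
    correlation statistics for epiallele expression differences; and a
    seeded synthetic pan-genome generator with recorded ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
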