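Package: dgetag
Title: Tag-Based Digital Gene Expression Profiling with the Audic-Claverie Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for SAGE-style digital gene expression (DGE)
    tag profiling against a reference transcriptome: construction of the
    CATG-anchored 21-nt reference tag database on both strands, clean-tag
    mapping with a one-mismatch tolerance and unambiguous-tag counting,
    normalization to transcripts per million clean tags (TPM), per-gene
    differential expression between two libraries by the Audic-Claverie
    exact conditional test with Benjamini-Hochberg false discovery rate
    control, time-course set algebra (three-way Venn partitions, common and
    unique gene sets, novel-gene detection), and GO-slim hypergeometric
    enrichment. A forward simulator emulates the NlaIII/MmeI library
    chemistry (3'-most CATG site capture, per-base substitution error,
    designated fold changes) so every stage can be exercised end-to-end
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
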