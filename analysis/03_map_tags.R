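#!/usr/bin/env Rscript
# Stage 3 — align each library's clean tags to the reference tag database
# (exact first, then one mismatch), discard ambiguous tags, count
# unambiguous tags per gene and normalize to TPM.
suppressPackageStartupMessages(library(dgetag))

out <- "results/analysis"
db <- read_refdb(file.path(out, "refdb.tsv"))
for (cid in c("control", "12h", "24h", "48h")) {
  lib <- read_tag_table(file.path(out, sprintf("tags_%s.tsv", cid)))
  m <- map_tags(lib, db, max_mismatch = 1L)
  write_expression(m, file.path(out, sprintf("expr_%s.tsv", cid)))
  jsonlite::write_json(m$report, file.path(out, sprintf("mapping_%s.json", cid)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  r <- m$report
  cat(sprintf("%-8s mapped %.2f%% of distinct tags (%.2f%% of copies); sense %.2f%%, antisense %.2f%%, ambiguous %.2f%%, unmapped %.2f%% of distinct\n",
              cid, 100 * r$mapped_distinct_fraction, 100 * r$mapped_copy_fraction,
              100 * r$distinct_fraction$sense_unique,
              100 * r$distinct_fraction$antisense_unique,
              100 * r$distinct_fraction$ambiguous,
              100 * r$distinct_fraction$unmapped))
}
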