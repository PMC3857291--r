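#!/usr/bin/env Rscript
# Stage 2 — scan every transcript (both strands) for CATG sites with at
# least 17 nt downstream and build the 21-nt reference tag database that
# the clean tags will be aligned against.
suppressPackageStartupMessages(library(dgetag))

out <- "results/analysis"
tx <- read_transcriptome(file.path(out, "transcriptome.fa"))
db <- extract_reference_tags(tx)
write_refdb(db, file.path(out, "refdb.tsv"), file.path(out, "refdb_summary.json"))

cat(sprintf("reference: %d genes, %d with CATG sites (%.1f%%), %d reference tags\n",
            db$n_genes, db$n_genes_with_sites,
            100 * db$n_genes_with_sites / db$n_genes, db$n_reference_tags))
cat(sprintf("  %d tag sequences ambiguous (shared by >= 2 genes), %d N-containing sites skipped\n",
            length(db$ambiguous_tags), db$n_skipped_n_sites))
cat(sprintf("  tags per gene with sites: %.2f\n",
            db$n_reference_tags / db$n_genes_with_sites))
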