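#!/usr/bin/env Rscript
# Stage 1 — forward-simulate the study design at desk scale: a reference
# transcriptome with known ground truth and four clean-tag libraries (one
# control, three cold-treatment time points), emulating the NlaIII/MmeI
# 21-nt tag chemistry. Everything downstream (02..06) re-reads the files
# written here, so each stage can be re-run and checked in isolation.
suppressPackageStartupMessages(library(dgetag))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42L
n_genes <- 2000L
depth <- 5e5L # scaled-down stand-in for the multi-million-tag libraries
conditions <- c("12h", "24h", "48h")

tx <- generate_transcriptome(n_genes, mean_length = 789, catg_density = 10,
                             seed = seed)
truth <- make_truth(tx$gene_id, conditions, frac_up = 0.10, frac_down = 0.05,
                    frac_novel = 0.01, log2fc_range = c(1, 3), seed = seed + 1L)
write_transcriptome(tx, file.path(out, "transcriptome.fa"))
write_truth(truth, file.path(out, "truth.tsv"))

cat(sprintf("simulated %d transcripts (mean length %.0f nt)\n",
            nrow(tx), mean(tx$length)))
for (cond in truth |> attr("conditions")) {
  dirs <- table(truth[[paste0("direction.", cond)]])
  cat(sprintf("  %s truth: %s\n", cond,
              paste(sprintf("%s=%d", names(dirs), dirs), collapse = ", ")))
}

for (i in seq_along(c("control", conditions))) {
  cid <- c("control", conditions)[i]
  lib <- simulate_tag_library(tx, truth,
                              library_spec(cid, depth, error_rate = 0.001,
                                           seed = seed + 10L + i))
  write_tag_table(lib, file.path(out, sprintf("tags_%s.tsv", cid)))
  cat(sprintf("library %-8s %d clean tags (%d distinct), %d dirty reads removed, %d genes unobservable\n",
              cid, lib$library_size, nrow(lib$entries), lib$n_dirty,
              length(lib$unobservable_genes)))
}
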