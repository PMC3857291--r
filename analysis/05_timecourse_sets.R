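#!/usr/bin/env Rscript
# Stage 5 — combine the three DE lists: per-direction Venn partitions
# across the time course, shared-percentage summaries, and novel genes
# (zero control tags, expressed under treatment), with truth-recovery
# numbers since the simulation ground truth is available.
suppressPackageStartupMessages(library(dgetag))

out <- "results/analysis"
conditions <- c("12h", "24h", "48h")
de <- lapply(conditions, function(cid) read_de(file.path(out, sprintf("de_%s.tsv", cid))))
names(de) <- conditions
sets <- timecourse_sets(de)
write_venn(sets$all, file.path(out, "venn_all.json"))
write_venn(sets$up, file.path(out, "venn_up.json"))
write_venn(sets$down, file.path(out, "venn_down.json"))
utils::write.table(sets$counts, file.path(out, "de_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("DE union across the time course: %d genes (%d up, %d down)\n",
            sets$n_de_union, sets$n_up_union, sets$n_down_union))
common_up <- sets$up$sizes[["ABC"]]
common_dn <- sets$down$sizes[["ABC"]]
cat(sprintf("common to all three time points: %d up (%.1f%% of %d), %d down (%.1f%% of %d)\n",
            common_up, shared_percentage(common_up, sets$n_up_union), sets$n_up_union,
            common_dn, shared_percentage(common_dn, sets$n_down_union), sets$n_down_union))

ctrl <- read_expression(file.path(out, "expr_control.tsv"))
novel_sets <- lapply(conditions, function(cid) {
  trt <- read_expression(file.path(out, sprintf("expr_%s.tsv", cid)))
  nv <- detect_novel(ctrl, trt, min_count = 1L)
  utils::write.table(nv, file.path(out, sprintf("novel_%s.tsv", cid)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nv$gene_id
})
nv_venn <- venn_partition(novel_sets[[1]], novel_sets[[2]], novel_sets[[3]], conditions)
write_venn(nv_venn, file.path(out, "venn_novel.json"))
cat(sprintf("novel genes per treatment: %s; expressed at all three: %d\n",
            paste(sprintf("%s=%d", conditions, lengths(novel_sets)), collapse = ", "),
            nv_venn$sizes[["ABC"]]))

truth <- read_truth(file.path(out, "truth.tsv"))
for (cid in conditions) {
  true_de <- truth$gene_id[truth[[paste0("direction.", cid)]] %in% c("up", "down")]
  called <- de[[cid]]$gene_id[de[[cid]]$tier == "significant"]
  tp <- length(intersect(called, true_de))
  cat(sprintf("recovery %-5s sensitivity %.3f (%d/%d), precision %.3f (%d/%d)\n",
              cid, tp / length(true_de), tp, length(true_de),
              tp / length(called), tp, length(called)))
}
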