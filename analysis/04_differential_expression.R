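#!/usr/bin/env Rscript
# Stage 4 — Audic-Claverie exact test per gene for each treatment against
# the control, BH-adjusted within each comparison, classified into the
# significant (FDR <= 0.001, >= 2-fold) and difference (sub-2-fold,
# p <= 0.01, FDR <= 0.001) tiers.
suppressPackageStartupMessages(library(dgetag))

out <- "results/analysis"
ctrl <- read_expression(file.path(out, "expr_control.tsv"))
for (cid in c("12h", "24h", "48h")) {
  trt <- read_expression(file.path(out, sprintf("expr_%s.tsv", cid)))
  de <- de_test(ctrl, trt, fdr_max = 0.001, p_max = 0.01, min_log2 = 1,
                floor_tpm = 0.001)
  write_de(de, file.path(out, sprintf("de_%s.tsv", cid)),
           volcano_path = file.path(out, sprintf("volcano_%s.tsv", cid)))
  cat(sprintf("%-5s %4d significant (%d up / %d down), %d difference-tier, %d genes tested\n",
              cid, sum(de$tier == "significant"),
              sum(de$tier == "significant" & de$direction == "up"),
              sum(de$tier == "significant" & de$direction == "down"),
              sum(de$tier == "difference"), nrow(de)))
}
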