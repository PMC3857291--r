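# Per-gene differential expression between a treatment and a control
# library, with two-tier classification:
#
#   significant — FDR <= 0.001 and |log2 ratio| >= 1 (>= 2-fold change);
#   difference  — fold ratio strictly between 1 and 2 with p <= 0.01 and
#                 FDR <= 0.001, i.e. reproducible but sub-2-fold shifts;
#   not_de      — everything else.
#
# The test uses the raw counts; the log2 ratio uses TPMs with zeros
# replaced by a small floor so that genes absent from one library (novel
# genes in particular) still get a finite, large-magnitude fold change.

#' Two-tier classification of differential-expression results
#'
#' Recomputes `log2_ratio` from the TPM columns with zeros floored at
#' `floor_tpm`, then assigns `tier` and `direction`.
#'
#' @param results data.frame with columns `tpm1`, `tpm2`, `p_value`, `fdr`.
#' @param fdr_max FDR ceiling shared by both tiers.
#' @param p_max p-value ceiling for the sub-2-fold `difference` tier.
#' @param min_log2 |log2 ratio| floor for the `significant` tier.
#' @param floor_tpm positive TPM substituted for zeros in the ratio.
#' @return `results` with `log2_ratio`, `tier` and `direction` columns.
#' @export
classify_de <- function(results, fdr_max = 0.001, p_max = 0.01,
                        min_log2 = 1, floor_tpm = 0.001) {
  if (!is.numeric(floor_tpm) || length(floor_tpm) != 1L || floor_tpm <= 0)
    stopf("'floor_tpm' must be a positive number")
  l2 <- log2(pmax(results$tpm2, floor_tpm) / pmax(results$tpm1, floor_tpm))
  fold <- 2^abs(l2)
  sig <- results$fdr <= fdr_max & abs(l2) >= min_log2
  diff_tier <- !sig & fold > 1 & fold < 2 &
    results$p_value <= p_max & results$fdr <= fdr_max
  results$log2_ratio <- l2
  results$tier <- ifelse(sig, "significant", ifelse(diff_tier, "difference", "not_de"))
  results$direction <- ifelse(results$tier == "not_de" | l2 == 0, "none",
                              ifelse(l2 > 0, "up", "down"))
  results
}

#' Differential expression between two libraries
#'
#' Joins two per-gene expression tables over the union of their gene
#' universes, computes the Audic-Claverie two-sided p-value per gene from
#' the raw unambiguous counts, adjusts across all genes of this one
#' comparison by Benjamini-Hochberg, and classifies into tiers. Results
#' are sorted by FDR, then |log2 ratio| descending.
#'
#' @param control,treatment lists with `expression` (data.frame `gene_id`,
#'   `count`, `tpm`) and `library_size` — as returned by [map_tags()] or
#'   [read_expression()].
#' @inheritParams classify_de
#' @return data.frame with columns `gene_id`, `x`, `y`, `N1`, `N2`,
#'   `tpm1`, `tpm2`, `log2_ratio`, `p_value`, `fdr`, `tier`, `direction`.
#' @export
de_test <- function(control, treatment, fdr_max = 0.001, p_max = 0.01,
                    min_log2 = 1, floor_tpm = 0.001) {
  N1 <- control$library_size
  N2 <- treatment$library_size
  if (is.null(N1) || is.null(N2)) stopf("both inputs need a 'library_size'")
  ce <- control$expression
  te <- treatment$expression
  genes <- union(ce$gene_id, te$gene_id)
  x <- stats::setNames(rep(0L, length(genes)), genes)
  y <- x
  x[ce$gene_id] <- ce$count
  y[te$gene_id] <- te$count

  res <- data.frame(
    gene_id = genes,
    x = as.integer(x), y = as.integer(y),
    N1 = N1, N2 = N2,
    tpm1 = normalize_tpm(as.numeric(x), N1),
    tpm2 = normalize_tpm(as.numeric(y), N2),
    stringsAsFactors = FALSE
  )
  res$p_value <- ac_pvalue(res$x, N1, res$y, N2)
  res$fdr <- adjust_fdr(res$p_value)
  res <- classify_de(res, fdr_max = fdr_max, p_max = p_max,
                     min_log2 = min_log2, floor_tpm = floor_tpm)
  res <- res[order(res$fdr, -abs(res$log2_ratio)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a differential-expression table
#'
#' Also emits a volcano companion table (log10 TPMs per gene with tier and
#' direction) when `volcano_path` is given.
#'
#' @param results data.frame from [de_test()].
#' @param path output TSV.
#' @param volcano_path optional TSV of log10-TPM coordinates for plotting.
#' @param floor_tpm floor applied before taking log10 for the volcano table.
#' @return `path`, invisibly.
#' @export
write_de <- function(results, path, volcano_path = NULL, floor_tpm = 0.001) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(volcano_path)) {
    v <- data.frame(gene_id = results$gene_id,
                    log10_tpm_control = log10(pmax(results$tpm1, floor_tpm)),
                    log10_tpm_treatment = log10(pmax(results$tpm2, floor_tpm)),
                    tier = results$tier, direction = results$direction,
                    stringsAsFactors = FALSE)
    utils::write.table(v, volcano_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a differential-expression table
#'
#' @param path TSV written by [write_de()].
#' @return the results data.frame.
#' @export
read_de <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
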