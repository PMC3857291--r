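# Simulation ground truth: per-gene baseline abundance plus a designated
# fold change and direction label for each treatment condition. "novel"
# genes are silent in the control (baseline 0) and switch on in at least
# one treatment at an abundance stored in `novel_abundance`.

#' Designate per-gene expression truth for a simulated time course
#'
#' Each gene is assigned a class (up, down, novel, or null) and, for
#' non-null genes, an active subset of the treatment conditions drawn
#' uniformly from the seven non-empty subsets — this is what creates
#' realistic Venn overlap structure between time points. Fold changes are
#' drawn per active condition as `2^u` with `u ~ Uniform(log2fc_range)`
#' (reciprocal for downregulated genes), so every true call is at least a
#' 2-fold change when `log2fc_range[1] >= 1`. Baseline abundances are
#' log-normal: dimensionless sampling weights, heavy tailed like real
#' transcript abundances.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param conditions treatment condition labels (the control is implicit:
#'   its weight is the baseline abundance).
#' @param frac_up,frac_down,frac_novel fractions of genes designated
#'   upregulated, downregulated and novel (silent in control).
#' @param log2fc_range range of |log2 fold change| for affected genes; a
#'   single value fixes the fold change exactly.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline abundance distribution.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `baseline`, `novel_abundance`
#'   and, per condition `c`, `fold_change.c` and `direction.c`.
#' @export
make_truth <- function(gene_ids, conditions = c("12h", "24h", "48h"),
                       frac_up = 0.10, frac_down = 0.05, frac_novel = 0.01,
                       log2fc_range = c(1, 3),
                       baseline_meanlog = 0, baseline_sdlog = 1,
                       seed = 1L) {
  if (anyDuplicated(gene_ids)) stopf("gene_ids must be unique")
  if (length(conditions) < 1L) stopf("at least one treatment condition required")
  if (frac_up + frac_down + frac_novel > 1) stopf("class fractions exceed 1")
  if (length(log2fc_range) == 1L) log2fc_range <- rep(log2fc_range, 2L)
  n <- length(gene_ids)

  withr::with_seed(as.integer(seed), {
    cls <- sample(c("up", "down", "novel", "null"), n, replace = TRUE,
                  prob = c(frac_up, frac_down, frac_novel,
                           1 - frac_up - frac_down - frac_novel))
    baseline <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
    novel_ab <- rep(0, n)
    baseline[cls == "novel"] <- 0
    novel_ab[cls == "novel"] <- stats::rlnorm(sum(cls == "novel"),
                                              baseline_meanlog, baseline_sdlog)

    nc <- length(conditions)
    # active-condition subset per non-null gene, uniform over non-empty subsets
    subset_code <- integer(n)
    affected <- cls != "null"
    subset_code[affected] <- sample.int(2^nc - 1L, sum(affected), replace = TRUE)

    truth <- data.frame(gene_id = as.character(gene_ids), baseline = baseline,
                        novel_abundance = novel_ab, stringsAsFactors = FALSE)
    for (j in seq_len(nc)) {
      active <- affected & bitwAnd(subset_code, bitwShiftL(1L, j - 1L)) > 0L
      u <- stats::runif(n, log2fc_range[1L], log2fc_range[2L])
      fc <- rep(1, n)
      fc[active & cls == "up"] <- 2^u[active & cls == "up"]
      fc[active & cls == "down"] <- 2^(-u[active & cls == "down"])
      dir <- rep("null", n)
      dir[active] <- cls[active]
      truth[[paste0("fold_change.", conditions[j])]] <- fc
      truth[[paste0("direction.", conditions[j])]] <- dir
    }
    attr(truth, "conditions") <- conditions
    truth
  })
}

#' Per-gene sampling weights implied by the truth table for one condition
#'
#' The control condition uses the baseline abundance directly; a treatment
#' condition uses `baseline * fold_change`, except for novel genes, whose
#' control baseline is 0 and whose active-treatment weight is
#' `novel_abundance`.
#'
#' @param truth data.frame from [make_truth()].
#' @param condition_id condition label; `control_id` selects the baseline.
#' @param control_id label naming the control.
#' @return named numeric vector of non-negative weights.
#' @export
truth_weights <- function(truth, condition_id, control_id = "control") {
  w <- truth$baseline
  if (!identical(condition_id, control_id)) {
    fc_col <- paste0("fold_change.", condition_id)
    dir_col <- paste0("direction.", condition_id)
    if (!fc_col %in% names(truth))
      stopf("condition '%s' not present in truth table", condition_id)
    w <- truth$baseline * truth[[fc_col]]
    novel_on <- truth[[dir_col]] == "novel"
    w[novel_on] <- truth$novel_abundance[novel_on]
  }
  stats::setNames(w, truth$gene_id)
}

#' @rdname read_truth
#' @param truth truth data.frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a simulation truth table as TSV
#'
#' @param path TSV path.
#' @return `read_truth` returns the truth data.frame; `write_truth` the path.
#' @export
read_truth <- function(path) {
  truth <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
  attr(truth, "conditions") <-
    sub("^fold_change\\.", "", grep("^fold_change\\.", names(truth), value = TRUE))
  truth
}
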