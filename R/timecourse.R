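# Time-course set algebra: three-way Venn partitions of per-comparison DE
# gene lists, shared percentages as printed in summary tables, and
# novel-gene detection (silent in control, expressed under treatment).

#' Partition three gene sets into the seven Venn regions
#'
#' @param setA,setB,setC character vectors of gene ids (duplicates ignored).
#' @param names labels for the three sets, used in region names.
#' @return a `venn_partition`: list with `regions` (named list of gene
#'   vectors for `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`, where e.g. `AB`
#'   means in A and B but not C), `sizes`, and `condition_ids`. The seven
#'   regions are pairwise disjoint and their union is A ∪ B ∪ C; this is
#'   asserted on every call.
#' @export
venn_partition <- function(setA, setB, setC, names = c("A", "B", "C")) {
  a <- unique(as.character(setA)); b <- unique(as.character(setB))
  c_ <- unique(as.character(setC))
  u <- unique(c(a, b, c_))
  code <- (u %in% a) + 2L * (u %in% b) + 4L * (u %in% c_)
  region_names <- c("A", "B", "AB", "C", "AC", "BC", "ABC")
  regions <- stats::setNames(lapply(1:7, function(k) u[code == k]), region_names)
  order_out <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  regions <- regions[order_out]
  sizes <- lengths(regions)
  stopifnot(sum(sizes) == length(u),
            !anyDuplicated(unlist(regions, use.names = FALSE)))
  structure(list(regions = regions, sizes = sizes, condition_ids = names),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition (", paste(x$condition_ids, collapse = ", "), "):\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' Percentage of a total that a shared set represents
#'
#' `100 * shared / total`, rounded half-up to `digits` decimals — the
#' rounding used in printed summary percentages.
#'
#' @param shared_count size of the shared subset.
#' @param total_count size of the reference total (>= 1).
#' @param digits decimal places (default 1).
#' @return the rounded percentage.
#' @export
shared_percentage <- function(shared_count, total_count, digits = 1L) {
  if (!is_count(total_count) || total_count < 1)
    stopf("'total_count' must be a positive integer")
  if (!is_count(shared_count) || shared_count > total_count)
    stopf("'shared_count' must be an integer in [0, total_count]")
  round_half_up(100 * shared_count / total_count, digits)
}

#' Detect novel genes induced by a treatment
#'
#' A novel gene has zero unambiguous tags in the control and at least
#' `min_count` in the treatment library. (This is an operational
#' definition — an expression-based reading of "novel"; it is not the only
#' possible one.) Raw treatment counts are returned for ranking.
#'
#' @param control_expr,treatment_expr lists with `expression` data.frames
#'   over the same reference gene universe ([map_tags()] output or
#'   [read_expression()]).
#' @param min_count minimum treatment count (>= 1).
#' @return data.frame `gene_id`, `raw_count`, sorted by count descending.
#' @export
detect_novel <- function(control_expr, treatment_expr, min_count = 1L) {
  if (!is_count(min_count) || min_count < 1) stopf("'min_count' must be >= 1")
  ce <- control_expr$expression
  te <- treatment_expr$expression
  m <- merge(ce[, c("gene_id", "count")], te[, c("gene_id", "count")],
             by = "gene_id", suffixes = c(".ctrl", ".trt"))
  novel <- m[m$count.ctrl == 0L & m$count.trt >= min_count, , drop = FALSE]
  out <- data.frame(gene_id = novel$gene_id, raw_count = novel$count.trt,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$raw_count, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a three-comparison time course
#'
#' Builds per-direction gene sets from three DE tables (genes in the
#' `significant` tier only), the Venn partitions for up, down and all-DE,
#' and a per-comparison tally table. Genes with inconsistent direction
#' across time points are counted once per direction, so the up and down
#' totals may together exceed the distinct DE gene count.
#'
#' @param de_list named list of three DE data.frames from [de_test()], in
#'   time order.
#' @return list with `up`, `down`, `all` (`venn_partition`s), `counts`
#'   (per-comparison up/down tallies), `n_de_union` and per-direction
#'   union sizes.
#' @export
timecourse_sets <- function(de_list) {
  if (length(de_list) != 3L) stopf("exactly three DE tables are required")
  ids <- names(de_list)
  if (is.null(ids)) ids <- paste0("t", 1:3)
  up <- lapply(de_list, function(d) d$gene_id[d$tier == "significant" & d$direction == "up"])
  dn <- lapply(de_list, function(d) d$gene_id[d$tier == "significant" & d$direction == "down"])
  all_de <- lapply(de_list, function(d) d$gene_id[d$tier == "significant"])
  counts <- data.frame(condition = ids,
                       up = lengths(up), down = lengths(dn),
                       total = lengths(all_de), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(up = venn_partition(up[[1]], up[[2]], up[[3]], ids),
       down = venn_partition(dn[[1]], dn[[2]], dn[[3]], ids),
       all = venn_partition(all_de[[1]], all_de[[2]], all_de[[3]], ids),
       counts = counts,
       n_de_union = length(unique(unlist(all_de, use.names = FALSE))),
       n_up_union = length(unique(unlist(up, use.names = FALSE))),
       n_down_union = length(unique(unlist(dn, use.names = FALSE))))
}

#' Write a Venn partition as JSON
#'
#' @param partition a `venn_partition`.
#' @param path output JSON.
#' @return `path`, invisibly.
#' @export
write_venn <- function(partition, path) {
  jsonlite::write_json(list(condition_ids = partition$condition_ids,
                            sizes = as.list(partition$sizes),
                            regions = lapply(partition$regions, as.character)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
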