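# Clean-tag to gene mapping with a 1-mismatch budget.
#
# Precedence is standard best-hit: exact matches first; only a tag with no
# exact match is considered at Hamming distance 1. A tag whose best-tier
# matches hit two or more distinct genes is ambiguous and its count is
# discarded from every gene — expression rests on unambiguous clean tags
# only. Both observed and reference tags begin with CATG, so a distance-1
# pair can differ only in the 17-nt extension; the mismatch neighbourhood
# is enumerated over positions 5..21 and looked up exactly, which the test
# suite checks against an all-pairs Hamming oracle.

validate_tag_entries <- function(entries) {
  bad <- which(nchar(entries$tag_sequence) != TAG_LENGTH |
               !startsWith(entries$tag_sequence, TAG_ANCHOR))
  if (length(bad))
    stopf("row %d: tag '%s' is not a 21-nt CATG-anchored tag",
          bad[1L], entries$tag_sequence[bad[1L]])
  if (any(entries$count < 1L)) stopf("tag counts must be positive integers")
  invisible(TRUE)
}

#' Normalize tag counts to transcripts per million clean tags
#'
#' `tpm_i = count_i / library_size * 1e6`. The denominator is the total
#' clean-tag count of the library (mappable or not), not the mapped total.
#'
#' @param counts non-negative per-gene tag counts (names preserved).
#' @param library_size total clean tags in the library (>= 1).
#' @return numeric TPM vector.
#' @export
normalize_tpm <- function(counts, library_size) {
  if (!is_count(library_size) || library_size < 1)
    stopf("'library_size' must be a positive integer")
  if (any(counts < 0)) stopf("counts must be non-negative")
  counts / library_size * 1e6
}

#' Map observed clean tags to a reference tag database
#'
#' Assigns every observed tag by precedence (exact, then 1-mismatch),
#' discards ambiguous tags (best-tier hits in >= 2 genes), accumulates
#' unambiguous counts per gene, and normalizes to TPM over the library
#' size. Tags whose only unambiguous hits are antisense are tabulated
#' separately and excluded from gene expression unless
#' `include_antisense = TRUE`.
#'
#' @param table a `tag_count_table` (see [read_tag_table()]).
#' @param db a `ref_tag_db` (see [extract_reference_tags()]).
#' @param max_mismatch 0 or 1 mismatching bases tolerated.
#' @param include_antisense count antisense-unique tags into gene totals.
#' @return a `tag_mapping`: list with `expression` (data.frame `gene_id`,
#'   `count`, `tpm` over every gene in the reference), `assignments`
#'   (per observed tag: category, tier, gene), and `report` (distinct-tag
#'   and copy-weighted fractions per category).
#' @export
map_tags <- function(table, db, max_mismatch = 1L, include_antisense = FALSE) {
  if (!max_mismatch %in% c(0L, 1L)) stopf("'max_mismatch' must be 0 or 1")
  entries <- table$entries
  validate_tag_entries(entries)

  ref <- db$tags
  ref_u <- unique(ref$tag_sequence)
  ref_row_tag <- match(ref$tag_sequence, ref_u)

  q <- entries$tag_sequence
  nq <- length(q)
  hit_rows <- vector("list", nq) # reference rows at the best tier
  tier <- rep(NA_character_, nq)

  exact <- match(q, ref_u)
  has_exact <- !is.na(exact)
  if (any(has_exact)) {
    rows_by_tag <- split(seq_len(nrow(ref)), ref_row_tag)
    hit_rows[has_exact] <- rows_by_tag[as.character(exact[has_exact])]
    tier[has_exact] <- "exact"
  }

  if (max_mismatch >= 1L && any(!has_exact)) {
    cand <- which(!has_exact)
    qs <- q[cand]
    acc_q <- integer(0); acc_tag <- integer(0)
    for (pos in (nchar(TAG_ANCHOR) + 1L):TAG_LENGTH) {
      orig <- substr(qs, pos, pos)
      for (b in DNA_BASES) {
        keep <- orig != b
        if (!any(keep)) next
        v <- qs[keep]
        substr(v, pos, pos) <- b
        mi <- match(v, ref_u)
        hit <- which(!is.na(mi))
        acc_q <- c(acc_q, cand[keep][hit])
        acc_tag <- c(acc_tag, mi[hit])
      }
    }
    if (length(acc_q)) {
      rows_by_tag <- split(seq_len(nrow(ref)), ref_row_tag)
      by_query <- split(acc_tag, acc_q)
      for (k in seq_along(by_query)) {
        qi <- as.integer(names(by_query)[k])
        hit_rows[[qi]] <- unlist(rows_by_tag[as.character(unique(by_query[[k]]))],
                                 use.names = FALSE)
        tier[qi] <- "mismatch"
      }
    }
  }

  category <- character(nq)
  gene_of <- rep(NA_character_, nq)
  for (i in seq_len(nq)) {
    rows <- hit_rows[[i]]
    if (is.null(rows) || length(rows) == 0L) { category[i] <- "unmapped"; next }
    genes <- unique(ref$gene_id[rows])
    if (length(genes) >= 2L) { category[i] <- "ambiguous"; next }
    gene_of[i] <- genes
    category[i] <- if (any(ref$strand[rows] == "sense")) "sense_unique"
                   else "antisense_unique"
  }

  counted <- category == "sense_unique" |
    (include_antisense & category == "antisense_unique")
  gene_counts <- stats::setNames(rep(0L, length(db$gene_ids)), db$gene_ids)
  if (any(counted)) {
    agg <- tapply(entries$count[counted], gene_of[counted], sum)
    gene_counts[names(agg)] <- as.integer(agg)
  }

  expression <- data.frame(gene_id = names(gene_counts),
                           count = as.integer(gene_counts),
                           tpm = normalize_tpm(as.numeric(gene_counts),
                                               table$library_size),
                           stringsAsFactors = FALSE)
  rownames(expression) <- NULL

  frac_of <- function(w) {
    tot <- sum(w)
    sapply(c("sense_unique", "antisense_unique", "ambiguous", "unmapped"),
           function(cat) sum(w[category == cat]) / tot)
  }
  report <- list(
    library_id = table$library_id,
    library_size = table$library_size,
    n_distinct_tags = nq,
    n_tag_copies = sum(entries$count),
    distinct_fraction = as.list(frac_of(rep(1, nq))),
    copy_fraction = as.list(frac_of(entries$count)),
    mapped_distinct_fraction = sum(category != "unmapped") / nq,
    mapped_copy_fraction = sum(entries$count[category != "unmapped"]) /
      sum(entries$count),
    tier_distinct = as.list(table(factor(tier[counted | category == "ambiguous"],
                                         levels = c("exact", "mismatch"))))
  )

  structure(list(
    expression = expression,
    assignments = data.frame(tag_sequence = q, count = entries$count,
                             category = category, tier = tier,
                             gene_id = gene_of, stringsAsFactors = FALSE),
    report = report,
    library_size = table$library_size
  ), class = "tag_mapping")
}

#' @export
print.tag_mapping <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("Tag mapping '%s': %d distinct tags (%d copies); ",
                     "mapped %.2f%% distinct / %.2f%% copies\n"),
              r$library_id, r$n_distinct_tags, r$n_tag_copies,
              100 * r$mapped_distinct_fraction, 100 * r$mapped_copy_fraction))
  invisible(x)
}

#' Write a per-gene expression table
#'
#' Three columns (`gene_id`, `count`, `tpm`) with `#library_id=` and
#' `#library_size=` headers so downstream tests can recover the TPM
#' denominator.
#'
#' @param mapping a `tag_mapping` (or a list with `expression` and
#'   `library_size`).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mapping, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lib_id <- if (!is.null(mapping$report)) mapping$report$library_id else "library"
  writeLines(c(sprintf("#library_id=%s", lib_id),
               sprintf("#library_size=%d", mapping$library_size),
               "gene_id\tcount\ttpm"), con)
  utils::write.table(mapping$expression, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' @param path TSV written by [write_expression()].
#' @return list with `expression` data.frame, `library_size`, `library_id`.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  size_line <- grep("^#library_size=", hdr, value = TRUE)
  if (length(size_line) != 1L) stopf("missing '#library_size=' header in %s", path)
  id_line <- grep("^#library_id=", hdr, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", "count", "tpm")
  list(expression = df,
       library_size = as.integer(sub("^#library_size=", "", size_line)),
       library_id = if (length(id_line)) sub("^#library_id=", "", id_line)
                    else basename(path))
}
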