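# Reference tag database construction.
#
# Every CATG occurrence with >= 17 nt downstream yields a 21-nt reference
# tag; the scan is run on the sense strand and, identically, on the reverse
# complement ("antisense" tags). CATG is palindromic, so an antisense tag's
# site coincides with a sense-strand CATG; its stored position is the
# 0-based sense-strand offset of that motif. All sites are indexed, not
# only the 3'-most one — observed libraries contain tags from internal
# sites whenever digestion or priming is imperfect — and the sense 3'-most
# tag is flagged for diagnostics. Sites whose 21-mer contains N are skipped:
# an N-bearing tag cannot be matched under a 1-mismatch budget without
# inflating ambiguity.

#' Build the reference tag database from a transcriptome
#'
#' @param transcripts transcriptome (data.frame with `gene_id`/`sequence`,
#'   `DNAStringSet`, or FASTA path). Alphabet A/C/G/T/N.
#' @return a `ref_tag_db`: list with `tags` (data.frame `tag_sequence`,
#'   `gene_id`, `position` (0-based sense-strand offset of the C of CATG),
#'   `strand` (`sense`/`antisense`), `is_3prime_most`), `gene_ids` (all
#'   input genes), `n_genes`, `n_genes_with_sites`, `n_reference_tags`,
#'   `ambiguous_tags` (tag sequences hitting >= 2 genes) and
#'   `n_skipped_n_sites`.
#' @export
extract_reference_tags <- function(transcripts) {
  tx <- as_transcriptome(transcripts)
  bad <- grepl("[^ACGTN]", tx$sequence)
  if (any(bad)) stopf("transcript '%s' contains characters outside A/C/G/T/N",
                      tx$gene_id[bad][1L])

  scan_strand <- function(sequence) {
    v <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    p <- find_catg_positions(v)
    p[p + TAG_LENGTH - 1L <= length(v)]
  }

  out <- vector("list", nrow(tx))
  n_skipped <- 0L
  for (i in seq_len(nrow(tx))) {
    s <- tx$sequence[i]
    len <- tx$length[i]
    ps <- scan_strand(s)
    sense_tags <- if (length(ps)) substring(s, ps, ps + TAG_LENGTH - 1L) else character(0)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    pa <- scan_strand(rc)
    anti_tags <- if (length(pa)) substring(rc, pa, pa + TAG_LENGTH - 1L) else character(0)
    # sense-strand 0-based offset of the palindromic site seen on the RC
    anti_pos <- len - 3L - pa # == len - 4 - (pa - 1)

    keep_s <- !grepl("N", sense_tags, fixed = TRUE)
    keep_a <- !grepl("N", anti_tags, fixed = TRUE)
    n_skipped <- n_skipped + sum(!keep_s) + sum(!keep_a)
    ps <- ps[keep_s]; sense_tags <- sense_tags[keep_s]
    anti_pos <- anti_pos[keep_a]; anti_tags <- anti_tags[keep_a]

    if (length(sense_tags) + length(anti_tags) == 0L) next
    three_prime <- if (length(ps)) ps == max(ps) else logical(0)
    out[[i]] <- data.frame(
      tag_sequence = c(sense_tags, anti_tags),
      gene_id = tx$gene_id[i],
      position = c(ps - 1L, anti_pos),
      strand = rep(c("sense", "antisense"), c(length(ps), length(anti_tags))),
      is_3prime_most = c(three_prime, rep(FALSE, length(anti_tags))),
      stringsAsFactors = FALSE
    )
  }
  tags <- do.call(rbind, out)
  rownames(tags) <- NULL

  genes_per_tag <- tapply(tags$gene_id, tags$tag_sequence,
                          function(g) length(unique(g)))
  structure(list(
    tags = tags,
    gene_ids = tx$gene_id,
    n_genes = nrow(tx),
    n_genes_with_sites = length(unique(tags$gene_id)),
    n_reference_tags = nrow(tags),
    ambiguous_tags = names(genes_per_tag)[genes_per_tag >= 2L],
    n_skipped_n_sites = n_skipped
  ), class = "ref_tag_db")
}

#' @export
print.ref_tag_db <- function(x, ...) {
  cat(sprintf(paste0("Reference tag DB: %d genes (%d with CATG sites), ",
                     "%d reference tags, %d ambiguous tag sequences\n"),
              x$n_genes, x$n_genes_with_sites, x$n_reference_tags,
              length(x$ambiguous_tags)))
  invisible(x)
}

#' Write a reference tag database
#'
#' Tags go to a 5-column TSV (`tag_sequence`, `gene_id`, `position`,
#' `strand`, `is_3prime_most`; positions 0-based); the summary (gene and
#' tag counts) to a JSON sidecar when `summary_path` is given.
#'
#' @param db a `ref_tag_db`.
#' @param path output TSV.
#' @param summary_path optional JSON path for the summary counts.
#' @return `path`, invisibly.
#' @export
write_refdb <- function(db, path, summary_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#genes=%s", paste(db$gene_ids, collapse = ",")), con)
  utils::write.table(db$tags, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(n_genes = db$n_genes,
                              n_genes_with_sites = db$n_genes_with_sites,
                              n_reference_tags = db$n_reference_tags,
                              n_ambiguous_tag_sequences = length(db$ambiguous_tags)),
                         summary_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a reference tag database TSV
#'
#' @param path TSV written by [write_refdb()].
#' @return a `ref_tag_db`.
#' @export
read_refdb <- function(path) {
  lines <- readLines(path)
  gene_line <- grep("^#genes=", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  tags <- utils::read.table(text = body, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  tags$is_3prime_most <- as.logical(tags$is_3prime_most)
  gene_ids <- if (length(gene_line) == 1L)
    strsplit(sub("^#genes=", "", gene_line), ",", fixed = TRUE)[[1L]]
  else unique(tags$gene_id)
  genes_per_tag <- tapply(tags$gene_id, tags$tag_sequence,
                          function(g) length(unique(g)))
  structure(list(tags = tags, gene_ids = gene_ids, n_genes = length(gene_ids),
                 n_genes_with_sites = length(unique(tags$gene_id)),
                 n_reference_tags = nrow(tags),
                 ambiguous_tags = names(genes_per_tag)[genes_per_tag >= 2L],
                 n_skipped_n_sites = NA_integer_),
            class = "ref_tag_db")
}
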