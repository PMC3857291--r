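# Forward simulation of DGE tag libraries.
#
# The library chemistry being emulated: poly(A)+ cDNA is digested with
# NlaIII (cuts at CATG), the 3'-most fragment is retained on oligo-dT
# beads, and MmeI then cuts 17 bp downstream of the CATG junction. Each
# transcript molecule therefore yields one 21-nt tag (CATG + 17 nt) at its
# 3'-most CATG site that has at least 17 nt downstream; transcripts with no
# usable site are invisible to the assay. Sequencing error is modelled as
# per-base substitution, uniform over the 21 positions and the 3
# alternative bases — the dominant Illumina error mode at this read length.

#' Library specification for the tag simulator
#'
#' @param condition_id condition label (e.g. `"control"`, `"12h"`).
#' @param depth total number of tags to emit (the clean-tag library size).
#' @param error_rate per-base substitution probability, in \[0, 0.05\].
#' @param seed integer seed fixing every stochastic draw for this library.
#' @return a `library_spec` list.
#' @export
library_spec <- function(condition_id, depth, error_rate = 0.001, seed = 1L) {
  if (!is_count(depth) || depth < 1) stopf("'depth' must be a positive integer")
  assert_scalar_number(error_rate, "error_rate")
  if (error_rate < 0 || error_rate > 0.05) stopf("'error_rate' must be in [0, 0.05]")
  structure(list(condition_id = as.character(condition_id),
                 depth = as.integer(depth),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "library_spec")
}

# Usable sense CATG site positions (1-based starts), ordered 3'-most first.
usable_tag_sites <- function(sequence) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  p <- find_catg_positions(v)
  p <- p[p + TAG_LENGTH - 1L <= length(v)]
  sort(p, decreasing = TRUE)
}

#' Draw per-gene tag counts for one library
#'
#' Multinomial sampling of `depth` tags with probabilities proportional to
#' the supplied weights. This is the count layer of the simulator, exposed
#' separately so statistical properties of downstream tests can be studied
#' without sequence-level detail.
#'
#' @param weights named non-negative sampling weights (zero = unobservable).
#' @param depth total tags to draw.
#' @param seed integer seed.
#' @return named integer vector of counts summing exactly to `depth`.
#' @export
simulate_library_counts <- function(weights, depth, seed = 1L) {
  if (any(weights < 0) || !any(weights > 0)) stopf("weights must be non-negative with a positive sum")
  if (!is_count(depth) || depth < 1) stopf("'depth' must be a positive integer")
  withr::with_seed(as.integer(seed),
    stats::setNames(as.integer(stats::rmultinom(1L, as.integer(depth), weights)),
                    names(weights)))
}

# apply per-base substitutions to a character vector of 21-nt tags
apply_substitution_errors <- function(tags, error_rate) {
  if (error_rate <= 0 || length(tags) == 0L) return(tags)
  n_mut <- stats::rbinom(length(tags), TAG_LENGTH, error_rate)
  idx <- which(n_mut > 0L)
  for (i in idx) {
    v <- strsplit(tags[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(TAG_LENGTH, n_mut[i])
    for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
    tags[i] <- paste(v, collapse = "")
  }
  tags
}

#' Simulate one DGE tag library
#'
#' Emits exactly `spec$depth` tags. Each tag is the 21-nt sequence at the
#' 3'-most usable CATG site of its source transcript (a site closer than
#' 17 nt to the 3' end is skipped in favour of the next one upstream), with
#' substitution errors applied at `spec$error_rate` uniformly over all 21
#' positions. Reads whose CATG anchor is corrupted by error no longer meet
#' the clean-tag definition and are removed, mirroring the upstream
#' dirty-tag filter; the table's `library_size` is the resulting clean-tag
#' count (`n_emitted` and `n_dirty` record the split). Genes are sampled
#' with weight `baseline * fold_change` for the condition (see
#' [truth_weights()]); genes with no usable site are silently unobservable
#' and are listed in the `unobservable_genes` field of the result.
#'
#' @param transcripts transcriptome (data.frame, `DNAStringSet` or FASTA path).
#' @param truth truth table from [make_truth()].
#' @param spec a [library_spec()].
#' @param control_id label of the control condition in `truth`.
#' @param partial_digestion probability that an emitted tag falls back from
#'   the 3'-most usable site to the next site upstream (geometric fallback);
#'   0 reproduces complete NlaIII digestion.
#' @return a `tag_count_table`: list with `library_id`, `entries`
#'   (data.frame `tag_sequence`, `count`), `library_size`, plus the true
#'   per-gene emitted counts in `$gene_counts` for recovery checks.
#' @export
simulate_tag_library <- function(transcripts, truth, spec,
                                 control_id = "control",
                                 partial_digestion = 0) {
  if (!inherits(spec, "library_spec")) stopf("'spec' must come from library_spec()")
  if (partial_digestion < 0 || partial_digestion >= 1)
    stopf("'partial_digestion' must be in [0, 1)")
  tx <- as_transcriptome(transcripts)
  w <- truth_weights(truth, spec$condition_id, control_id)
  miss <- setdiff(names(w), tx$gene_id)
  if (length(miss)) stopf("truth gene '%s' absent from transcriptome", miss[1L])

  sites <- lapply(tx$sequence, usable_tag_sites)
  names(sites) <- tx$gene_id
  n_sites <- lengths(sites)[names(w)]
  unobservable <- names(w)[w > 0 & n_sites == 0L]
  w[n_sites == 0L] <- 0
  if (!any(w > 0)) stopf("no expressed gene has a usable CATG site")

  seq_by_gene <- stats::setNames(tx$sequence, tx$gene_id)
  tag_at <- function(gene, site_idx) {
    p <- sites[[gene]][site_idx]
    substr(seq_by_gene[[gene]], p, p + TAG_LENGTH - 1L)
  }

  withr::with_seed(spec$seed, {
    counts <- stats::setNames(
      as.integer(stats::rmultinom(1L, spec$depth, w)), names(w))
    expressed <- names(counts)[counts > 0L]
    tags <- character(0)
    if (partial_digestion == 0) {
      tags <- rep(vapply(expressed, function(g) tag_at(g, 1L), ""),
                  counts[expressed])
    } else {
      for (g in expressed) {
        fall <- stats::rgeom(counts[g], prob = 1 - partial_digestion)
        idx <- pmin(fall + 1L, length(sites[[g]]))
        tags <- c(tags, vapply(idx, function(i) tag_at(g, i), ""))
      }
    }
    tags <- apply_substitution_errors(tags, spec$error_rate)
    # reads whose CATG anchor was corrupted fail the clean-tag definition
    # and are removed, exactly as the upstream dirty-tag filter would
    dirty <- !startsWith(tags, TAG_ANCHOR)
    tab <- table(tags[!dirty])
    entries <- data.frame(tag_sequence = names(tab),
                          count = as.integer(tab), stringsAsFactors = FALSE)
    entries <- entries[order(entries$tag_sequence), , drop = FALSE]
    rownames(entries) <- NULL
    structure(list(library_id = spec$condition_id,
                   entries = entries,
                   library_size = spec$depth - sum(dirty),
                   n_emitted = spec$depth,
                   n_dirty = sum(dirty),
                   gene_counts = counts,
                   unobservable_genes = unobservable),
              class = "tag_count_table")
  })
}

#' @export
print.tag_count_table <- function(x, ...) {
  cat(sprintf("DGE tag library '%s': %d tags (%d distinct), %d unobservable genes\n",
              x$library_id, x$library_size, nrow(x$entries),
              length(x$unobservable_genes)))
  invisible(x)
}

#' Write a tag count table as TSV
#'
#' Two columns (`tag_sequence`, `count`) preceded by `#library_id=` and
#' `#library_size=` header lines; the library size is the total clean-tag
#' count and is the TPM denominator downstream.
#'
#' @param table a `tag_count_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_tag_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#library_id=%s", table$library_id),
               sprintf("#library_size=%d", table$library_size),
               "tag_sequence\tcount"), con)
  utils::write.table(table$entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tag count table TSV
#'
#' @param path TSV written by [write_tag_table()] (or any 2-column
#'   tag/count TSV with the `#library_size=` header).
#' @return a `tag_count_table`.
#' @export
read_tag_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    h <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(h) != 1L) stopf("missing '#%s=' header in %s", key, path)
    sub(paste0("^#", key, "="), "", h)
  }
  lib_size <- as.integer(get_hdr("library_size"))
  lib_id <- tryCatch(get_hdr("library_id"), error = function(e) basename(path))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer"))
  names(df) <- c("tag_sequence", "count")
  if (any(df$count < 1L)) stopf("tag counts must be >= 1 in %s", path)
  structure(list(library_id = lib_id, entries = df, library_size = lib_size,
                 gene_counts = NULL, unobservable_genes = character(0)),
            class = "tag_count_table")
}
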