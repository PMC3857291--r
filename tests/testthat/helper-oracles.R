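# Independent brute-force oracles and small fixture builders. Every oracle
# here is deliberately naive — regex scans, all-pairs Hamming distances,
# direct tail summation, exhaustive enumeration of draws — so that it shares
# no code path with the implementation it checks.

# count CATG-anchored 21-mers on both strands by regex scan
oracle_count_ref_tags <- function(sequences) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  count_one_strand <- function(s) {
    n <- 0L
    start <- 1L
    repeat {
      m <- regexpr("CATG", substr(s, start, nchar(s)), fixed = TRUE)
      if (m == -1L) break
      pos <- start + as.integer(m) - 1L
      if (pos + 20L <= nchar(s)) n <- n + 1L
      start <- pos + 1L
    }
    n
  }
  sum(vapply(sequences, function(s) count_one_strand(s) + count_one_strand(revcomp(s)), 0L))
}

# naive direct summation of the AC conditional tails; mirrors the
# orientation-symmetric two-sided construction but shares no code
oracle_ac_pvalue <- function(x, N1, y, N2) {
  pmf <- function(k, x0, r) exp(k * log(r) + lgamma(x0 + k + 1) - lgamma(x0 + 1) -
                                lgamma(k + 1) - (x0 + k + 1) * log(1 + r))
  upper <- function(x0, y0, r) {
    # sum the tail far beyond the mass; direct summation keeps full
    # relative precision for small tails. The conditional has mean
    # (x0+1)r and variance (x0+1)r(1+r); extend well past both the
    # observation and the bulk.
    kmax <- ceiling(max(y0, (x0 + 1) * r) + 50 * sqrt((x0 + 1) * r * (1 + r))) + 2000L
    ks <- y0:kmax
    sum(pmf(ks, x0, r))
  }
  up <- if (y == 0) 1 else upper(x, y, N2 / N1)
  down <- if (x == 0) 1 else upper(y, x, N1 / N2)
  min(1, 2 * min(up, down))
}

# all-pairs Hamming mapping oracle with exact-first precedence and
# ambiguous-discard: every observed tag is compared against every
# reference tag position by position (a 21 x n_refs character matrix),
# with no index structure shared with the implementation
oracle_map_tags <- function(entries, ref, include_antisense = FALSE) {
  ref_mat <- vapply(strsplit(ref$tag_sequence, ""), identity, character(21))
  gene_counts <- list()
  category <- character(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    v <- strsplit(entries$tag_sequence[i], "")[[1]]
    d <- colSums(ref_mat != v)
    best <- if (any(d == 0L)) which(d == 0L) else which(d == 1L)
    if (!length(best)) { category[i] <- "unmapped"; next }
    genes <- unique(ref$gene_id[best])
    if (length(genes) >= 2L) { category[i] <- "ambiguous"; next }
    strands <- ref$strand[best]
    category[i] <- if (any(strands == "sense")) "sense_unique" else "antisense_unique"
    if (category[i] == "sense_unique" || include_antisense)
      gene_counts[[genes]] <- (gene_counts[[genes]] %||% 0L) + entries$count[i]
  }
  list(counts = unlist(gene_counts), category = category)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# hypergeometric upper tail by exhaustive enumeration of all C(M, n) draws
oracle_hypergeom_enum <- function(k, K, n, M) {
  draws <- utils::combn(M, n)
  hits <- colSums(draws <= K) # the first K population items carry the term
  mean(hits >= k)
}

# membership-bitmask tabulation of three-set Venn region sizes
oracle_venn_sizes <- function(a, b, c_) {
  u <- unique(c(a, b, c_))
  code <- paste0(as.integer(u %in% a), as.integer(u %in% b), as.integer(u %in% c_))
  tab <- table(factor(code, levels = c("100", "010", "001", "110", "101", "011", "111")))
  stats::setNames(as.integer(tab), c("A", "B", "C", "AB", "AC", "BC", "ABC"))
}

# deterministic toy transcriptome with hand-placed CATG sites
toy_transcriptome <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    sequence = c(
      # one usable site at offset 3 (0-based), 17 nt after CATG
      "AAACATGTTTTTTTTTTTTTTTTTA",
      # two sites: offset 0 usable, offset 30 too close to the 3' end
      paste0("CATGAAAAAAAAAAAAAAAAACCCCCCCCC", "CATGAA"),
      # no CATG at all
      paste0(strrep("AGCT", 20))
    ),
    stringsAsFactors = FALSE
  )
}

expr_from_counts <- function(counts, library_size, library_id = "lib") {
  list(expression = data.frame(gene_id = names(counts),
                               count = as.integer(counts),
                               tpm = counts / library_size * 1e6,
                               stringsAsFactors = FALSE),
       library_size = library_size,
       report = list(library_id = library_id))
}
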