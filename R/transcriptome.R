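# Synthetic transcriptome generation.
#
# Transcripts stand in for assembled unigenes: one sequence per gene, plain
# A/C/G/T alphabet. CATG (the NlaIII recognition site) anchors every DGE tag,
# so the density of that motif is the controllable quantity: the background
# is i.i.d. uniform nucleotides scrubbed of incidental CATG occurrences, and
# motifs are then injected at a Poisson rate to hit the requested density.
# Because CATG has no self-overlap and no 4-window overlapping an injected
# motif can itself read CATG, the final motif count equals the injected count.

# positions (1-based) where v[p..p+3] == CATG
find_catg_positions <- function(v) {
  n <- length(v)
  if (n < 4L) return(integer(0))
  which(v[1:(n - 3L)] == "C" & v[2:(n - 2L)] == "A" &
        v[3:(n - 1L)] == "T" & v[4:n] == "G")
}

# mutate the A of every CATG until none remain
scrub_catg <- function(v) {
  repeat {
    hits <- find_catg_positions(v)
    if (length(hits) == 0L) return(v)
    v[hits + 1L] <- sample(c("C", "G", "T"), length(hits), replace = TRUE)
  }
}

# overwrite k non-overlapping 4-mers with CATG; returns modified vector
inject_catg <- function(v, k) {
  n <- length(v)
  if (k == 0L || n < 4L) return(v)
  starts <- sample.int(n - 3L)
  taken <- integer(0)
  for (p in starts) {
    if (length(taken) >= k) break
    if (all(abs(taken - p) >= 4L)) taken <- c(taken, p)
  }
  for (p in taken) v[p:(p + 3L)] <- c("C", "A", "T", "G")
  v
}

#' Generate a synthetic transcriptome
#'
#' Draws `n_genes` transcript sequences with geometric-like lengths (heavy
#' tailed, as real unigene length distributions are), truncated at a 60-nt
#' minimum, and with NlaIII CATG sites placed at a controllable density.
#' With `catg_density = 0` the emitted sequences contain no CATG at all.
#'
#' @param n_genes number of transcripts (>= 1).
#' @param mean_length target mean transcript length in nt (>= 60).
#' @param catg_density expected CATG sites per kb of transcript.
#' @param seed integer seed; the call is fully deterministic given it.
#' @param prefix gene identifier prefix.
#' @return data.frame with columns `gene_id`, `sequence`, `length`.
#' @export
generate_transcriptome <- function(n_genes, mean_length = 789, catg_density = 10,
                                   seed = 1L, prefix = "gene") {
  if (!is_count(n_genes) || n_genes < 1) stopf("'n_genes' must be a positive integer")
  assert_scalar_number(mean_length, "mean_length")
  if (mean_length < 60) stopf("'mean_length' must be >= 60 nt")
  assert_scalar_number(catg_density, "catg_density")
  if (catg_density < 0) stopf("'catg_density' must be >= 0")
  n_genes <- as.integer(n_genes)

  withr::with_seed(as.integer(seed), {
    lens <- 60L + stats::rgeom(n_genes, prob = 1 / (mean_length - 59))
    seqs <- character(n_genes)
    for (i in seq_len(n_genes)) {
      v <- sample(DNA_BASES, lens[i], replace = TRUE)
      v <- scrub_catg(v)
      k <- stats::rpois(1L, lens[i] * catg_density / 1000)
      v <- inject_catg(v, k)
      seqs[i] <- paste(v, collapse = "")
    }
    data.frame(
      gene_id = sprintf("%s%05d", prefix, seq_len(n_genes)),
      sequence = seqs,
      length = lens,
      stringsAsFactors = FALSE
    )
  })
}

# Coerce the accepted transcriptome representations (data.frame, named
# DNAStringSet, FASTA path) to the internal data.frame form.
as_transcriptome <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "sequence") %in% names(x)))
      stopf("transcriptome data.frame needs 'gene_id' and 'sequence' columns")
    out <- data.frame(gene_id = as.character(x$gene_id),
                      sequence = toupper(as.character(x$sequence)),
                      stringsAsFactors = FALSE)
  } else if (methods::is(x, "DNAStringSet")) {
    out <- data.frame(gene_id = names(x), sequence = as.character(x),
                      stringsAsFactors = FALSE)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    out <- data.frame(gene_id = sub("\\s.*$", "", names(ss)),
                      sequence = as.character(ss), stringsAsFactors = FALSE)
  } else {
    stopf("cannot interpret transcriptome input of class '%s'", class(x)[1L])
  }
  if (nrow(out) == 0L) stopf("transcriptome is empty")
  if (anyDuplicated(out$gene_id)) stopf("duplicate gene_id in transcriptome: %s",
                                        out$gene_id[duplicated(out$gene_id)][1L])
  out$length <- nchar(out$sequence)
  out
}

#' Write a transcriptome as FASTA
#'
#' @param transcripts data.frame from [generate_transcriptome()].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_transcriptome <- function(transcripts, path) {
  tx <- as_transcriptome(transcripts)
  ss <- Biostrings::DNAStringSet(stats::setNames(tx$sequence, tx$gene_id))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a transcriptome FASTA
#'
#' @param path FASTA file, one record per unigene.
#' @return data.frame with columns `gene_id`, `sequence`, `length`.
#' @export
read_transcriptome <- function(path) as_transcriptome(path)
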