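# Tag-to-gene mapping with exact-first precedence, 1-mismatch tolerance,
# ambiguous-tag discard and TPM normalization.

make_table <- function(tags, counts, library_size = sum(counts), id = "lib") {
  structure(list(library_id = id,
                 entries = data.frame(tag_sequence = tags, count = as.integer(counts),
                                      stringsAsFactors = FALSE),
                 library_size = as.integer(library_size)),
            class = "tag_count_table")
}

ref_db_from <- function(tags, genes, strand = "sense") {
  structure(list(
    tags = data.frame(tag_sequence = tags, gene_id = genes, position = 0L,
                      strand = strand, is_3prime_most = FALSE,
                      stringsAsFactors = FALSE),
    gene_ids = unique(genes), n_genes = length(unique(genes)),
    n_genes_with_sites = length(unique(genes)),
    n_reference_tags = length(tags), ambiguous_tags = character(0),
    n_skipped_n_sites = 0L), class = "ref_tag_db")
}

test_that("an exact unique match assigns the full tag count to its gene", {
  db <- ref_db_from("CATGAAAAAAAAAAAAAAAAA", "G")
  m <- map_tags(make_table("CATGAAAAAAAAAAAAAAAAA", 7), db)
  expect_equal(m$expression$count[m$expression$gene_id == "G"], 7L)
  expect_identical(m$assignments$category, "sense_unique")
})

test_that("a 1-mismatch tie between two genes is discarded as ambiguous", {
  db <- ref_db_from(c("CATGAAAAAAAAAAAAAAAAA", "CATGCAAAAAAAAAAAAAAAC"),
                    c("G1", "G2"))
  # query at distance 1 from both references, no exact match
  m <- map_tags(make_table("CATGCAAAAAAAAAAAAAAAA", 5), db)
  expect_identical(m$assignments$category, "ambiguous")
  expect_true(all(m$expression$count == 0L))
})

test_that("exact matches take precedence over closer-by-mismatch genes", {
  db <- ref_db_from(c("CATGAAAAAAAAAAAAAAAAA", "CATGAAAAAAAAAAAAAAAAC"),
                    c("A", "B"))
  m <- map_tags(make_table("CATGAAAAAAAAAAAAAAAAA", 3), db)
  expect_equal(m$expression$count[m$expression$gene_id == "A"], 3L)
  expect_equal(m$expression$count[m$expression$gene_id == "B"], 0L)
})

test_that("antisense-only hits are excluded from expression unless opted in", {
  db <- ref_db_from("CATGGGGGGGGGGGGGGGGGG", "G", strand = "antisense")
  tab <- make_table("CATGGGGGGGGGGGGGGGGGG", 4)
  m <- map_tags(tab, db)
  expect_identical(m$assignments$category, "antisense_unique")
  expect_equal(m$expression$count[m$expression$gene_id == "G"], 0L)
  m2 <- map_tags(tab, db, include_antisense = TRUE)
  expect_equal(m2$expression$count[m2$expression$gene_id == "G"], 4L)
})

test_that("malformed tags raise a format error naming the offending row", {
  db <- ref_db_from("CATGAAAAAAAAAAAAAAAAA", "G")
  expect_error(map_tags(make_table("AATGAAAAAAAAAAAAAAAAA", 1), db), "row 1")
  expect_error(map_tags(make_table("CATGAAAA", 1), db), "21-nt")
})

test_that("mapping equals the all-pairs Hamming oracle on random instances", {
  set.seed(101)
  for (rep in 1:12) {
    tx <- generate_transcriptome(12, 250, 12, seed = 200 + rep)
    db <- extract_reference_tags(tx)
    ref_pool <- unique(db$tags$tag_sequence)
    n_tags <- 60L
    pick <- sample(ref_pool, n_tags, replace = TRUE)
    # perturb a third of them by 0-2 substitutions anywhere in the extension
    for (i in sample(n_tags, 20L)) {
      v <- strsplit(pick[i], "")[[1]]
      for (p in sample(5:21, sample(0:2, 1))) v[p] <- sample(c("A","C","G","T"), 1)
      pick[i] <- paste(v, collapse = "")
    }
    tab_df <- as.data.frame(table(pick), stringsAsFactors = FALSE)
    tab <- make_table(tab_df$pick, tab_df$Freq)
    m <- map_tags(tab, db)
    o <- oracle_map_tags(tab$entries, db$tags)
    expect_identical(m$assignments$category, o$category)
    got <- m$expression$count[match(names(o$counts), m$expression$gene_id)]
    expect_equal(got, unname(o$counts))
    expect_equal(sum(m$expression$count),
                 sum(o$counts[names(o$counts) %in% m$expression$gene_id]))
  }
})

test_that("mismatch-0 assignments are a gene-wise subset of mismatch-1", {
  tx <- generate_transcriptome(20, 300, 10, seed = 31)
  truth <- make_truth(tx$gene_id, conditions = "t", seed = 32)
  lib <- simulate_tag_library(tx, truth, library_spec("t", 8000, 0.01, seed = 33))
  db <- extract_reference_tags(tx)
  m0 <- map_tags(lib, db, max_mismatch = 0L)
  m1 <- map_tags(lib, db, max_mismatch = 1L)
  expect_true(all(m0$expression$count <= m1$expression$count))
})

test_that("TPM normalization follows its definition", {
  expect_equal(normalize_tpm(c(A = 5, B = 5), 10), c(A = 5e5, B = 5e5))
  expect_equal(normalize_tpm(c(A = 0), 1e6), c(A = 0))
  expect_equal(normalize_tpm(3, 4810000L), 3 / 4810000 * 1e6)
  expect_error(normalize_tpm(c(1, 2), 0), "library_size")
  expect_error(normalize_tpm(-1, 10), "non-negative")
})

test_that("TPM sums to 1e6 * mapped/total and never exceeds 1e6", {
  tx <- generate_transcriptome(40, 350, 10, seed = 41)
  truth <- make_truth(tx$gene_id, conditions = "t", seed = 42)
  lib <- simulate_tag_library(tx, truth, library_spec("t", 20000, 0.01, seed = 43))
  db <- extract_reference_tags(tx)
  m <- map_tags(lib, db)
  expect_equal(sum(m$expression$tpm),
               1e6 * sum(m$expression$count) / lib$library_size,
               tolerance = 1e-9)
  expect_lte(sum(m$expression$tpm), 1e6 * (1 + 1e-9))
})

test_that("expression TSV round-trips counts, TPM and library size", {
  tx <- generate_transcriptome(15, 300, 10, seed = 51)
  truth <- make_truth(tx$gene_id, conditions = "t", seed = 52)
  lib <- simulate_tag_library(tx, truth, library_spec("t", 3000, 0, seed = 53))
  m <- map_tags(lib, extract_reference_tags(tx))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path)
  expect_equal(back$expression$count, m$expression$count)
  expect_equal(back$expression$tpm, m$expression$tpm, tolerance = 1e-12)
  expect_equal(back$library_size, lib$library_size)
})
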