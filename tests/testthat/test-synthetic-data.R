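# Forward simulator: transcriptome generation and tag library emission.

test_that("catg_density = 0 suppresses the motif entirely", {
  tx <- generate_transcriptome(n_genes = 25, mean_length = 100,
                               catg_density = 0, seed = 1)
  expect_false(any(grepl("CATG", tx$sequence, fixed = TRUE)))
  expect_true(all(tx$length >= 60))
  expect_false(anyDuplicated(tx$gene_id) > 0)
})

test_that("default CATG density leaves >= 90% of transcripts with a site", {
  tx <- generate_transcriptome(n_genes = 500, mean_length = 789,
                               catg_density = 10, seed = 7)
  has_site <- grepl("CATG", tx$sequence, fixed = TRUE)
  expect_gte(mean(has_site), 0.90)
})

test_that("transcriptome generation is deterministic and FASTA round-trips", {
  a <- generate_transcriptome(50, 300, 10, seed = 7)
  b <- generate_transcriptome(50, 300, 10, seed = 7)
  expect_identical(a, b)
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_transcriptome(a, fa1)
  write_transcriptome(b, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  back <- read_transcriptome(fa1)
  expect_identical(back$sequence, a$sequence)
})

test_that("parameter errors are raised for degenerate generator input", {
  expect_error(generate_transcriptome(0, 100, 5), "n_genes")
  expect_error(generate_transcriptome(5, 59, 5), "mean_length")
})

test_that("a single error-free gene yields one distinct tag at full depth", {
  tx <- toy_transcriptome()[1, , drop = FALSE]
  truth <- data.frame(gene_id = "g1", baseline = 1, novel_abundance = 0,
                      `fold_change.t` = 1, `direction.t` = "null",
                      check.names = FALSE, stringsAsFactors = FALSE)
  lib <- simulate_tag_library(tx, truth, library_spec("control", 10, 0, seed = 3))
  expect_equal(nrow(lib$entries), 1L)
  expect_equal(lib$entries$count, 10L)
  expect_identical(lib$entries$tag_sequence, "CATGTTTTTTTTTTTTTTTTT")
  expect_equal(lib$library_size, 10L)
})

test_that("sampling respects abundance weights within binomial error", {
  tx <- generate_transcriptome(2, 200, 15, seed = 11)
  # ensure both transcripts carry a usable site
  expect_true(all(vapply(tx$sequence, function(s)
    grepl("CATG", substr(s, 1, nchar(s) - 20), fixed = TRUE), TRUE)))
  truth <- data.frame(gene_id = tx$gene_id, baseline = c(1, 3),
                      novel_abundance = 0,
                      `fold_change.t` = 1, `direction.t` = "null",
                      check.names = FALSE, stringsAsFactors = FALSE)
  depth <- 100000L
  lib <- simulate_tag_library(tx, truth, library_spec("control", depth, 0, seed = 5))
  p <- 3 / 4
  se <- sqrt(depth * p * (1 - p))
  expect_lt(abs(lib$gene_counts[tx$gene_id[2]] - depth * p), 3 * se)
  expect_equal(sum(lib$gene_counts), depth)
})

test_that("per-base substitution error corrupts the expected tag fraction", {
  tx <- generate_transcriptome(30, 400, 12, seed = 21)
  truth <- data.frame(gene_id = tx$gene_id, baseline = 1, novel_abundance = 0,
                      `fold_change.t` = 1, `direction.t` = "null",
                      check.names = FALSE, stringsAsFactors = FALSE)
  depth <- 40000L
  err <- simulate_tag_library(tx, truth, library_spec("t", depth, 0.01, seed = 9))
  clean <- simulate_tag_library(tx, truth, library_spec("t", depth, 0, seed = 9))
  # identical seed => identical multinomial gene counts before the error layer
  expect_identical(err$gene_counts, clean$gene_counts)
  source_tags <- clean$entries$tag_sequence
  intact <- sum(err$entries$count[err$entries$tag_sequence %in% source_tags])
  frac_changed <- 1 - intact / err$n_emitted
  p_expected <- 1 - 0.99^21
  se <- sqrt(p_expected * (1 - p_expected) / depth)
  # small upward bias possible: an errored tag can coincide with another
  # source tag; allow 4 binomial SEs plus that collision slack
  expect_lt(abs(frac_changed - p_expected), 4 * se + 0.005)
  # emission-count invariant: clean entries + dirty reads == depth
  expect_equal(sum(err$entries$count) + err$n_dirty, err$n_emitted)
  expect_equal(err$n_emitted, depth)
})

test_that("a 3'-proximal site is skipped in favour of the next one upstream", {
  tx <- toy_transcriptome()[2, , drop = FALSE] # 3'-most CATG has < 17 nt after
  truth <- data.frame(gene_id = "g2", baseline = 1, novel_abundance = 0,
                      `fold_change.t` = 1, `direction.t` = "null",
                      check.names = FALSE, stringsAsFactors = FALSE)
  lib <- simulate_tag_library(tx, truth, library_spec("t", 5, 0, seed = 1))
  expect_identical(lib$entries$tag_sequence,
                   substr(tx$sequence, 1, 21)) # falls back to the 5' site
})

test_that("genes without usable sites are unobservable and logged", {
  tx <- toy_transcriptome()
  truth <- data.frame(gene_id = tx$gene_id, baseline = 1, novel_abundance = 0,
                      `fold_change.t` = 1, `direction.t` = "null",
                      check.names = FALSE, stringsAsFactors = FALSE)
  lib <- simulate_tag_library(tx, truth, library_spec("t", 1000, 0, seed = 2))
  expect_true("g3" %in% lib$unobservable_genes)
  expect_equal(unname(lib$gene_counts["g3"]), 0L)
})

test_that("identical inputs yield identical libraries; TSV round-trips", {
  tx <- generate_transcriptome(40, 300, 10, seed = 3)
  truth <- make_truth(tx$gene_id, conditions = "12h", seed = 4)
  spec <- library_spec("12h", 5000, 0.005, seed = 6)
  a <- simulate_tag_library(tx, truth, spec)
  b <- simulate_tag_library(tx, truth, spec)
  expect_identical(a$entries, b$entries)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tag_table(a, path)
  back <- read_tag_table(path)
  expect_identical(back$entries, a$entries)
  expect_equal(back$library_size, a$library_size)
})

test_that("error-free tags are all present in the reference tag database", {
  tx <- generate_transcriptome(60, 400, 10, seed = 8)
  truth <- make_truth(tx$gene_id, conditions = "12h", seed = 9)
  lib <- simulate_tag_library(tx, truth, library_spec("12h", 20000, 0, seed = 10))
  db <- extract_reference_tags(tx)
  expect_true(all(lib$entries$tag_sequence %in% db$tags$tag_sequence))
})

test_that("truth weights encode fold changes and novel-gene switching", {
  truth <- make_truth(paste0("g", 1:2000), conditions = c("12h", "24h", "48h"),
                      frac_up = 0.1, frac_down = 0.05, frac_novel = 0.02,
                      seed = 12)
  w0 <- truth_weights(truth, "control")
  w1 <- truth_weights(truth, "12h")
  novel_on <- truth$`direction.12h` == "novel"
  expect_true(all(w0[novel_on] == 0))
  expect_true(all(w1[novel_on] > 0))
  up <- truth$`direction.12h` == "up"
  expect_true(all(w1[up] / w0[up] >= 2)) # log2fc_range starts at 1
  dn <- truth$`direction.12h` == "down"
  expect_true(all(w1[dn] / w0[dn] <= 0.5))
  null_g <- truth$`direction.12h` == "null" & truth$baseline > 0
  expect_equal(w1[null_g], w0[null_g])
})
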