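# OBO parsing, nearest-slim mapping and hypergeometric enrichment.

chain_graph <- function() {
  # a -> b -> c (is_a chains point child -> parent)
  ontology_graph(data.frame(id = c("a", "b", "c"),
                            name = c("a", "b", "c"),
                            namespace = "biological_process",
                            stringsAsFactors = FALSE),
                 list(a = "b", b = "c"))
}

diamond_graph <- function() {
  # a -> b -> d and a -> c -> d
  ontology_graph(data.frame(id = c("a", "b", "c", "d"),
                            name = c("a", "b", "c", "d"),
                            namespace = "biological_process",
                            stringsAsFactors = FALSE),
                 list(a = c("b", "c"), b = "d", c = "d"))
}

test_that("a slim term maps to itself and shields its ancestors", {
  g <- chain_graph()
  m <- map_to_slim(list(g1 = "b"), g, slim_terms = c("b", "c"))
  expect_identical(m$g1, "b")
  # annotated below the slim chain: nearest slim only
  m2 <- map_to_slim(list(g1 = "a"), g, slim_terms = c("b", "c"))
  expect_identical(m2$g1, "b")
})

test_that("distinct paths each keep their own nearest slim term", {
  g <- diamond_graph()
  m <- map_to_slim(list(g1 = "a"), g, slim_terms = c("b", "c"))
  expect_setequal(m$g1, c("b", "c"))
  # with the apex also slim, b and c still shield it
  m2 <- map_to_slim(list(g1 = "a"), g, slim_terms = c("b", "c", "d"))
  expect_setequal(m2$g1, c("b", "c"))
})

test_that("genes with no slim ancestor map to nothing and are logged", {
  g <- chain_graph()
  m <- map_to_slim(list(g1 = "c"), g, slim_terms = "b") # c is above b
  expect_length(m$g1, 0)
  expect_identical(attr(m, "unmapped_genes"), "g1")
  expect_warning(map_to_slim(list(g1 = c("a", "zzz")), g, slim_terms = "b"),
                 "unknown")
})

test_that("every assigned slim term is reachable from an annotated term", {
  onto <- make_random_ontology(seed = 5)
  g <- onto$graph
  ancestors <- function(t) {
    out <- character(0); frontier <- t
    while (length(frontier)) {
      out <- union(out, frontier)
      frontier <- unique(unlist(g$parents[frontier], use.names = FALSE))
    }
    out
  }
  gene2go <- simulate_annotations(paste0("g", 1:40), g, seed = 6)
  m <- map_to_slim(gene2go, g, onto$slim_terms)
  byg <- split(gene2go$term_id, gene2go$gene_id)
  for (gene in names(m)) {
    reach <- unique(unlist(lapply(byg[[gene]], ancestors)))
    expect_true(all(m[[gene]] %in% reach))
  }
})

test_that("cycles and unknown edge endpoints are format errors", {
  terms <- data.frame(id = c("a", "b"), name = c("a", "b"),
                      namespace = "biological_process", stringsAsFactors = FALSE)
  expect_error(ontology_graph(terms, list(a = "b", b = "a")), "cycle")
  expect_error(ontology_graph(terms, list(a = "nope")), "not a declared term")
})

test_that("the minimal OBO parser reads terms, is_a links and skips obsolete", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
           "[Term]", "id: GO:0000002", "name: child",
           "namespace: biological_process", "is_a: GO:0000001 ! root", "",
           "[Term]", "id: GO:0000003", "name: dead", "is_obsolete: true", "",
           "[Typedef]", "id: part_of")
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, path)
  g <- read_obo(path)
  expect_setequal(g$terms$id, c("GO:0000001", "GO:0000002"))
  expect_identical(g$parents$`GO:0000002`, "GO:0000001")
  expect_identical(map_to_slim(list(x = "GO:0000002"), g, "GO:0000001")$x,
                   "GO:0000001")
})

test_that("hypergeometric p matches the closed-form worked example", {
  # M=10, K=5, n=4, k=4 -> C(5,4)C(5,0)/C(10,4) = 5/210
  g2s <- c(lapply(paste0("in", 1:5), function(i) "T"),
           lapply(paste0("out", 1:5), function(i) character(0)))
  names(g2s) <- c(paste0("in", 1:5), paste0("out", 1:5))
  res <- hypergeom_enrich(paste0("in", 1:4), names(g2s), g2s)
  expect_equal(res$p_value[res$term_id == "T"], 5 / 210, tolerance = 1e-12)
  expect_equal(res$k[res$term_id == "T"], 4L)
  expect_equal(res$percentage[res$term_id == "T"], 100)
})

test_that("k = 0 and study = population are degenerate with p = 1", {
  g2s <- list(a = "T", b = "T", c = character(0), d = "U")
  res0 <- hypergeom_enrich(c("c", "d"), names(g2s), g2s)
  expect_equal(res0$p_value[res0$term_id == "T"], 1)
  res_all <- hypergeom_enrich(names(g2s), names(g2s), g2s)
  expect_true(all(res_all$p_value == 1))
  expect_true(all(res_all$k == res_all$K))
  expect_error(hypergeom_enrich(c("a", "zzz"), names(g2s), g2s), "subset")
})

test_that("enrichment p equals exhaustive draw enumeration for M <= 12", {
  set.seed(71)
  for (rep in 1:20) {
    M <- sample(4:12, 1)
    K <- sample(1:M, 1)
    n <- sample(1:M, 1)
    genes <- paste0("g", seq_len(M))
    g2s <- stats::setNames(c(lapply(seq_len(K), function(i) "T"),
                             lapply(seq_len(M - K), function(i) character(0))),
                           genes)
    study <- sample(genes, n)
    res <- hypergeom_enrich(study, genes, g2s)
    k <- sum(study %in% genes[seq_len(K)])
    expect_equal(res$p_value[res$term_id == "T"],
                 oracle_hypergeom_enum(k, K, n, M), tolerance = 1e-12)
    # cross-check against the standard distribution function
    expect_equal(res$p_value[res$term_id == "T"],
                 phyper(k - 1, K, M - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("slim TSV/list readers and BH option behave", {
  onto <- make_random_ontology(seed = 9)
  slim_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# slim vocabulary", onto$slim_terms), slim_path)
  expect_identical(read_slim(slim_path), onto$slim_terms)
  gene2go <- simulate_annotations(paste0("g", 1:30), onto$graph, seed = 10)
  g2s <- map_to_slim(gene2go, onto$graph, onto$slim_terms)
  res <- hypergeom_enrich(paste0("g", 1:10), paste0("g", 1:30), g2s,
                          graph = onto$graph, adjust = TRUE)
  expect_true(all(res$fdr >= res$p_value))
  expect_true(all(c("term_name", "namespace") %in% names(res)))
  expect_true(all(res$k <= pmin(res$n, res$K)))
})
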