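# GO-slim mapping and hypergeometric enrichment.
#
# The ontology is consumed as a minimal OBO subset — [Term] stanzas with
# id, name, namespace and is_a only; part_of and other relationship types
# are ignored. Annotations are lifted to the slim vocabulary by the
# nearest-slim-ancestor-per-path rule used by the classic map2slim tool:
# an annotated term maps to every slim term s (ancestor-or-self) for which
# some is_a path from the term to s carries no other slim term strictly
# between them. Over-representation of a slim term in a study set is then
# the hypergeometric upper tail against a population.

#' Construct an ontology graph
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents named list: term id -> character vector of is_a parents.
#' @return an `ontology_graph`; errors if the edges contain a cycle or an
#'   endpoint missing from `terms`.
#' @export
ontology_graph <- function(terms, parents) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id)) stopf("duplicate term id in ontology")
  parents <- parents[intersect(names(parents), terms$id)]
  all_parents <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(all_parents, terms$id)
  if (length(unknown)) stopf("is_a parent '%s' is not a declared term", unknown[1L])

  # Kahn topological sort; leftovers mean a cycle
  ids <- terms$id
  out_deg <- stats::setNames(lengths(parents)[match(ids, names(parents))], ids)
  out_deg[is.na(out_deg)] <- 0L
  children <- split(rep(names(parents), lengths(parents)),
                    unlist(parents, use.names = FALSE))
  queue <- ids[out_deg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      out_deg[ch] <- out_deg[ch] - 1L
      if (out_deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) stopf("cycle detected in ontology is_a graph")

  structure(list(terms = terms, parents = parents), class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("Ontology graph: %d terms (%s), %d is_a edges\n",
              nrow(x$terms),
              paste(sprintf("%s: %d", names(table(x$terms$namespace)),
                            table(x$terms$namespace)), collapse = ", "),
              sum(lengths(x$parents))))
  invisible(x)
}

#' Parse a minimal OBO file
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `namespace` and `is_a`
#' (trailing `! comment` text stripped). Obsolete terms and `[Typedef]`
#' stanzas are skipped; all other relationship types are ignored.
#'
#' @param path OBO file.
#' @return an `ontology_graph`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) stopf("no stanzas found in %s", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  for (s in seq_along(stanza_starts)) {
    block <- lines[bounds[s]:(bounds[s + 1L] - 1L)]
    if (!identical(block[1L], "[Term]")) next
    field <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      sub("\\s*!.*$", "", v)
    }
    if (length(field("is_obsolete")) && any(field("is_obsolete") == "true")) next
    id <- field("id")
    if (length(id) != 1L) stopf("[Term] stanza without a single id in %s", path)
    ids <- c(ids, id)
    nms <- c(nms, if (length(field("name"))) field("name")[1L] else id)
    nss <- c(nss, if (length(field("namespace"))) field("namespace")[1L]
                  else "biological_process")
    isa <- field("is_a")
    if (length(isa)) parents[[id]] <- isa
  }
  ontology_graph(data.frame(id = ids, name = nms, namespace = nss,
                            stringsAsFactors = FALSE), parents)
}

#' Map gene annotations onto a slim vocabulary
#'
#' Implements the nearest-slim-ancestor-or-self rule per is_a path: a term
#' that is itself in the slim maps to itself only; otherwise it maps to
#' the union of its parents' slim images, so a slim term shields its own
#' ancestors along that path while distinct paths keep their own nearest
#' slim terms.
#'
#' @param gene2go named list (gene -> character vector of annotated term
#'   ids) or data.frame with columns `gene_id`, `term_id`.
#' @param graph an `ontology_graph`.
#' @param slim_terms character vector of slim term ids (must be in `graph`).
#' @return named list gene -> sorted slim term ids; genes whose
#'   annotations reach no slim term map to `character(0)` and are listed
#'   in the `unmapped_genes` attribute.
#' @export
map_to_slim <- function(gene2go, graph, slim_terms) {
  if (is.data.frame(gene2go))
    gene2go <- split(as.character(gene2go$term_id), gene2go$gene_id)
  if (!inherits(graph, "ontology_graph")) stopf("'graph' must be an ontology_graph")
  unknown_slim <- setdiff(slim_terms, graph$terms$id)
  if (length(unknown_slim)) stopf("slim term '%s' not in ontology", unknown_slim[1L])
  slim <- unique(slim_terms)

  memo <- new.env(parent = emptyenv())
  nearest <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    res <- if (t %in% slim) t
           else unique(unlist(lapply(graph$parents[[t]], nearest), use.names = FALSE))
    if (is.null(res)) res <- character(0)
    memo[[t]] <- res
    res
  }

  known <- graph$terms$id
  out <- lapply(gene2go, function(terms) {
    bad <- setdiff(terms, known)
    if (length(bad)) {
      warning(sprintf("skipping %d unknown term(s), e.g. '%s'",
                      length(bad), bad[1L]), call. = FALSE)
      terms <- intersect(terms, known)
    }
    sort(unique(unlist(lapply(terms, nearest), use.names = FALSE)))
  })
  attr(out, "unmapped_genes") <- names(out)[lengths(out) == 0L]
  out
}

# hypergeometric upper tail P(X >= k), X ~ Hypergeom(M, K, n), summed in
# log space term by term
hypergeom_upper <- function(k, K, n, M) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  lt <- lchoose(K, i) + lchoose(M - K, n - i) - lchoose(M, n)
  exp(logsumexp(lt))
}

#' Hypergeometric enrichment of slim terms in a study gene set
#'
#' For each slim term with at least one population annotation: k = study
#' genes carrying the term, K = population genes carrying it, n = study
#' size, M = population size; p = P(X >= k) for X ~ Hypergeometric(M, K, n).
#' No multiple-testing adjustment is applied by default; `adjust = TRUE`
#' appends a Benjamini-Hochberg column.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of population gene ids; by
#'   convention all genes with at least one slim mapping, but any
#'   superset of the study works.
#' @param gene2slim named list gene -> slim term ids (see [map_to_slim()]).
#' @param graph optional `ontology_graph` used to attach term names and
#'   namespaces.
#' @param adjust append a BH-adjusted column.
#' @return data.frame `term_id`, `term_name`, `namespace`, `k`, `n`, `K`,
#'   `M`, `percentage` (100 k / n), `p_value`, sorted by p.
#' @export
hypergeom_enrich <- function(study, population, gene2slim, graph = NULL,
                             adjust = FALSE) {
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (!length(population)) stopf("population is empty")
  if (!all(study %in% population)) stopf("study set must be a subset of the population")

  g2s <- gene2slim[intersect(names(gene2slim), population)]
  terms <- sort(unique(unlist(g2s, use.names = FALSE)))
  if (!length(terms)) stopf("no slim annotations in the population")
  M <- length(population)
  n <- length(study)
  pop_hits <- table(factor(unlist(g2s, use.names = FALSE), levels = terms))
  study_terms <- unlist(g2s[intersect(names(g2s), study)], use.names = FALSE)
  study_hits <- table(factor(study_terms, levels = terms))

  res <- data.frame(term_id = terms,
                    k = as.integer(study_hits), n = n,
                    K = as.integer(pop_hits), M = M,
                    stringsAsFactors = FALSE)
  res$percentage <- 100 * res$k / res$n
  res$p_value <- mapply(hypergeom_upper, res$k, res$K,
                        MoreArgs = list(n = n, M = M))
  if (!is.null(graph)) {
    m <- match(res$term_id, graph$terms$id)
    res$term_name <- graph$terms$name[m]
    res$namespace <- graph$terms$namespace[m]
    res <- res[, c("term_id", "term_name", "namespace", "k", "n", "K", "M",
                   "percentage", "p_value")]
  }
  if (adjust) res$fdr <- adjust_fdr(res$p_value)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Generate a small random ontology for simulation
#'
#' Builds, per namespace, a layered is_a DAG: one root, a slim layer, and
#' a leaf layer in which each leaf has 1-2 parents drawn from the slim
#' layer. Leaves are what genes get annotated to; the slim layer is the
#' natural slim vocabulary for it.
#'
#' @param n_slim,n_leaf terms per namespace in the slim and leaf layers.
#' @param namespaces namespace labels.
#' @param seed integer seed.
#' @return list with `graph` (an `ontology_graph`) and `slim_terms`.
#' @export
make_random_ontology <- function(n_slim = 6L, n_leaf = 30L,
                                 namespaces = c("biological_process",
                                                "molecular_function",
                                                "cellular_component"),
                                 seed = 1L) {
  withr::with_seed(as.integer(seed), {
    ids <- character(0); nms <- character(0); nss <- character(0)
    parents <- list()
    slim_all <- character(0)
    for (ns in namespaces) {
      tag <- toupper(substr(ns, 1, 2))
      root <- sprintf("GO:%s0000", tag)
      slim <- sprintf("GO:%s1%03d", tag, seq_len(n_slim))
      leaf <- sprintf("GO:%s2%03d", tag, seq_len(n_leaf))
      ids <- c(ids, root, slim, leaf)
      nms <- c(nms, paste(ns, "root"), paste0(ns, " slim ", seq_len(n_slim)),
               paste0(ns, " leaf ", seq_len(n_leaf)))
      nss <- c(nss, rep(ns, 1L + n_slim + n_leaf))
      for (s in slim) parents[[s]] <- root
      for (l in leaf)
        parents[[l]] <- sample(slim, sample(1:2, 1L))
      slim_all <- c(slim_all, slim)
    }
    list(graph = ontology_graph(
           data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE), parents),
         slim_terms = slim_all)
  })
}

#' Randomly annotate genes with ontology leaf terms
#'
#' @param gene_ids genes to annotate.
#' @param graph an `ontology_graph` (typically from
#'   [make_random_ontology()]).
#' @param mean_terms mean annotations per gene (Poisson, min 1).
#' @param seed integer seed.
#' @return data.frame `gene_id`, `term_id`.
#' @export
simulate_annotations <- function(gene_ids, graph, mean_terms = 3, seed = 1L) {
  leaves <- setdiff(graph$terms$id, unlist(graph$parents, use.names = FALSE))
  withr::with_seed(as.integer(seed), {
    n_terms <- pmin(pmax(1L, stats::rpois(length(gene_ids), mean_terms)),
                    length(leaves))
    data.frame(
      gene_id = rep(gene_ids, n_terms),
      term_id = unlist(lapply(n_terms, function(k) sample(leaves, k))),
      stringsAsFactors = FALSE
    )
  })
}

#' Read a gene-to-GO annotation TSV (columns `gene_id`, `term_id`)
#'
#' @param path TSV path.
#' @return data.frame `gene_id`, `term_id`.
#' @export
read_gene2go <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "term_id")
  df
}

#' Read a slim term list (one term id per line, `#` comments allowed)
#'
#' @param path text file.
#' @return character vector of term ids.
#' @export
read_slim <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
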