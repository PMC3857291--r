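# End-to-end pipeline on synthetic data: simulate a transcriptome and four
# tag libraries with known truth, build the reference tag database, map
# each library, test each treatment against the control, partition the DE
# lists across the time course, detect novel genes, and run GO-slim
# enrichment on the DE union. Deterministic given the config seed; every
# stage failure is re-raised with the stage name attached, and no record
# category is dropped silently — unobservable genes, ambiguous tags and
# unmapped tags are all tallied in the report.

#' Pipeline configuration
#'
#' Defaults describe the emulated study design scaled to desk size: one
#' control plus three cold-treatment libraries (12, 24, 48 h), one library
#' per condition, tag depths that scale down the multi-million-tag
#' originals, and the published significance thresholds (FDR <= 0.001 with
#' at least a 2-fold TPM change; sub-2-fold "difference" tier at
#' p <= 0.01).
#'
#' @param n_genes transcripts in the synthetic transcriptome.
#' @param mean_length mean transcript length (nt).
#' @param catg_density expected CATG sites per kb.
#' @param conditions treatment labels, in time order.
#' @param control control condition label.
#' @param depth clean-tag library depth per condition.
#' @param error_rate per-base substitution error rate.
#' @param frac_up,frac_down,frac_novel truth class fractions.
#' @param log2fc_range |log2 fold change| range for affected genes.
#' @param fdr_max,p_max,min_log2,floor_tpm DE thresholds (see [de_test()]).
#' @param min_count novel-gene minimum treatment count.
#' @param max_mismatch tag-mapping mismatch budget (0 or 1).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory; when set, every intermediate file
#'   and the report are written there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_genes = 500L, mean_length = 789, catg_density = 10,
                            conditions = c("12h", "24h", "48h"),
                            control = "control",
                            depth = 1e5, error_rate = 0.001,
                            frac_up = 0.10, frac_down = 0.05, frac_novel = 0.01,
                            log2fc_range = c(1, 3),
                            fdr_max = 0.001, p_max = 0.01, min_log2 = 1,
                            floor_tpm = 0.001, min_count = 1L,
                            max_mismatch = 1L, seed = 42L, out_dir = NULL) {
  if (control %in% conditions) stopf("'control' must not appear among 'conditions'")
  if (length(conditions) != 3L) stopf("the time-course pipeline expects exactly 3 treatments")
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full synthetic DGE pipeline
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list: per-stage record counts, mapping
#'   fractions, per-comparison DE tallies, Venn region sizes, novel-gene
#'   counts, enrichment summaries, and truth-recovery metrics
#'   (sensitivity, precision, log2-ratio accuracy) per comparison.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("'config' must come from pipeline_config()")
  cf <- config
  out <- cf$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  save <- function(fun, obj, file, ...) {
    if (!is.null(out)) fun(obj, file.path(out, file), ...)
  }

  # -- simulate ---------------------------------------------------------
  tx <- run_stage("simulate", generate_transcriptome(
    cf$n_genes, cf$mean_length, cf$catg_density, seed = derive_seed(cf$seed, 1L)))
  truth <- run_stage("simulate", make_truth(
    tx$gene_id, cf$conditions, cf$frac_up, cf$frac_down, cf$frac_novel,
    cf$log2fc_range, seed = derive_seed(cf$seed, 2L)))
  save(write_transcriptome, tx, "transcriptome.fa")
  save(write_truth, truth, "truth.tsv")

  all_conditions <- c(cf$control, cf$conditions)
  libs <- lapply(seq_along(all_conditions), function(i) {
    cid <- all_conditions[i]
    run_stage(paste0("simulate:", cid), simulate_tag_library(
      tx, truth,
      library_spec(cid, cf$depth, cf$error_rate, derive_seed(cf$seed, 10L + i)),
      control_id = cf$control))
  })
  names(libs) <- all_conditions
  for (cid in all_conditions)
    save(write_tag_table, libs[[cid]], sprintf("tags_%s.tsv", cid))

  # -- reference --------------------------------------------------------
  db <- run_stage("build_ref", extract_reference_tags(tx))
  save(write_refdb, db, "refdb.tsv")

  # -- mapping ----------------------------------------------------------
  maps <- lapply(libs, function(l)
    run_stage(paste0("map:", l$library_id),
              map_tags(l, db, max_mismatch = cf$max_mismatch)))
  for (cid in all_conditions)
    save(write_expression, maps[[cid]], sprintf("expr_%s.tsv", cid))

  # -- differential expression ------------------------------------------
  de <- lapply(cf$conditions, function(cid)
    run_stage(paste0("de:", cid), de_test(
      maps[[cf$control]], maps[[cid]],
      fdr_max = cf$fdr_max, p_max = cf$p_max,
      min_log2 = cf$min_log2, floor_tpm = cf$floor_tpm)))
  names(de) <- cf$conditions
  for (cid in cf$conditions)
    save(write_de, de[[cid]], sprintf("de_%s.tsv", cid))

  # -- time-course sets and novel genes ---------------------------------
  sets <- run_stage("timecourse", timecourse_sets(de))
  novel <- lapply(cf$conditions, function(cid)
    run_stage("novel", detect_novel(maps[[cf$control]], maps[[cid]],
                                    min_count = cf$min_count)))
  names(novel) <- cf$conditions
  novel_venn <- run_stage("novel", venn_partition(
    novel[[1L]]$gene_id, novel[[2L]]$gene_id, novel[[3L]]$gene_id, cf$conditions))
  if (!is.null(out)) {
    write_venn(sets$all, file.path(out, "venn_all.json"))
    write_venn(sets$up, file.path(out, "venn_up.json"))
    write_venn(sets$down, file.path(out, "venn_down.json"))
    write_venn(novel_venn, file.path(out, "venn_novel.json"))
    for (cid in cf$conditions)
      utils::write.table(novel[[cid]], file.path(out, sprintf("novel_%s.tsv", cid)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- enrichment -------------------------------------------------------
  onto <- run_stage("enrich", make_random_ontology(seed = derive_seed(cf$seed, 3L)))
  gene2go <- run_stage("enrich", simulate_annotations(
    tx$gene_id, onto$graph, seed = derive_seed(cf$seed, 4L)))
  gene2slim <- run_stage("enrich", map_to_slim(gene2go, onto$graph, onto$slim_terms))
  de_union <- unique(unlist(lapply(de, function(d)
    d$gene_id[d$tier == "significant"]), use.names = FALSE))
  population <- names(gene2slim)[lengths(gene2slim) > 0L]
  enrich <- run_stage("enrich", hypergeom_enrich(
    intersect(de_union, population), population, gene2slim, onto$graph))
  if (!is.null(out))
    utils::write.table(enrich, file.path(out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # -- truth recovery ---------------------------------------------------
  recovery <- lapply(cf$conditions, function(cid) {
    dir_true <- truth[[paste0("direction.", cid)]]
    fc_true <- truth[[paste0("fold_change.", cid)]]
    true_de <- truth$gene_id[dir_true %in% c("up", "down")]
    d <- de[[cid]]
    called <- d$gene_id[d$tier == "significant"]
    tp <- intersect(called, true_de)
    m <- match(tp, d$gene_id)
    l2_obs <- d$log2_ratio[m]
    l2_true <- log2(fc_true[match(tp, truth$gene_id)])
    list(condition = cid,
         n_true_de = length(true_de),
         n_called = length(called),
         sensitivity = if (length(true_de)) length(tp) / length(true_de) else NA,
         precision = if (length(called)) length(tp) / length(called) else NA,
         log2_within_0.5 = if (length(tp)) mean(abs(l2_obs - l2_true) <= 0.5) else NA)
  })
  names(recovery) <- cf$conditions

  report <- list(
    config = cf[setdiff(names(cf), "out_dir")],
    simulate = list(n_genes = nrow(tx),
                    n_unobservable = length(libs[[cf$control]]$unobservable_genes),
                    depth = cf$depth),
    reference = list(n_genes = db$n_genes,
                     n_genes_with_sites = db$n_genes_with_sites,
                     n_reference_tags = db$n_reference_tags,
                     n_ambiguous_tag_sequences = length(db$ambiguous_tags)),
    mapping = lapply(maps, function(m) m$report),
    de = lapply(de, function(d) list(
      n_significant = sum(d$tier == "significant"),
      n_up = sum(d$tier == "significant" & d$direction == "up"),
      n_down = sum(d$tier == "significant" & d$direction == "down"),
      n_difference = sum(d$tier == "difference"))),
    timecourse = list(counts = sets$counts,
                      venn_all = as.list(sets$all$sizes),
                      venn_up = as.list(sets$up$sizes),
                      venn_down = as.list(sets$down$sizes),
                      n_de_union = sets$n_de_union,
                      n_up_union = sets$n_up_union,
                      n_down_union = sets$n_down_union),
    novel = list(counts = stats::setNames(vapply(novel, nrow, 0L), cf$conditions),
                 venn = as.list(novel_venn$sizes)),
    enrichment = list(n_terms = nrow(enrich),
                      n_population = length(population),
                      top_terms = utils::head(enrich$term_id, 5L)),
    truth_recovery = recovery
  )
  # cross-file consistency: report tallies must equal the DE table contents
  stopifnot(vapply(cf$conditions, function(cid)
    report$de[[cid]]$n_significant == sum(de[[cid]]$tier == "significant"), TRUE))

  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    jsonlite::write_json(cf[setdiff(names(cf), "out_dir")],
                         file.path(out, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(format_run_report(report), file.path(out, "report.txt"))
  }
  structure(c(report, list(results = list(
    transcriptome = tx, truth = truth, refdb = db, libraries = libs,
    mappings = maps, de = de, sets = sets, novel = novel,
    novel_venn = novel_venn, enrichment = enrich))),
    class = "run_report")
}

format_run_report <- function(report) {
  c(sprintf("DGE pipeline report (seed %d)", report$config$seed),
    sprintf("transcriptome: %d genes; reference: %d with CATG sites, %d tags",
            report$simulate$n_genes, report$reference$n_genes_with_sites,
            report$reference$n_reference_tags),
    vapply(names(report$mapping), function(cid) {
      r <- report$mapping[[cid]]
      sprintf("mapping %-8s %6d distinct tags, mapped %.2f%% distinct / %.2f%% copies",
              cid, r$n_distinct_tags, 100 * r$mapped_distinct_fraction,
              100 * r$mapped_copy_fraction)
    }, ""),
    vapply(names(report$de), function(cid) {
      d <- report$de[[cid]]
      sprintf("DE %-8s %4d significant (%d up / %d down), %d difference-tier",
              cid, d$n_significant, d$n_up, d$n_down, d$n_difference)
    }, ""),
    sprintf("DE union: %d genes (%d up, %d down); common to all: %d",
            report$timecourse$n_de_union, report$timecourse$n_up_union,
            report$timecourse$n_down_union, report$timecourse$venn_all$ABC),
    sprintf("novel genes: %s",
            paste(sprintf("%s=%d", names(report$novel$counts),
                          report$novel$counts), collapse = ", ")),
    vapply(names(report$truth_recovery), function(cid) {
      r <- report$truth_recovery[[cid]]
      sprintf("recovery %-8s sensitivity %.3f, precision %.3f, |dlog2|<=0.5: %.3f",
              cid, r$sensitivity, r$precision, r$log2_within_0.5)
    }, ""))
}

#' @export
print.run_report <- function(x, ...) {
  writeLines(format_run_report(x))
  invisible(x)
}
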