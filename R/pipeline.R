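#' Run the whole signature-extraction pipeline
#'
#' Orchestrates the stages in order: sample filtering (sex, tumor/normal),
#' CPM expression filter, annotation filter, upper-quartile/length
#' normalization with log2 transform, pooled tumor-vs-normal log
#' fold-change pre-filter, PCA-based unsupervised feature extraction with
#' the dual correlation thresholds, then (optionally) gene-set enrichment
#' and interaction-network construction around the signature genes. All
#' stages are deterministic: re-running on identical inputs reproduces all
#' outputs exactly.
#'
#' The enrichment universe is the assayable transcriptome — the genes
#' surviving the annotation filter — not the union of the gene sets.
#' When fewer than two genes survive the fold-change pre-filter, the
#' signature set is empty and the downstream stages are skipped.
#'
#' @param counts a [count_matrix] of raw counts (all cohorts merged; see
#'   [merge_cohorts()]).
#' @param samples sample table covering the counts columns.
#' @param annotated_ids optional character vector of annotated gene ids;
#'   `NULL` skips the annotation filter.
#' @param gene_sets optional named list of gene sets (see [read_gmt()]).
#' @param interactions optional `interaction_graph` edge table.
#' @param cpm_threshold,cpm_min_fraction CPM filter parameters (0.5, 0.9).
#' @param logfc_threshold absolute log2 fold-change cut-off (1).
#' @param variance_target cumulative variance fraction for component
#'   retention (0.6).
#' @param percentile,alpha dual selection thresholds (95, 0.001).
#' @param min_score enrichment significance threshold on -log10(p) (1.3).
#' @param max_network_size molecule cap per interaction network (35).
#' @param keep_sex,keep_unknown_sex,keep_types sample filters; defaults
#'   keep female samples of both tumor and normal type.
#' @param out_dir optional directory; when given, every stage artifact is
#'   written there as TSV plus a `report.json`.
#' @return Class `sigsim_pipeline`: list with `report` (per-stage
#'   accounting), `expression`, `fold_changes`, `candidates`, `pca`,
#'   `signatures`, `enrichment`, `networks`.
#' @export
run_pipeline <- function(counts, samples,
                         annotated_ids = NULL,
                         gene_sets = NULL,
                         interactions = NULL,
                         cpm_threshold = 0.5, cpm_min_fraction = 0.9,
                         logfc_threshold = 1,
                         variance_target = 0.6,
                         percentile = 95, alpha = 0.001,
                         min_score = 1.3, max_network_size = 35,
                         keep_sex = "female", keep_unknown_sex = FALSE,
                         keep_types = c("tumor", "normal"),
                         out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  fs <- filter_samples(counts, samples, keep_sex = keep_sex,
                       keep_types = keep_types,
                       keep_unknown_sex = keep_unknown_sex)
  acct <- sample_accounting(fs$samples)
  genes_input <- nrow(fs$counts)

  cm <- filter_by_cpm(fs$counts, cpm_threshold, cpm_min_fraction)
  genes_cpm <- nrow(cm)
  if (!is.null(annotated_ids)) cm <- filter_by_annotation(cm, annotated_ids)
  genes_annot <- nrow(cm)

  expr <- normalize_uqua(cm)
  fc <- compute_logfc(expr, fs$samples)
  candidates <- filter_by_logfc(fc, logfc_threshold)

  pca <- NULL
  m <- NA_integer_
  if (length(candidates) >= 2) {
    pca <- run_pca(expr, candidates)
    m <- select_components(pca, variance_target)
    corr <- correlate_genes(expr, pca, m)
    signatures <- extract_signatures(corr, fc, percentile, alpha)
  } else {
    signatures <- extract_signatures(
      structure(list(r = matrix(numeric(0), 0, 1), p = matrix(numeric(0), 0, 1),
                     n_samples = ncol(expr)), class = "gene_pc_cor"),
      fc, percentile, alpha)
  }

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    enrichment <- fisher_enrichment(signatures$gene_id, gene_sets,
                                    universe = rownames(expr),
                                    min_score = min_score)
  }
  networks <- NULL
  if (!is.null(interactions) && nrow(signatures) > 0) {
    networks <- build_networks(interactions, signatures$gene_id,
                               max_size = max_network_size)
  }

  report <- list(
    samples_tumor = unname(acct["tumor"]),
    samples_normal = unname(acct["normal"]),
    samples_total = unname(acct["total"]),
    genes_input = genes_input,
    genes_after_cpm = genes_cpm,
    genes_after_annotation = genes_annot,
    genes_after_logfc = length(candidates),
    components_retained = m,
    n_signatures = nrow(signatures),
    n_up = sum(signatures$direction == "up"),
    n_down = sum(signatures$direction == "down"),
    n_significant_sets = if (is.null(enrichment)) NA_integer_ else
      sum(enrichment$significant),
    n_networks = if (is.null(networks)) NA_integer_ else nrow(networks),
    parameters = list(cpm_threshold = cpm_threshold,
                      cpm_min_fraction = cpm_min_fraction,
                      logfc_threshold = logfc_threshold,
                      variance_target = variance_target,
                      percentile = percentile, alpha = alpha,
                      min_score = min_score,
                      max_network_size = max_network_size,
                      keep_sex = keep_sex, keep_types = keep_types),
    package_version = as.character(utils::packageVersion("sigsim"))
  )
  res <- structure(list(report = report, expression = expr,
                        fold_changes = fc, candidates = candidates,
                        pca = pca, signatures = signatures,
                        enrichment = enrichment, networks = networks,
                        samples = fs$samples),
                   class = "sigsim_pipeline")
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' Write every pipeline artifact to a directory
#'
#' TSVs for the normalized matrix, fold changes, signatures, enrichment and
#' networks (where computed), a scree table of per-component variance
#' fractions, and `report.json` with the stage accounting.
#'
#' @param res a `sigsim_pipeline` result.
#' @param dir output directory (created if needed).
#' @export
write_pipeline_results <- function(res, dir) {
  stopifnot(inherits(res, "sigsim_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_df <- data.frame(gene_id = rownames(res$expression), res$expression,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr_df, file.path(dir, "normalized_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$fold_changes, file.path(dir, "fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$signatures),
                     file.path(dir, "signatures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$pca)) {
    scree <- data.frame(component = seq_along(res$pca$variance_fraction),
                        variance_fraction = res$pca$variance_fraction,
                        cumulative = cumsum(res$pca$variance_fraction))
    utils::write.table(scree, file.path(dir, "scree.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$enrichment)) {
    utils::write.table(res$enrichment, file.path(dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$networks)) {
    utils::write.table(res$networks, file.path(dir, "networks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.sigsim_pipeline <- function(x, ...) {
  r <- x$report
  cat("Expression similarity signature pipeline\n")
  cat(sprintf("  samples: %d tumor + %d normal = %d\n", r$samples_tumor,
              r$samples_normal, r$samples_total))
  cat(sprintf("  genes: %d -> %d (CPM) -> %d (annotation) -> %d (|logFC|)\n",
              r$genes_input, r$genes_after_cpm, r$genes_after_annotation,
              r$genes_after_logfc))
  cat(sprintf("  components retained: %s\n", r$components_retained))
  cat(sprintf("  signatures: %d (%d up, %d down)\n", r$n_signatures,
              r$n_up, r$n_down))
  if (!is.na(r$n_significant_sets)) {
    cat(sprintf("  significant gene sets: %d\n", r$n_significant_sets))
  }
  if (!is.na(r$n_networks)) {
    cat(sprintf("  interaction networks: %d\n", r$n_networks))
  }
  invisible(x)
}
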