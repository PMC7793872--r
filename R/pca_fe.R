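#' Principal component analysis over samples
#'
#' Samples are the observations and genes the variables: the expression
#' matrix is transposed, each gene is mean-centered (not scaled — the data
#' are already on a common log scale after normalization, and unit-variance
#' scaling would erase the magnitude information the fold-change pre-filter
#' acts on) and decomposed with [stats::prcomp()]. All components are kept.
#'
#' @param expr normalized expression matrix (genes x samples).
#' @param gene_subset gene ids to decompose (>= 2); defaults to all genes.
#' @param scale. if `TRUE`, additionally scale genes to unit variance
#'   (sensitivity analysis only; off by default).
#' @return An object of class `pca_result`: list with `scores` (samples x
#'   components), `variance_fraction` (fraction of total variance per
#'   component, summing to 1), and `genes` (the subset used).
#' @export
run_pca <- function(expr, gene_subset = rownames(expr), scale. = FALSE) {
  gene_subset <- as.character(gene_subset)
  if (length(gene_subset) < 2) {
    stop("need at least 2 genes for PCA", call. = FALSE)
  }
  missing <- setdiff(gene_subset, rownames(expr))
  if (length(missing) > 0) {
    stop("gene subset not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- t(expr[gene_subset, , drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 samples for PCA", call. = FALSE)
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var <= 0 || !is.finite(total_var)) {
    stop("degenerate input: zero total variance", call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale.)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, variance_fraction = vf, genes = gene_subset),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d genes, %d components\n",
              nrow(x$scores), length(x$genes), ncol(x$scores)))
  invisible(x)
}

#' Number of components reaching a cumulative-variance target
#'
#' @param pca a `pca_result`.
#' @param target cumulative variance fraction in (0, 1]; default 0.6,
#'   i.e. retain the components explaining at least 60% of total variance.
#' @return The smallest integer m whose cumulative variance fraction
#'   reaches the target.
#' @export
select_components <- function(pca, target = 0.6) {
  stopifnot(inherits(pca, "pca_result"))
  if (!(target > 0 && target <= 1)) {
    stop("target must be in (0, 1]", call. = FALSE)
  }
  cs <- cumsum(pca$variance_fraction)
  which(cs >= target - 1e-12)[1]
}

#' Gene-component Pearson correlations and p-values
#'
#' For each gene g and retained component j, `r(g, j)` is the Pearson
#' correlation between the gene's expression across samples and the
#' component's score vector; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. Genes
#' with zero variance get `NA` correlations (flagged, never selected).
#'
#' @param expr normalized expression matrix (genes x samples).
#' @param pca a `pca_result` computed on the same samples.
#' @param m number of leading components to correlate against.
#' @param genes gene ids to test; defaults to `pca$genes` (the candidate
#'   set the decomposition was run on).
#' @return Class `gene_pc_cor`: list with matrices `r` and `p` (genes x m)
#'   and `n_samples`.
#' @export
correlate_genes <- function(expr, pca, m, genes = pca$genes) {
  stopifnot(inherits(pca, "pca_result"))
  if (m < 1 || m > ncol(pca$scores)) {
    stop("m must be between 1 and the number of components", call. = FALSE)
  }
  genes <- as.character(genes)
  e <- t(expr[genes, , drop = FALSE])
  n <- nrow(e)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (n != nrow(pca$scores)) {
    stop("expression and PCA scores cover different samples", call. = FALSE)
  }
  s <- pca$scores[, seq_len(m), drop = FALSE]
  zero_var <- apply(e, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(e, s))
  r[zero_var, ] <- NA_real_
  # guard against tiny numerical overshoot beyond +/-1
  r <- pmin(pmax(r, -1), 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  p <- pmin(p, 1)
  dimnames(r) <- dimnames(p) <- list(genes, colnames(s))
  structure(list(r = r, p = p, n_samples = n), class = "gene_pc_cor")
}

#' Dual-threshold signature extraction
#'
#' For each retained component j, let `q_j` be the `percentile`-th
#' percentile (linear interpolation) of the absolute correlations of all
#' candidate genes with component j. Gene g is selected by component j iff
#' `|r(g, j)| > q_j` (strict, so boundary ties are excluded) and
#' `p(g, j) < alpha`. The signature set is the union over components; each
#' member is annotated with every selecting component, its largest absolute
#' correlation among them, and the up/down direction carried over from the
#' fold-change table.
#'
#' Selection uses `|r|`, so flipping the sign of any component's scores
#' changes nothing; with a degenerate (constant) correlation distribution
#' no gene can strictly exceed its own percentile, so nothing is selected.
#'
#' @param corr a `gene_pc_cor` from [correlate_genes()].
#' @param fc fold-change table from [compute_logfc()] supplying directions.
#' @param percentile percentile of `|r|` per component (default 95).
#' @param alpha correlation p-value cut-off (default 0.001, unadjusted).
#' @param adjust_p if `TRUE`, apply Benjamini-Hochberg within each
#'   component before the alpha test (off by default).
#' @return Class `signature_set`: `data.frame` with columns `gene_id`,
#'   `components` (comma-separated indices), `n_components`, `max_abs_r`,
#'   `p_value` (at the best component) and `direction`.
#' @export
extract_signatures <- function(corr, fc, percentile = 95, alpha = 0.001,
                               adjust_p = FALSE) {
  stopifnot(inherits(corr, "gene_pc_cor"))
  if (!(percentile > 0 && percentile < 100)) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  absr <- abs(corr$r)
  p <- corr$p
  if (adjust_p) p <- apply(p, 2, stats::p.adjust, method = "BH")
  sel <- matrix(FALSE, nrow(absr), ncol(absr), dimnames = dimnames(absr))
  for (j in seq_len(ncol(absr))) {
    col <- absr[, j]
    ok <- !is.na(col)
    if (!any(ok)) next
    q <- stats::quantile(col[ok], percentile / 100, names = FALSE)
    sel[, j] <- ok & col > q & p[, j] < alpha
  }
  hit <- rowSums(sel) > 0
  genes <- rownames(absr)[hit]
  dir_map <- stats::setNames(fc$direction, fc$gene_id)
  rows <- lapply(genes, function(g) {
    js <- which(sel[g, ])
    best <- js[which.max(absr[g, js])]
    data.frame(
      gene_id = g,
      components = paste(js, collapse = ","),
      n_components = length(js),
      max_abs_r = unname(absr[g, best]),
      p_value = unname(p[g, best]),
      direction = if (g %in% names(dir_map)) unname(dir_map[g]) else "none",
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(gene_id = character(0), components = character(0),
               n_components = integer(0), max_abs_r = numeric(0),
               p_value = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(-out$max_abs_r, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signature_set", "data.frame")
  out
}
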