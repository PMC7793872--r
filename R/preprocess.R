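#' Counts per million
#'
#' `cpm(g, s) = counts(g, s) / libsize(s) * 1e6` with `libsize(s)` the
#' column sum. Every column of the result sums to one million.
#'
#' @param counts a [count_matrix] or plain counts matrix.
#' @return Numeric matrix of CPM values with the input's dimnames.
#' @export
cpm <- function(counts) {
  m <- as_count_mat(counts)
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(m)[libsize == 0], collapse = ", "), call. = FALSE)
  }
  sweep(m, 2, libsize, "/") * 1e6
}

#' Expression filter on counts per million
#'
#' Retains gene g iff CPM(g, s) exceeds `threshold` (strictly) in at least
#' `ceiling(min_fraction * n_samples)` samples. With the defaults this is
#' the standard low-expression filter: CPM above 0.5 in at least 90% of
#' samples.
#'
#' @param counts a [count_matrix].
#' @param threshold CPM cut-off (strict `>`).
#' @param min_fraction minimum fraction of samples, in (0, 1]; the sample
#'   count requirement is `ceiling(min_fraction * n)`.
#' @return The row-subset [count_matrix].
#' @export
filter_by_cpm <- function(counts, threshold = 0.5, min_fraction = 0.9) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  x <- cpm(counts)
  need <- ceiling(min_fraction * ncol(x))
  keep <- rowSums(x > threshold) >= need
  subset_genes(counts, rownames(x)[keep])
}

#' Restrict a count matrix to annotated genes
#'
#' Keeps exactly the genes present in `annotated_ids`, preserving the
#' matrix's gene order. An empty result is a warning, not an error.
#'
#' @param counts a [count_matrix].
#' @param annotated_ids character vector of annotated gene ids.
#' @return The row-subset [count_matrix].
#' @export
filter_by_annotation <- function(counts, annotated_ids) {
  stopifnot(inherits(counts, "count_matrix"))
  keep <- rownames(counts)[rownames(counts) %in% annotated_ids]
  if (length(keep) == 0) {
    warning("no genes left after the annotation filter")
    return(count_matrix(counts$counts[integer(0), , drop = FALSE]))
  }
  subset_genes(counts, keep)
}

#' Upper-quartile normalization with gene-length correction
#'
#' Three steps: (1) length correction, `v(g,s) = counts(g,s) / (length_g /
#' 1000)` (reads per kilobase of gene); (2) per-sample upper-quartile
#' scaling, `w(g,s) = v(g,s) * ref / UQ_s`, where `UQ_s` is the 75th
#' percentile (linear interpolation) of the nonzero length-corrected values
#' of sample s and `ref` is the geometric mean of the `UQ_s` — a symmetric,
#' order-independent reference, so after scaling all samples share the same
#' upper quartile; (3) `log2(w + 1)`.
#'
#' Doubling a sample's counts leaves its normalized values unchanged
#' (scale invariance), and re-running the procedure on an already
#' normalized matrix (gene lengths 1 kb) is a no-op.
#'
#' @param counts a [count_matrix]; every gene must have a length.
#' @param log2 if `FALSE`, return the scaled values `w` before the log
#'   transform (useful for checking the upper-quartile property).
#' @return Numeric matrix on the `log2(normalized + 1)` scale (or `w` when
#'   `log2 = FALSE`), same dimnames as the input.
#' @export
normalize_uqua <- function(counts, log2 = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  gl <- counts$gene_lengths
  if (anyNA(gl)) {
    bad <- names(gl)[is.na(gl)]
    stop("gene(s) without length, cannot length-correct: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  m <- counts$counts
  v <- m / (gl / 1000)
  uq <- vapply(seq_len(ncol(m)), function(s) {
    nz <- v[m[, s] > 0, s]
    if (length(nz) == 0) {
      stop("sample '", colnames(m)[s], "' has no nonzero counts",
           call. = FALSE)
    }
    stats::quantile(nz, 0.75, names = FALSE)
  }, numeric(1))
  if (any(uq == 0)) {
    stop("zero 75th percentile for sample(s): ",
         paste(colnames(m)[uq == 0], collapse = ", "), call. = FALSE)
  }
  ref <- exp(mean(log(uq)))
  w <- sweep(v, 2, ref / uq, "*")
  if (log2) base::log2(w + 1) else w
}

#' Tumor-versus-normal log2 fold changes on normalized expression
#'
#' `logFC(g)` is the mean over all tumor samples minus the mean over all
#' normal samples of `expr(g, .)`, pooled across cohorts (cohorts without
#' normal samples contribute tumors only — the reason a normal-free cohort
#' cannot be processed on its own). Direction is the sign of the logFC.
#'
#' @param expr normalized expression matrix (genes x samples) on the
#'   `log2(normalized + 1)` scale.
#' @param meta sample table covering `colnames(expr)`.
#' @param per_cohort if `TRUE`, add one diagnostic `logfc_<cohort>` column
#'   per cohort that has both tumor and normal samples.
#' @return A `data.frame` with columns `gene_id`, `logfc` and `direction`
#'   (`up` / `down` / `none`).
#' @export
compute_logfc <- function(expr, meta, per_cohort = FALSE) {
  meta <- validate_sample_table(meta)
  meta <- meta[meta$sample_id %in% colnames(expr), , drop = FALSE]
  tum <- meta$sample_id[meta$sample_type == "tumor"]
  nor <- meta$sample_id[meta$sample_type == "normal"]
  if (length(tum) == 0 || length(nor) == 0) {
    stop("need at least one tumor and one normal sample among the columns",
         call. = FALSE)
  }
  lf <- rowMeans(expr[, tum, drop = FALSE]) -
    rowMeans(expr[, nor, drop = FALSE])
  out <- data.frame(
    gene_id = rownames(expr),
    logfc = unname(lf),
    direction = ifelse(lf > 0, "up", ifelse(lf < 0, "down", "none")),
    stringsAsFactors = FALSE
  )
  if (per_cohort) {
    for (co in unique(meta$cohort)) {
      ct <- meta$sample_id[meta$cohort == co & meta$sample_type == "tumor"]
      cn <- meta$sample_id[meta$cohort == co & meta$sample_type == "normal"]
      if (length(ct) > 0 && length(cn) > 0) {
        out[[paste0("logfc_", co)]] <-
          unname(rowMeans(expr[, ct, drop = FALSE]) -
                   rowMeans(expr[, cn, drop = FALSE]))
      }
    }
  }
  out
}

#' Select genes by absolute log fold change
#'
#' Strict inequality: a gene at exactly the threshold is excluded.
#'
#' @param fc fold-change table from [compute_logfc()].
#' @param threshold non-negative logFC cut-off (default 1).
#' @return Character vector of gene ids with `|logFC| > threshold`.
#' @export
filter_by_logfc <- function(fc, threshold = 1) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  fc$gene_id[abs(fc$logfc) > threshold]
}
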