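#' Read a count matrix from TSV or MatrixMarket files
#'
#' The TSV dialect has a header row of sample ids and the gene id in the
#' first column. The MTX dialect expects a directory containing
#' `matrix.mtx` (MatrixMarket triplet, genes x samples), `genes.tsv` (one
#' gene id per line) and `samples.tsv` (one sample id per line).
#'
#' Validation errors (duplicate ids, negative values) name the offending
#' identifier and, for TSV input, the file line. Genes without a length in
#' `gene_lengths` are kept with `NA` length and flagged downstream.
#'
#' @param path TSV file path, or directory path for `format = "mtx"`.
#' @param format `"tsv"` or `"mtx"`.
#' @param gene_lengths optional named vector of gene lengths in bp.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), gene_lengths = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, fill = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("count TSV needs a gene id column plus >= 1 sample",
                           call. = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      first_dup <- ids[duplicated(ids)][1]
      line <- which(ids == first_dup)[2] + 1L  # +1 for the header line
      stop(sprintf("duplicate gene id '%s' at line %d of %s",
                   first_dup, line, path), call. = FALSE)
    }
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) stop("non-numeric count values in ", path,
                               call. = FALSE)
    if (any(mat < 0)) {
      row <- which(apply(mat < 0, 1, any))[1]
      stop(sprintf("negative count at line %d of %s (gene '%s')",
                   row + 1L, path, ids[row]), call. = FALSE)
    }
    rownames(mat) <- ids
    return(count_matrix(mat, gene_lengths))
  }
  mtx <- file.path(path, "matrix.mtx")
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- readLines(file.path(path, "genes.tsv"))
  samples <- readLines(file.path(path, "samples.tsv"))
  if (length(genes) != nrow(m) || length(samples) != ncol(m)) {
    stop("index files do not match matrix dimensions in ", path, call. = FALSE)
  }
  dimnames(m) <- list(genes, samples)
  count_matrix(m, gene_lengths)
}

#' Write a count matrix to TSV or MatrixMarket files
#'
#' Inverse of [read_counts()]; `write_counts` then `read_counts` round-trips
#' exactly (counts are integers).
#'
#' @param x a [count_matrix].
#' @param path output TSV path, or output directory for `format = "mtx"`.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  m <- as_count_mat(x)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "genes.tsv"))
    writeLines(colnames(m), file.path(path, "samples.tsv"))
  }
  invisible(path)
}

sample_types <- c("tumor", "normal")
sex_levels <- c("female", "male", "unknown")

#' Read and validate a sample metadata table
#'
#' Expects tab-separated columns `sample_id`, `patient_id`, `cohort`,
#' `sample_type` (tumor/normal) and `sex` (female/male/unknown).
#'
#' @param path TSV file path.
#' @return A `data.frame` with the five columns, validated.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param meta a sample table `data.frame` to validate or write.
#' @export
validate_sample_table <- function(meta) {
  need <- c("sample_id", "patient_id", "cohort", "sample_type", "sex")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    stop("sample table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop("duplicate sample id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(meta$sample_type), sample_types)
  if (length(bad_type) > 0) {
    stop("sample_type outside {tumor, normal}: ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(unique(meta$sex), sex_levels)
  if (length(bad_sex) > 0) {
    stop("sex outside {female, male, unknown}: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  meta[, need]
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(meta, path) {
  utils::write.table(validate_sample_table(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a gene annotation table (gene_id, length_bp, biotype)
#'
#' @param path TSV file path.
#' @return A `data.frame` with columns `gene_id`, `length_bp`, `biotype`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp", "biotype")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[, need]
}

#' @rdname read_gene_annotation
#' @param annotation annotation `data.frame` to write.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter samples by sex and tumor/normal type
#'
#' Restricts a count matrix and its metadata to samples matching both
#' filters, keeping the two aligned. This is the bookkeeping step that, on
#' the TCGA-style cohort summary (BRCA/OV/UCEC with 12 male breast-tumor
#' samples), takes 2,175 samples down to the 2,163 analyzed female samples.
#'
#' @param counts a [count_matrix], or `NULL` to filter metadata alone.
#' @param meta sample table (see [read_sample_table()]); every counts column
#'   must appear in `meta$sample_id`.
#' @param keep_sex character subset of `c("female", "male", "unknown")`.
#' @param keep_types character subset of `c("tumor", "normal")`.
#' @param keep_unknown_sex if `TRUE`, samples with unknown sex are retained
#'   in addition to `keep_sex` (off by default: a conservative reading of a
#'   female-only filter drops unannotated samples).
#' @return A list with elements `counts` (possibly `NULL`) and `samples`,
#'   restricted and aligned; counts column order is preserved.
#' @export
filter_samples <- function(counts, meta,
                           keep_sex = sex_levels,
                           keep_types = sample_types,
                           keep_unknown_sex = FALSE) {
  meta <- validate_sample_table(meta)
  keep_sex <- match.arg(keep_sex, sex_levels, several.ok = TRUE)
  keep_types <- match.arg(keep_types, sample_types, several.ok = TRUE)
  if (keep_unknown_sex) keep_sex <- union(keep_sex, "unknown")
  if (!is.null(counts)) {
    orphan <- setdiff(colnames(counts), meta$sample_id)
    if (length(orphan) > 0) {
      stop("counts column(s) absent from metadata: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }
  keep <- meta$sex %in% keep_sex & meta$sample_type %in% keep_types
  meta_kept <- meta[keep, , drop = FALSE]
  if (is.null(counts)) {
    return(list(counts = NULL, samples = meta_kept))
  }
  kept_cols <- colnames(counts)[colnames(counts) %in% meta_kept$sample_id]
  out <- subset_samples(counts, kept_cols)
  meta_kept <- meta_kept[meta_kept$sample_id %in% kept_cols, , drop = FALSE]
  list(counts = out, samples = meta_kept)
}

#' Per-type sample accounting
#'
#' @param meta sample table.
#' @return Named numeric vector: `tumor`, `normal`, `total`.
#' @export
sample_accounting <- function(meta) {
  meta <- validate_sample_table(meta)
  c(tumor = sum(meta$sample_type == "tumor"),
    normal = sum(meta$sample_type == "normal"),
    total = nrow(meta))
}

#' Merge cohort count matrices on their common gene universe
#'
#' Column-wise concatenation restricted to the intersection of gene ids
#' (gene order follows the first matrix), preserving each input's sample
#' order. Gene lengths must agree across inputs wherever both are known.
#'
#' @param matrices list of two or more [count_matrix] objects with
#'   pairwise-disjoint sample ids.
#' @return A merged [count_matrix].
#' @export
merge_cohorts <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2) {
    stop("merge_cohorts needs a list of >= 2 count matrices", call. = FALSE)
  }
  stopifnot(all(vapply(matrices, inherits, logical(1), "count_matrix")))
  all_samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_samples)) {
    dup <- unique(all_samples[duplicated(all_samples)])
    stop("sample id(s) shared across cohorts: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (length(genes) == 0) {
    warning("merged gene universe is empty")
  }
  lengths <- rep(NA_real_, length(genes))
  names(lengths) <- genes
  for (m in matrices) {
    gl <- m$gene_lengths[genes]
    known_both <- !is.na(gl) & !is.na(lengths)
    if (any(known_both & gl != lengths)) {
      bad <- genes[known_both & gl != lengths]
      stop("conflicting gene lengths across cohorts for: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    lengths[!is.na(gl)] <- gl[!is.na(gl)]
  }
  merged <- do.call(cbind, lapply(matrices, function(m) {
    m$counts[genes, , drop = FALSE]
  }))
  count_matrix(merged, lengths)
}
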