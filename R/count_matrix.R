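#' Gene-by-sample count container
#'
#' A light-weight container (in the spirit of edgeR's `DGEList`) holding a
#' non-negative integer count matrix indexed by gene and sample identifiers,
#' together with per-gene lengths in base pairs. Gene lengths may be missing
#' (`NA`) for some genes: such genes are flagged, not dropped, and only the
#' length-aware steps (upper-quartile normalization) refuse to run on them.
#'
#' @param counts numeric matrix of non-negative counts with unique row names
#'   (gene ids) and unique column names (sample ids).
#' @param gene_lengths optional named numeric vector of gene lengths in bp;
#'   names are matched against `rownames(counts)`. Lengths must be positive.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `gene_lengths` (named vector aligned to the rows, `NA`
#'   where unknown).
#' @examples
#' m <- matrix(0:3, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cm <- count_matrix(m, c(g1 = 1000, g2 = 2500))
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_lengths = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) {
      stop("counts must carry gene ids as rownames and sample ids as colnames",
           call. = FALSE)
    }
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) {
      stop("counts must carry gene ids as rownames and sample ids as colnames",
           call. = FALSE)
    }
    colnames(counts) <- character(0)
  }
  storage.mode(counts) <- "double"
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g) > 0) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s) > 0) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  gl <- rep(NA_real_, nrow(counts))
  names(gl) <- rownames(counts)
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths))) {
      if (length(gene_lengths) != nrow(counts)) {
        stop("unnamed gene_lengths must match the number of genes",
             call. = FALSE)
      }
      names(gene_lengths) <- rownames(counts)
    }
    hit <- intersect(names(gene_lengths), rownames(counts))
    if (any(!is.na(gene_lengths[hit]) & gene_lengths[hit] <= 0)) {
      bad <- hit[!is.na(gene_lengths[hit]) & gene_lengths[hit] <= 0]
      stop("non-positive gene length for: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    gl[hit] <- as.numeric(gene_lengths[hit])
  }
  structure(list(counts = counts, gene_lengths = gl), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d gene(s) without length)\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$gene_lengths))))
  invisible(x)
}

#' Subset a count matrix by gene or sample ids
#'
#' Row/column subsetting that keeps counts and gene lengths aligned. The
#' output follows the order of `ids`.
#'
#' @param x a `count_matrix`.
#' @param ids character vector of gene ids (`subset_genes`) or sample ids
#'   (`subset_samples`); must all be present.
#' @return A `count_matrix` restricted to `ids`.
#' @export
subset_genes <- function(x, ids) {
  stopifnot(inherits(x, "count_matrix"))
  missing <- setdiff(ids, rownames(x$counts))
  if (length(missing) > 0) {
    stop("unknown gene id(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  count_matrix(x$counts[ids, , drop = FALSE], x$gene_lengths[ids])
}

#' @rdname subset_genes
#' @export
subset_samples <- function(x, ids) {
  stopifnot(inherits(x, "count_matrix"))
  missing <- setdiff(ids, colnames(x$counts))
  if (length(missing) > 0) {
    stop("unknown sample id(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  count_matrix(x$counts[, ids, drop = FALSE], x$gene_lengths)
}

# internal: pull the bare matrix out of either representation
as_count_mat <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}
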