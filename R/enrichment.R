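#' Read a GMT gene-set collection
#'
#' Standard gene-matrix-transposed dialect: one set per line, tab-separated
#' `name`, `description`, then member gene ids. Duplicate members within a
#' line are counted once; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (the sets), with set
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]),
         call. = FALSE)
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    stop("duplicate gene set name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0)) {
    stop("empty gene set(s): ",
         paste(nm[lengths(sets) == 0], collapse = ", "), call. = FALSE)
  }
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2), nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors to write.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# hypergeometric upper tail P(X >= k) for X ~ Hypergeom(N, K, n);
# the kernel shared by gene-set enrichment and network scoring
hyper_p_right <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Right-tailed Fisher (hypergeometric) gene-set enrichment
#'
#' For each set, the overlap k between the signature and the set (both
#' intersected with the gene universe) is scored with the hypergeometric
#' upper tail `P(X >= k)` for `X ~ Hypergeom(N, K, n)` — equivalently the
#' one-sided Fisher exact test on the 2x2 overlap table — and reported as
#' `score = -log10(p)`. The score threshold 1.3 corresponds to p <= 0.05.
#' Sets smaller than `min_set_size` after universe intersection are
#' reported untested (degenerate tables).
#'
#' @param signature character vector of selected gene ids; must be a subset
#'   of `universe`.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe background gene ids — by default the assayable set, i.e.
#'   the genes surviving the annotation filter, not the union of the GMT.
#' @param min_score significance threshold on `-log10(p)` (default 1.3).
#' @param min_set_size smallest testable set size after universe
#'   intersection (default 3).
#' @return `data.frame` sorted by score (descending, untested sets last):
#'   columns `set`, `k`, `K`, `n`, `N`, `p_right`, `score`, `significant`,
#'   `tested`, `overlap_genes`.
#' @export
fisher_enrichment <- function(signature, sets, universe, min_score = 1.3,
                              min_set_size = 3) {
  signature <- unique(as.character(signature))
  universe <- unique(as.character(universe))
  stray <- setdiff(signature, universe)
  if (length(stray) > 0) {
    stop("signature gene(s) outside the universe: ",
         paste(utils::head(stray, 10), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(signature)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    K <- length(set_u)
    tested <- K >= min_set_size
    ov <- intersect(signature, set_u)
    k <- length(ov)
    p <- if (tested) hyper_p_right(k, K, n, N) else NA_real_
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p_right = p,
               score = if (tested) -log10(p) else NA_real_,
               significant = isTRUE(tested && -log10(p) >= min_score),
               tested = tested,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_right = numeric(0),
                      score = numeric(0), significant = logical(0),
                      tested = logical(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out$p_adjust_bh <- NA_real_
  out$p_adjust_bh[out$tested] <- stats::p.adjust(out$p_right[out$tested],
                                                 method = "BH")
  ord <- order(!out$tested, -ifelse(out$tested, out$score, -Inf), out$set)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap fraction of a gene set, as a percentage
#'
#' `100 * k / K`: the share of a set's (universe-restricted) members found
#' in the signature, e.g. 11 of 26 members is about 42%.
#'
#' @param k overlap count, `0 <= k <= K`.
#' @param K set size, `> 0`.
#' @return The percentage as a real number; round to the nearest integer
#'   for reporting.
#' @export
overlap_fraction <- function(k, K) {
  if (any(K == 0)) stop("undefined overlap fraction: set size K = 0",
                        call. = FALSE)
  if (any(k < 0 | k > K)) stop("need 0 <= k <= K", call. = FALSE)
  100 * k / K
}
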