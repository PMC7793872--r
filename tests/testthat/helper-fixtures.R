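# Small in-code fixtures shared across the suite.

tiny_counts <- function(nr = 5, nc = 4, seed = 42, lambda = 20) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(nr * nc, lambda), nr,
                dimnames = list(sprintf("g%02d", seq_len(nr)),
                                sprintf("s%02d", seq_len(nc))))
    count_matrix(m, stats::setNames(sample(500:5000, nr), rownames(m)))
  })
}

tiny_meta <- function(ids, types, cohort = "C1", sex = "female") {
  data.frame(sample_id = ids, patient_id = paste0("p_", ids),
             cohort = cohort, sample_type = types, sex = sex,
             stringsAsFactors = FALSE)
}

# scaled-down three-cohort simulation (middle cohort has no normals)
small_sim <- function(seed = 1, n_planted_up = 20, n_planted_down = 20,
                      tissue_effect_sd = 0.5) {
  generate_cohorts(synth_config(
    n_genes = 400,
    cohorts = list(cohort_spec("A", 40, 15), cohort_spec("B", 30, 0),
                   cohort_spec("C", 30, 10)),
    n_planted_up = n_planted_up, n_planted_down = n_planted_down,
    tissue_effect_sd = tissue_effect_sd, seed = seed))
}

# metadata table mirroring the published three-cohort sample summary:
# 1,102 / 374 / 551 tumors (12 of the breast tumors male), 113 + 35 normals
table1_meta <- function() {
  mk <- function(cohort, type, n, prefix, sex = "female") {
    data.frame(sample_id = sprintf("%s_%s%04d", cohort, prefix, seq_len(n)),
               patient_id = sprintf("%s_pt%04d", cohort, seq_len(n)),
               cohort = cohort, sample_type = type, sex = sex,
               stringsAsFactors = FALSE)
  }
  brca_t <- mk("BRCA", "tumor", 1102, "T")
  brca_t$sex[seq_len(12)] <- "male"
  rbind(brca_t,
        mk("OV", "tumor", 374, "T"),
        mk("UCEC", "tumor", 551, "T"),
        mk("BRCA", "normal", 113, "N"),
        mk("UCEC", "normal", 35, "N"))
}

# hypergeometric upper tail by explicit binomial-coefficient summation
brute_hyper_right <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# straight-line reimplementation of the whole component-correlation
# selector (eigendecomposition route, no shared code with the package)
brute_selector <- function(expr, target = 0.6, pct = 95, alpha = 0.001) {
  x <- scale(t(expr), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  vf <- pmax(ev$values, 0) / sum(pmax(ev$values, 0))
  m <- which(cumsum(vf) >= target - 1e-12)[1]
  scores <- x %*% ev$vectors
  n <- nrow(x)
  selected <- character(0)
  for (j in seq_len(m)) {
    rj <- vapply(rownames(expr), function(g) {
      a <- expr[g, ] - mean(expr[g, ])
      b <- scores[, j] - mean(scores[, j])
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, numeric(1))
    tj <- abs(rj) * sqrt((n - 2) / (1 - rj^2))
    pj <- 2 * stats::pt(tj, n - 2, lower.tail = FALSE)
    q <- stats::quantile(abs(rj), pct / 100, names = FALSE)
    selected <- union(selected, names(rj)[abs(rj) > q & pj < alpha])
  }
  sort(selected)
}

# package route for the same selector, end to end
package_selector <- function(expr, fc, target = 0.6, pct = 95,
                             alpha = 0.001) {
  pca <- run_pca(expr)
  m <- select_components(pca, target)
  corr <- correlate_genes(expr, pca, m)
  sort(extract_signatures(corr, fc, pct, alpha)$gene_id)
}

constant_fc <- function(genes, direction = "up") {
  data.frame(gene_id = genes,
             logfc = if (direction == "up") 2 else -2,
             direction = direction, stringsAsFactors = FALSE)
}
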