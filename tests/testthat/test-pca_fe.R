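make_expr <- function(ng, ns, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    matrix(stats::rnorm(ng * ns, sd = sd), ng,
           dimnames = list(sprintf("g%03d", seq_len(ng)),
                           sprintf("s%03d", seq_len(ns))))
  })
}

test_that("a rank-1 matrix puts all variance on the first component", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
                g2 = rep(2, 6), g3 = rep(7, 6))
  colnames(expr) <- paste0("s", 1:6)
  pca <- run_pca(expr)
  expect_equal(pca$variance_fraction[1], 1, tolerance = 1e-12)
  expect_error(run_pca(expr[c("g2", "g3"), ]), "degenerate")
  expect_error(run_pca(expr, "g1"), "2 genes")
})

test_that("variance fractions match an independent eigendecomposition", {
  expr <- make_expr(10, 8, seed = 3)
  pca <- run_pca(expr)
  ev <- eigen(stats::cov(t(expr)), symmetric = TRUE, only.values = TRUE)
  vals <- pmax(ev$values, 0)
  k <- ncol(expr) - 1  # components beyond n_samples - 1 are numerical zeros
  expect_equal(pca$variance_fraction[1:k], (vals / sum(vals))[1:k],
               tolerance = 1e-8)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-8)
  # score columns are mutually orthogonal (among non-degenerate components)
  g <- crossprod(pca$scores[, 1:k])
  g <- g / sqrt(outer(diag(g), diag(g)))
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("duplicating every sample leaves variance fractions unchanged", {
  expr <- make_expr(12, 9, seed = 5)
  doubled <- cbind(expr, expr)
  colnames(doubled) <- sprintf("s%03d", seq_len(18))
  a <- run_pca(expr)$variance_fraction
  b <- run_pca(doubled)$variance_fraction
  k <- ncol(expr) - 1
  expect_equal(b[1:k], a[1:k], tolerance = 1e-8)
})

test_that("component retention takes the smallest m reaching the target", {
  fake <- structure(list(variance_fraction = c(0.5, 0.3, 0.2)),
                    class = "pca_result")
  expect_identical(select_components(fake, 0.6), 2L)
  expect_identical(select_components(fake, 0.5), 1L)
  expect_identical(select_components(fake, 1.0), 3L)
  # trailing zero-variance components never count toward target 1
  fake0 <- structure(list(variance_fraction = c(0.7, 0.3, 0, 0)),
                     class = "pca_result")
  expect_identical(select_components(fake0, 1.0), 2L)
  expect_error(select_components(fake, 0), "target")
})

test_that("gene-component correlations match the textbook formula", {
  expr <- make_expr(15, 30, seed = 7)
  pca <- run_pca(expr)
  m <- 4
  corr <- correlate_genes(expr, pca, m)
  n <- ncol(expr)
  for (g in rownames(expr)[c(1, 7, 15)]) {
    for (j in seq_len(m)) {
      x <- expr[g, ] - mean(expr[g, ])
      y <- pca$scores[, j] - mean(pca$scores[, j])
      r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
      t <- abs(r) * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(t, n - 2, lower.tail = FALSE)
      expect_equal(corr$r[g, j], r, tolerance = 1e-10)
      expect_equal(corr$p[g, j], p, tolerance = 1e-10)
    }
  }
})

test_that("perfect, orthogonal and constant genes behave at the extremes", {
  expr <- make_expr(6, 25, seed = 9)
  pca <- run_pca(expr)
  probe <- rbind(expr,
                 copy1 = pca$scores[, 1],   # identical to PC1 scores
                 ortho = pca$scores[, 2],   # orthogonal to PC1
                 flat = rep(1, 25))         # zero variance
  corr <- correlate_genes(probe, pca, m = 2,
                          genes = c("copy1", "ortho", "flat"))
  expect_equal(corr$r["copy1", 1], 1, tolerance = 1e-10)
  expect_lt(corr$p["copy1", 1], 1e-12)
  expect_lt(abs(corr$r["ortho", 1]), 1e-10)
  expect_gt(corr$p["ortho", 1], 1 - 1e-8)
  expect_true(all(is.na(corr$r["flat", ])))
})

test_that("an identically correlated ensemble selects nothing", {
  r <- matrix(0.9, 50, 2, dimnames = list(sprintf("g%02d", 1:50), NULL))
  p <- matrix(1e-9, 50, 2, dimnames = dimnames(r))
  corr <- structure(list(r = r, p = p, n_samples = 40),
                    class = "gene_pc_cor")
  fc <- constant_fc(rownames(r))
  expect_identical(nrow(extract_signatures(corr, fc)), 0L)
})

test_that("exactly the top 5 of 100 distinct correlations pass a component", {
  withr::with_seed(33, {
    vals <- sample(seq(0.01, 0.99, length.out = 100))
  })
  r <- matrix(vals, 100, 1, dimnames = list(sprintf("g%03d", 1:100), NULL))
  p <- matrix(1e-9, 100, 1, dimnames = dimnames(r))
  corr <- structure(list(r = r, p = p, n_samples = 50),
                    class = "gene_pc_cor")
  sig <- extract_signatures(corr, constant_fc(rownames(r)))
  top5 <- rownames(r)[order(-abs(r[, 1]))][1:5]
  expect_setequal(sig$gene_id, top5)
  # when the p criterion fails everywhere, nothing is selected
  p_big <- matrix(0.5, 100, 1, dimnames = dimnames(r))
  corr2 <- structure(list(r = r, p = p_big, n_samples = 50),
                     class = "gene_pc_cor")
  expect_identical(nrow(extract_signatures(corr2, constant_fc(rownames(r)))),
                   0L)
})

test_that("selection is invariant to flipping component signs", {
  expr <- make_expr(40, 20, seed = 11)
  pca <- run_pca(expr)
  m <- select_components(pca, 0.6)
  corr <- correlate_genes(expr, pca, m)
  flipped <- corr
  flipped$r <- -flipped$r
  fc <- constant_fc(rownames(expr))
  a <- extract_signatures(corr, fc, alpha = 0.05)
  b <- extract_signatures(flipped, fc, alpha = 0.05)
  expect_setequal(a$gene_id, b$gene_id)
})

test_that("each component selects at most 5% of tie-free genes", {
  for (seed in c(41, 42)) {
    expr <- make_expr(60, 15, seed = seed)
    pca <- run_pca(expr)
    corr <- correlate_genes(expr, pca, m = 3)
    for (j in 1:3) {
      q <- stats::quantile(abs(corr$r[, j]), 0.95, names = FALSE)
      expect_lte(sum(abs(corr$r[, j]) > q), floor(0.05 * nrow(expr)))
    }
  }
})

test_that("the selector agrees with a straight-line reimplementation", {
  withr::with_seed(55, {
    dims <- data.frame(ng = sample(5:50, 10, replace = TRUE),
                       ns = sample(5:20, 10, replace = TRUE),
                       seed = sample.int(1e6, 10))
  })
  for (i in seq_len(nrow(dims))) {
    expr <- make_expr(dims$ng[i], dims$ns[i], seed = dims$seed[i])
    fc <- constant_fc(rownames(expr))
    expect_identical(package_selector(expr, fc, alpha = 0.01),
                     brute_selector(expr, alpha = 0.01),
                     info = paste("case", i))
  }
})
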