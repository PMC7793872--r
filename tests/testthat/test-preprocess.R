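test_that("cpm matches the per-entry definition and its oracle", {
  m <- matrix(c(1, 1, 0, 10), 2, dimnames = list(c("g1", "g2"),
                                                 c("s1", "s2")))
  x <- cpm(count_matrix(m))
  expect_equal(unname(x[, "s1"]), c(5e5, 5e5))
  expect_equal(unname(x[, "s2"]), c(0, 1e6))

  cm <- tiny_counts(5, 4, seed = 13)
  got <- cpm(cm)
  # brute-force per-entry computation
  expected <- cm$counts
  for (s in seq_len(ncol(expected))) {
    for (g in seq_len(nrow(expected))) {
      expected[g, s] <- cm$counts[g, s] / sum(cm$counts[, s]) * 1e6
    }
  }
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(unname(colSums(got)), rep(1e6, 4), tolerance = 1e-6)
  # independent implementation from the standard RNA-seq toolkit
  expect_equal(got, edgeR::cpm(cm$counts), tolerance = 1e-10,
               ignore_attr = TRUE)
  zero <- count_matrix(matrix(c(1, 0), 1, 2,
                              dimnames = list("g", c("ok", "empty"))))
  expect_error(cpm(zero), "empty")
})

test_that("the CPM filter applies the ceiling rule over samples", {
  # 4 samples at min_fraction 0.9: ceil(3.6) = 4 of 4 must pass
  patterns <- expand.grid(rep(list(c(0, 1000)), 4))
  m <- as.matrix(patterns) * 1  # genes = all pass/fail patterns
  rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", 1:4)
  filler <- matrix(1e6, 1, 4, dimnames = list("filler", colnames(m)))
  cm <- count_matrix(rbind(m, filler))
  kept <- rownames(filter_by_cpm(cm, threshold = 0.5, min_fraction = 0.9))
  n_pass <- rowSums(cpm(cm) > 0.5)
  expect_setequal(kept, names(n_pass)[n_pass >= 4])
  expect_false(any(rowSums(m > 0) < 4 & rownames(m) %in% kept))
  # a gene with all-zero counts is removed for any positive threshold
  expect_false("p01" %in% kept)
})

test_that("raising the CPM threshold never adds genes", {
  cm <- tiny_counts(40, 8, seed = 21, lambda = 5)
  k1 <- rownames(filter_by_cpm(cm, threshold = 100, min_fraction = 0.5))
  k2 <- rownames(filter_by_cpm(cm, threshold = 1000, min_fraction = 0.5))
  k3 <- rownames(filter_by_cpm(cm, threshold = 5e4, min_fraction = 0.5))
  expect_true(all(k2 %in% k1))
  expect_true(all(k3 %in% k2))
})

test_that("the annotation filter keeps exactly the annotated genes, in order", {
  cm <- tiny_counts(6, 3, seed = 2)
  expect_identical(filter_by_annotation(cm, rownames(cm))$counts, cm$counts)
  sub <- filter_by_annotation(cm, c("g04", "g02", "zzz"))
  expect_identical(rownames(sub), c("g02", "g04"))  # matrix order kept
  expect_warning(empty <- filter_by_annotation(cm, "absent"), "no genes")
  expect_identical(dim(empty), c(0L, 3L))
  expect_identical(colnames(empty), colnames(cm))
})

test_that("upper-quartile normalization has its defining symmetries", {
  cm <- tiny_counts(30, 5, seed = 31, lambda = 50)
  # identical samples: scaling factors are all 1
  same <- count_matrix(matrix(rep(cm$counts[, 1], 4), ncol = 4,
                              dimnames = list(rownames(cm),
                                              paste0("s", 1:4))),
                       cm$gene_lengths)
  out <- normalize_uqua(same)
  v <- same$counts[, 1] / (same$gene_lengths / 1000)
  expect_equal(unname(out[, 1]), unname(log2(v + 1)), tolerance = 1e-12)
  # a sample that is an exact 2x rescaling of another normalizes to it
  m2 <- cbind(cm$counts, twiceS1 = 2 * cm$counts[, 1])
  out2 <- normalize_uqua(count_matrix(m2, cm$gene_lengths))
  expect_equal(unname(out2[, "twiceS1"]), unname(out2[, 1]),
               tolerance = 1e-12)
})

test_that("after scaling, nonzero upper quartiles agree to 1e-9 (oracle)", {
  for (seed in c(101, 202, 303)) {
    sim <- generate_cohorts(synth_config(
      n_genes = 50, cohorts = list(cohort_spec("A", 3, 3)),
      n_planted_up = 5, n_planted_down = 5, seed = seed))
    w <- normalize_uqua(sim$counts, log2 = FALSE)
    # independent linear-interpolation percentile (type-7 definition)
    pct75 <- function(x) {
      x <- sort(x)
      h <- (length(x) - 1) * 0.75 + 1
      lo <- floor(h)
      x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
    }
    uqs <- vapply(seq_len(ncol(w)), function(s) {
      pct75(w[sim$counts$counts[, s] > 0, s])
    }, numeric(1))
    expect_lt(max(abs(uqs / uqs[1] - 1)), 1e-9)
  }
})

test_that("re-running scaling on 1kb-corrected values changes nothing", {
  cm <- tiny_counts(40, 6, seed = 17, lambda = 30)
  w <- normalize_uqua(cm, log2 = FALSE)
  lens <- stats::setNames(rep(1000, nrow(w)), rownames(w))
  w2 <- normalize_uqua(count_matrix(w, lens), log2 = FALSE)
  expect_equal(w2, w, tolerance = 1e-9)
})

test_that("log fold changes follow the pooled group-mean definition", {
  expr <- rbind(gU = c(3, 3, 3, 1, 1), gN = c(2, 2, 2, 2, 2))
  colnames(expr) <- paste0("s", 1:5)
  meta <- tiny_meta(colnames(expr),
                    c("tumor", "tumor", "tumor", "normal", "normal"))
  fc <- compute_logfc(expr, meta)
  expect_equal(fc$logfc[fc$gene_id == "gU"], 2)
  expect_identical(fc$direction[fc$gene_id == "gU"], "up")
  expect_equal(fc$logfc[fc$gene_id == "gN"], 0)
  expect_identical(fc$direction[fc$gene_id == "gN"], "none")
  # no normals at all mirrors why a normal-free cohort cannot stand alone
  expect_error(compute_logfc(expr, tiny_meta(colnames(expr),
                                             rep("tumor", 5))),
               "normal")
})

test_that("planted effects survive normalization to within 0.3 log2 units", {
  sim <- small_sim(seed = 12)
  kept <- filter_by_cpm(sim$counts)
  expr <- normalize_uqua(kept)
  fc <- compute_logfc(expr, sim$samples)
  up <- intersect(sim$truth$planted_up, fc$gene_id)
  dn <- intersect(sim$truth$planted_down, fc$gene_id)
  expect_lt(abs(mean(fc$logfc[match(up, fc$gene_id)]) - 2), 0.3)
  expect_lt(abs(mean(fc$logfc[match(dn, fc$gene_id)]) + 2), 0.3)
})

test_that("the logFC threshold is strict and sign-blind", {
  fc <- data.frame(gene_id = c("a", "b", "c"),
                   logfc = c(1.0, -1.5, 0.99),
                   direction = c("up", "down", "up"),
                   stringsAsFactors = FALSE)
  expect_identical(filter_by_logfc(fc, 1), "b")
  expect_error(filter_by_logfc(fc, -1), ">= 0")
})

test_that("the full front end passes at least 95% of planted genes", {
  rates <- vapply(1:3, function(s) {
    sim <- generate_cohorts(synth_config(seed = s))
    kept <- filter_by_cpm(sim$counts)
    expr <- normalize_uqua(kept)
    cand <- filter_by_logfc(compute_logfc(expr, sim$samples))
    planted <- c(sim$truth$planted_up, sim$truth$planted_down)
    length(intersect(cand, planted)) / length(planted)
  }, numeric(1))
  expect_gte(mean(rates), 0.95)
})
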