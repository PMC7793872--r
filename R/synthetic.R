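#' Specify one synthetic cohort
#'
#' @param name cohort label.
#' @param n_tumor,n_normal non-negative sample counts; a cohort may have no
#'   normal samples (as for ovarian solid-tissue normals, which TCGA lacks).
#' @return A list with the three fields, for use in [synth_config()].
#' @export
cohort_spec <- function(name, n_tumor, n_normal) {
  list(name = as.character(name), n_tumor = as.integer(n_tumor),
       n_normal = as.integer(n_normal))
}

#' Configuration for the multi-cohort count simulator
#'
#' Defaults describe the study conditions the package is validated under:
#' three cohorts with tumors 150/100/120 and normals 30/0/20 (the middle
#' cohort, like ovarian, has no normals), 3,000 genes, 100 up- plus 100
#' downregulated planted genes at |log2 fold change| 2, negative-binomial
#' dispersion 0.2, and per-cohort tissue baseline shifts of sd 0.5 (log2).
#' Gene abundances are log-normal (natural-log mean 4.5, sd 1.2), so the
#' simulated universe behaves like a predominantly expressed transcriptome
#' in which the CPM filter trims only a low-abundance tail.
#'
#' @param n_genes number of genes.
#' @param cohorts list of [cohort_spec()] entries; at least one cohort must
#'   have normal samples (a pooled normal reference must exist).
#' @param n_planted_up,n_planted_down numbers of planted up/downregulated
#'   genes; their sum cannot exceed `n_genes`.
#' @param effect_log2fc planted absolute log2 fold change (> 0).
#' @param baseline_log_mean,baseline_log_sd natural-log mean/sd of per-gene
#'   baseline abundance.
#' @param tissue_effect_sd sd (log2 scale) of the per-(cohort, gene)
#'   baseline shift; drawn once per cohort and gene so cohorts separate in
#'   expression space and the global normalization plus component-based
#'   selection must look past tissue of origin.
#' @param dispersion negative-binomial dispersion alpha in the
#'   `var = mu + alpha * mu^2` convention (> 0).
#' @param libsize_log_mean,libsize_log_sd natural-log mean/sd of library
#'   sizes; only the spread matters for CPM-scale quantities.
#' @param gene_length_range two positive integers (bp); lengths are uniform
#'   on the range and fixed per gene.
#' @param seed single integer controlling all randomness.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 3000,
                         cohorts = list(cohort_spec("BRCA", 150, 30),
                                        cohort_spec("OV", 100, 0),
                                        cohort_spec("UCEC", 120, 20)),
                         n_planted_up = 100, n_planted_down = 100,
                         effect_log2fc = 2,
                         baseline_log_mean = 4.5, baseline_log_sd = 1.2,
                         tissue_effect_sd = 0.5,
                         dispersion = 0.2,
                         libsize_log_mean = 13.2, libsize_log_sd = 0.35,
                         gene_length_range = c(200L, 10000L),
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), cohorts = cohorts,
              n_planted_up = as.integer(n_planted_up),
              n_planted_down = as.integer(n_planted_down),
              effect_log2fc = effect_log2fc,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              tissue_effect_sd = tissue_effect_sd,
              dispersion = dispersion,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              gene_length_range = as.integer(gene_length_range),
              seed = as.integer(seed))
  bad <- function(field, msg) {
    stop(sprintf("invalid configuration: %s %s", field, msg), call. = FALSE)
  }
  if (cfg$n_genes < 1) bad("n_genes", "must be positive")
  if (!is.list(cfg$cohorts) || length(cfg$cohorts) == 0) {
    bad("cohorts", "must be a non-empty list of cohort_spec()")
  }
  for (co in cfg$cohorts) {
    if (co$n_tumor < 0) bad("n_tumor", paste0("is negative in cohort ", co$name))
    if (co$n_normal < 0) bad("n_normal", paste0("is negative in cohort ", co$name))
  }
  if (all(vapply(cfg$cohorts, `[[`, integer(1), "n_normal") == 0)) {
    bad("cohorts", "must include at least one cohort with normal samples")
  }
  if (cfg$n_planted_up < 0) bad("n_planted_up", "must be non-negative")
  if (cfg$n_planted_down < 0) bad("n_planted_down", "must be non-negative")
  if (cfg$n_planted_up + cfg$n_planted_down > cfg$n_genes) {
    bad("n_planted_up + n_planted_down", "exceeds n_genes")
  }
  if (cfg$effect_log2fc <= 0) bad("effect_log2fc", "must be positive")
  if (cfg$baseline_log_sd < 0) bad("baseline_log_sd", "must be non-negative")
  if (cfg$tissue_effect_sd < 0) bad("tissue_effect_sd", "must be non-negative")
  if (cfg$dispersion <= 0) bad("dispersion", "must be positive")
  if (cfg$libsize_log_sd < 0) bad("libsize_log_sd", "must be non-negative")
  if (length(cfg$gene_length_range) != 2 || any(cfg$gene_length_range <= 0) ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2]) {
    bad("gene_length_range", "must be two positive integers, min <= max")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate multi-cohort RNA-seq counts with planted dysregulation
#'
#' Counts are negative-binomial: for gene g, cohort c, sample s,
#' `mu = exp(baseline_g + log(2) * (tissue_cg + delta_g * is_tumor)) *
#' libsize_s / reference_libsize`, with `delta_g = +/- effect_log2fc` for
#' planted genes and 0 otherwise, `var = mu + dispersion * mu^2`, and the
#' reference library size `exp(libsize_log_mean)`. Tissue shifts are drawn
#' once per (cohort, gene); planted gene indices are drawn once and split
#' exactly between the up and down sets. A single seed drives every draw,
#' so identical configurations give bit-identical output.
#'
#' @param config a [synth_config()].
#' @return Class `synthetic_cohorts`: list with `counts` (a [count_matrix]
#'   with gene lengths), `samples` (sample table: sample_id, patient_id,
#'   cohort, sample_type, sex), `annotation` (gene_id, length_bp, biotype)
#'   and `truth` (list: `planted_up`, `planted_down`, `true_log2fc` named
#'   over all genes).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    ng <- config$n_genes
    gene_ids <- sprintf("G%05d", seq_len(ng))
    lengths <- sample(seq(config$gene_length_range[1],
                          config$gene_length_range[2]), ng, replace = TRUE)
    names(lengths) <- gene_ids
    baseline <- stats::rnorm(ng, config$baseline_log_mean,
                             config$baseline_log_sd)
    n_planted <- config$n_planted_up + config$n_planted_down
    planted_idx <- if (n_planted > 0) sample.int(ng, n_planted) else integer(0)
    up_idx <- utils::head(planted_idx, config$n_planted_up)
    down_idx <- utils::tail(planted_idx, config$n_planted_down)
    delta <- numeric(ng)
    delta[up_idx] <- config$effect_log2fc
    delta[down_idx] <- -config$effect_log2fc
    names(delta) <- gene_ids

    blocks <- list()
    meta <- list()
    for (co in config$cohorts) {
      n_s <- co$n_tumor + co$n_normal
      if (n_s == 0) next
      tissue <- stats::rnorm(ng, 0, config$tissue_effect_sd)
      libsize <- stats::rlnorm(n_s, config$libsize_log_mean,
                               config$libsize_log_sd)
      is_tumor <- c(rep(TRUE, co$n_tumor), rep(FALSE, co$n_normal))
      ids <- c(sprintf("%s_T%03d", co$name, seq_len(co$n_tumor)),
               sprintf("%s_N%03d", co$name, seq_len(co$n_normal)))
      log_mu <- baseline + log(2) * tissue +
        log(2) * outer(delta, as.numeric(is_tumor))
      mu <- exp(log_mu) *
        rep(libsize / exp(config$libsize_log_mean), each = ng)
      cnt <- matrix(stats::rnbinom(ng * n_s, mu = mu,
                                   size = 1 / config$dispersion),
                    nrow = ng, dimnames = list(gene_ids, ids))
      blocks[[co$name]] <- cnt
      meta[[co$name]] <- data.frame(
        sample_id = ids,
        patient_id = paste0("P_", ids),
        cohort = co$name,
        sample_type = ifelse(is_tumor, "tumor", "normal"),
        sex = "female",
        stringsAsFactors = FALSE)
    }
    counts <- count_matrix(do.call(cbind, blocks), lengths)
    samples <- do.call(rbind, meta)
    rownames(samples) <- NULL
    annotation <- data.frame(gene_id = gene_ids,
                             length_bp = unname(lengths),
                             biotype = "protein_coding",
                             stringsAsFactors = FALSE)
    truth <- list(planted_up = gene_ids[sort(up_idx)],
                  planted_down = gene_ids[sort(down_idx)],
                  true_log2fc = delta)
    structure(list(counts = counts, samples = samples,
                   annotation = annotation, truth = truth,
                   config = config),
              class = "synthetic_cohorts")
  })
}

#' @export
print.synthetic_cohorts <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohorts: %d genes x %d samples, %d planted up / %d down\n",
    nrow(x$counts), ncol(x$counts), length(x$truth$planted_up),
    length(x$truth$planted_down)))
  invisible(x)
}

#' Write the simulator outputs as plain-text tables
#'
#' Writes `counts.tsv`, `metadata.tsv`, `annotation.tsv` and `truth.tsv`
#' (gene_id, true_log2fc) into `dir`.
#'
#' @param x a `synthetic_cohorts` object.
#' @param dir output directory (created if needed).
#' @export
write_cohorts <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohorts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(x$counts, file.path(dir, "counts.tsv"))
  write_sample_table(x$samples, file.path(dir, "metadata.tsv"))
  write_gene_annotation(x$annotation, file.path(dir, "annotation.tsv"))
  utils::write.table(
    data.frame(gene_id = names(x$truth$true_log2fc),
               true_log2fc = unname(x$truth$true_log2fc)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Synthetic gene-set collection with planted signal sets
#'
#' A stand-in for a curated pathway collection: `n_signal` sets draw a
#' fraction of their members from `signal_genes` (e.g. the planted
#' dysregulated genes), the rest and the `n_background` null sets are
#' uniform draws from `genes`. Labelled synthetic; it mimics set-size
#' structure only, not curated biology.
#'
#' @param genes gene universe to draw from.
#' @param signal_genes genes enriched in the signal sets.
#' @param n_signal,n_background numbers of signal / null sets.
#' @param set_size members per set.
#' @param signal_fraction fraction of each signal set drawn from
#'   `signal_genes`.
#' @param seed integer seed.
#' @return Named list of gene sets (GMT-compatible, see [write_gmt()]).
#' @export
simulate_gene_sets <- function(genes, signal_genes = character(0),
                               n_signal = 5, n_background = 20,
                               set_size = 40, signal_fraction = 0.5,
                               seed = 1L) {
  withr::with_seed(seed, {
    sets <- list()
    n_sig_members <- min(ceiling(set_size * signal_fraction),
                         length(signal_genes))
    for (i in seq_len(n_signal)) {
      sig <- sample(signal_genes, n_sig_members)
      rest <- sample(setdiff(genes, sig), set_size - n_sig_members)
      sets[[sprintf("SIGNAL_SET_%02d", i)]] <- c(sig, rest)
    }
    for (i in seq_len(n_background)) {
      sets[[sprintf("NULL_SET_%02d", i)]] <- sample(genes,
                                                    min(set_size,
                                                        length(genes)))
    }
    attr(sets, "description") <- stats::setNames(
      rep("synthetic gene set", length(sets)), names(sets))
    sets
  })
}

#' Synthetic interaction edge list with focus-gene hubs
#'
#' A stand-in for a curated interaction knowledge base: a few hub nodes are
#' wired preferentially to `focus` genes, plus uniform background edges.
#' Relation codes (E/T/P/PP), directness and signs are sampled. Labelled
#' synthetic; topology only, no curated biology.
#'
#' @param genes gene universe.
#' @param focus genes the hubs preferentially connect to.
#' @param n_hubs number of hub nodes (named `HUB_01`, ...).
#' @param hub_degree edges per hub (drawn mostly toward `focus`).
#' @param n_background number of uniform background edges.
#' @param seed integer seed.
#' @return An `interaction_graph` edge table.
#' @export
simulate_interactions <- function(genes, focus = character(0), n_hubs = 3,
                                  hub_degree = 20, n_background = 200,
                                  seed = 1L) {
  withr::with_seed(seed, {
    rows <- list()
    for (h in seq_len(n_hubs)) {
      hub <- sprintf("HUB_%02d", h)
      pool <- if (length(focus) >= hub_degree) focus else genes
      tgt <- sample(pool, min(hub_degree, length(pool)))
      rows[[length(rows) + 1]] <- data.frame(
        source = hub, target = tgt,
        directness = sample(directness_codes, length(tgt), replace = TRUE),
        relation = sample(relation_codes, length(tgt), replace = TRUE),
        sign = sample(sign_codes, length(tgt), replace = TRUE,
                      prob = c(0.45, 0.25, 0.3)),
        stringsAsFactors = FALSE)
    }
    src <- sample(genes, n_background, replace = TRUE)
    tgt <- sample(genes, n_background, replace = TRUE)
    keep <- src != tgt
    rows[[length(rows) + 1]] <- data.frame(
      source = src[keep], target = tgt[keep],
      directness = sample(directness_codes, sum(keep), replace = TRUE),
      relation = sample(relation_codes, sum(keep), replace = TRUE),
      sign = sample(sign_codes, sum(keep), replace = TRUE,
                    prob = c(0.45, 0.25, 0.3)),
      stringsAsFactors = FALSE)
    suppressWarnings(validate_interactions(do.call(rbind, rows)))
  })
}
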