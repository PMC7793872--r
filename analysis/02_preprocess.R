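#!/usr/bin/env Rscript
# Front end: keep female samples, drop low-expression genes (CPM > 0.5 in
# >= 90% of samples), keep annotated genes, upper-quartile/length
# normalize, and pre-filter genes at |log2FC| > 1 between tumor and the
# pooled normals.
library(sigsim)

data_dir <- "results/data"
out <- "results"
annotation <- read_gene_annotation(file.path(data_dir, "annotation.tsv"))
counts <- read_counts(file.path(data_dir, "counts.tsv"),
                      gene_lengths = stats::setNames(annotation$length_bp,
                                                     annotation$gene_id))
meta <- read_sample_table(file.path(data_dir, "metadata.tsv"))

fs <- filter_samples(counts, meta, keep_sex = "female")
cat(sprintf("samples kept: %d tumor + %d normal\n",
            sum(fs$samples$sample_type == "tumor"),
            sum(fs$samples$sample_type == "normal")))

cm <- filter_by_cpm(fs$counts)
cat(sprintf("genes after CPM filter: %d of %d\n", nrow(cm), nrow(counts)))
cm <- filter_by_annotation(cm, annotation$gene_id)
cat(sprintf("genes after annotation filter: %d\n", nrow(cm)))

expr <- normalize_uqua(cm)
fc <- compute_logfc(expr, fs$samples, per_cohort = TRUE)
cand <- filter_by_logfc(fc)
cat(sprintf("genes with |logFC| > 1: %d (%d up, %d down)\n", length(cand),
            sum(fc$logfc > 1), sum(fc$logfc < -1)))

expr_df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
write.table(expr_df, file.path(out, "normalized_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fc, file.path(out, "fold_changes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(cand, file.path(out, "candidate_genes.txt"))
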